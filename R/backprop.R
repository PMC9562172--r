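# Hand-derived backpropagation for the gene-wise scalar attention layer.
#
# Forward (per sample, per layer):
#   q = wq * x ; k = wk * x ; v = wv * x          (elementwise, per head)
#   L[g, i] = q_g k_i, L[g, g] = -Inf
#   A = row-softmax(L)                            (diag exactly 0)
#   z_h = A v
#   m = Z head_mix ; mhat = (m - mean) / sd ; out = gain*mhat + bias
#   z_out = x + out                               (skip connection)
# The input x feeds both the skip path and, through q/k/v, the attention
# path, so its gradient is the sum of the two.

# Backward through one layer. dz: gradient wrt z_out. Returns parameter
# gradients and dx (gradient wrt the layer input).
.layer_backward_sample <- function(dz, cc, lp) {
  H <- length(lp$head_mix)
  dgain <- dz * cc$mhat
  dbias <- dz
  dmhat <- dz * lp$ln_gain
  # layernorm backward (population mean/var over the G genes)
  dm <- (dmhat - mean(dmhat) - cc$mhat * mean(dmhat * cc$mhat)) / cc$sd
  dZ <- tcrossprod(dm, lp$head_mix)
  dhead_mix <- as.vector(crossprod(cc$Z, dm))
  dx <- dz # skip path
  G <- length(cc$x_in)
  dWq <- matrix(0, G, H); dWk <- matrix(0, G, H); dWv <- matrix(0, G, H)
  for (h in seq_len(H)) {
    hd <- cc$heads[[h]]
    dzh <- dZ[, h]
    A <- hd$A
    dv <- as.vector(crossprod(A, dzh))
    dA <- tcrossprod(dzh, hd$v)
    # masked softmax backward; rows of A have zero diagonal, so the
    # self-logit receives no gradient
    dL <- A * (dA - rowSums(A * dA))
    dq <- as.vector(dL %*% hd$k)
    dk <- as.vector(crossprod(dL, hd$q))
    dWq[, h] <- dq * cc$x_in
    dWk[, h] <- dk * cc$x_in
    dWv[, h] <- dv * cc$x_in
    dx <- dx + dq * lp$Wq[, h] + dk * lp$Wk[, h] + dv * lp$Wv[, h]
  }
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dhead_mix = dhead_mix,
       dln_gain = dgain, dln_bias = dbias)
}

# Backward from a gradient on the logits down to layer `down_to`.
# Returns per-layer parameter gradients, classifier gradients, and the
# gradient wrt the output of layer `down_to` (dz_boundary), which the IG
# machinery turns into gradients wrt that layer's attention weights.
.backward_sample <- function(model, fw, dlogits, down_to = 1L) {
  L <- length(model$layers)
  dphi <- as.vector(crossprod(model$classifier$W, dlogits))
  dW <- dlogits %o% fw$phi
  db <- dlogits
  dz <- dphi * .act_grad(fw$zL, model$classifier$activation)
  layer_grads <- vector("list", L)
  l <- L
  while (l >= down_to) {
    g <- .layer_backward_sample(dz, fw$caches[[l]], model$layers[[l]])
    layer_grads[[l]] <- g[c("dWq", "dWk", "dWv", "dhead_mix", "dln_gain", "dln_bias")]
    dz <- g$dx
    l <- l - 1L
  }
  list(layers = layer_grads, dW = dW, db = db, dz_boundary = dz)
}

# Gradient of the mean negative log-likelihood of one sample:
# dlogits = p - onehot(y).
.nll_grad_sample <- function(model, x, y_index) {
  fw <- .forward_sample(model, x)
  dlogits <- fw$probs
  dlogits[y_index] <- dlogits[y_index] - 1
  g <- .backward_sample(model, fw, dlogits)
  list(loss = -log(max(fw$probs[y_index], .Machine$double.xmin)), grads = g)
}

# --- flat parameter vector interface (for Adam and numerical checks) ---

.params_get <- function(model) {
  unlist(c(lapply(model$layers, function(lp)
    list(Wq = lp$Wq, Wk = lp$Wk, Wv = lp$Wv, head_mix = lp$head_mix,
         ln_gain = lp$ln_gain, ln_bias = lp$ln_bias)),
    list(W = model$classifier$W, b = model$classifier$b)), use.names = FALSE)
}

.params_set <- function(model, theta) {
  pos <- 0L
  take <- function(n) {
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  for (l in seq_along(model$layers)) {
    lp <- model$layers[[l]]
    G <- nrow(lp$Wq); H <- ncol(lp$Wq)
    lp$Wq <- matrix(take(G * H), G, H)
    lp$Wk <- matrix(take(G * H), G, H)
    lp$Wv <- matrix(take(G * H), G, H)
    lp$head_mix <- take(H)
    lp$ln_gain <- take(G)
    lp$ln_bias <- take(G)
    model$layers[[l]] <- lp
  }
  C <- nrow(model$classifier$W); G <- ncol(model$classifier$W)
  model$classifier$W <- matrix(take(C * G), C, G)
  model$classifier$b <- take(C)
  stopifnot(pos == length(theta))
  model
}

.grads_flatten <- function(model, grads) {
  unlist(c(lapply(grads$layers, function(g)
    list(g$dWq, g$dWk, g$dWv, g$dhead_mix, g$dln_gain, g$dln_bias)),
    list(grads$dW, grads$db)), use.names = FALSE)
}
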