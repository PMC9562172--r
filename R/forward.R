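#' Scalar Query/Key/Value projections for one head
#'
#' Each gene g has its own scalar weights, so the projections are plain
#' elementwise products: `q = wq * x`, `k = wk * x`, `v = wv * x`.
#'
#' @param x numeric vector of length G (normalized log expression).
#' @param head a list with numeric vectors `wq`, `wk`, `wv` of length G.
#' @return list with components `q`, `k`, `v`, each of length G.
#' @export
compute_qkv <- function(x, head) {
  G <- length(x)
  if (!all(is.finite(x))) stop("expression vector contains non-finite values")
  if (length(head$wq) != G || length(head$wk) != G || length(head$wv) != G)
    stop(sprintf("dimension error: head weights have length %d/%d/%d but x has length %d",
                 length(head$wq), length(head$wk), length(head$wv), G))
  list(q = head$wq * x, k = head$wk * x, v = head$wv * x)
}

#' Attention distribution of one Query gene over its Key genes
#'
#' Computes `a_gi = softmax(q_g * k_i)` over all Key genes `i != g`, with
#' max-subtraction stabilization. The self-entry is excluded, so the
#' result has length `G - 1` and sums to 1.
#'
#' @param q numeric Query vector of length G.
#' @param k numeric Key vector of length G.
#' @param g index of the Query gene (1-based).
#' @return probability vector of length `G - 1`, named by the Key gene
#'   indices it covers.
#' @examples
#' attention_weights(q = c(1, 1, 1), k = c(0, log(3), 0), g = 1)
#' @export
attention_weights <- function(q, k, g) {
  G <- length(q)
  if (length(k) != G) stop("dimension error: q and k differ in length")
  if (G < 2L) stop("degenerate input: attention needs at least 2 genes (no Key genes)")
  if (g < 1L || g > G) stop("query index out of range")
  logits <- q[g] * k[-g]
  e <- exp(logits - max(logits))
  a <- e / sum(e)
  names(a) <- seq_len(G)[-g]
  a
}

#' Head representation of one Query gene
#'
#' The head output for Query gene g is the attention-weighted sum of the
#' Values of all other genes: `z_g = sum_i a_gi * v_i` over `i != g`.
#'
#' @param a_g attention probability vector over the Key genes (sums to 1).
#' @param v_minus_g Value vector over the same Key genes.
#' @return scalar `z_g`.
#' @export
head_representation <- function(a_g, v_minus_g) {
  if (length(a_g) != length(v_minus_g))
    stop("dimension error: attention and value vectors differ in length")
  if (abs(sum(a_g) - 1) > 1e-6)
    stop("attention weights must sum to 1")
  sum(a_g * v_minus_g)
}

# Full G x G attention matrix for one head and sample.
# Row g holds the distribution of Query gene g over Key genes; the
# diagonal (self) entry is masked to -Inf before the stabilized softmax,
# hence exactly 0 in the result.
.attention_matrix <- function(q, k) {
  G <- length(q)
  logits <- tcrossprod(q, k)
  diag(logits) <- -Inf
  mi <- max.col(logits, ties.method = "first")
  mx <- logits[cbind(seq_len(G), mi)]
  e <- exp(logits - mx)
  e / rowSums(e)
}

# Forward pass of one layer for a single sample, returning the full
# cache needed by backpropagation and by the interpretation methods.
.layer_forward_sample <- function(x, lp, eps = 1e-5) {
  G <- length(x)
  H <- ncol(lp$Wq)
  heads <- vector("list", H)
  Z <- matrix(0, G, H)
  for (h in seq_len(H)) {
    q <- lp$Wq[, h] * x
    k <- lp$Wk[, h] * x
    v <- lp$Wv[, h] * x
    A <- .attention_matrix(q, k)
    heads[[h]] <- list(q = q, k = k, v = v, A = A)
    Z[, h] <- as.vector(A %*% v)
  }
  m <- as.vector(Z %*% lp$head_mix)
  mu <- mean(m)
  sd_ <- sqrt(mean((m - mu)^2) + eps)
  mhat <- (m - mu) / sd_
  list(x_in = x, heads = heads, Z = Z, m = m, sd = sd_, mhat = mhat,
       z_out = x + lp$ln_gain * mhat + lp$ln_bias)
}

#' Forward computation of one attention layer
#'
#' Runs every head of a layer on an input vector, mixes the head outputs
#' with the head-mixing weights, applies layer normalization over the
#' gene dimension and adds the skip connection:
#' `z = x + layernorm(head_mix' Z)`.
#'
#' @param x_in numeric input vector of length G.
#' @param layer one element of `model$layers` (`Wq`/`Wk`/`Wv` `G x H`
#'   matrices, `head_mix`, `ln_gain`, `ln_bias`).
#' @param eps layer normalization epsilon.
#' @return list with `z_out` (length G) and `attention`, a list of H
#'   `G x G` row-stochastic matrices with zero diagonal.
#' @export
layer_forward <- function(x_in, layer, eps = 1e-5) {
  if (!all(is.finite(x_in))) stop("layer input contains non-finite values")
  if (length(x_in) != nrow(layer$Wq))
    stop("dimension error: input length does not match layer weights")
  cc <- .layer_forward_sample(x_in, layer, eps = eps)
  list(z_out = cc$z_out, attention = lapply(cc$heads, `[[`, "A"))
}

.act <- function(x, type) {
  switch(type,
         none = x,
         relu = pmax(x, 0),
         gelu = x * stats::pnorm(x),
         stop("unknown activation: ", type))
}

.act_grad <- function(x, type) {
  switch(type,
         none = rep(1, length(x)),
         relu = as.numeric(x > 0),
         gelu = stats::pnorm(x) + x * stats::dnorm(x),
         stop("unknown activation: ", type))
}

.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Per-sample forward pass with full caches (used by training, IG and the
# probe/pruning diagnostics).
.forward_sample <- function(model, x) {
  caches <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    caches[[l]] <- .layer_forward_sample(x, model$layers[[l]], eps = model$ln_eps)
    x <- caches[[l]]$z_out
  }
  phi <- .act(x, model$classifier$activation)
  logits <- as.vector(model$classifier$W %*% phi) + model$classifier$b
  list(probs = .softmax(logits), logits = logits, zL = x, phi = phi,
       caches = caches)
}

#' Forward pass of a T-GEM model
#'
#' Chains the attention layers and the classification layer for one or
#' more samples and returns class probabilities (and, optionally, the
#' full attention tensor for interpretation).
#'
#' @param model a `tgem_model`.
#' @param x numeric matrix `N x G` (or a single length-G vector) of
#'   normalized expression; if it has column (or element) names they are
#'   checked against the model's gene order.
#' @param attention if `TRUE`, also return per-layer, per-head, per-sample
#'   `G x G` attention matrices (memory grows as `L*H*N*G^2`; intended
#'   for modest N).
#' @return list with `probs` (`N x C` matrix, rows sum to 1), `logits`
#'   (`N x C`) and, when requested, `attention[[l]][[h]][[n]]` matrices.
#' @export
tgem_forward <- function(model, x, attention = FALSE) {
  d <- .check_model(model)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != d$G)
    stop(sprintf("dimension error: %d genes in input, model has %d", ncol(x), d$G))
  if (!is.null(colnames(x))) .check_gene_alignment(model, colnames(x))
  N <- nrow(x)
  probs <- matrix(0, N, d$C, dimnames = list(rownames(x), model$class_names))
  logits <- probs
  att <- if (attention)
    lapply(seq_len(d$L), function(l) lapply(seq_len(d$H), function(h) vector("list", N)))
  else NULL
  for (n in seq_len(N)) {
    fw <- .forward_sample(model, as.numeric(x[n, ]))
    probs[n, ] <- fw$probs
    logits[n, ] <- fw$logits
    if (attention) {
      for (l in seq_len(d$L)) for (h in seq_len(d$H))
        att[[l]][[h]][[n]] <- fw$caches[[l]]$heads[[h]]$A
    }
  }
  out <- list(probs = probs, logits = logits)
  if (attention) out$attention <- att
  out
}

#' Predict class labels
#'
#' @param object a `tgem_model`.
#' @param x `N x G` expression matrix (already preprocessed).
#' @param type `"class"` for hard labels (0-based integer indices into
#'   `class_names`), `"prob"` for the probability matrix.
#' @param ... unused.
#' @return integer vector or probability matrix.
#' @export
predict.tgem_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- tgem_forward(object, x)$probs
  if (type == "prob") return(p)
  max.col(p, ties.method = "first") - 1L
}
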