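#' Shannon entropy of an attention distribution
#'
#' `H(a) = -sum_i a_i ln(a_i)` in nats, with `0 * ln 0 := 0`. For a
#' Query gene attending uniformly over `G - 1` Key genes this equals
#' `ln(G - 1)`; a point mass has entropy 0.
#'
#' @param a_g non-negative probability vector summing to 1 (within
#'   1e-6). Zero entries (e.g. the masked self-entry) are allowed.
#' @return entropy in nats.
#' @export
attention_entropy <- function(a_g) {
  if (any(a_g < 0)) stop("attention weights must be non-negative")
  if (abs(sum(a_g) - 1) > 1e-6) stop("attention weights must sum to 1")
  nz <- a_g > 0
  -sum(a_g[nz] * log(a_g[nz]))
}

#' Attention-entropy profile of a model
#'
#' Runs the forward pass on every sample, computes the entropy of each
#' Query gene's attention distribution in every layer and head, and
#' averages across samples. Low entropy marks Query genes with focused
#' attention on few Key genes; the maximum `ln(G - 1)` marks uniform
#' (broad) attention.
#'
#' @param model a `tgem_model`.
#' @param x `N x G` matrix of preprocessed expression.
#' @return numeric array with dimensions (layer, head, gene) holding the
#'   mean entropy in nats, with dimnames; class `tgem_entropy_profile`.
#' @export
entropy_profile <- function(model, x) {
  d <- .check_model(model)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  N <- nrow(x)
  if (N < 1L) stop("at least one sample is required")
  acc <- array(0, dim = c(d$L, d$H, d$G),
               dimnames = list(layer = seq_len(d$L), head = seq_len(d$H),
                               gene = model$gene_names))
  for (n in seq_len(N)) {
    fw <- .forward_sample(model, as.numeric(x[n, ]))
    for (l in seq_len(d$L)) for (h in seq_len(d$H)) {
      A <- fw$caches[[l]]$heads[[h]]$A
      P <- A
      P[P == 0] <- 1 # 0 * log 0 := 0
      acc[l, h, ] <- acc[l, h, ] - rowSums(A * log(P))
    }
  }
  structure(acc / N, class = c("tgem_entropy_profile", "array"))
}

#' Export an entropy profile as a long-format data frame
#'
#' @param profile a `tgem_entropy_profile`.
#' @return data.frame with columns layer, head, query_gene, entropy.
#' @export
entropy_profile_table <- function(profile) {
  d <- dim(profile)
  df <- expand.grid(layer = seq_len(d[1]), head = seq_len(d[2]),
                    query_gene = dimnames(profile)$gene,
                    stringsAsFactors = FALSE)
  df$entropy <- as.vector(profile)
  df
}

# Integrated-gradients machinery ---------------------------------------

# Gradient of the target-class logit with respect to the attention
# weights of one layer, evaluated with those weights scaled by `alpha`
# (the straight-line path from the zero baseline). The Values and the
# layer input are held at their actual forward values; downstream layers
# are recomputed from the perturbed layer output.
.ig_grad_at <- function(model, fw0, layer, target, alpha) {
  L <- length(model$layers)
  lp <- model$layers[[layer]]
  cc0 <- fw0$caches[[layer]]
  H <- length(lp$head_mix)
  G <- length(cc0$x_in)
  Z <- matrix(0, G, H)
  for (h in seq_len(H))
    Z[, h] <- as.vector((alpha * cc0$heads[[h]]$A) %*% cc0$heads[[h]]$v)
  m <- as.vector(Z %*% lp$head_mix)
  mu <- mean(m)
  sd_ <- sqrt(mean((m - mu)^2) + model$ln_eps)
  mhat <- (m - mu) / sd_
  z <- cc0$x_in + lp$ln_gain * mhat + lp$ln_bias
  caches <- vector("list", L)
  if (layer < L) {
    for (l in (layer + 1L):L) {
      caches[[l]] <- .layer_forward_sample(z, model$layers[[l]], eps = model$ln_eps)
      z <- caches[[l]]$z_out
    }
  }
  phi <- .act(z, model$classifier$activation)
  logits <- as.vector(model$classifier$W %*% phi) + model$classifier$b
  # backward for d logit[target] / d A
  dlogits <- numeric(length(logits))
  dlogits[target] <- 1
  dphi <- as.vector(crossprod(model$classifier$W, dlogits))
  dz <- dphi * .act_grad(z, model$classifier$activation)
  if (layer < L) {
    for (l in L:(layer + 1L)) {
      g <- .layer_backward_sample(dz, caches[[l]], model$layers[[l]])
      dz <- g$dx
    }
  }
  dmhat <- dz * lp$ln_gain
  dm <- (dmhat - mean(dmhat) - mhat * mean(dmhat * mhat)) / sd_
  dA <- vector("list", H)
  for (h in seq_len(H))
    dA[[h]] <- (dm * lp$head_mix[h]) %o% cc0$heads[[h]]$v
  list(F = logits[target], dA = dA)
}

#' Integrated-gradients attribution of attention weights
#'
#' Attributes the target-class logit to the attention weights of one
#' layer by integrated gradients along the straight line from a zero
#' baseline to the actual attention weights:
#' `IG(a_gi) = a_gi * integral_0^1 dF(alpha * a) / da_gi d alpha`,
#' approximated by a Riemann sum. The scaling is applied to the
#' post-softmax attention probabilities (the attributed quantity),
#' leaving the Values, the layer input and all parameters fixed;
#' downstream layers are recomputed. Scores of the same Query-Key pair
#' are averaged over heads and then over samples.
#'
#' @param model a `tgem_model`.
#' @param x `N x G` matrix of preprocessed samples, all carrying the
#'   target class label.
#' @param target_class 0-based class index (or class name) whose logit
#'   is attributed.
#' @param layer layer whose attention weights are attributed (defaults
#'   to the last layer).
#' @param n_steps number of Riemann steps (>= 2; default 50).
#' @param rule quadrature rule for the path integral. The default
#'   `"midpoint"` is a midpoint Riemann sum on a square-root-stretched
#'   grid (`alpha = u^2` with `u` at uniform midpoints): its weights sum
#'   exactly to 1, so attributions of a linear logit are exact at any
#'   step count, and the stretching resolves the sharp layer-norm
#'   gradient near the zero-attention baseline (where the normalization
#'   variance falls below its epsilon), which a uniform grid
#'   underresolves. `"left"` and `"trapezoid"` are the uniform-grid
#'   variants.
#' @return object of class `tgem_attribution`: list with `scores`
#'   (`G x G` matrix, rows = Query gene, columns = Key gene, zero
#'   diagonal), `layer`, `class_label`, `n_steps`, `baseline` (0) and
#'   `completeness` (mean over samples of `sum(IG)` summed over heads
#'   and of `F(a) - F(0)`).
#' @export
ig_attribution <- function(model, x, target_class, layer = NULL,
                           n_steps = 50L,
                           rule = c("midpoint", "left", "trapezoid")) {
  rule <- match.arg(rule)
  d <- .check_model(model)
  if (is.null(layer)) layer <- d$L
  if (layer < 1L || layer > d$L) stop("layer index out of range")
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (is.character(target_class)) {
    target <- match(target_class, model$class_names)
    if (is.na(target)) stop("unknown class: ", target_class)
  } else {
    target <- as.integer(target_class) + 1L
    if (target < 1L || target > d$C) stop("target class index out of range")
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  N <- nrow(x)
  if (N < 1L) stop("at least one sample of the target class is required")

  if (rule == "midpoint") {
    u <- (seq_len(n_steps) - 0.5) / n_steps
    alphas <- u^2
    wts <- 2 * u / n_steps # sum to exactly 1
  } else if (rule == "left") {
    alphas <- (seq_len(n_steps) - 1L) / n_steps
    wts <- rep(1 / n_steps, n_steps)
  } else {
    alphas <- (0:n_steps) / n_steps
    wts <- c(1, rep(2, n_steps - 1L), 1) / (2 * n_steps)
  }

  total <- matrix(0, d$G, d$G)
  sum_ig <- 0
  delta_F <- 0
  for (n in seq_len(N)) {
    fw0 <- .forward_sample(model, as.numeric(x[n, ]))
    acc <- lapply(seq_len(d$H), function(h) matrix(0, d$G, d$G))
    F0 <- NULL; F1 <- NULL
    for (t in seq_along(alphas)) {
      gr <- .ig_grad_at(model, fw0, layer, target, alphas[t])
      if (any(!vapply(gr$dA, function(M) all(is.finite(M)), logical(1))))
        stop(sprintf("non-finite attention gradient at sample %d, alpha = %.3f", n, alphas[t]))
      for (h in seq_len(d$H)) acc[[h]] <- acc[[h]] + wts[t] * gr$dA[[h]]
      if (alphas[t] == 0) F0 <- gr$F
      if (alphas[t] == 1) F1 <- gr$F
    }
    if (is.null(F0)) F0 <- .ig_grad_at(model, fw0, layer, target, 0)$F
    if (is.null(F1)) F1 <- .ig_grad_at(model, fw0, layer, target, 1)$F
    per_head_sum <- 0
    mean_heads <- matrix(0, d$G, d$G)
    for (h in seq_len(d$H)) {
      igh <- fw0$caches[[layer]]$heads[[h]]$A * acc[[h]]
      per_head_sum <- per_head_sum + sum(igh)
      mean_heads <- mean_heads + igh / d$H
    }
    total <- total + mean_heads
    sum_ig <- sum_ig + per_head_sum
    delta_F <- delta_F + (F1 - F0)
  }
  scores <- total / N
  dimnames(scores) <- list(query = model$gene_names, key = model$gene_names)
  structure(list(scores = scores, layer = layer,
                 class_label = model$class_names[target],
                 n_steps = as.integer(n_steps), rule = rule, baseline = 0,
                 n_samples = N,
                 completeness = list(sum_ig = sum_ig / N,
                                     delta_F = delta_F / N)),
            class = "tgem_attribution")
}

#' @exportS3Method base::print
print.tgem_attribution <- function(x, ...) {
  cat(sprintf(
    "attention attribution: layer %d, class '%s', %d sample(s), %d IG steps (%s rule)\n",
    x$layer, x$class_label, x$n_samples, x$n_steps, x$rule))
  cat(sprintf("  completeness: sum IG = %.4g vs F(a) - F(0) = %.4g\n",
              x$completeness$sum_ig, x$completeness$delta_F))
  invisible(x)
}

#' Export an attribution matrix as a long-format data frame
#'
#' @param attrib a `tgem_attribution`.
#' @param drop_zero drop zero entries (including the diagonal).
#' @return data.frame with columns layer, query_gene, key_gene, score.
#' @export
attribution_table <- function(attrib, drop_zero = TRUE) {
  S <- attrib$scores
  df <- expand.grid(query_gene = rownames(S), key_gene = colnames(S),
                    stringsAsFactors = FALSE)
  df$layer <- attrib$layer
  df$score <- as.vector(S)
  if (drop_zero) df <- df[df$score != 0, ]
  df[, c("layer", "query_gene", "key_gene", "score")]
}

# Pruning --------------------------------------------------------------

#' Prune one attention head
#'
#' Returns a copy of the model with the head's entry of the head-mixing
#' vector set to 0 while keeping the remaining entries; the original
#' model is untouched.
#'
#' @param model a `tgem_model`.
#' @param layer layer index.
#' @param head head index within the layer.
#' @return the pruned model copy.
#' @export
prune_head <- function(model, layer, head) {
  d <- .check_model(model)
  if (layer < 1L || layer > d$L) stop("layer index out of range")
  if (head < 1L || head > d$H) stop("head index out of range")
  model$layers[[layer]]$head_mix[head] <- 0
  model
}

#' Prune a whole attention layer
#'
#' Zeroes the head-mixing weights of every head in the layer. With zero
#' layer-norm bias the pruned layer reduces to the identity (the skip
#' connection alone).
#'
#' @param model a `tgem_model`.
#' @param layer layer index.
#' @return the pruned model copy.
#' @export
prune_layer <- function(model, layer) {
  d <- .check_model(model)
  if (layer < 1L || layer > d$L) stop("layer index out of range")
  model$layers[[layer]]$head_mix[] <- 0
  model
}

#' Pruning scan over all layers and heads
#'
#' Measures test accuracy after pruning each layer and each individual
#' head, one target at a time. The larger the accuracy drop, the more
#' important the pruned component.
#'
#' @param model a `tgem_model`.
#' @param x `N x G` preprocessed test matrix.
#' @param y integer labels in `[0, C)`.
#' @return data.frame with columns `target` ("none", "layer" or
#'   "head"), `layer`, `head`, `accuracy_after`, `accuracy_drop`; the
#'   first row is the unpruned reference.
#' @export
prune_scan <- function(model, x, y) {
  d <- .check_model(model)
  if (nrow(x) < 1L) stop("test set must be non-empty")
  acc_of <- function(m) mean(predict(m, x) == y)
  ref <- acc_of(model)
  rows <- list(data.frame(target = "none", layer = NA_integer_,
                          head = NA_integer_, accuracy_after = ref,
                          accuracy_drop = 0))
  for (l in seq_len(d$L)) {
    a <- acc_of(prune_layer(model, l))
    rows[[length(rows) + 1L]] <- data.frame(target = "layer", layer = l,
                                            head = NA_integer_,
                                            accuracy_after = a,
                                            accuracy_drop = ref - a)
    for (h in seq_len(d$H)) {
      a <- acc_of(prune_head(model, l, h))
      rows[[length(rows) + 1L]] <- data.frame(target = "head", layer = l,
                                              head = h, accuracy_after = a,
                                              accuracy_drop = ref - a)
    }
  }
  do.call(rbind, rows)
}

#' Reshape a pruning scan into a wide table
#'
#' One row per layer with columns LAYER (whole-layer pruning accuracy)
#' and HEAD 1..H (per-head pruning accuracies).
#'
#' @param scan output of [prune_scan()].
#' @return data.frame, with the unpruned reference accuracy as attribute
#'   `"reference"`.
#' @export
prune_scan_table <- function(scan) {
  ref <- scan$accuracy_after[scan$target == "none"]
  layers <- sort(unique(scan$layer[scan$target == "layer"]))
  heads <- sort(unique(scan$head[scan$target == "head"]))
  out <- data.frame(layer = layers)
  out$LAYER <- vapply(layers, function(l)
    scan$accuracy_after[scan$target == "layer" & scan$layer == l], numeric(1))
  for (h in heads) {
    out[[paste0("HEAD", h)]] <- vapply(layers, function(l)
      scan$accuracy_after[scan$target == "head" & scan$layer == l &
                            scan$head == h], numeric(1))
  }
  attr(out, "reference") <- ref
  out
}

# Probe classifiers ----------------------------------------------------

# Extract per-sample representations: the raw input, a layer's output
# (after the skip connection), or a single head's output taken before
# head mixing / layer norm / skip.
.representations <- function(model, x, what, layer = NULL, head = NULL) {
  if (what == "input") return(as.matrix(x))
  d <- .check_model(model)
  if (is.null(layer) || layer < 1L || layer > d$L) stop("layer index out of range")
  if (what == "head" && (is.null(head) || head < 1L || head > d$H))
    stop("head index out of range")
  N <- nrow(x)
  R <- matrix(0, N, d$G)
  for (n in seq_len(N)) {
    fw <- .forward_sample(model, as.numeric(x[n, ]))
    R[n, ] <- if (what == "head") fw$caches[[layer]]$Z[, head]
              else fw$caches[[layer]]$z_out
  }
  R
}

#' Probe classifier on intermediate representations
#'
#' Trains a linear-kernel support vector machine (one-vs-rest for
#' multi-class, cost 1) on a layer's or head's representations of the
#' training samples and reports accuracy on the test samples. Head
#' outputs are taken before the skip connection (before head mixing and
#' layer normalization); layer outputs are taken after the skip. The
#' higher the probe accuracy, the more class information the component
#' carries.
#'
#' @param model a `tgem_model`.
#' @param x_train,y_train,x_test,y_test preprocessed matrices and
#'   integer labels.
#' @param what `"input"`, `"layer"` or `"head"`.
#' @param layer,head indices selecting the probed component.
#' @return test accuracy in `[0, 1]`.
#' @export
probe_classifier <- function(model, x_train, y_train, x_test, y_test,
                             what = c("layer", "head", "input"),
                             layer = NULL, head = NULL) {
  what <- match.arg(what)
  if (length(unique(y_train)) < 2L)
    stop("degenerate training set: probe needs at least 2 classes")
  Rtr <- .representations(model, x_train, what, layer, head)
  Rte <- .representations(model, x_test, what, layer, head)
  fit <- e1071::svm(x = Rtr, y = factor(y_train), kernel = "linear",
                    cost = 1, scale = FALSE, type = "C-classification")
  pred <- stats::predict(fit, Rte)
  mean(as.character(pred) == as.character(y_test))
}
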