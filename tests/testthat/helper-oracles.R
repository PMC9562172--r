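# Independent reference implementations used as oracles. These are
# deliberately written as explicit loops / first-principles formulas,
# sharing no code path with the package internals they check.

# Triple-loop forward pass: loops over layers, heads, query genes and
# key genes with scalar arithmetic only.
oracle_forward <- function(model, x) {
  eps <- model$ln_eps
  for (lp in model$layers) {
    G <- length(x)
    H <- length(lp$head_mix)
    Z <- matrix(0, G, H)
    for (h in seq_len(H)) {
      for (g in seq_len(G)) {
        logits <- numeric(0)
        vs <- numeric(0)
        for (i in seq_len(G)) {
          if (i != g) {
            logits <- c(logits, (lp$Wq[g, h] * x[g]) * (lp$Wk[i, h] * x[i]))
            vs <- c(vs, lp$Wv[i, h] * x[i])
          }
        }
        e <- exp(logits - max(logits))
        a <- e / sum(e)
        Z[g, h] <- sum(a * vs)
      }
    }
    m <- numeric(G)
    for (g in seq_len(G)) m[g] <- sum(lp$head_mix * Z[g, ])
    mu <- mean(m)
    s <- sqrt(mean((m - mu)^2) + eps)
    x <- x + lp$ln_gain * (m - mu) / s + lp$ln_bias
  }
  act <- model$classifier$activation
  phi <- vapply(x, function(t)
    switch(act, none = t, relu = max(t, 0), gelu = t * pnorm(t)), numeric(1))
  logits <- as.numeric(model$classifier$W %*% phi) + model$classifier$b
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Small model with fully randomized parameters (including head_mix,
# layer-norm gain/bias and classifier).
random_small_model <- function(G, H, L, C = 3L, seed = 1L,
                               activation = NULL) {
  if (is.null(activation)) {
    set.seed(seed)
    activation <- sample(c("none", "relu", "gelu"), 1)
  }
  m <- tgem_model(sprintf("g%02d", seq_len(G)), paste0("c", seq_len(C)),
                  n_layers = L, n_heads = H, activation = activation,
                  seed = seed)
  set.seed(seed + 10000L)
  theta <- tgem:::.params_get(m)
  tgem:::.params_set(m, rnorm(length(theta), 0, 0.8))
}

# Apply one permutation to the gene axis of a model's per-gene
# parameters (and return the permuted model).
permute_model_genes <- function(model, perm) {
  for (l in seq_along(model$layers)) {
    lp <- model$layers[[l]]
    lp$Wq <- lp$Wq[perm, , drop = FALSE]
    lp$Wk <- lp$Wk[perm, , drop = FALSE]
    lp$Wv <- lp$Wv[perm, , drop = FALSE]
    lp$ln_gain <- lp$ln_gain[perm]
    lp$ln_bias <- lp$ln_bias[perm]
    model$layers[[l]] <- lp
  }
  model$classifier$W <- model$classifier$W[, perm, drop = FALSE]
  model$gene_names <- model$gene_names[perm]
  model
}

# Mann-Whitney pair-counting AUC for a binary problem.
pair_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Exhaustive-enumeration hypergeometric upper tail: over all
# choose(N, n) draws of the informative set, the fraction with overlap
# >= m against a fixed K-subset.
hyper_p_enum <- function(N, K, n, m) {
  draws <- utils::combn(N, n)
  inset <- seq_len(K)
  hits <- 0
  for (j in seq_len(ncol(draws))) {
    if (sum(draws[, j] %in% inset) >= m) hits <- hits + 1
  }
  hits / ncol(draws)
}

# A model in which the class logits are (numerically) linear in the
# attention weights: single layer, tiny Value weights so the layer-norm
# variance is dominated by its epsilon and the normalization acts as a
# fixed linear map.
near_linear_model <- function(G = 5L, C = 2L, seed = 4L) {
  m <- tgem_model(sprintf("g%02d", seq_len(G)), paste0("c", seq_len(C)),
                  n_layers = 1L, n_heads = 1L, activation = "none",
                  seed = seed)
  set.seed(seed + 1L)
  m$layers[[1]]$Wv <- matrix(runif(G, 0.5, 1) * 1e-6, G, 1)
  m$layers[[1]]$head_mix <- 1
  m
}

# Shared small synthetic fixture for training-dependent tests (built
# once per test run).
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_expression(
        n_classes = 3L, n_genes = 30L, n_samples_per_class = 40L,
        n_markers_per_class = 5L, marker_effect = 3, modules = list(),
        seed = 11L)
    }
    cache
  }
})
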