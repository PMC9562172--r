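# A hand-built two-class problem whose class signal is only readable
# through the attention path. Gene 1 is shifted by `delta` in class 1;
# head 1 (uniform attention, Values on genes 1-2) relays that shift
# into the layer-normalized mixed output at gene 2's position, while
# gene 2's own expression is identical across classes. The classifier
# reads gene 2 only (a nearest-centroid readout in logit form), so
# pruning head 1 (whose head_mix entry carries all the weight) severs
# the only informative path; head 2's head_mix entry is already 0.
make_interaction_fixture <- function(n_per_class = 60, delta = 0.5,
                                     noise = 0.05, seed = 42) {
  set.seed(seed)
  G <- 4L
  m <- tgem_model(paste0("g", 1:G), c("c0", "c1"), n_layers = 1, n_heads = 2,
                  activation = "none", seed = seed)
  lp <- m$layers[[1]]
  lp$Wq[] <- 0 # uniform attention in both heads
  lp$Wk[] <- 0
  lp$Wv[, 1] <- c(1, 1, 0, 0)
  lp$Wv[, 2] <- runif(G)
  lp$head_mix <- c(1, 0)
  lp$ln_gain <- rep(1, G)
  lp$ln_bias <- rep(0, G)
  m$layers[[1]] <- lp

  X <- matrix(1, 2 * n_per_class, G) +
    matrix(rnorm(2 * n_per_class * G, 0, noise), 2 * n_per_class, G)
  y <- rep(0:1, each = n_per_class)
  X[y == 1, 1] <- X[y == 1, 1] + delta

  # nearest-centroid readout on gene 2's layer output
  r2 <- vapply(seq_len(nrow(X)), function(n)
    tgem:::.forward_sample(m, as.numeric(X[n, ]))$caches[[1]]$z_out[2],
    numeric(1))
  mu <- c(mean(r2[y == 0]), mean(r2[y == 1]))
  lam <- 50
  W <- matrix(0, 2, G)
  W[, 2] <- lam * mu
  m$classifier$W <- W
  m$classifier$b <- -lam * mu^2 / 2
  list(model = m, X = X, y = y)
}
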