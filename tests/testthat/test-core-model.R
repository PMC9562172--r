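test_that("scalar Q/K/V projections are elementwise products", {
  head <- list(wq = c(2, 3, 4), wk = c(1, 1, 1), wv = c(0.5, 0.5, 0.5))
  expect_equal(compute_qkv(c(0, 0, 0), head)$q, c(0, 0, 0))
  expect_equal(compute_qkv(c(1, 1, 1), head)$q, c(2, 3, 4))
  r <- compute_qkv(c(0.5, 2, 1), list(wq = c(2, 1, 3), wk = 1:3, wv = 1:3))
  expect_equal(r$q, c(1, 2, 3))
  expect_equal(r$k, c(0.5, 4, 3))
  expect_error(compute_qkv(c(1, 2), head), "dimension")
})

test_that("attention over Key genes is a stabilized masked softmax", {
  # identical logits -> uniform over the G-1 keys
  expect_equal(unname(attention_weights(q = rep(1, 4), k = rep(2, 4), g = 2)),
               rep(1 / 3, 3))
  # zero logits
  expect_equal(unname(attention_weights(q = c(1, 0, 0), k = c(5, 0, 0), g = 1)),
               c(0.5, 0.5))
  # direct softmax evaluation: e^{ln 3} / (e^{ln 3} + 1) = 0.75
  a <- attention_weights(q = c(1, 0, 0), k = c(0, log(3), 0), g = 1)
  expect_equal(unname(a), c(0.75, 0.25))
  # huge logits do not overflow thanks to max-subtraction
  a2 <- attention_weights(q = c(1000, 0, 0), k = c(0, 2, 1), g = 1)
  expect_true(all(is.finite(a2)) && abs(sum(a2) - 1) < 1e-12)
  expect_error(attention_weights(1, 1, 1), "degenerate")
})

test_that("head representation is the attention-weighted Value sum", {
  expect_equal(head_representation(c(0.5, 0.5), c(2, 4)), 3)
  expect_equal(head_representation(c(0.3, 0.7), c(0, 0)), 0)
  expect_equal(head_representation(c(0.75, 0.25), c(1, -1)), 0.5)
  expect_error(head_representation(c(0.5, 0.5), c(1, 2, 3)), "dimension")
})

test_that("zeroed head mixing turns a layer into the identity (skip path)", {
  m <- random_small_model(G = 5, H = 2, L = 1, seed = 2)
  lp <- m$layers[[1]]
  lp$head_mix <- c(0, 0)
  lp$ln_gain <- rep(1, 5)
  lp$ln_bias <- rep(0, 5)
  x <- runif(5)
  out <- layer_forward(x, lp)
  expect_equal(out$z_out, x)
  expect_length(out$attention, 2)
  expect_equal(unname(rowSums(out$attention[[1]])), rep(1, 5))
})

test_that("vectorized forward matches the triple-loop oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    G <- sample(3:8, 1); H <- sample(1:3, 1); L <- sample(1:3, 1)
    m <- random_small_model(G, H, L, C = sample(2:4, 1), seed = seed)
    x <- runif(G)
    got <- as.numeric(tgem_forward(m, matrix(x, 1))$probs)
    want <- oracle_forward(m, x)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("attention rows are stochastic with zero self-weight", {
  m <- random_small_model(G = 7, H = 3, L = 2, seed = 5)
  fw <- tgem_forward(m, matrix(runif(7), 1), attention = TRUE)
  for (l in 1:2) for (h in 1:3) {
    A <- fw$attention[[l]][[h]][[1]]
    expect_equal(unname(diag(A)), rep(0, 7))
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
    expect_true(all(A >= 0 & A <= 1))
  }
})

test_that("class probabilities respect degenerate classifiers", {
  m <- random_small_model(G = 6, H = 2, L = 1, C = 4, seed = 3)
  m$classifier$W[] <- 0
  m$classifier$b[] <- 0
  p <- tgem_forward(m, matrix(runif(6), 1))$probs
  expect_equal(as.numeric(p), rep(0.25, 4))
})

test_that("a head-silenced one-layer model reduces to a linear classifier", {
  m <- random_small_model(G = 5, H = 2, L = 1, C = 3, seed = 9,
                          activation = "none")
  m$layers[[1]]$head_mix <- c(0, 0)
  m$layers[[1]]$ln_gain <- rep(1, 5)
  m$layers[[1]]$ln_bias <- rep(0, 5)
  m$classifier$b[] <- 0
  x <- runif(5)
  want <- exp(as.numeric(m$classifier$W %*% x))
  want <- want / sum(want)
  expect_equal(as.numeric(tgem_forward(m, matrix(x, 1))$probs), want,
               tolerance = 1e-12)
})

test_that("gene permutation of inputs and parameters leaves probabilities unchanged", {
  for (seed in 1:6) {
    set.seed(seed + 200)
    G <- sample(4:8, 1)
    m <- random_small_model(G, H = 2, L = 2, seed = seed)
    x <- runif(G)
    perm <- sample(G)
    p1 <- as.numeric(tgem_forward(m, matrix(x, 1))$probs)
    p2 <- as.numeric(tgem_forward(permute_model_genes(m, perm),
                                  matrix(x[perm], 1))$probs)
    expect_lt(max(abs(p1 - p2)), 1e-6)
  }
})

test_that("batched forward equals per-sample forward", {
  m <- random_small_model(G = 6, H = 2, L = 2, seed = 8)
  X <- matrix(runif(30), 5, 6)
  batched <- tgem_forward(m, X)$probs
  for (n in 1:5) {
    single <- tgem_forward(m, X[n, ])$probs
    expect_equal(as.numeric(batched[n, ]), as.numeric(single))
  }
})

test_that("parameter count matches the closed-form census", {
  m <- tgem_model(paste0("g", 1:10), c("a", "b"), n_layers = 1, n_heads = 1)
  expect_identical(parameter_count(m), 73L)
  # doubling H adds exactly L*(3G + 1) parameters
  m2 <- tgem_model(paste0("g", 1:10), c("a", "b"), n_layers = 2, n_heads = 2)
  m1 <- tgem_model(paste0("g", 1:10), c("a", "b"), n_layers = 2, n_heads = 1)
  expect_identical(parameter_count(m2) - parameter_count(m1), 2L * (3L * 10L + 1L))
  expect_error(tgem_model(paste0("g", 1:10), c("a", "b"), n_heads = 0), "n_heads")
  # exhaustive census by enumerating the parameter arrays
  m3 <- random_small_model(G = 7, H = 3, L = 2, C = 4, seed = 1)
  expect_identical(parameter_count(m3), length(tgem:::.params_get(m3)))
})

test_that("gene-name mismatches are reported by name", {
  m <- tgem_model(c("TP53", "EGFR", "MYC"), c("a", "b"))
  X <- matrix(runif(3), 1, dimnames = list(NULL, c("TP53", "MYC", "EGFR")))
  expect_error(tgem_forward(m, X), "EGFR|MYC")
})
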