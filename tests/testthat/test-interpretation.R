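test_that("attention entropy follows the Shannon formula in nats", {
  expect_equal(attention_entropy(c(0.5, 0.5)), log(2))
  expect_equal(attention_entropy(c(1, 0, 0)), 0)
  expect_equal(attention_entropy(c(0.75, 0.25)),
               -0.75 * log(0.75) - 0.25 * log(0.25))
  expect_equal(attention_entropy(c(0.75, 0.25)), 0.5623, tolerance = 1e-4)
  expect_error(attention_entropy(c(1.2, -0.2)), "non-negative")
})

test_that("entropy profiles average per-sample entropies and respect bounds", {
  G <- 6
  # all-zero Query weights give uniform attention: entropy == ln(G-1)
  m <- random_small_model(G = G, H = 2, L = 1, seed = 41)
  m$layers[[1]]$Wq[] <- 0
  X <- matrix(runif(2 * G), 2, G)
  prof <- entropy_profile(m, X)
  expect_equal(as.vector(prof), rep(log(G - 1), length(prof)),
               tolerance = 1e-12)
  # a profile is the elementwise mean of single-sample profiles
  m2 <- random_small_model(G = G, H = 2, L = 2, seed = 43)
  p12 <- entropy_profile(m2, X)
  p1 <- entropy_profile(m2, X[1, , drop = FALSE])
  p2 <- entropy_profile(m2, X[2, , drop = FALSE])
  expect_equal(as.vector(p12), as.vector((unclass(p1) + unclass(p2)) / 2))
  expect_true(all(p12 >= 0 & p12 <= log(G - 1) + 1e-12))
  # long-format export covers every (layer, head, gene) cell
  tab <- entropy_profile_table(p12)
  expect_equal(nrow(tab), 2 * 2 * G)
})

test_that("IG is exact when the logit is linear in the attention weights", {
  m <- near_linear_model(G = 5, seed = 4)
  x <- runif(5, 0.2, 1)
  ig2 <- ig_attribution(m, x, 0, layer = 1, n_steps = 2)
  ig100 <- ig_attribution(m, x, 0, layer = 1, n_steps = 100)
  expect_lt(max(abs(ig2$scores - ig100$scores)), 1e-10)
  expect_equal(unname(diag(ig2$scores)), rep(0, 5))
  # independent oracle: finite differences of the target logit over the
  # attention entries, holding Values and the skip input fixed
  fw <- tgem:::.forward_sample(m, x)
  A0 <- fw$caches[[1]]$heads[[1]]$A
  v <- fw$caches[[1]]$heads[[1]]$v
  Fof <- function(A) {
    mm <- as.vector(A %*% v)
    mu <- mean(mm)
    sd_ <- sqrt(mean((mm - mu)^2) + m$ln_eps)
    z <- x + m$layers[[1]]$ln_gain * (mm - mu) / sd_ + m$layers[[1]]$ln_bias
    (as.vector(m$classifier$W %*% z) + m$classifier$b)[1]
  }
  h <- 1e-7
  w <- matrix(0, 5, 5)
  for (g in 1:5) for (i in 1:5) {
    Ap <- A0; Ap[g, i] <- Ap[g, i] + h
    Am <- A0; Am[g, i] <- Am[g, i] - h
    w[g, i] <- (Fof(Ap) - Fof(Am)) / (2 * h)
  }
  expect_equal(unname(ig2$scores), unname(A0 * w), tolerance = 1e-4)
  # completeness is exact up to the linearization
  expect_equal(ig2$completeness$sum_ig, ig2$completeness$delta_F,
               tolerance = 1e-6)
})

test_that("IG satisfies completeness on nonlinear models", {
  for (seed in c(51, 52)) {
    set.seed(seed)
    m <- random_small_model(G = 6, H = 2, L = 2, seed = seed)
    x <- runif(6)
    for (layer in 1:2) {
      ig <- ig_attribution(m, x, 1, layer = layer, n_steps = 200)
      rel <- abs(ig$completeness$sum_ig - ig$completeness$delta_F) /
        max(abs(ig$completeness$delta_F), 1e-12)
      expect_lt(rel, 0.01)
    }
  }
})

test_that("trapezoid and left-sum IG agree as the step count grows", {
  m <- random_small_model(G = 5, H = 1, L = 1, seed = 61)
  x <- runif(5)
  lt <- ig_attribution(m, x, 0, n_steps = 400, rule = "left")
  tz <- ig_attribution(m, x, 0, n_steps = 50, rule = "trapezoid")
  denom <- max(abs(lt$scores))
  expect_lt(max(abs(lt$scores - tz$scores)) / denom, 0.02)
})

test_that("head and layer pruning zero the head-mixing weights on a copy", {
  m <- random_small_model(G = 5, H = 3, L = 2, seed = 71)
  pm <- prune_head(m, 2, 3)
  expect_equal(pm$layers[[2]]$head_mix[3], 0)
  expect_equal(pm$layers[[2]]$head_mix[1:2], m$layers[[2]]$head_mix[1:2])
  expect_false(m$layers[[2]]$head_mix[3] == 0) # original untouched
  pl <- prune_layer(m, 1)
  expect_equal(pl$layers[[1]]$head_mix, rep(0, 3))
  expect_error(prune_head(m, 3, 1), "layer index")
  expect_error(prune_head(m, 1, 4), "head index")
  # pruning an already-silent head changes nothing
  m0 <- prune_head(m, 1, 2)
  X <- matrix(runif(15), 3, 5)
  expect_equal(tgem_forward(prune_head(m0, 1, 2), X)$probs,
               tgem_forward(m0, X)$probs)
})

test_that("pruning every layer reduces the network to its classifier", {
  m <- random_small_model(G = 6, H = 2, L = 3, seed = 73, activation = "gelu")
  for (l in 1:3) {
    m$layers[[l]]$ln_bias <- rep(0, 6)
    m <- prune_layer(m, l)
  }
  X <- matrix(runif(12), 2, 6)
  got <- tgem_forward(m, X)$probs
  for (n in 1:2) {
    phi <- X[n, ] * pnorm(X[n, ])
    lg <- as.numeric(m$classifier$W %*% phi) + m$classifier$b
    expect_equal(as.numeric(got[n, ]), as.numeric(exp(lg - max(lg)) / sum(exp(lg - max(lg)))),
                 tolerance = 1e-12)
  }
})

test_that("the prune scan isolates the informative head", {
  fx <- make_interaction_fixture()
  scan <- prune_scan(fx$model, fx$X, fx$y)
  expect_equal(nrow(scan), 1 + 1 + 2) # reference + layer + 2 heads
  ref <- scan$accuracy_after[scan$target == "none"]
  expect_gte(ref, 0.95)
  expect_equal(scan$accuracy_drop, ref - scan$accuracy_after)
  drop_h1 <- scan$accuracy_drop[scan$target == "head" & scan$head == 1]
  drop_h2 <- scan$accuracy_drop[scan$target == "head" & scan$head == 2]
  drop_layer <- scan$accuracy_drop[scan$target == "layer"]
  expect_equal(drop_h2, 0) # head 2 is already silent
  expect_gte(drop_h1, 0.3) # the only informative path
  expect_equal(drop_h1, max(scan$accuracy_drop))
  expect_equal(drop_h1, drop_layer)
  wide <- prune_scan_table(scan)
  expect_equal(nrow(wide), 1)
  expect_named(wide, c("layer", "LAYER", "HEAD1", "HEAD2"))
  expect_equal(attr(wide, "reference"), ref)
})

test_that("probe classifiers read out separable representations", {
  fx <- make_interaction_fixture(n_per_class = 40)
  tr <- c(1:30, 41:70)
  te <- setdiff(seq_along(fx$y), tr)
  # the raw input is separable through gene 1's shift
  acc_in <- probe_classifier(fx$model, fx$X[tr, ], fx$y[tr],
                             fx$X[te, ], fx$y[te], what = "input")
  expect_gte(acc_in, 0.95)
  acc_layer <- probe_classifier(fx$model, fx$X[tr, ], fx$y[tr],
                                fx$X[te, ], fx$y[te], what = "layer", layer = 1)
  expect_gte(acc_layer, 0.95)
  acc_head <- probe_classifier(fx$model, fx$X[tr, ], fx$y[tr],
                               fx$X[te, ], fx$y[te], what = "head",
                               layer = 1, head = 1)
  expect_gte(acc_head, 0.95)
  expect_error(probe_classifier(fx$model, fx$X[1:5, ], rep(0, 5),
                                fx$X[te, ], fx$y[te], what = "input"),
               "degenerate")
})
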