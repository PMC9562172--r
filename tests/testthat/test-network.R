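test_that("thresholding retains high-attribution pairs and flags informative genes", {
  S <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  S[1, 2] <- 5; S[2, 1] <- 1; S[3, 1] <- 0.5; S[1, 3] <- 0.2
  # only one pair clears the 90th percentile of the off-diagonal scores
  r <- threshold_informative(S, rule = list(method = "percentile", q = 0.9))
  expect_equal(nrow(r$edges), 1)
  expect_equal(r$edges$query, "g1") # row = Query, column = Key
  expect_equal(r$edges$key, "g2")
  expect_equal(r$informative, "g1")
  expect_setequal(r$non_informative, c("g2", "g3"))
  # a threshold above the global max empties the network with a warning
  expect_warning(r0 <- threshold_informative(S, rule = list(method = "absolute",
                                                            value = 10)),
                 "no edges")
  expect_equal(nrow(r0$edges), 0)
  expect_length(r0$informative, 0)
  # -Inf keeps all G*(G-1) ordered pairs
  rall <- threshold_informative(S, rule = list(method = "absolute", value = -Inf))
  expect_equal(nrow(rall$edges), 6)
  # per-query top-k keeps exactly k keys per query
  rk <- threshold_informative(S, rule = list(method = "top_k", k = 1))
  expect_equal(nrow(rk$edges), 3)
  expect_equal(sort(table(rk$edges$query)), sort(table(paste0("g", 1:3))))
})

test_that("raising the threshold never adds edges", {
  set.seed(91)
  for (i in 1:5) {
    S <- matrix(rnorm(64), 8, 8, dimnames = list(paste0("g", 1:8), paste0("g", 1:8)))
    diag(S) <- 0
    prev <- NULL
    for (q in c(0.5, 0.8, 0.95)) {
      r <- suppressWarnings(threshold_informative(S, list(method = "percentile", q = q)))
      key <- paste(r$edges$key, r$edges$query)
      if (!is.null(prev)) {
        expect_true(all(key %in% prev$key))
        expect_true(all(r$informative %in% prev$informative))
      }
      prev <- list(key = key, informative = r$informative)
    }
  }
})

test_that("hub ranking uses degree, then incident score, then name", {
  star_edges <- data.frame(key = "hub", query = paste0("leaf", 1:4),
                           score = c(1, 1, 1, 1), stringsAsFactors = FALSE)
  nodes <- data.frame(gene = c("hub", paste0("leaf", 1:4)),
                      out_degree = c(4, 0, 0, 0, 0),
                      in_degree = c(0, 1, 1, 1, 1),
                      degree = c(4, 1, 1, 1, 1),
                      score_sum = c(4, 1, 2, 1, 1),
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = star_edges, nodes = nodes),
                   class = "tgem_network")
  h <- find_hubs(net, 3)
  expect_equal(h$gene[1], "hub")
  expect_equal(h$gene[2], "leaf2") # tie on degree, higher score_sum wins
  expect_equal(h$gene[3], "leaf1") # remaining ties alphabetical
  expect_equal(nrow(find_hubs(net, 100)), 5) # k capped at node count
  empty <- structure(list(edges = star_edges[0, ], nodes = nodes[0, ]),
                     class = "tgem_network")
  expect_error(find_hubs(empty), "empty")
})

test_that("hypergeometric enrichment reproduces exact tail probabilities", {
  universe <- paste0("g", 1:20)
  coll <- geneset_collection(list(S = paste0("g", 1:5)), universe)
  res <- hypergeometric_enrichment(paste0("g", c(1:4, 10)), coll)
  # P(X >= 4) with N=20, K=5, n=5: (C(5,4)C(15,1) + C(5,5)) / C(20,5)
  expect_equal(res$p, 76 / 15504, tolerance = 1e-15)
  expect_equal(res$overlap, 4)
  # no overlap -> p = 1; informative = universe -> overlap forced, p = 1
  expect_equal(hypergeometric_enrichment(paste0("g", 11:15), coll)$p, 1)
  expect_equal(hypergeometric_enrichment(universe, coll)$p, 1)
  expect_equal(hypergeometric_enrichment(character(0), coll)$p, 1)
  expect_error(hypergeometric_enrichment("not_a_gene", coll), "universe")
})

test_that("p-values match exhaustive enumeration on small universes", {
  cases <- list(c(N = 10, K = 4, n = 3, m = 2), c(N = 12, K = 5, n = 6, m = 3),
                c(N = 9, K = 3, n = 4, m = 1), c(N = 11, K = 6, n = 5, m = 5))
  for (cs in cases) {
    universe <- paste0("g", seq_len(cs["N"]))
    coll <- geneset_collection(list(S = universe[seq_len(cs["K"])]), universe)
    informative <- c(universe[seq_len(cs["m"])],
                     if (cs["n"] > cs["m"])
                       universe[cs["K"] + seq_len(cs["n"] - cs["m"])])
    got <- hypergeometric_enrichment(informative, coll)$p
    want <- hyper_p_enum(cs["N"], cs["K"], cs["n"], cs["m"])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("BH correction never reports an FDR below the raw p-value", {
  set.seed(71)
  universe <- paste0("g", 1:40)
  sets <- c(lapply(1:6, function(i) sample(universe, 8)), list(hit = universe[1:8]))
  names(sets) <- c(paste0("s", 1:6), "hit")
  coll <- geneset_collection(sets, universe)
  res <- hypergeometric_enrichment(universe[1:10], coll)
  expect_true(all(res$fdr >= res$p - 1e-15))
  expect_true(all(diff(res$fdr) >= -1e-15)) # sorted by FDR
})

test_that("class-specific networks are deterministic and internally consistent", {
  m <- random_small_model(G = 10, H = 2, L = 2, seed = 101)
  set.seed(102)
  Xa <- matrix(runif(30), 3, 10)
  Xb <- matrix(runif(30, 1, 2), 3, 10)
  rule <- list(method = "percentile", q = 0.9)
  n1 <- extract_network(m, Xa, 0, rule = rule, n_steps = 8)
  n2 <- extract_network(m, Xa, 0, rule = rule, n_steps = 8)
  expect_identical(n1$edges, n2$edges)
  expect_setequal(n1$nodes$gene, union(n1$edges$key, n1$edges$query))
  expect_false(any(n1$edges$key == n1$edges$query)) # no self-edges
  expect_true(all(n1$edges$score >= n1$threshold))
  # different class/sample composition yields a different edge set
  n3 <- extract_network(m, Xb, 1, rule = rule, n_steps = 8)
  expect_false(identical(n1$edges[, c("key", "query")],
                         n3$edges[, c("key", "query")]))
})

test_that("cross-layer links connect pathways through their Key genes", {
  universe <- paste0("g", 1:30)
  P <- universe[1:5]
  coll <- geneset_collection(list(P = P, Q = universe[11:15]), universe)
  net_of <- function(edges) {
    nodes_v <- sort(union(edges$key, edges$query))
    structure(list(edges = edges, informative = sort(unique(edges$query)),
                   nodes = data.frame(gene = nodes_v)),
              class = "tgem_network")
  }
  # layer 2: module P feeds itself -> expect a self-link P(2) -> P(1)
  e2 <- data.frame(key = P, query = P[c(2:5, 1)], score = 1)
  e1 <- data.frame(key = P, query = P[c(3:5, 1:2)], score = 1)
  nets <- list(net_of(e1), net_of(e2))
  enr <- lapply(nets, function(n) hypergeometric_enrichment(n$informative, coll))
  links <- link_layers(enr, nets, coll)
  expect_equal(nrow(links), 1)
  expect_equal(links$pathway, "P")
  expect_equal(links$linked_pathway, "P")
  expect_equal(links$prev_layer, 1)
  # nothing enriched at the previous layer -> no links
  enr_none <- enr
  enr_none[[1]]$fdr <- 1
  expect_equal(nrow(link_layers(enr_none, nets, coll)), 0)
  # links are a subset of enriched(l) x enriched(l-1)
  expect_true(all(links$pathway %in% enr[[2]]$set[enr[[2]]$fdr < 0.05]))
  expect_true(all(links$linked_pathway %in% enr[[1]]$set[enr[[1]]$fdr < 0.05]))
})
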