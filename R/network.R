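#' Threshold an attribution matrix into informative edges
#'
#' Retains Query-Key pairs whose attribution score clears the threshold
#' rule. Query genes with at least one retained edge are the
#' "informative" genes; Query genes with none are non-informative.
#'
#' Available rules:
#' * `percentile` (default): keep scores at or above the given quantile
#'   (`q`, default 0.995) of the off-diagonal score distribution;
#' * `absolute`: keep scores `>= value`;
#' * `top_k`: keep the `k` highest-scoring Key genes per Query gene.
#' Set `use_abs = TRUE` to threshold on absolute scores.
#'
#' @param attrib a `tgem_attribution` (or a bare `G x G` score matrix
#'   with dimnames).
#' @param rule list describing the threshold, e.g.
#'   `list(method = "percentile", q = 0.995)`,
#'   `list(method = "absolute", value = 0.1)` or
#'   `list(method = "top_k", k = 3)`; optionally `use_abs = TRUE`.
#' @return list with `edges` (data.frame `key`, `query`, `score`),
#'   `informative`, `non_informative` (character vectors of Query
#'   genes) and `threshold` (the realized cutoff, `NA` for top_k).
#' @export
threshold_informative <- function(attrib,
                                  rule = list(method = "percentile", q = 0.995)) {
  S <- if (inherits(attrib, "tgem_attribution")) attrib$scores else as.matrix(attrib)
  if (any(!is.finite(S))) stop("attribution scores must be finite")
  G <- nrow(S)
  genes <- rownames(S)
  if (is.null(genes)) genes <- as.character(seq_len(G))
  vals <- if (isTRUE(rule$use_abs)) abs(S) else S
  off <- !diag(TRUE, G)
  method <- if (is.null(rule$method)) "percentile" else rule$method
  keep <- matrix(FALSE, G, G)
  thr <- NA_real_
  if (method == "percentile") {
    q <- if (is.null(rule$q)) 0.995 else rule$q
    thr <- stats::quantile(vals[off], q, names = FALSE)
    keep <- off & vals >= thr
  } else if (method == "absolute") {
    thr <- rule$value
    keep <- off & vals >= thr
  } else if (method == "top_k") {
    k <- rule$k
    for (g in seq_len(G)) {
      cand <- vals[g, ]
      cand[g] <- -Inf
      ord <- order(-cand)[seq_len(min(k, G - 1L))]
      keep[g, ord] <- TRUE
    }
  } else stop("unknown threshold method: ", method)
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(key = genes[idx[, 2]], query = genes[idx[, 1]],
                      score = S[idx], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$score, edges$query, edges$key), ]
  rownames(edges) <- NULL
  informative <- sort(unique(edges$query))
  if (nrow(edges) == 0L)
    warning("threshold retained no edges; empty network")
  list(edges = edges, informative = informative,
       non_informative = setdiff(genes, informative), threshold = thr)
}

#' Extract a Key-to-Query regulatory network
#'
#' Composes integrated-gradients attribution of the attention weights
#' (for the samples of one class, by default in the last layer) with
#' thresholding. Edges are directed Key gene -> Query gene: the Key
#' genes act as the regulators whose information flows into the Query
#' genes' representations.
#'
#' @param model a `tgem_model`.
#' @param x preprocessed samples, all of the target class.
#' @param target_class 0-based class index or class name.
#' @param layer layer to attribute (defaults to the last).
#' @param rule threshold rule, see [threshold_informative()].
#' @param n_steps IG steps.
#' @return object of class `tgem_network`: list with `edges`
#'   (key/query/score), `nodes` (gene, in_degree, out_degree, degree,
#'   score_sum), `informative`, `non_informative`, `class_label`,
#'   `layer`, `threshold_rule`, `threshold`.
#' @export
extract_network <- function(model, x, target_class, layer = NULL,
                            rule = list(method = "percentile", q = 0.995),
                            n_steps = 50L) {
  attrib <- ig_attribution(model, x, target_class, layer = layer,
                           n_steps = n_steps)
  thr <- threshold_informative(attrib, rule)
  edges <- thr$edges
  nodes_v <- sort(union(edges$key, edges$query))
  nodes <- data.frame(gene = nodes_v, stringsAsFactors = FALSE)
  nodes$out_degree <- vapply(nodes_v, function(g) sum(edges$key == g), numeric(1))
  nodes$in_degree <- vapply(nodes_v, function(g) sum(edges$query == g), numeric(1))
  nodes$degree <- nodes$in_degree + nodes$out_degree
  nodes$score_sum <- vapply(nodes_v, function(g)
    sum(edges$score[edges$key == g | edges$query == g]), numeric(1))
  structure(list(edges = edges, nodes = nodes,
                 informative = thr$informative,
                 non_informative = thr$non_informative,
                 class_label = attrib$class_label, layer = attrib$layer,
                 threshold_rule = rule, threshold = thr$threshold),
            class = "tgem_network")
}

#' @exportS3Method base::print
print.tgem_network <- function(x, ...) {
  cat(sprintf(
    "regulatory network (class '%s', layer %d): %d edges, %d nodes, %d informative Query genes\n",
    x$class_label, x$layer, nrow(x$edges), nrow(x$nodes),
    length(x$informative)))
  invisible(x)
}

#' Rank hub genes of a regulatory network
#'
#' Ranks nodes by total degree (in + out); ties are broken by the
#' summed incident edge score, then by gene name.
#'
#' @param network a `tgem_network`.
#' @param k number of hubs to return (capped at the node count).
#' @return data.frame `gene`, `degree`, `in_degree`, `out_degree`,
#'   `score_sum`, ordered by rank.
#' @export
find_hubs <- function(network, k = 10L) {
  nodes <- network$nodes
  if (is.null(nodes) || nrow(nodes) == 0L) stop("empty network: no hubs to rank")
  ord <- order(-nodes$degree, -nodes$score_sum, nodes$gene)
  out <- nodes[ord, c("gene", "degree", "in_degree", "out_degree", "score_sum")]
  rownames(out) <- NULL
  utils::head(out, min(k, nrow(out)))
}

#' Hypergeometric geneset enrichment of informative genes
#'
#' For each geneset S the overlap m between S (restricted to the
#' universe, size K) and the n informative genes is tested against the
#' upper-tail hypergeometric distribution,
#' `p = P(X >= m)` with `X ~ Hypergeometric(N, K, n)` on a universe of
#' size N, followed by Benjamini-Hochberg correction across the
#' collection.
#'
#' @param informative character vector of informative genes (must lie in
#'   the collection's universe).
#' @param collection a [geneset_collection()].
#' @return data.frame `set`, `overlap`, `set_size`, `n_informative`,
#'   `p`, `fdr`, sorted by FDR then p.
#' @export
hypergeometric_enrichment <- function(informative, collection) {
  stopifnot(inherits(collection, "tgem_geneset_collection"))
  universe <- collection$universe
  informative <- unique(as.character(informative))
  if (!all(informative %in% universe))
    stop("informative genes must be a subset of the universe")
  N <- length(universe)
  n <- length(informative)
  res <- data.frame(set = names(collection$sets), overlap = NA_integer_,
                    set_size = NA_integer_, n_informative = n,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(collection$sets)) {
    S <- intersect(collection$sets[[i]], universe)
    K <- length(S)
    m <- length(intersect(S, informative))
    res$overlap[i] <- m
    res$set_size[i] <- K
    # upper tail P(X >= m); P(X >= 0) = 1
    res$p[i] <- if (m == 0L) 1 else
      stats::phyper(m - 1L, K, N - K, n, lower.tail = FALSE)
  }
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$fdr, res$p, res$set), ]
  rownames(res) <- NULL
  res
}

#' Link enriched pathways across consecutive layers
#'
#' For each pathway P enriched at layer l, collects the Key genes that
#' feed P's informative Query genes in layer l's network, enriches that
#' Key-gene set against the collection, and links P to every pathway
#' that is both enriched among those Key genes and enriched at layer
#' l - 1. This traces how pathway-level information propagates upward
#' through the attention stack.
#'
#' @param enrichments list indexed by layer of enrichment data.frames
#'   (from [hypergeometric_enrichment()]).
#' @param networks list indexed by layer of `tgem_network` objects.
#' @param collection the geneset collection.
#' @param alpha FDR threshold for calling a pathway enriched (default
#'   0.05).
#' @return data.frame `layer`, `pathway`, `prev_layer`, `linked_pathway`,
#'   `key_fdr` (FDR of the linked pathway among the Key genes); zero
#'   rows when nothing links.
#' @export
link_layers <- function(enrichments, networks, collection, alpha = 0.05) {
  out <- list()
  for (l in seq_along(enrichments)) {
    if (l == 1L) next
    enr_l <- enrichments[[l]]
    enr_prev <- enrichments[[l - 1L]]
    if (is.null(enr_l) || is.null(enr_prev)) next
    prev_enriched <- enr_prev$set[enr_prev$fdr < alpha]
    if (length(prev_enriched) == 0L) next
    net <- networks[[l]]
    for (p in enr_l$set[enr_l$fdr < alpha]) {
      members <- intersect(collection$sets[[p]], collection$universe)
      queries <- intersect(net$informative, members)
      if (length(queries) == 0L) next
      keys <- unique(net$edges$key[net$edges$query %in% queries])
      if (length(keys) == 0L) next
      key_enr <- hypergeometric_enrichment(keys, collection)
      linked <- key_enr[key_enr$fdr < alpha & key_enr$set %in% prev_enriched, ]
      if (nrow(linked) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        layer = l, pathway = p, prev_layer = l - 1L,
        linked_pathway = linked$set, key_fdr = linked$fdr,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(layer = integer(0), pathway = character(0),
                      prev_layer = integer(0), linked_pathway = character(0),
                      key_fdr = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
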