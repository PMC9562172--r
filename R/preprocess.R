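#' Log transform and per-gene min-max normalization
#'
#' Applies `log2(x + 1)` (or `log(x + 1)`) to a raw non-negative
#' expression matrix and rescales each gene to `[0, 1]` by its min and
#' max. When `stats` from a training split are supplied, the training
#' min/max are reused and the result is clipped to `[0, 1]` — this is
#' the leakage-free mode used for validation/test data. Genes that are
#' constant in the reference data (max == min) map to 0.
#'
#' @param x `N x G` non-negative matrix, or a `tgem_dataset` (its matrix
#'   is used).
#' @param stats optional list as returned in `$stats` (fields
#'   `per_gene_min`, `per_gene_max`, `log_base`); if `NULL` the min/max
#'   are computed from `x` itself.
#' @param log_base `"log2p1"` (default, TCGA convention) or `"ln1p"`.
#' @return list with `matrix` (normalized, in `[0, 1]`) and `stats`.
#' @examples
#' r <- log_minmax_normalize(matrix(c(0, 3), 2, 1))
#' r$matrix  # 0 and 1 (log2(4) = 2 is this gene's max)
#' @export
log_minmax_normalize <- function(x, stats = NULL, log_base = c("log2p1", "ln1p")) {
  if (inherits(x, "tgem_dataset")) x <- x$matrix
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values")
  if (any(x < 0)) stop("expression matrix contains negative values; raw expression must be non-negative")
  if (is.null(stats)) {
    log_base <- match.arg(log_base)
  } else {
    log_base <- stats$log_base
  }
  lx <- switch(log_base, log2p1 = log2(x + 1), ln1p = log1p(x),
               stop("unknown log_base: ", log_base))
  if (is.null(stats)) {
    stats <- list(per_gene_min = apply(lx, 2, min),
                  per_gene_max = apply(lx, 2, max),
                  log_base = log_base)
    clip <- FALSE
  } else {
    if (length(stats$per_gene_min) != ncol(lx))
      stop("preprocessing stats do not match the number of genes")
    clip <- TRUE
  }
  rng <- stats$per_gene_max - stats$per_gene_min
  const <- rng <= 0
  rng[const] <- 1
  y <- sweep(lx, 2, stats$per_gene_min, "-")
  y <- sweep(y, 2, rng, "/")
  y[, const] <- 0
  if (clip) y <- pmin(pmax(y, 0), 1)
  list(matrix = y, stats = stats)
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-transformed expression and
#' returns the indices of the top `n_top`, in their original column
#' order. Ties on variance are broken in favour of the lexicographically
#' smaller gene name.
#'
#' @param x raw `N x G` matrix with gene column names, or a
#'   `tgem_dataset`.
#' @param n_top number of genes to keep (`<= G`).
#' @param log_base log transform applied before the variance ranking.
#' @return integer vector of column indices (sorted ascending, i.e. the
#'   retained genes keep their input order).
#' @export
select_hvg <- function(x, n_top, log_base = c("log2p1", "ln1p")) {
  log_base <- match.arg(log_base)
  if (inherits(x, "tgem_dataset")) x <- x$matrix
  x <- as.matrix(x)
  G <- ncol(x)
  if (n_top > G) stop(sprintf("n_top (%d) exceeds the number of genes (%d)", n_top, G))
  nms <- colnames(x)
  if (is.null(nms)) nms <- as.character(seq_len(G))
  lx <- switch(log_base, log2p1 = log2(x + 1), ln1p = log1p(x))
  v <- apply(lx, 2, stats::var)
  ord <- order(-v, nms)
  sort(ord[seq_len(n_top)])
}

#' Stratified train/validation/test split
#'
#' For each class, shuffles its samples with the given seed and
#' partitions them `floor(train_frac * n)` / `floor(val_frac * n)` /
#' remainder. The default fractions are 70/10/20.
#'
#' @param dataset a `tgem_dataset` (or an integer label vector).
#' @param train_frac,val_frac,test_frac fractions summing to 1.
#' @param seed integer seed for the per-class shuffles.
#' @return list with integer index vectors `train`, `val`, `test`
#'   (disjoint and exhaustive).
#' @export
stratified_split <- function(dataset, train_frac = 0.7, val_frac = 0.1,
                             test_frac = 0.2, seed = 0L) {
  labels <- if (inherits(dataset, "tgem_dataset")) dataset$labels else as.integer(dataset)
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-8)
    stop("split fractions must sum to 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n <- length(idx)
    if (n < 3L)
      stop(sprintf("stratification error: class %d has only %d sample(s); need >= 3", cl, n))
    idx <- idx[sample.int(n)]
    n_tr <- floor(train_frac * n)
    n_va <- floor(val_frac * n)
    train <- c(train, idx[seq_len(n_tr)])
    val <- c(val, idx[n_tr + seq_len(n_va)])
    test <- c(test, idx[(n_tr + n_va + 1L):n])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}
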