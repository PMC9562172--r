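#' Simulate a labeled expression dataset with planted structure
#'
#' Generates multi-class expression data suitable for exercising the
#' whole pipeline (training, attention interpretation, network
#' extraction, enrichment) with a known ground truth. Each gene gets a
#' baseline mean log2 expression drawn from a shared normal
#' distribution; genes belonging to a module share a per-sample latent
#' factor so that their within-module correlation equals `rho`; samples
#' of class c have `marker_effect * noise_sd` added to that class's
#' marker genes in log space; finally the log values are exponentiated
#' to a non-negative raw scale (so the standard log + min-max
#' preprocessing applies).
#'
#' Marker sets are disjoint across classes and disjoint from modules.
#'
#' @param n_classes number of classes.
#' @param n_genes number of genes.
#' @param n_samples_per_class samples per class.
#' @param n_markers_per_class planted marker genes per class.
#' @param marker_effect mean shift of marker genes, in units of
#'   `noise_sd` (log space).
#' @param modules list of modules, each `list(name =, size =, rho =)`;
#'   or `NULL` for the default four 15-gene modules with rho 0.5. Pass
#'   `list()` for no modules.
#' @param noise_sd standard deviation of per-gene log-space noise.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   mean log2 expression.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return list with `dataset` (a [tgem_dataset()]) and `truth`, a list
#'   with `markers` (per-class gene-name vectors), `modules` (name,
#'   members, rho) and the simulation parameters.
#' @export
simulate_expression <- function(n_classes = 3L, n_genes = 200L,
                                n_samples_per_class = 300L,
                                n_markers_per_class = 20L,
                                marker_effect = 2.0,
                                modules = NULL,
                                noise_sd = 1.0,
                                baseline_mean = 4.0, baseline_sd = 1.0,
                                seed = 0L) {
  if (n_markers_per_class * n_classes > n_genes)
    stop("marker sets are disjoint across classes: n_markers_per_class * n_classes must be <= n_genes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  genes <- sprintf("g%04d", seq_len(n_genes))
  N <- n_classes * n_samples_per_class
  labels <- rep(seq_len(n_classes) - 1L, each = n_samples_per_class)
  sample_ids <- sprintf("s%05d", seq_len(N))

  # planted markers: disjoint across classes
  marker_pool <- sample(genes, n_markers_per_class * n_classes)
  markers <- split(marker_pool, rep(seq_len(n_classes) - 1L, each = n_markers_per_class))
  names(markers) <- paste0("class", seq_len(n_classes) - 1L)

  # modules drawn from the remaining genes, disjoint from each other
  if (is.null(modules)) {
    modules <- lapply(seq_len(4L), function(i)
      list(name = paste0("module", i), size = 15L, rho = 0.5))
  }
  free <- setdiff(genes, marker_pool)
  module_truth <- list()
  for (mod in modules) {
    size <- if (!is.null(mod$size)) mod$size else length(mod$members)
    if (!is.null(mod$members)) {
      members <- mod$members
      if (!all(members %in% genes)) stop("module members must be in the gene universe")
    } else {
      if (size > length(free)) stop("not enough non-marker genes left for module ", mod$name)
      members <- sample(free, size)
      free <- setdiff(free, members)
    }
    rho <- mod$rho
    if (rho < 0 || rho >= 1) stop("module rho must be in [0, 1)")
    module_truth[[mod$name]] <- list(name = mod$name, members = members, rho = rho)
  }

  mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  names(mu) <- genes

  # independent noise, then replace module-gene noise with the
  # factor-sharing mixture sqrt(rho)*u_m + sqrt(1-rho)*e
  eps <- matrix(stats::rnorm(N * n_genes), N, n_genes)
  for (mt in module_truth) {
    j <- match(mt$members, genes)
    u <- stats::rnorm(N)
    eps[, j] <- sqrt(mt$rho) * u + sqrt(1 - mt$rho) * eps[, j]
  }
  logx <- sweep(noise_sd * eps, 2, mu, "+")
  for (cl in seq_len(n_classes) - 1L) {
    j <- match(markers[[cl + 1L]], genes)
    logx[labels == cl, j] <- logx[labels == cl, j] + marker_effect * noise_sd
  }
  raw <- 2^logx

  dataset <- tgem_dataset(raw, genes, sample_ids, labels,
                          class_names = paste0("class", seq_len(n_classes) - 1L))
  truth <- list(markers = markers, modules = module_truth,
                params = list(n_classes = n_classes, n_genes = n_genes,
                              n_samples_per_class = n_samples_per_class,
                              n_markers_per_class = n_markers_per_class,
                              marker_effect = marker_effect,
                              noise_sd = noise_sd, seed = as.integer(seed)))
  list(dataset = dataset, truth = truth)
}

#' Build a geneset collection from simulation ground truth
#'
#' Emits one geneset per planted module, one per class marker set, and
#' `n_decoys` random decoy sets of matched sizes drawn (without
#' replacement within a set) from the non-marker genes.
#'
#' @param truth the `truth` element returned by [simulate_expression()],
#'   plus access to the gene universe via `universe`.
#' @param universe character vector of all gene names (the model input
#'   genes).
#' @param n_decoys number of decoy sets.
#' @param seed seed for the decoy draws.
#' @return a `tgem_geneset_collection`: list with `sets` (named list of
#'   gene-name vectors) and `universe`.
#' @export
make_geneset_collection <- function(truth, universe, n_decoys = 10L, seed = 0L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sets <- list()
  for (mt in truth$modules) sets[[mt$name]] <- mt$members
  for (cl in names(truth$markers)) sets[[paste0("markers_", cl)]] <- truth$markers[[cl]]
  marker_pool <- unlist(truth$markers, use.names = FALSE)
  non_marker <- setdiff(universe, marker_pool)
  sizes <- vapply(sets, length, integer(1))
  for (i in seq_len(n_decoys)) {
    sz <- sizes[((i - 1L) %% length(sizes)) + 1L]
    sets[[paste0("decoy", i)]] <- sample(non_marker, min(sz, length(non_marker)))
  }
  geneset_collection(sets, universe)
}

#' Construct a geneset collection
#'
#' @param sets named list of character vectors (gene symbols); members
#'   need not all lie in the universe — enrichment uses the
#'   intersection.
#' @param universe character vector of gene names forming the enrichment
#'   universe (typically the model's input genes).
#' @return object of class `tgem_geneset_collection`.
#' @export
geneset_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("genesets must be named")
  structure(list(sets = lapply(sets, as.character),
                 universe = as.character(universe)),
            class = "tgem_geneset_collection")
}

#' @exportS3Method base::print
print.tgem_geneset_collection <- function(x, ...) {
  cat(sprintf("geneset collection: %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}
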