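# Readers and writers for the package's on-disk formats: expression
# TSV/CSV and MatrixMarket triplets, label tables, GMT geneset
# collections, SIF/GraphML network exports, model checkpoints and
# JSON-lines training logs.

#' Read an expression matrix
#'
#' Expression tables are samples x genes: first column = sample ID,
#' header = gene symbols, tab- or comma-separated (by file extension).
#' Alternatively `path` may be a directory holding a MatrixMarket
#' triplet (`matrix.mtx` genes x cells, `features.tsv`, `barcodes.tsv`),
#' which is transposed to samples x genes on load.
#'
#' @param path file (.tsv/.txt/.csv) or MTX directory.
#' @return numeric matrix with sample rownames and gene colnames.
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc)) if (!file.exists(f)) stop("missing MTX file: ", f)
    m <- Matrix::readMM(mtx)
    genes <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bc, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("MTX dimensions do not match features/barcodes")
    x <- t(as.matrix(m))
    dimnames(x) <- list(cells, genes)
    return(x)
  }
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyDuplicated(colnames(x))) stop("duplicate gene symbols in header")
  rownames(x) <- ids
  x
}

#' Write an expression matrix as TSV
#'
#' @param x numeric samples x genes matrix with dimnames, or a
#'   `tgem_dataset`.
#' @param path output path.
#' @param id_col name of the sample-ID column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_col = "sample_id") {
  if (inherits(x, "tgem_dataset")) x <- x$matrix
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV with columns sample_id, class_label (header optional
#'   but recommended).
#' @return data.frame with `sample_id` and `class_label` character
#'   columns.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label file needs two columns: sample_id, class_label")
  data.frame(sample_id = as.character(df[[1]]),
             class_label = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a label table
#'
#' @param dataset a `tgem_dataset` (labels are written as class names).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_ids,
                   class_label = dataset$class_names[dataset$labels + 1L],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a dataset from expression and label files
#'
#' Sample IDs present in the expression matrix must all be labeled;
#' mismatches are reported by name.
#'
#' @param expression_path expression TSV/CSV or MTX directory.
#' @param labels_path label TSV.
#' @return a [tgem_dataset()].
#' @export
read_dataset <- function(expression_path, labels_path) {
  x <- read_expression(expression_path)
  lab <- read_labels(labels_path)
  missing <- setdiff(rownames(x), lab$sample_id)
  if (length(missing))
    stop("samples without labels: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  lab <- lab[match(rownames(x), lab$sample_id), ]
  class_names <- sort(unique(lab$class_label))
  labels <- match(lab$class_label, class_names) - 1L
  tgem_dataset(x, colnames(x), rownames(x), labels, class_names)
}

# GMT ------------------------------------------------------------------

#' Read a GMT geneset file
#'
#' Standard tab-separated GMT: set name, description, then member gene
#' symbols.
#'
#' @param path GMT file.
#' @param universe gene universe for the returned collection (defaults
#'   to the union of all members).
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  geneset_collection(sets, universe)
}

#' Write a geneset collection as GMT
#'
#' @param collection a `tgem_geneset_collection`.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to
#'   the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  nm <- names(collection$sets)
  if (is.null(descriptions)) descriptions <- nm
  lines <- vapply(seq_along(nm), function(i)
    paste(c(nm[i], descriptions[i], collection$sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# Network exports ------------------------------------------------------

#' Write a regulatory network in SIF format
#'
#' One line per edge: `key <TAB> regulates <TAB> query`, loadable by
#' Cytoscape.
#'
#' @param network a `tgem_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  lines <- sprintf("%s\tregulates\t%s", network$edges$key, network$edges$query)
  writeLines(lines, path)
  invisible(path)
}

#' Write a regulatory network as GraphML
#'
#' Nodes carry degree and hub attributes, edges carry the attribution
#' score; the file is loadable by Cytoscape and igraph.
#'
#' @param network a `tgem_network`.
#' @param path output path.
#' @param n_hubs number of top-degree nodes flagged as hubs.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path, n_hubs = 10L) {
  if (nrow(network$edges) == 0L) stop("cannot export an empty network")
  hubs <- find_hubs(network, n_hubs)$gene
  g <- igraph::graph_from_data_frame(
    network$edges[, c("key", "query", "score")], directed = TRUE,
    vertices = transform(network$nodes, hub = network$nodes$gene %in% hubs))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Checkpoints ----------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes `<prefix>.rds` (the exact parameter archive) and a sidecar
#' `<prefix>.json` describing the architecture, gene and class names,
#' preprocessing statistics, seed and training configuration. Loading
#' the checkpoint reproduces forward outputs bit-identically.
#'
#' @param fit a `tgem_fit` (or a bare `tgem_model`).
#' @param prefix path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
save_checkpoint <- function(fit, prefix) {
  if (inherits(fit, "tgem_model")) fit <- list(model = fit, stats = NULL,
                                               config = NULL, log = NULL)
  model <- fit$model
  saveRDS(list(model = model, stats = fit$stats, config = fit$config,
               log = fit$log, best_epoch = fit$best_epoch), paste0(prefix, ".rds"))
  d <- .model_dims(model)
  side <- list(
    gene_names = model$gene_names, class_names = model$class_names,
    n_layers = d$L, n_heads = d$H,
    activation = model$classifier$activation,
    ln_eps = model$ln_eps, seed = model$seed,
    preprocess = if (!is.null(fit$stats)) list(
      log_base = fit$stats$log_base,
      per_gene_min = fit$stats$per_gene_min,
      per_gene_max = fit$stats$per_gene_max) else NULL,
    train_config = if (!is.null(fit$config)) unclass(fit$config) else NULL,
    package_version = as.character(utils::packageVersion("tgem")))
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' Load a model checkpoint
#'
#' @param prefix checkpoint path prefix used in [save_checkpoint()].
#' @return a `tgem_fit`-like list with `model`, `stats`, `config`,
#'   `log`, `best_epoch`.
#' @export
load_checkpoint <- function(prefix) {
  rds <- paste0(prefix, ".rds")
  if (!file.exists(rds)) stop("checkpoint not found: ", rds)
  obj <- readRDS(rds)
  structure(obj, class = "tgem_fit")
}

# Training log ---------------------------------------------------------

#' Write a training log as JSON lines
#'
#' One record per epoch: `{epoch, train_loss, val_acc}`.
#'
#' @param log the `log` data.frame of a `tgem_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i)
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
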