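#' Construct an expression dataset
#'
#' Bundles a raw (non-negative) samples x genes expression matrix with
#' sample identifiers and integer class labels.
#'
#' @param matrix numeric `N x G` matrix of raw non-negative expression.
#' @param gene_names length-G character vector of unique gene symbols.
#' @param sample_ids length-N character vector of unique sample IDs.
#' @param labels length-N integer labels in `[0, C)`.
#' @param class_names optional length-C character vector naming the
#'   classes; defaults to `class0 ... class{C-1}`.
#' @return object of class `tgem_dataset`.
#' @export
tgem_dataset <- function(matrix, gene_names, sample_ids, labels,
                         class_names = NULL) {
  matrix <- as.matrix(matrix)
  gene_names <- as.character(gene_names)
  sample_ids <- as.character(sample_ids)
  labels <- as.integer(labels)
  if (ncol(matrix) != length(gene_names))
    stop("gene_names length does not match the number of columns")
  if (nrow(matrix) != length(sample_ids) || nrow(matrix) != length(labels))
    stop("sample_ids/labels length does not match the number of rows")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (anyDuplicated(gene_names)) stop("duplicate gene_names")
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stop("expression matrix must be finite and non-negative")
  if (any(labels < 0)) stop("labels must be non-negative integers")
  C <- max(labels) + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C) - 1L)
  if (length(class_names) < C) stop("class_names shorter than the number of labels")
  if (length(setdiff(seq_len(length(class_names)) - 1L, unique(labels))) > 0 &&
      !all(seq_len(length(class_names)) - 1L %in% labels))
    stop(sprintf("every class must have at least 1 sample; missing: %s",
                 paste(setdiff(seq_along(class_names) - 1L, unique(labels)),
                       collapse = ", ")))
  dimnames(matrix) <- list(sample_ids, gene_names)
  structure(list(matrix = matrix, gene_names = gene_names,
                 sample_ids = sample_ids, labels = labels,
                 class_names = as.character(class_names)),
            class = "tgem_dataset")
}

#' @exportS3Method base::print
print.tgem_dataset <- function(x, ...) {
  cat(sprintf("tgem_dataset: %d samples x %d genes, %d classes\n",
              nrow(x$matrix), ncol(x$matrix), length(x$class_names)))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  print(tab)
  invisible(x)
}

# Subset a dataset by sample indices, keeping all classes' names.
.dataset_subset <- function(dataset, idx) {
  structure(list(matrix = dataset$matrix[idx, , drop = FALSE],
                 gene_names = dataset$gene_names,
                 sample_ids = dataset$sample_ids[idx],
                 labels = dataset$labels[idx],
                 class_names = dataset$class_names),
            class = "tgem_dataset")
}
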