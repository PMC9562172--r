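#' Construct a T-GEM model
#'
#' T-GEM is a Transformer-style architecture for gene expression in which
#' every gene carries its own scalar Query, Key and Value weight per head.
#' A layer computes, for each Query gene g, a probability distribution of
#' attention over all other (Key) genes from the product of scalar
#' projections `q_g * k_i`, mixes the per-head representations with a
#' learned head-mixing vector, applies layer normalization over the gene
#' dimension, and adds a skip connection to the layer input. A dense
#' `C x G` affine readout (optionally preceded by a ReLU or GELU
#' activation) produces class logits.
#'
#' Per-gene Query/Key/Value weights are initialized uniformly on
#' `[-1, 1] / sqrt(G)`, head-mixing weights at `1/H`, layer-norm gain at 1
#' and bias at 0, and the classifier with the same fan-in scaling; the
#' draw is governed by `seed` so that model construction is reproducible.
#'
#' @param gene_names character vector of G unique gene symbols.
#' @param class_names character vector of C >= 2 unique class labels.
#' @param n_layers number of attention layers (L >= 1).
#' @param n_heads number of attention heads per layer (H >= 1).
#' @param activation activation of the classification layer: `"none"`,
#'   `"relu"` or `"gelu"`.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `tgem_model`: a list with elements `layers`
#'   (each a list with `Wq`, `Wk`, `Wv` `G x H` matrices, `head_mix`,
#'   `ln_gain`, `ln_bias`), `classifier` (`W`, `b`, `activation`),
#'   `gene_names` and `class_names`.
#' @examples
#' m <- tgem_model(paste0("g", 1:5), c("A", "B"), n_layers = 1, n_heads = 2)
#' parameter_count(m)
#' @export
tgem_model <- function(gene_names, class_names, n_layers = 1L, n_heads = 1L,
                       activation = c("none", "relu", "gelu"), seed = 1L) {
  activation <- match.arg(activation)
  gene_names <- as.character(gene_names)
  class_names <- as.character(class_names)
  G <- length(gene_names)
  C <- length(class_names)
  if (G < 2L) stop("a T-GEM model needs at least 2 genes (no Key genes to attend to)")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  if (C < 2L) stop("at least 2 classes are required")
  if (anyDuplicated(class_names)) stop("class_names must be unique")
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (n_heads < 1L) stop("n_heads must be >= 1")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  sc <- 1 / sqrt(G)
  layers <- lapply(seq_len(n_layers), function(l) {
    list(
      Wq = matrix(stats::runif(G * n_heads, -1, 1) * sc, G, n_heads),
      Wk = matrix(stats::runif(G * n_heads, -1, 1) * sc, G, n_heads),
      Wv = matrix(stats::runif(G * n_heads, -1, 1) * sc, G, n_heads),
      head_mix = rep(1 / n_heads, n_heads),
      ln_gain = rep(1, G),
      ln_bias = rep(0, G)
    )
  })
  classifier <- list(
    W = matrix(stats::runif(C * G, -1, 1) * sc, C, G),
    b = rep(0, C),
    activation = activation
  )
  structure(
    list(layers = layers, classifier = classifier,
         gene_names = gene_names, class_names = class_names,
         ln_eps = 1e-5, seed = as.integer(seed)),
    class = "tgem_model"
  )
}

# Save/restore the global RNG stream so that seeded constructors do not
# disturb the caller's random sequence.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @exportS3Method base::print
print.tgem_model <- function(x, ...) {
  G <- length(x$gene_names)
  cat(sprintf(
    "T-GEM model: %d genes, %d classes, %d layer(s) x %d head(s), activation '%s'\n",
    G, length(x$class_names), length(x$layers),
    length(x$layers[[1]]$head_mix), x$classifier$activation))
  cat(sprintf("  parameters: %d\n", parameter_count(x)))
  invisible(x)
}

.model_dims <- function(model) {
  list(G = length(model$gene_names),
       C = length(model$class_names),
       L = length(model$layers),
       H = length(model$layers[[1]]$head_mix))
}

.check_model <- function(model) {
  if (!inherits(model, "tgem_model")) stop("not a tgem_model")
  d <- .model_dims(model)
  for (lp in model$layers) {
    stopifnot(nrow(lp$Wq) == d$G, nrow(lp$Wk) == d$G, nrow(lp$Wv) == d$G,
              ncol(lp$Wq) == d$H, length(lp$head_mix) == d$H,
              length(lp$ln_gain) == d$G, length(lp$ln_bias) == d$G)
  }
  stopifnot(nrow(model$classifier$W) == d$C, ncol(model$classifier$W) == d$G,
            length(model$classifier$b) == d$C)
  invisible(d)
}

#' Number of free parameters of a T-GEM model
#'
#' Counts per-gene Query/Key/Value weights (`3*G*H` per layer), the
#' head-mixing vector (`H`), layer-norm gain and bias (`2*G`) for each of
#' the L layers, plus the `C x G` classifier weights and C biases:
#' `L*(3*G*H + H + 2*G) + C*G + C`.
#'
#' @param model a `tgem_model`.
#' @return integer parameter count.
#' @export
parameter_count <- function(model) {
  d <- .check_model(model)
  as.integer(d$L * (3 * d$G * d$H + d$H + 2 * d$G) + d$C * d$G + d$C)
}

# Align a sample/matrix gene order against the model's gene order.
.check_gene_alignment <- function(model, gene_names) {
  if (length(gene_names) != length(model$gene_names) ||
      any(gene_names != model$gene_names)) {
    bad <- which(gene_names != model$gene_names[seq_along(gene_names)])[1]
    if (is.na(bad)) bad <- min(length(gene_names), length(model$gene_names)) + 1L
    stop(sprintf(
      "gene names do not match the model (first mismatch at position %d: '%s' vs model '%s')",
      bad,
      if (bad <= length(gene_names)) gene_names[bad] else "<missing>",
      if (bad <= length(model$gene_names)) model$gene_names[bad] else "<missing>"))
  }
  invisible(TRUE)
}
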