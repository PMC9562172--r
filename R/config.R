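#' Read a run configuration file
#'
#' Accepts a JSON or YAML file (by extension) whose fields mirror
#' [tgem_config()] (`n_layers`, `n_heads`, `activation`, `batch_size`,
#' `epochs`, `learning_rate`, `log_base`, `normalize_on`, `seed`) plus
#' optional split fractions (`train_frac`, `val_frac`, `test_frac`).
#' Unknown fields are rejected so that typos fail loudly; absent fields
#' fall back to the package defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return list with `config` (a `tgem_config`) and `split` (a list of
#'   the three fractions).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  split_fields <- c("train_frac", "val_frac", "test_frac")
  cfg_fields <- names(formals(tgem_config))
  unknown <- setdiff(names(raw), c(cfg_fields, split_fields))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- do.call(tgem_config, raw[intersect(names(raw), cfg_fields)])
  split <- list(train_frac = 0.7, val_frac = 0.1, test_frac = 0.2)
  for (f in split_fields) if (!is.null(raw[[f]])) split[[f]] <- raw[[f]]
  if (abs(sum(unlist(split)) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  list(config = config, split = split)
}
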