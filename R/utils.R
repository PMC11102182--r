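# Internal helpers shared across modules.
#
# The package-wide convention for omic tables is a "wide tibble": one id
# column (plus optional annotation columns) followed by one numeric column
# per sample. These helpers move between that form and plain matrices, which
# stats::dist / stats::cor / svd want.

#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# wide tibble -> matrix with rownames taken from `id_col`; annotation columns
# listed in `drop` are removed first
omic_matrix <- function(x, id_col, drop = character()) {
  stopifnot(is.data.frame(x))
  if (!id_col %in% names(x)) {
    abort(sprintf("column '%s' not found in table", id_col))
  }
  keep <- setdiff(names(x), c(id_col, drop))
  m <- as.matrix(x[keep])
  if (!is.numeric(m)) abort("sample columns must all be numeric")
  rownames(m) <- as.character(x[[id_col]])
  m
}

matrix_tibble <- function(m, id_col) {
  out <- tibble::as_tibble(m, rownames = id_col)
  out
}

# population standard deviation (divide by n); the row-scaling convention
pop_sd <- function(v) {
  v <- v[!is.na(v)]
  sqrt(mean((v - mean(v))^2))
}

sample_cols <- function(x, id_col, drop = character()) {
  setdiff(names(x), c(id_col, drop))
}

# consistent sample naming for generated designs
format_sample_id <- function(condition, timepoint, replicate) {
  sprintf("CN%s_T%s_R%d", format(condition, trim = TRUE),
          format(timepoint, trim = TRUE), as.integer(replicate))
}

cell_id <- function(condition, timepoint) {
  sprintf("CN%s_T%s", format(condition, trim = TRUE),
          format(timepoint, trim = TRUE))
}

check_design <- function(design) {
  needed <- c("sample_id", "condition", "timepoint", "replicate", "nitrogen_state")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    abort(paste0("design table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(design)
}
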