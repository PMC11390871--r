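# Internal helpers shared across modules.

# Split a domain tibble/data.frame into twin ids and a numeric feature matrix.
# Convention: the identifier column is named `twin_id` (or the first
# non-numeric column); every other column is a feature.
split_domain <- function(data, id_col = "twin_id") {
  data <- as_tibble(data)
  if (!id_col %in% names(data)) {
    abort(sprintf("domain data must contain an identifier column '%s'", id_col))
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids) > 0) {
    abort("duplicated twin ids in domain data")
  }
  feats <- data[setdiff(names(data), id_col)]
  if (ncol(feats) == 0L) abort("domain data has no feature columns")
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric feature columns: ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(feats)
  rownames(m) <- ids
  list(ids = ids, values = m, feature_names = colnames(m))
}

rebuild_domain <- function(ids, values, id_col = "twin_id") {
  out <- as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble(!!id_col := ids), out)
  out
}

# Sample sd over observed values, divisor n - 1.
col_sds <- function(m) apply(m, 2, sd, na.rm = TRUE)

check_fraction <- function(x, name, lo = 0, hi = 1,
                           open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (x > lo || (!open_lo && x == lo)) && (x < hi || (!open_hi && x == hi))
  if (!ok) abort(sprintf("`%s` must be a fraction in the valid range", name))
  invisible(x)
}
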