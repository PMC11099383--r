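# Shared input checks and TSV helpers.

stop_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "gpcraxes_schema_error")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema("%s is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

check_prob <- function(p, what = "p-values") {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop_schema("%s must lie in [0, 1]; found %s",
                what, paste(utils::head(format(p[bad]), 3), collapse = ", "))
  }
  invisible(p)
}

# Split "a;b;c" annotation fields into character vectors.
split_terms <- function(x) {
  out <- stringr::str_split(dplyr::coalesce(x, ""), ";")
  lapply(out, function(v) {
    v <- stringr::str_trim(v)
    v[nzchar(v)]
  })
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  comment = "#", ...)
}

# All pipeline outputs are TSV with a leading commented header describing
# the columns, so stage outputs stay diff-able.
write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  readr::write_tsv(df, con)
  invisible(path)
}
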