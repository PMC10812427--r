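# Internal helpers shared across modules.

GO_ID_PATTERN <- "^GO:\\d{7}$"

#' @noRd
is_go_id <- function(x) grepl(GO_ID_PATTERN, x)

# Split a multi-valued TSV field on ";" or ",", trim whitespace, strip any
# bracketed descriptive text ("GO:0005886 [plasma membrane]" -> "GO:0005886").
#' @noRd
split_multi <- function(x) {
  if (is.na(x) || !nzchar(str_trim(x))) return(character(0))
  parts <- unlist(strsplit(x, "[;,]"))
  parts <- sub("\\[[^]]*\\]", "", parts)
  parts <- str_trim(parts)
  parts[nzchar(parts)]
}

#' @noRd
join_multi <- function(x) {
  if (length(x) == 0) return("")
  paste(x, collapse = ";")
}

# "-" and empty strings encode absent values in printed tables and TSV fields.
#' @noRd
na_if_blank <- function(x) {
  x <- str_trim(x)
  ifelse(is.na(x) | x == "" | x == "-", NA_character_, x)
}

#' @noRd
check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "File '%s' is missing required column(s): %s",
        path, paste(missing, collapse = ", ")
      ),
      class = "surfscreen_format_error"
    )
  }
  invisible(df)
}

#' @noRd
check_go_ids <- function(ids, where) {
  bad <- ids[!is_go_id(ids)]
  if (length(bad) > 0) {
    abort(
      sprintf(
        "Invalid GO ID(s) in %s: %s (expected 'GO:' followed by 7 digits)",
        where, paste(unique(bad), collapse = ", ")
      ),
      class = "surfscreen_format_error"
    )
  }
  invisible(ids)
}

#' @noRd
integrity_abort <- function(msg) abort(msg, class = "surfscreen_integrity_error")

#' @noRd
read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
random_protein <- function(n) {
  paste(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}
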