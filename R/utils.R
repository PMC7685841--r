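#' Write a numeric matrix as TSV with row names in the first column
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param rowname_col header for the row-name column.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, rowname_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- rowname_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV file with a header row and row names in the first column.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

write_df_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_df_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Derive a per-stage seed from a master seed
#'
#' One master seed deterministically spawns stage seeds so that individual
#' stages can be re-run (or skipped) reproducibly.
#'
#' @param seed master seed (integer).
#' @param stage stage index or name.
#' @return an integer seed < 2^31.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.double(seed) * 7919 + as.double(stage) * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
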