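# plain-text writers shared across modules; fixed options keep outputs
# byte-identical across runs
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

writeMatrixTsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  writeTsv(df, path)
}

readMatrixTsv <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  m
}

#' Percentage share, as printed in summary reports
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 0).
#' @return Numeric percentage, rounded.
#' @examples
#' percentShare(337, 449)  # 75
#' percentShare(23, 112)   # 21
#' @export
percentShare <- function(k, n, digits = 0) {
  if (n <= 0) stop("denominator must be positive")
  round(100 * k / n, digits)
}
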