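#' Harmonic-number coefficients
#'
#' \code{a1(n)} is the (n-1)-th harmonic number and \code{a2(n)} the
#' corresponding sum of inverse squares; both appear throughout the
#' segregating-sites theory (Watterson's estimator, Tajima's D, the HKA
#' variances).
#'
#' @param n sample size (number of sequences), n >= 2.
#' @return a numeric scalar.
#' @export
harmonic_a1 <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

#' @rdname harmonic_a1
#' @export
harmonic_a2 <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1)^2)
}

# strict scalar checks used by the public entry points
.check_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name))
  as.integer(x)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
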