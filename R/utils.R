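#' @importFrom stats median plogis quantile rbinom rlnorm rmultinom rnorm
#'   rpois runif setNames
#' @importFrom utils read.table write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a character vector of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()]. `N` is
#' preserved; input must be uppercase ACGTN.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

# all substrings of length k starting at 1..(nchar(x)-k+1)
chop_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

assert_scalar_chr <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single string", name), call. = FALSE)
  }
}
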