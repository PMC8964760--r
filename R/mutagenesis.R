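#' In-silico saturation-mutagenesis importance track
#'
#' For a target donor site, substitutes each of A, C, G, T at every
#' position of an analysis window and rescores the site. The importance
#' of a position is
#' `s_actual - (s_A + s_C + s_G + s_T) / 4`,
#' where `s_actual` is the score on the unmodified sequence and `s_X` the
#' score with base X substituted at that position (one of the four always
#' equals `s_actual`). Positive importance means the genuine base
#' contributes strength the average substitution would remove.
#'
#' The shipped default scorer is [df_scorer()]; any scorer meeting the
#' contract (e.g. a deep-learning splice model wrapped externally) can be
#' substituted, and substitutions the scorer cannot score (for instance a
#' destroyed GT/GC under a scorer defined only for essential
#' dinucleotides) take the scorer's floor, flagged in the output.
#'
#' @param genome a `dw_genome`.
#' @param contig,strand,donor_pos the target site's location (`donor_pos`
#'   = genomic coordinate of its D+1).
#' @param scorer a scorer function over 12-nt windows.
#' @param flank positions analysed each side of the E-4..D+8 window
#'   (default 20 nt).
#' @return data.frame, one row per analysed position: `position` (signed
#'   offset from the target's D+1), `base_actual`, `s_A`, `s_C`, `s_G`,
#'   `s_T`, `importance`, `floored` (TRUE when any substitution fell back
#'   to the scorer floor).
#' @export
importance_scores <- function(genome, contig, donor_pos, strand, scorer,
                              flank = 20L) {
  floor_ <- attr(scorer, "floor") %||% 0
  jn <- list(contig = contig, strand = strand, donor_pos = donor_pos)
  lo <- -4L - flank; hi <- 7L + flank
  reg <- junction_region(genome, jn, lo, hi)
  win_at <- function(seq) {
    i <- -4L - reg$lo + 1L
    substring(seq, i, i + 11L)
  }
  s_actual <- scorer(win_at(reg$seq))
  bases <- c("A", "C", "G", "T")
  positions <- seq(max(lo, reg$lo), min(hi, reg$hi))
  rows <- lapply(positions, function(p) {
    i <- p - reg$lo + 1L
    actual <- substring(reg$seq, i, i)
    sc <- vapply(bases, function(b) {
      s <- reg$seq
      substr(s, i, i) <- b
      if (b == actual) return(s_actual)
      v <- tryCatch(scorer(win_at(s)), error = function(e) NA_real_)
      if (is.na(v)) floor_ else v
    }, numeric(1))
    floored <- any(vapply(bases, function(b) {
      if (b == actual) return(FALSE)
      s <- reg$seq; substr(s, i, i) <- b
      is.na(tryCatch(scorer(win_at(s)), error = function(e) NA_real_))
    }, logical(1)))
    data.frame(position = p, base_actual = actual,
               s_A = sc[["A"]], s_C = sc[["C"]], s_G = sc[["G"]],
               s_T = sc[["T"]],
               importance = s_actual - mean(sc), floored = floored,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
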