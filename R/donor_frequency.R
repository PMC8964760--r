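#' Build a Donor Frequency index from annotated donors
#'
#' Donor Frequency (DF) measures donor strength by how many annotated
#' donors carry the exact same sequence. The 12-nt extended window
#' (E-4..D+8) of every index donor is cut into four consecutive 9-nt
#' windows (positions 1-9, 2-10, 3-11, 4-12); each window position gets a
#' count table of 9-mers over all index donors. A donor's raw score is the
#' median of its four positional counts, and scores are reported as the
#' percentile of that median on the empirical distribution over the index.
#'
#' @param junctions junction data.frame from [enumerate_junctions()], or
#'   any data.frame with `contig`, `strand`, `donor_pos`.
#' @param genome a `dw_genome`.
#' @param window_length length of each positional window (default 9 nt; 9
#'   was found to best encompass the splice site).
#' @return a `df_index`: list with `window_tables` (list of named integer
#'   count vectors, one per window position), `median_distribution`
#'   (sorted per-donor median raw counts), `n_donors`, `window_length`.
#' @export
build_df_index <- function(junctions, genome, window_length = 9L) {
  if (nrow(junctions) == 0L) {
    stop("cannot build a DF index from an empty junction set", call. = FALSE)
  }
  n_win <- 12L - window_length + 1L
  wins <- character(nrow(junctions))
  for (ctg in unique(junctions$contig)) {
    for (std in unique(junctions$strand)) {
      sel <- junctions$contig == ctg & junctions$strand == std
      if (!any(sel)) next
      dw <- donor_window(genome, ctg, junctions$donor_pos[sel], std)
      if (any(dw$truncated)) {
        stop("DF index requires untruncated 12-nt donor windows",
             call. = FALSE)
      }
      wins[sel] <- dw$window
    }
  }
  if (any(grepl("N", wins, fixed = TRUE))) {
    stop("DF index windows must not contain N", call. = FALSE)
  }
  window_tables <- vector("list", n_win)
  counts <- matrix(0L, nrow = length(wins), ncol = n_win)
  for (w in seq_len(n_win)) {
    km <- substring(wins, w, w + window_length - 1L)
    tab <- table(km)
    window_tables[[w]] <- setNames(as.integer(tab), names(tab))
    counts[, w] <- window_tables[[w]][km]
  }
  medians <- apply(counts, 1L, median)
  structure(
    list(window_tables = window_tables,
         median_distribution = sort(medians),
         n_donors = length(wins),
         window_length = as.integer(window_length)),
    class = "df_index"
  )
}

#' @export
print.df_index <- function(x, ...) {
  cat(sprintf("DF index: %d donors, %d positional %d-mer tables\n",
              x$n_donors, length(x$window_tables), x$window_length))
  invisible(x)
}

#' Score donor windows against a DF index
#'
#' For each query 12-nt window, looks up its four positional 9-mers in the
#' index tables (unseen 9-mers count 0), takes the median (mean of the two
#' middle values), and converts it to a percentile: the fraction of index
#' donors whose median raw count is less than or equal to the query's.
#' A window absent from the index everywhere scores percentile 0; every
#' index donor scores > 0 against its own index.
#'
#' @param window character vector of 12-nt windows (uppercase ACGT).
#' @param index a `df_index`.
#' @return data.frame with `raw_counts` (list column of the four counts),
#'   `median_raw`, `percentile` in \[0, 1\], and `undefined` (TRUE when the
#'   window contains N or is not 12 nt; such rows have NA scores,
#'   distinguishable from a genuine 0).
#' @export
df_score <- function(window, index) {
  stopifnot(inherits(index, "df_index"))
  n_win <- length(index$window_tables)
  wl <- index$window_length
  undefined <- nchar(window) != 12L | grepl("[^ACGT]", window)
  cnt <- matrix(0, nrow = length(window), ncol = n_win)
  for (w in seq_len(n_win)) {
    km <- substring(window, w, w + wl - 1L)
    v <- index$window_tables[[w]][km]
    v[is.na(v)] <- 0L
    cnt[, w] <- v
  }
  med <- apply(cnt, 1L, median)
  pct <- findInterval(med, index$median_distribution) / index$n_donors
  med[undefined] <- NA_real_
  pct[undefined] <- NA_real_
  out <- data.frame(median_raw = med, percentile = pct,
                    undefined = undefined)
  out$raw_counts <- lapply(seq_len(nrow(cnt)), function(i) cnt[i, ])
  out
}

#' Relative Donor Frequency of a decoy versus its annotated donor
#'
#' A decoy is *competitive* when its DF percentile is at least 10% of the
#' nearby annotated donor's (boundary inclusive).
#'
#' @param decoy_percentile,annotated_percentile DF percentiles in \[0, 1\]
#'   (vectorised; recycled).
#' @param threshold competitiveness threshold on the ratio (default 0.1).
#' @return data.frame with `ratio`, `competitive`, and `undefined` (TRUE
#'   where the annotated percentile is 0 or either score is NA, in which
#'   case ratio and flag are NA).
#' @export
relative_df <- function(decoy_percentile, annotated_percentile,
                        threshold = 0.1) {
  n <- max(length(decoy_percentile), length(annotated_percentile))
  d <- rep_len(decoy_percentile, n)
  a <- rep_len(annotated_percentile, n)
  undefined <- is.na(d) | is.na(a) | a == 0
  ratio <- ifelse(undefined, NA_real_, d / a)
  data.frame(ratio = ratio,
             competitive = ifelse(undefined, NA, ratio >= threshold),
             undefined = undefined)
}

#' A DF scorer satisfying the scorer contract
#'
#' Wraps a DF index as a scorer: a function mapping a character vector of
#' 12-nt windows to scores in \[0, 1\] (the DF percentile). Windows whose
#' D+1/D+2 (positions 5-6) are not GT/GC score the floor (0): the measure
#' is only defined for sites carrying an essential donor dinucleotide.
#' Undefined windows (N, wrong length) also score the floor.
#'
#' @param index a `df_index`.
#' @return a function `(windows) -> numeric`, with attributes `floor` (0)
#'   and `label` ("DF").
#' @export
df_scorer <- function(index) {
  force(index)
  f <- function(windows) {
    s <- df_score(windows, index)$percentile
    ess <- substring(windows, 5L, 6L) %in% c("GT", "GC")
    s[!ess | is.na(s)] <- 0
    s
  }
  attr(f, "floor") <- 0
  attr(f, "label") <- "DF"
  f
}

#' Write a DF index to a TSV file
#'
#' Format: one `window_idx<TAB>ninemer<TAB>count` row per table entry,
#' followed by a `#MEDIANS` section with the sorted per-donor medians.
#' `.gz` paths are compressed transparently.
#'
#' @param index a `df_index`.
#' @param path output path.
#' @export
write_df_index <- function(index, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#WINDOW_LENGTH\t%d", index$window_length), con)
  for (w in seq_along(index$window_tables)) {
    tab <- index$window_tables[[w]]
    if (length(tab)) {
      writeLines(sprintf("%d\t%s\t%d", w - 1L, names(tab), tab), con)
    }
  }
  writeLines("#MEDIANS", con)
  writeLines(format(index$median_distribution, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Read a DF index written by [write_df_index()]
#' @param path index file path.
#' @return a `df_index`.
#' @export
read_df_index <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  wl <- 9L
  if (startsWith(lines[1], "#WINDOW_LENGTH")) {
    wl <- as.integer(strsplit(lines[1], "\t")[[1]][2])
    lines <- lines[-1]
  }
  sep <- which(lines == "#MEDIANS")
  if (length(sep) != 1L) stop("malformed DF index: no #MEDIANS section",
                              call. = FALSE)
  body <- lines[seq_len(sep - 1L)]
  meds <- as.numeric(lines[-seq_len(sep)])
  parts <- strsplit(body, "\t", fixed = TRUE)
  widx <- vapply(parts, `[[`, character(1), 1L)
  kmer <- vapply(parts, `[[`, character(1), 2L)
  cnt <- as.integer(vapply(parts, `[[`, character(1), 3L))
  n_win <- 12L - wl + 1L
  window_tables <- lapply(seq_len(n_win) - 1L, function(w) {
    sel <- widx == as.character(w)
    setNames(cnt[sel], kmer[sel])
  })
  structure(list(window_tables = window_tables,
                 median_distribution = sort(meds),
                 n_donors = length(meds), window_length = wl),
            class = "df_index")
}
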