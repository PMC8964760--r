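#' Dinucleotide-preserving (Euler) shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide multiset
#' (and therefore also its mononucleotide composition, length, and first
#' and last characters). The sequence is viewed as an Eulerian path on the
#' transition multigraph (vertices = characters, edges = adjacent pairs);
#' a uniformly random out-edge ordering is drawn for every vertex and
#' accepted when the vertices' last edges form an arborescence into the
#' final character, which by the BEST-theorem correspondence makes the
#' resulting walk uniform over all valid arrangements.
#'
#' @param seq a single string (length < 2 is returned unchanged).
#' @param seed optional integer seed; when given, the shuffle consumes a
#'   private RNG stream and leaves the global RNG untouched.
#' @return the shuffled string.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  if (nchar(seq) < 2L) return(seq)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(x)
  verts <- unique(x)
  final <- x[n]
  out_edges <- split(x[-1], factor(x[-n], levels = verts))

  repeat {
    perm <- lapply(out_edges, function(e) if (length(e) > 1L) sample(e) else e)
    last_edge <- setNames(rep(NA_character_, length(verts)), verts)
    for (v in verts) {
      e <- perm[[v]]
      if (length(e)) last_edge[v] <- e[length(e)]
    }
    ok <- TRUE
    status <- setNames(rep(0L, length(verts)), verts)
    status[final] <- 1L
    for (v in verts) {
      path <- character(0); w <- v
      while (status[w] == 0L && !is.na(last_edge[w]) && !(w %in% path)) {
        path <- c(path, w); w <- last_edge[w]
      }
      if (status[w] == 1L) { status[path] <- 1L } else { ok <- FALSE; break }
    }
    if (ok) break
  }
  # walk the Eulerian path in the accepted edge order
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- x[1]
  v <- x[1]
  for (i in 2:n) {
    nxt <- perm[[v]][ptr[v]]
    ptr[v] <- ptr[v] + 1L
    res[i] <- nxt
    v <- nxt
  }
  paste(res, collapse = "")
}

#' Shuffle/depletion analysis configuration
#'
#' @param n_shuffles number of independent shuffles averaged into the
#'   expected counts (default 15).
#' @param seed integer seed for the shuffle RNG stream.
#' @param exon_extent exonic analysis extent in nt (clipped per junction
#'   to the exon length).
#' @param intron_extent intronic analysis extent in nt (clipped per
#'   junction to `intron_length - acceptor_buffer`).
#' @param acceptor_buffer intronic nucleotides left untouched upstream of
#'   the acceptor (default 50).
#' @param min_intron decoys whose use would leave an intron shorter than
#'   this are outside the counting domain (default 80 nt).
#' @return a `dw_shuffle_config` list.
#' @export
shuffle_config <- function(n_shuffles = 15L, seed = 1L,
                           exon_extent = 150L, intron_extent = 150L,
                           acceptor_buffer = 50L, min_intron = 80L) {
  stopifnot(n_shuffles >= 1L, exon_extent >= 0L, intron_extent >= 0L)
  structure(list(n_shuffles = as.integer(n_shuffles),
                 seed = as.integer(seed),
                 exon_extent = as.integer(exon_extent),
                 intron_extent = as.integer(intron_extent),
                 acceptor_buffer = as.integer(acceptor_buffer),
                 min_intron = as.integer(min_intron)),
            class = "dw_shuffle_config")
}

# analysis extents for one junction: exon offsets -Lx..-1, intron offsets
# 0..Li-1 (offset 0 = D+1)
segment_extents <- function(junction, config) {
  Lx <- min(config$exon_extent, junction$exon_length)
  Li <- max(0L, min(config$intron_extent,
                    junction$intron_length - config$acceptor_buffer))
  list(Lx = Lx, Li = Li)
}

# offsets at which decoys are counted for this junction: excludes the
# annotated donor (0) and intronic offsets violating the min-intron rule;
# identical for real and shuffled sequence so O/E is like-for-like
countable_offsets <- function(junction, config) {
  ext <- segment_extents(junction, config)
  hi <- min(ext$Li - 1L, junction$intron_length - config$min_intron)
  c(if (ext$Lx >= 2L) seq(-ext$Lx, -1L) else integer(0),
    if (hi >= 1L) seq(1L, hi) else integer(0))
}

# oriented sequence around the donor with the exon/intron analysis
# segments optionally replaced by shuffles; returns list(seq, lo)
composite_region <- function(junction, genome, config, shuffle = FALSE) {
  ext <- segment_extents(junction, config)
  reg <- junction_region(genome, junction, -ext$Lx - 12L, ext$Li + 12L)
  if (!shuffle) return(reg)
  s <- reg$seq
  idx <- function(o) o - reg$lo + 1L
  if (ext$Lx >= 2L) {
    i1 <- idx(-ext$Lx); i2 <- idx(-1L)
    substr(s, i1, i2) <- dinucleotide_shuffle(substring(s, i1, i2))
  }
  if (ext$Li >= 2L) {
    i1 <- idx(0L); i2 <- idx(ext$Li - 1L)
    substr(s, i1, i2) <- dinucleotide_shuffle(substring(s, i1, i2))
  }
  list(seq = s, lo = reg$lo, hi = reg$hi)
}

# one row per GT/GC decoy in `region` at the countable offsets, with
# stratum labels; ann_pct = DF percentile of the (real) annotated donor
decoy_stratum_table <- function(region, offsets_dom, junction,
                                index = NULL, ann_pct = NA_real_) {
  ch <- strsplit(region$seq, "", fixed = TRUE)[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  offs <- region$lo + seq_along(di) - 1L
  sel <- di %in% c("GT", "GC") & offs %in% offsets_dom
  offs <- offs[sel]; dinuc <- di[sel]
  if (!length(offs)) {
    return(data.frame(offset = integer(0), dinuc = character(0),
                      frame = character(0), df_bin = character(0),
                      g_triplet = character(0), stringsAsFactors = FALSE))
  }
  frame <- ifelse(offs < 0L & abs(offs) %% 3L == 0L, "in", "out")
  # windows for DF / G-triplet strata
  i1 <- offs - 4L - region$lo + 1L
  i2 <- offs + 7L - region$lo + 1L
  okw <- i1 >= 1L & i2 <= nchar(region$seq)
  win <- rep(NA_character_, length(offs))
  win[okw] <- substring(region$seq, i1[okw], i2[okw])
  df_bin <- rep(NA_character_, length(offs))
  if (!is.null(index)) {
    pct <- rep(NA_real_, length(offs))
    pct[okw] <- df_score(win[okw], index)$percentile
    rel <- relative_df(pct, ann_pct)
    df_bin <- cut(rel$ratio, c(-Inf, 0, 0.1, 0.5, 0.9, Inf),
                  labels = c("0", "(0,0.1)", "[0.1,0.5)", "[0.5,0.9)",
                             ">=0.9"),
                  right = FALSE)
    df_bin <- as.character(df_bin)
    df_bin[!is.na(pct) & pct == 0] <- "0"
  }
  g3 <- gregexpr("G{3,}", region$seq)[[1]]
  g3_overlap <- rep(FALSE, length(offs))
  if (g3[1] != -1L) {
    run_lo <- region$lo + as.integer(g3) - 1L
    run_hi <- run_lo + attr(g3, "match.length") - 1L
    for (r in seq_along(run_lo)) {
      g3_overlap <- g3_overlap | (run_lo[r] <= offs + 7L &
                                    run_hi[r] >= offs - 4L)
    }
  }
  data.frame(offset = offs, dinuc = dinuc, frame = frame,
             df_bin = df_bin, g_triplet = ifelse(g3_overlap, "yes", "no"),
             stringsAsFactors = FALSE)
}

#' Expected decoy counts from dinucleotide-preserving shuffles
#'
#' For each junction the exonic and intronic analysis segments are
#' shuffled independently `n_shuffles` times; decoys are counted per
#' signed offset on each shuffle, and the expected count is the mean over
#' shuffles, summed across junctions.
#'
#' @param junctions junction data.frame.
#' @param genome a `dw_genome`.
#' @param config a [shuffle_config()].
#' @return data.frame `offset`, `dinuc`, `expected`.
#' @export
expected_decoy_counts <- function(junctions, genome,
                                  config = shuffle_config()) {
  stopifnot(nrow(junctions) >= 1L)
  dc <- depletion_curve(junctions, genome, config, stratify = character(0))
  dc[, c("offset", "dinuc", "expected")]
}

#' Observed/expected decoy-donor depletion curves
#'
#' Observed decoy counts per signed offset on the real sequence are
#' compared with the mean count over dinucleotide-preserving shuffles of
#' the same exonic and intronic segments. Counts can be stratified by
#' reading frame (exonic in-frame vs out-of-frame/intronic), relative-DF
#' bin (decoy DF / annotated DF: 0, (0,0.1), \[0.1,0.5), \[0.5,0.9),
#' >=0.9), and G-triplet overlap; the GT/GC dinucleotide stratum is always
#' present. Strata of shuffled decoys are computed from the shuffled
#' sequence's own windows, so each stratum carries a self-consistent null.
#'
#' @inheritParams expected_decoy_counts
#' @param index optional `df_index`, required for `"df"` stratification.
#' @param stratify character subset of `c("frame", "df", "g3")`.
#' @return long data.frame: `offset`, `dinuc`, stratum columns,
#'   `observed`, `expected`, `oe` (`NA` where expected is 0).
#' @export
depletion_curve <- function(junctions, genome, config = shuffle_config(),
                            index = NULL, stratify = c("frame")) {
  stopifnot(nrow(junctions) >= 1L)
  if ("df" %in% stratify && is.null(index)) {
    stop("DF stratification requires a df_index", call. = FALSE)
  }
  set.seed(config$seed)
  keys <- c("offset", "dinuc",
            if ("frame" %in% stratify) "frame",
            if ("df" %in% stratify) "df_bin",
            if ("g3" %in% stratify) "g_triplet")
  obs_list <- vector("list", nrow(junctions))
  exp_list <- vector("list", nrow(junctions) * config$n_shuffles)
  for (j in seq_len(nrow(junctions))) {
    jn <- as.list(junctions[j, ])
    dom <- countable_offsets(jn, config)
    if (!length(dom)) next
    ann_pct <- NA_real_
    if ("df" %in% stratify) {
      aw <- donor_window(genome, jn$contig, jn$donor_pos, jn$strand)
      ann_pct <- df_score(aw$window, index)$percentile
    }
    real <- composite_region(jn, genome, config, shuffle = FALSE)
    obs_list[[j]] <- decoy_stratum_table(real, dom, jn, index, ann_pct)
    for (s in seq_len(config$n_shuffles)) {
      shuf <- composite_region(jn, genome, config, shuffle = TRUE)
      exp_list[[(j - 1L) * config$n_shuffles + s]] <-
        decoy_stratum_table(shuf, dom, jn, index, ann_pct)
    }
  }
  obs <- do.call(rbind, obs_list)
  exp_ <- do.call(rbind, exp_list)
  count_by <- function(d) {
    if (is.null(d) || nrow(d) == 0L) {
      out <- data.frame(offset = integer(0), dinuc = character(0),
                        frame = character(0), df_bin = character(0),
                        g_triplet = character(0),
                        stringsAsFactors = FALSE)[, keys, drop = FALSE]
      out$n <- integer(0)
      return(out)
    }
    k <- d[, keys, drop = FALSE]
    k[is.na(k)] <- "NA"
    stats::aggregate(list(n = rep(1L, nrow(k))), by = k, FUN = sum)
  }
  co <- count_by(obs)
  ce <- count_by(exp_)
  names(co)[names(co) == "n"] <- "observed"
  names(ce)[names(ce) == "n"] <- "expected_total"
  m <- merge(co, ce, by = keys, all = TRUE)
  m$observed[is.na(m$observed)] <- 0L
  m$expected_total[is.na(m$expected_total)] <- 0L
  m$expected <- m$expected_total / config$n_shuffles
  m$expected_total <- NULL
  m$oe <- ifelse(m$expected > 0, m$observed / m$expected, NA_real_)
  m <- m[order(m$offset), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Positional nucleotide and dinucleotide profiles around donors
#'
#' Frequencies of each base (and each dinucleotide starting at the
#' position) at every signed offset around the annotated donors, over the
#' supplied junctions. Only junctions whose exon/intron actually covers an
#' offset contribute to it; frequencies at each position sum to 1.
#'
#' @inheritParams expected_decoy_counts
#' @param extent profile half-width in nt.
#' @param groups optional factor (one value per junction) splitting the
#'   profile, e.g. by intron-length quantile, D+3 base, or annotated-DF
#'   quantile.
#' @return list with data.frames `mono` (`group`, `offset`, `base`,
#'   `freq`) and `di` (`group`, `offset`, `dinuc`, `freq`).
#' @export
positional_profile <- function(junctions, genome, extent = 150L,
                               groups = NULL) {
  stopifnot(nrow(junctions) >= 1L)
  if (is.null(groups)) groups <- rep("all", nrow(junctions))
  groups <- as.character(groups)
  rows_m <- list(); rows_d <- list()
  for (g in unique(groups)) {
    js <- junctions[groups == g, , drop = FALSE]
    mono <- list(); di <- list()
    for (j in seq_len(nrow(js))) {
      jn <- as.list(js[j, ])
      lo <- max(-extent, -jn$exon_length)
      hi <- min(extent, jn$intron_length) - 1L
      reg <- junction_region(genome, jn, lo, hi)
      ch <- strsplit(reg$seq, "", fixed = TRUE)[[1]]
      offs <- reg$lo + seq_along(ch) - 1L
      mono[[j]] <- data.frame(offset = offs, sym = ch)
      if (length(ch) > 1L) {
        di[[j]] <- data.frame(offset = offs[-length(offs)],
                              sym = paste0(ch[-length(ch)], ch[-1]))
      }
    }
    freq_table <- function(d) {
      tab <- table(d$offset, d$sym)
      f <- prop.table(tab, margin = 1L)
      df <- as.data.frame(f, stringsAsFactors = FALSE)
      names(df) <- c("offset", "sym", "freq")
      df$offset <- as.integer(df$offset)
      df
    }
    fm <- freq_table(do.call(rbind, mono)); fm$group <- g
    fd <- freq_table(do.call(rbind, di)); fd$group <- g
    rows_m[[g]] <- fm; rows_d[[g]] <- fd
  }
  mono <- do.call(rbind, rows_m); rownames(mono) <- NULL
  di <- do.call(rbind, rows_d); rownames(di) <- NULL
  names(mono)[names(mono) == "sym"] <- "base"
  names(di)[names(di) == "sym"] <- "dinuc"
  list(mono = mono[, c("group", "offset", "base", "freq")],
       di = di[, c("group", "offset", "dinuc", "freq")])
}
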