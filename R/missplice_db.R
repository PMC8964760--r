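#' Read one per-sample splice-junction file
#'
#' Two dialects are supported. `star_sj` is the STAR `SJ.out.tab` layout
#' (contig, 1-based first intronic base, 1-based last intronic base,
#' strand code 0/1/2, motif, annotated flag, unique reads, multimapping
#' reads, max overhang): the unique-read count is used, rows with 0 unique
#' reads are dropped, strand codes map 1 to `+` and 2 to `-`, and
#' undetermined-strand rows (code 0) are dropped with a warning. `tsv` is
#' a headered table `chrom`, `start`, `end`, `strand`, `reads` with the
#' same coordinate convention.
#'
#' @param path path to the junction file.
#' @param dialect `"star_sj"` or `"tsv"`.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return a `sample_junctions` list: `sample_id` plus a data.frame
#'   `junctions` (`contig`, `start`, `end`, `strand`, `reads`).
#' @export
read_junction_file <- function(path, dialect = c("star_sj", "tsv"),
                               sample_id = NULL) {
  dialect <- match.arg(dialect)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "star_sj") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    f <- strsplit(lines, "[\t ]+")
    bad <- which(lengths(f) != 9L)
    if (length(bad)) {
      stop("STAR SJ file '", path, "': line ", bad[1], " has ",
           lengths(f)[bad[1]], " columns, expected 9", call. = FALSE)
    }
    d <- data.frame(
      contig = vapply(f, `[[`, character(1), 1L),
      start = as.integer(vapply(f, `[[`, character(1), 2L)),
      end = as.integer(vapply(f, `[[`, character(1), 3L)),
      strand_code = as.integer(vapply(f, `[[`, character(1), 4L)),
      reads = as.integer(vapply(f, `[[`, character(1), 7L)),
      stringsAsFactors = FALSE
    )
    d <- d[d$reads > 0L, , drop = FALSE]
    undet <- d$strand_code == 0L
    if (any(undet)) {
      warning(sum(undet), " undetermined-strand junction(s) dropped from ",
              basename(path), call. = FALSE)
      d <- d[!undet, , drop = FALSE]
    }
    d$strand <- c("+", "-")[d$strand_code]
    d <- d[, c("contig", "start", "end", "strand", "reads")]
  } else {
    d <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "strand", "reads")
    if (!all(need %in% names(d))) {
      stop("TSV junction file '", path, "' must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    d <- data.frame(contig = as.character(d$chrom),
                    start = as.integer(d$start), end = as.integer(d$end),
                    strand = as.character(d$strand),
                    reads = as.integer(d$reads), stringsAsFactors = FALSE)
    d <- d[d$reads > 0L, , drop = FALSE]
  }
  rownames(d) <- NULL
  structure(list(sample_id = sample_id, junctions = d),
            class = "sample_junctions")
}

#' Write a sample-junction set in the TSV dialect
#'
#' @param x a `sample_junctions` object.
#' @param path output path.
#' @export
write_junction_file <- function(x, path) {
  d <- x$junctions
  out <- data.frame(chrom = d$contig, start = d$start, end = d$end,
                    strand = d$strand, reads = d$reads)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate splice junctions across samples
#'
#' Read counts are summarised across all samples for each unique junction
#' key (contig, start, end, strand): the number of samples the junction
#' appears in, the total read count, and the largest count in any one
#' sample. Order of samples does not matter.
#'
#' @param samples list of `sample_junctions` objects.
#' @return data.frame: `contig`, `start`, `end`, `strand`,
#'   `sample_count`, `total_reads`, `max_reads`.
#' @export
aggregate_junctions <- function(samples) {
  stopifnot(length(samples) >= 1L)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ", ids[duplicated(ids)][1],
         " (would double-count)", call. = FALSE)
  }
  all <- do.call(rbind, lapply(samples, `[[`, "junctions"))
  key <- paste(all$contig, all$start, all$end, all$strand, sep = "\r")
  agg <- data.frame(
    key = names(tapply(all$reads, key, sum)),
    sample_count = as.integer(tapply(rep(1L, nrow(all)), key, sum)),
    total_reads = as.integer(tapply(all$reads, key, sum)),
    max_reads = as.integer(tapply(all$reads, key, max)),
    stringsAsFactors = FALSE
  )
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    contig = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[[`, character(1), 3L)),
    strand = vapply(parts, `[[`, character(1), 4L),
    sample_count = agg$sample_count,
    total_reads = agg$total_reads,
    max_reads = agg$max_reads,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Extract cryptic-donor mis-splicing events
#'
#' Keeps aggregated junctions that splice to an annotated junction's
#' acceptor exactly, from a donor that is not itself annotated, lies
#' between the 5' end of the exon and the 3' end of the intron, and sits
#' within `max_dist` nt of the annotated donor, in at least `min_samples`
#' samples. Offsets are signed distances from the annotated donor in
#' transcript orientation.
#'
#' @param aggregated data.frame from [aggregate_junctions()].
#' @param junctions annotated junction set from [enumerate_junctions()].
#' @param max_dist maximum |offset| (nt).
#' @param min_samples minimum number of supporting samples.
#' @return data.frame of events: `transcript_id`, `contig`, `strand`,
#'   `annotated_donor_pos`, `cryptic_donor_pos`, `offset`,
#'   `sample_count`, `total_reads`, `max_reads`.
#' @export
extract_cryptic_events <- function(aggregated, junctions,
                                   max_dist = 250L, min_samples = 3L) {
  annotated_donors <- paste(junctions$contig, junctions$strand,
                            junctions$donor_pos)
  rows <- list()
  for (j in seq_len(nrow(junctions))) {
    jn <- junctions[j, ]
    if (jn$strand == "+") {
      acc_side <- aggregated$end; don_side <- aggregated$start
    } else {
      acc_side <- aggregated$start; don_side <- aggregated$end
    }
    hit <- aggregated$contig == jn$contig &
      aggregated$strand == jn$strand &
      acc_side == jn$acceptor_pos
    if (!any(hit)) next
    cand <- aggregated[hit, , drop = FALSE]
    don <- don_side[hit]
    offset <- if (jn$strand == "+") don - jn$donor_pos
              else jn$donor_pos - don
    keep <- don != jn$donor_pos &
      !(paste(jn$contig, jn$strand, don) %in% annotated_donors) &
      offset >= -jn$exon_length &
      offset <= jn$intron_length - 1L &
      abs(offset) <= max_dist &
      cand$sample_count >= min_samples
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = jn$transcript_id, contig = jn$contig,
      strand = jn$strand, annotated_donor_pos = jn$donor_pos,
      cryptic_donor_pos = don[keep], offset = offset[keep],
      sample_count = cand$sample_count[keep],
      total_reads = cand$total_reads[keep],
      max_reads = cand$max_reads[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    transcript_id = character(0), contig = character(0),
    strand = character(0), annotated_donor_pos = integer(0),
    cryptic_donor_pos = integer(0), offset = integer(0),
    sample_count = integer(0), total_reads = integer(0),
    max_reads = integer(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Rank mis-splicing events within each annotated junction
#'
#' Events at one junction are ranked by descending sample count; ties
#' break by descending total reads, then by smaller |offset|, then exonic
#' (negative offset) before intronic, so top-k membership is
#' deterministic. Ranks are dense, 1..n per junction.
#'
#' @param events data.frame from [extract_cryptic_events()].
#' @return the same data.frame with a `rank` column, sorted by junction
#'   and rank.
#' @export
rank_events <- function(events) {
  if (nrow(events) == 0L) { events$rank <- integer(0); return(events) }
  grp <- paste(events$transcript_id, events$annotated_donor_pos)
  ord <- order(grp, -events$sample_count, -events$total_reads,
               abs(events$offset), events$offset >= 0L)
  events <- events[ord, , drop = FALSE]
  grp <- grp[ord]
  events$rank <- as.integer(stats::ave(seq_len(nrow(events)), grp,
                                       FUN = seq_along))
  rownames(events) <- NULL
  events
}

#' Build the ranked mis-splicing database
#'
#' End-to-end convenience wrapper: aggregate per-sample junction sets,
#' extract cryptic-donor events at the supplied annotated junctions, and
#' rank them.
#'
#' @param samples list of `sample_junctions`.
#' @inheritParams extract_cryptic_events
#' @return ranked event data.frame (see [rank_events()]).
#' @export
build_missplice_db <- function(samples, junctions, max_dist = 250L,
                               min_samples = 3L) {
  agg <- aggregate_junctions(samples)
  rank_events(extract_cryptic_events(agg, junctions,
                                     max_dist = max_dist,
                                     min_samples = min_samples))
}

#' Fraction of decoy donors present in the database, by offset
#'
#' For every enumerated decoy around the supplied junctions, checks
#' whether a matching event (same junction, same offset) exists in the
#' database, and reports per-offset (optionally per-stratum) presence
#' fractions: |decoys with an event| / |decoys|.
#'
#' @param db ranked event data.frame.
#' @param junctions annotated junction set.
#' @param genome a `dw_genome`.
#' @param index optional `df_index` for the relative-DF stratum.
#' @param stratify character subset of `c("df", "g3")`.
#' @param max_dist decoy enumeration distance.
#' @return data.frame: `offset`, stratum columns, `n_decoys`, `n_present`,
#'   `fraction`.
#' @export
presence_profile <- function(db, junctions, genome, index = NULL,
                             stratify = character(0), max_dist = 250L) {
  rows <- list()
  for (j in seq_len(nrow(junctions))) {
    jn <- as.list(junctions[j, ])
    dec <- enumerate_decoys(jn, genome, max_exonic = max_dist,
                            max_intronic = max_dist)
    if (nrow(dec) == 0L) next
    ev <- db[db$transcript_id == jn$transcript_id &
               db$annotated_donor_pos == jn$donor_pos, , drop = FALSE]
    dec$present <- dec$offset %in% ev$offset
    dec$df_bin <- NA_character_
    if ("df" %in% stratify) {
      if (is.null(index)) stop("df stratification requires an index",
                               call. = FALSE)
      aw <- donor_window(genome, jn$contig, jn$donor_pos, jn$strand)
      ann_pct <- df_score(aw$window, index)$percentile
      pct <- df_score(dec$window, index)$percentile
      rel <- relative_df(pct, ann_pct)
      dec$df_bin <- as.character(cut(rel$ratio,
                                     c(-Inf, 0, 0.1, 0.5, 0.9, Inf),
                                     labels = c("0", "(0,0.1)",
                                                "[0.1,0.5)", "[0.5,0.9)",
                                                ">=0.9"), right = FALSE))
    }
    rows[[length(rows) + 1L]] <- dec
  }
  dec <- do.call(rbind, rows)
  if (is.null(dec)) {
    return(data.frame(offset = integer(0), n_decoys = integer(0),
                      n_present = integer(0), fraction = numeric(0)))
  }
  keys <- c("offset", if ("df" %in% stratify) "df_bin",
            if ("g3" %in% stratify) "g_triplet_overlap")
  k <- dec[, keys, drop = FALSE]
  k[is.na(k)] <- "NA"
  agg <- stats::aggregate(list(n_decoys = rep(1L, nrow(k)),
                               n_present = as.integer(dec$present)),
                          by = k, FUN = sum)
  agg$fraction <- agg$n_present / agg$n_decoys
  agg[order(agg$offset), , drop = FALSE]
}
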