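#' Read a genome from a FASTA file
#'
#' Loads every FASTA record as one contig. Sequence is uppercased and any
#' character outside the A/C/G/T/N alphabet is mapped to N, so downstream
#' window extraction never sees IUPAC ambiguity codes.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a `dw_genome`: a named character vector, one element per contig,
#'   names taken from the first whitespace-delimited token of each header.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtR"), fa)
#' g <- read_genome(fa)
#' g[["chr1"]]  # "ACGTN"
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0L) stop("FASTA '", path, "' contains no records",
                             call. = FALSE)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  bad <- which(nm == "" | is.na(nm))
  if (length(bad)) {
    stop("malformed FASTA: record ", bad[1], " has an empty name",
         call. = FALSE)
  }
  genome <- setNames(unname(seqs), nm)
  class(genome) <- "dw_genome"
  genome
}

#' Extract a genomic subsequence with bounds checking
#'
#' @param genome a `dw_genome`.
#' @param contig contig name (exact match; no chr-aliasing).
#' @param start,end 1-based inclusive genomic coordinates.
#' @return the subsequence; length is always `end - start + 1`.
#' @export
genome_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) {
    stop("unknown contig: ", contig, call. = FALSE)
  }
  n <- nchar(genome[[contig]])
  if (any(start < 1L) || any(end > n) || any(end < start)) {
    stop(sprintf("coordinates [%s, %s] outside contig %s (length %d)",
                 min(start), max(end), contig, n), call. = FALSE)
  }
  substring(genome[[contig]], start, end)
}

#' Read transcript models from a GTF file
#'
#' Groups `exon` features by `transcript_id` and orders them in transcript
#' orientation (5' to 3'; for minus-strand transcripts the first exon is the
#' one with the highest genomic coordinate). `CDS` features, when present,
#' are unioned into a single genomic CDS span per transcript.
#'
#' @param path path to a GTF file (GTF2.2 attributes:
#'   `transcript_id "X"; gene_id "Y";`).
#' @return a `dw_transcripts` list; each element has `transcript_id`,
#'   `gene_id`, `contig`, `strand`, `exons` (two-column matrix of 1-based
#'   inclusive start/end, rows in transcript orientation) and `cds`
#'   (`c(start, end)` or `NULL`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stop("GTF '", path, "' has no exon features",
                             call. = FALSE)
  tid <- as.character(md$transcript_id)
  if (any(is.na(tid) | tid == "")) {
    stop("GTF record without transcript_id (feature ",
         which(is.na(tid) | tid == "")[1], ")", call. = FALSE)
  }
  gid <- as.character(md$gene_id %||% tid)
  gid[is.na(gid)] <- tid[is.na(gid)]
  df <- data.frame(
    transcript_id = tid, gene_id = gid,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    type = as.character(md$type), stringsAsFactors = FALSE
  )
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L) return(NULL)
    strand <- ex$strand[1]
    if (!strand %in% c("+", "-")) {
      stop("transcript ", d$transcript_id[1], " has no usable strand",
           call. = FALSE)
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", d$transcript_id[1],
           call. = FALSE)
    }
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    list(
      transcript_id = ex$transcript_id[1],
      gene_id = ex$gene_id[1],
      contig = ex$contig[1],
      strand = strand,
      exons = cbind(start = ex$start, end = ex$end),
      cds = if (nrow(cds)) c(min(cds$start), max(cds$end)) else NULL
    )
  })
  out <- out[!vapply(out, is.null, logical(1))]
  class(out) <- "dw_transcripts"
  out
}

# genomic coordinate of the base at signed offset `o` from the donor D+1,
# in transcript orientation (o = 0 is D+1, o = -1 is E-1)
offset_to_genomic <- function(donor_pos, strand, o) {
  donor_pos + ifelse(strand == "+", 1L, -1L) * o
}

#' Enumerate filtered exon-intron junctions
#'
#' Builds the set of canonical exon-intron junctions used as the reference
#' donor universe. Filters (each individually switchable):
#' single-exon transcripts are always excluded; `first_last` drops each
#' transcript's first and last intron; `orf` keeps only junctions whose
#' donor and paired acceptor both lie inside the transcript's CDS span
#' (transcripts without a CDS are dropped when this filter is on);
#' `alt_ends` drops junctions whose donor or acceptor exon overlaps an exon
#' with a different 5' or 3' boundary in another transcript of the same
#' gene; finally only junctions whose first two intronic bases are GT or GC
#' are retained.
#'
#' @param transcripts a `dw_transcripts` list from [read_annotation()].
#' @param genome a `dw_genome` (for the GT/GC check).
#' @param first_last,orf,alt_ends logical; apply the respective filter.
#' @return data.frame with one row per retained junction: `transcript_id`,
#'   `gene_id`, `contig`, `strand`, `donor_pos` (genomic coordinate of the
#'   first intronic base D+1), `acceptor_pos` (genomic coordinate of the
#'   last intronic base), `exon_length`, `intron_length`, `donor_dinuc`.
#'   A `filter_summary` attribute records how many junctions each filter
#'   dropped.
#' @export
enumerate_junctions <- function(transcripts, genome,
                                first_last = TRUE, orf = TRUE,
                                alt_ends = TRUE) {
  stopifnot(inherits(transcripts, "dw_transcripts"))
  rows <- list()
  summary <- c(single_exon = 0L, first_last = 0L, orf = 0L,
               alt_ends = 0L, not_gt_gc = 0L, retained = 0L)

  # gene -> set of exon intervals from all transcripts, for the alt-ends check
  all_ex <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               start = tx$exons[, "start"], end = tx$exons[, "end"],
               stringsAsFactors = FALSE)
  }))
  has_alt_boundary <- function(tx, ex_start, ex_end) {
    g <- all_ex[all_ex$gene_id == tx$gene_id &
                  all_ex$transcript_id != tx$transcript_id, , drop = FALSE]
    if (nrow(g) == 0L) return(FALSE)
    ov <- g$start <= ex_end & g$end >= ex_start
    any(ov & (g$start != ex_start | g$end != ex_end))
  }

  for (tx in transcripts) {
    ne <- nrow(tx$exons)
    if (ne < 2L) { summary["single_exon"] <- summary["single_exon"] + 1L; next }
    n_introns <- ne - 1L
    for (i in seq_len(n_introns)) {
      if (first_last && (i == 1L || i == n_introns)) {
        summary["first_last"] <- summary["first_last"] + 1L
        next
      }
      e1 <- tx$exons[i, ]; e2 <- tx$exons[i + 1L, ]
      if (tx$strand == "+") {
        donor_pos <- e1[["end"]] + 1L
        acceptor_pos <- e2[["start"]] - 1L
        intron_length <- acceptor_pos - donor_pos + 1L
      } else {
        donor_pos <- e1[["start"]] - 1L
        acceptor_pos <- e2[["end"]] + 1L
        intron_length <- donor_pos - acceptor_pos + 1L
      }
      if (intron_length < 1L) next
      if (orf) {
        if (is.null(tx$cds) ||
            min(donor_pos, acceptor_pos) < tx$cds[1] ||
            max(donor_pos, acceptor_pos) > tx$cds[2]) {
          summary["orf"] <- summary["orf"] + 1L
          next
        }
      }
      if (alt_ends &&
          (has_alt_boundary(tx, e1[["start"]], e1[["end"]]) ||
           has_alt_boundary(tx, e2[["start"]], e2[["end"]]))) {
        summary["alt_ends"] <- summary["alt_ends"] + 1L
        next
      }
      d2 <- sort(offset_to_genomic(donor_pos, tx$strand, c(0L, 1L)))
      dinuc <- genome_seq(genome, tx$contig, d2[1], d2[2])
      if (tx$strand == "-") dinuc <- revcomp(dinuc)
      if (!dinuc %in% c("GT", "GC")) {
        summary["not_gt_gc"] <- summary["not_gt_gc"] + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, gene_id = tx$gene_id,
        contig = tx$contig, strand = tx$strand,
        donor_pos = donor_pos, acceptor_pos = acceptor_pos,
        exon_length = e1[["end"]] - e1[["start"]] + 1L,
        intron_length = intron_length,
        donor_dinuc = dinuc, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    transcript_id = character(0), gene_id = character(0),
    contig = character(0), strand = character(0),
    donor_pos = integer(0), acceptor_pos = integer(0),
    exon_length = integer(0), intron_length = integer(0),
    donor_dinuc = character(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  summary["retained"] <- nrow(out)
  attr(out, "filter_summary") <- summary
  out
}

#' Extract the 12-nt extended donor window (E-4..D+8)
#'
#' The extended donor region runs from the fourth-to-last exonic base (E-4)
#' to the eighth intronic base (D+8): 4 exonic + 8 intronic nucleotides,
#' reported in transcript orientation (reverse-complemented on the minus
#' strand). Windows that run off a contig edge are clipped, not padded, and
#' flagged as truncated.
#'
#' @param genome a `dw_genome`.
#' @param contig,strand contig name and strand of the site.
#' @param donor_pos genomic coordinate of the site's D+1 (vectorised).
#' @return data.frame with columns `window` and `truncated`.
#' @export
donor_window <- function(genome, contig, donor_pos, strand) {
  n <- nchar(genome[[contig]])
  if (is.null(n)) stop("unknown contig: ", contig, call. = FALSE)
  plus <- identical(strand, "+")
  lo <- donor_pos - (if (plus) 4L else 7L)
  hi <- donor_pos + (if (plus) 7L else 4L)
  if (any(donor_pos < 1L | donor_pos > n)) {
    stop("donor position outside contig ", contig, call. = FALSE)
  }
  truncated <- lo < 1L | hi > n
  lo_c <- pmax(lo, 1L); hi_c <- pmin(hi, n)
  w <- substring(genome[[contig]], lo_c, hi_c)
  if (!plus) w <- revcomp(w)
  data.frame(window = w, truncated = truncated, stringsAsFactors = FALSE)
}

# oriented sequence around a junction's donor covering signed offsets
# [lo, hi] (clipped to the contig); returns seq plus the offset of its
# first character, so character i corresponds to offset lo_eff + i - 1
junction_region <- function(genome, junction, lo, hi) {
  g <- offset_to_genomic(junction$donor_pos, junction$strand, c(lo, hi))
  n <- nchar(genome[[junction$contig]])
  g1 <- max(min(g), 1L); g2 <- min(max(g), n)
  seq <- genome_seq(genome, junction$contig, g1, g2)
  if (junction$strand == "+") {
    lo_eff <- g1 - junction$donor_pos
  } else {
    seq <- revcomp(seq)
    lo_eff <- junction$donor_pos - g2
  }
  list(seq = seq, lo = lo_eff, hi = lo_eff + nchar(seq) - 1L)
}

#' Enumerate decoy donors around an annotated junction
#'
#' Scans for every GT/GC dinucleotide whose D+1 lies within
#' `[-min(max_exonic, exon_length), +min(max_intronic, intron_length)]` of
#' the annotated donor (offset 0 itself excluded), in transcript
#' orientation. Intronic decoys whose use would leave an intron shorter
#' than `min_intron` nucleotides (the 1st percentile of human intron
#' length, 80 nt) are removed. Offsets are signed distances between D+1
#' positions: negative = exonic/upstream, positive = intronic/downstream.
#'
#' @param junction one junction: a one-row data.frame or list with fields
#'   `contig`, `strand`, `donor_pos`, `exon_length`, `intron_length`.
#' @param genome a `dw_genome`.
#' @param max_exonic,max_intronic maximum scan distance into the exon and
#'   the intron, in nt.
#' @param min_intron smallest spliceable intron, in nt.
#' @return data.frame of donor sites: `offset`, `dinuc`, `window`,
#'   `truncated`, `kind` ("decoy"), `in_frame` (`|offset| %% 3 == 0`),
#'   `g_triplet_overlap` (a GGG run in the reference sequence intersects
#'   the site's 12-nt window).
#' @export
enumerate_decoys <- function(junction, genome,
                             max_exonic = 250L, max_intronic = 250L,
                             min_intron = 80L) {
  junction <- as.list(junction)
  lo <- -min(max_exonic, junction$exon_length)
  hi <- min(max_intronic, junction$intron_length)
  # +1 so the dinucleotide at offset hi is visible; +/- margin for windows
  reg <- junction_region(genome, junction, lo - 6L, hi + 9L)
  ch <- strsplit(reg$seq, "", fixed = TRUE)[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  offs <- reg$lo + seq_along(di) - 1L     # offset of each dinucleotide's D+1
  is_site <- di %in% c("GT", "GC") & offs >= lo & offs <= hi & offs != 0L
  offs_keep <- offs[is_site]
  dinuc_keep <- di[is_site]
  # intronic decoys leaving an intron shorter than min_intron
  ok <- !(offs_keep > 0L &
            junction$intron_length - offs_keep < min_intron)
  offs_keep <- offs_keep[ok]; dinuc_keep <- dinuc_keep[ok]
  if (length(offs_keep) == 0L) {
    return(data.frame(offset = integer(0), dinuc = character(0),
                      window = character(0), truncated = logical(0),
                      kind = character(0), in_frame = logical(0),
                      g_triplet_overlap = logical(0),
                      stringsAsFactors = FALSE))
  }
  d1 <- offset_to_genomic(junction$donor_pos, junction$strand, offs_keep)
  win <- donor_window(genome, junction$contig, d1, junction$strand)
  # G-triplet runs in the oriented reference sequence
  g3 <- gregexpr("G{3,}", reg$seq)[[1]]
  g3_overlap <- rep(FALSE, length(offs_keep))
  if (g3[1] != -1L) {
    run_lo <- reg$lo + as.integer(g3) - 1L
    run_hi <- run_lo + attr(g3, "match.length") - 1L
    w_lo <- offs_keep - 4L; w_hi <- offs_keep + 7L
    for (r in seq_along(run_lo)) {
      g3_overlap <- g3_overlap | (run_lo[r] <= w_hi & run_hi[r] >= w_lo)
    }
  }
  data.frame(
    offset = offs_keep, dinuc = dinuc_keep,
    window = win$window, truncated = win$truncated,
    kind = "decoy", in_frame = abs(offs_keep) %% 3L == 0L,
    g_triplet_overlap = g3_overlap, stringsAsFactors = FALSE
  )
}
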