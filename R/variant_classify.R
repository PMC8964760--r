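#' Read a variant table
#'
#' TSV columns: `contig`, `pos`, `ref`, `alt`, `transcript_id`,
#' `cryptic_offsets` (comma-separated signed offsets of observed activated
#' cryptic donors; may be empty). Alleles follow the VCF convention
#' (left-anchored, on the plus strand of the reference).
#'
#' @param path path to the TSV (with header).
#' @return data.frame with `cryptic_offsets` as a list column of integer
#'   vectors.
#' @export
read_variants <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "")
  need <- c("contig", "pos", "ref", "alt", "transcript_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$pos <- as.integer(df$pos)
  if (is.null(df$cryptic_offsets)) df$cryptic_offsets <- ""
  df$cryptic_offsets <- lapply(df$cryptic_offsets, function(x) {
    if (is.na(x) || x == "") integer(0)
    else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  df
}

#' Read the first five columns of a VCF as a variant table
#'
#' Convenience reader for VCF input; `transcript_id` is taken from the ID
#' column and `cryptic_offsets` is left empty. Multi-allelic records are
#' rejected.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return data.frame in the layout of [read_variants()].
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("VCF '", path, "' has no records",
                                call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 5L)
  if (length(bad)) stop("VCF line ", bad[1], " has fewer than 5 columns",
                        call. = FALSE)
  alt <- vapply(f, `[[`, character(1), 5L)
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic VCF records are not supported", call. = FALSE)
  }
  df <- data.frame(
    contig = vapply(f, `[[`, character(1), 1L),
    pos = as.integer(vapply(f, `[[`, character(1), 2L)),
    ref = vapply(f, `[[`, character(1), 4L),
    alt = alt,
    transcript_id = vapply(f, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  df$cryptic_offsets <- rep(list(integer(0)), nrow(df))
  df
}

#' Apply a variant to a sequence region
#'
#' Edits a plus-strand genomic region string with one variant and returns
#' the edited sequence together with a monotone coordinate map from REF to
#' VAR genomic positions. Deleted bases map to the left edge of the
#' deletion and are flagged.
#'
#' @param seq plus-strand region sequence.
#' @param region_start genomic coordinate of `seq`'s first base.
#' @param variant list/one-row data.frame with `pos`, `ref`, `alt`
#'   (VCF-style, plus strand).
#' @return list: `seq` (VAR sequence), `map(p)` (function mapping REF
#'   genomic positions to VAR positions in the same frame), `deleted(p)`
#'   (function flagging REF positions removed by the variant), `shift`
#'   (`nchar(alt) - nchar(ref)`).
#' @export
apply_variant <- function(seq, region_start, variant) {
  v <- as.list(variant)
  pos <- as.integer(v$pos)
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  nref <- nchar(ref); nalt <- nchar(alt)
  i <- pos - region_start + 1L
  if (i < 1L || i + nref - 1L > nchar(seq)) {
    stop("variant at ", pos, " lies outside the supplied region",
         call. = FALSE)
  }
  obs <- substring(seq, i, i + nref - 1L)
  if (obs != ref) {
    stop(sprintf("reference allele mismatch at %d: expected '%s', genome has '%s'",
                 pos, ref, obs), call. = FALSE)
  }
  var_seq <- paste0(substring(seq, 1L, i - 1L), alt,
                    substring(seq, i + nref, nchar(seq)))
  shift <- nalt - nref
  map <- function(p) {
    ifelse(p < pos, p,
           ifelse(p <= pos + nref - 1L,
                  pmin(p, pos + nalt - 1L),
                  p + shift))
  }
  deleted <- function(p) p >= pos + nalt & p <= pos + nref - 1L
  list(seq = var_seq, map = map, deleted = deleted, shift = shift)
}

# the set of reference bases actually changed by a left-anchored variant:
# list(type = "range", lo, hi) or list(type = "ins", left = p) for a pure
# insertion between p and p+1
variant_footprint <- function(variant) {
  v <- as.list(variant)
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  pos <- as.integer(v$pos)
  k <- 0L
  while (k < min(nchar(ref), nchar(alt)) &&
         substring(ref, k + 1L, k + 1L) == substring(alt, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  if (nchar(ref) == nchar(alt)) {
    # SNV/MNV: changed block (unanchored SNVs have k = 0)
    lo <- pos + k
    list(type = "range", lo = lo, hi = pos + nchar(ref) - 1L)
  } else if (nchar(ref) > nchar(alt)) {
    list(type = "range", lo = pos + k, hi = pos + nchar(ref) - 1L)
  } else {
    list(type = "ins", left = pos + k - 1L)
  }
}

# genomic interval [lo, hi] of the E-4..D+8 window of the site at signed
# `offset` from the junction's annotated donor
window_interval <- function(junction, offset = 0L) {
  d1 <- offset_to_genomic(junction$donor_pos, junction$strand, offset)
  if (junction$strand == "+") c(d1 - 4L, d1 + 7L) else c(d1 - 7L, d1 + 4L)
}

footprint_intersects <- function(fp, interval) {
  wlo <- interval[1]; whi <- interval[2]
  if (fp$type == "range") {
    fp$lo <= whi && fp$hi >= wlo
  } else {
    # an insertion point between left and left+1 is inside the window iff
    # both flanking bases are window bases
    fp$left >= wlo && fp$left <= whi - 1L
  }
}

#' Classify a variant as AM, CM or AM/CM
#'
#' Category is assigned from the intersection of the variant's reference
#' footprint with 12-nt extended donor windows: `AM` when it touches only
#' the annotated donor's E-4..D+8, `CM` when it touches only a cryptic
#' donor's, `AMCM` when it touches both, `excluded` when it touches
#' neither. Categories are mutually exclusive and exhaustive.
#'
#' @param variant list/one-row data.frame with `pos`, `ref`, `alt`.
#' @param junction the affected junction (list or one-row data.frame).
#' @param cryptic_offsets integer vector of observed activated cryptic
#'   offsets.
#' @return one of `"AM"`, `"CM"`, `"AMCM"`, `"excluded"`.
#' @export
classify_variant <- function(variant, junction, cryptic_offsets) {
  junction <- as.list(junction)
  fp <- variant_footprint(variant)
  am <- footprint_intersects(fp, window_interval(junction, 0L))
  cm <- any(vapply(cryptic_offsets, function(o) {
    footprint_intersects(fp, window_interval(junction, o))
  }, logical(1)))
  if (am && cm) "AMCM" else if (am) "AM" else if (cm) "CM" else "excluded"
}

#' Check a variant record against the database inclusion criteria
#'
#' A record is excluded when (a) the variant lies outside E-4..D+8 of both
#' the annotated donor and every observed cryptic donor; (b) an observed
#' cryptic donor lies outside the affected exon/intron (between the 5' end
#' of the exon and the 3' end of the intron); or (c) any cryptic VAR
#' window lacks an essential GT/GC at its D+1/D+2 (guarding against
#' misannotated variants).
#'
#' @inheritParams classify_variant
#' @param genome a `dw_genome`.
#' @return `"pass"`, or one of the reason codes `"outside_windows"`,
#'   `"cryptic_outside_region"`, `"no_var_essential_dinuc"`.
#' @export
validate_variant_record <- function(variant, junction, cryptic_offsets,
                                    genome) {
  junction <- as.list(junction)
  if (classify_variant(variant, junction, cryptic_offsets) == "excluded") {
    return("outside_windows")
  }
  lo <- -junction$exon_length
  hi <- junction$intron_length - 1L
  if (any(cryptic_offsets < lo | cryptic_offsets > hi)) {
    return("cryptic_outside_region")
  }
  if (length(cryptic_offsets)) {
    ctx <- build_variant_context(variant, junction, genome,
                                 cryptic_offsets = cryptic_offsets,
                                 include_decoys = FALSE)
    cr <- ctx$sites[ctx$sites$kind == "cryptic", , drop = FALSE]
    ess <- substring(cr$var_window, 5L, 6L)
    if (any(is.na(cr$var_window)) || any(!ess %in% c("GT", "GC"))) {
      return("no_var_essential_dinuc")
    }
  }
  "pass"
}

# 12-nt window at genomic D+1 position p, read from an arbitrary
# plus-strand region string (used for VAR sequence windows)
window_from_region <- function(seq, region_start, p, strand) {
  if (strand == "+") { lo <- p - 4L; hi <- p + 7L } else { lo <- p - 7L; hi <- p + 4L }
  i <- lo - region_start + 1L; j <- hi - region_start + 1L
  if (i < 1L || j > nchar(seq)) return(NA_character_)
  w <- substring(seq, i, j)
  if (strand == "-") w <- revcomp(w)
  w
}

#' Build the REF/VAR sequence context of a variant
#'
#' Extracts up to `max_dist` exonic and `max_dist` intronic nucleotides
#' around the annotated donor, applies the variant, and reports the
#' E-4..D+8 window before (REF) and after (VAR) the variant for the
#' annotated donor, every observed cryptic donor, and (optionally) every
#' enumerated decoy. Offsets of cryptic/decoy donors are recomputed on the
#' VAR sequence so indel-induced shifts are visible.
#'
#' @inheritParams validate_variant_record
#' @param max_dist scan distance into exon and intron (nt).
#' @param include_decoys also enumerate and window all decoy donors.
#' @return a `variant_context` list: `category`; `annotated` (data.frame
#'   with `ref_window`, `var_window`, `var_absent` — TRUE when the variant
#'   deletes the annotated D+1/D+2); `sites` (data.frame with `kind`
#'   cryptic/decoy, `offset_ref`, `offset_var`, `ref_window`,
#'   `var_window`, `modified`, `excluded_unmodified_cryptic` — TRUE for
#'   unmodified cryptics co-activated alongside an AM/CM variant, which
#'   are dropped from category-level analyses).
#' @export
build_variant_context <- function(variant, junction, genome,
                                  cryptic_offsets = NULL,
                                  max_dist = 250L, include_decoys = TRUE) {
  junction <- as.list(junction)
  variant <- as.list(variant)
  if (is.null(cryptic_offsets)) {
    cryptic_offsets <- variant$cryptic_offsets
    if (is.list(cryptic_offsets)) cryptic_offsets <- cryptic_offsets[[1]]
    cryptic_offsets <- as.integer(cryptic_offsets %||% integer(0))
  }
  lo <- -min(max_dist, junction$exon_length)
  hi <- min(max_dist, junction$intron_length)
  # plus-strand genomic region with margin so every 12-nt window fits
  span <- sort(offset_to_genomic(junction$donor_pos, junction$strand,
                                 c(lo - 12L, hi + 12L)))
  n <- nchar(genome[[junction$contig]])
  g1 <- max(span[1], 1L); g2 <- min(span[2], n)
  ref_region <- genome_seq(genome, junction$contig, g1, g2)
  ed <- apply_variant(ref_region, g1, variant)
  fp <- variant_footprint(variant)

  ann_d1 <- junction$donor_pos
  ann_d2 <- offset_to_genomic(ann_d1, junction$strand, 1L)
  ann_ref <- window_from_region(ref_region, g1, ann_d1, junction$strand)
  ann_d1_var <- ed$map(ann_d1)
  ann_absent <- ed$deleted(ann_d1) || ed$deleted(ann_d2)
  ann_var <- if (ann_absent) NA_character_ else
    window_from_region(ed$seq, g1, ann_d1_var, junction$strand)

  site_rows <- function(offsets, kind) {
    if (length(offsets) == 0L) return(NULL)
    d1 <- offset_to_genomic(junction$donor_pos, junction$strand, offsets)
    ref_w <- vapply(d1, function(p)
      window_from_region(ref_region, g1, p, junction$strand), character(1))
    d1_var <- ed$map(d1)
    gone <- ed$deleted(d1) |
      ed$deleted(offset_to_genomic(junction$donor_pos, junction$strand,
                                   offsets + 1L))
    var_w <- rep(NA_character_, length(offsets))
    var_w[!gone] <- vapply(d1_var[!gone], function(p)
      window_from_region(ed$seq, g1, p, junction$strand), character(1))
    off_var <- if (junction$strand == "+") d1_var - ann_d1_var
               else ann_d1_var - d1_var
    off_var[gone | ann_absent] <- NA_integer_
    modified <- vapply(offsets, function(o)
      footprint_intersects(fp, window_interval(junction, o)), logical(1))
    data.frame(kind = kind, offset_ref = offsets, offset_var = off_var,
               ref_window = ref_w, var_window = var_w, modified = modified,
               stringsAsFactors = FALSE)
  }

  sites <- site_rows(cryptic_offsets, "cryptic")
  if (include_decoys) {
    dec <- enumerate_decoys(junction, genome, max_exonic = max_dist,
                            max_intronic = max_dist)
    dec_off <- setdiff(dec$offset, cryptic_offsets)
    sites <- rbind(sites, site_rows(dec_off, "decoy"))
  }
  if (is.null(sites)) {
    sites <- data.frame(kind = character(0), offset_ref = integer(0),
                        offset_var = integer(0), ref_window = character(0),
                        var_window = character(0), modified = logical(0),
                        stringsAsFactors = FALSE)
  }
  category <- classify_variant(variant, junction, cryptic_offsets)
  # AM/CM variants sometimes co-activate a second, unmodified cryptic;
  # those cryptics are flagged out of category-level analyses
  sites$excluded_unmodified_cryptic <-
    category == "AMCM" & sites$kind == "cryptic" & !sites$modified
  structure(
    list(variant = variant, junction = junction, category = category,
         annotated = data.frame(ref_window = ann_ref, var_window = ann_var,
                                var_absent = ann_absent,
                                stringsAsFactors = FALSE),
         sites = sites),
    class = "variant_context"
  )
}
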