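# fixtures are built in code; nothing is read from disk

# a dw_genome from a named character vector
as_genome <- function(x) {
  x <- toupper(x)
  class(x) <- "dw_genome"
  x
}

# contig with a designed exon tail / intron head around one donor:
# [C-flank | exon_seq | intron_seq | C-flank]; returns genome + junction
toy_junction <- function(exon_seq = "TAGGTC",
                         intron_seq = paste0("GTACGC", strrep("A", 100)),
                         flank = 30L, strand = "+", contig = "chrT") {
  ts <- paste0(strrep("C", flank), exon_seq, intron_seq,
               strrep("C", flank))
  L <- nchar(ts)
  if (strand == "+") {
    seq <- ts
    donor_pos <- flank + nchar(exon_seq) + 1L
  } else {
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ts)))
    donor_pos <- L - (flank + nchar(exon_seq) + 1L) + 1L
  }
  genome <- setNames(seq, contig)
  list(
    genome = as_genome(genome),
    junction = list(contig = contig, strand = strand,
                    donor_pos = donor_pos,
                    exon_length = nchar(exon_seq),
                    intron_length = nchar(intron_seq),
                    transcript_id = "toy", gene_id = "toyg",
                    acceptor_pos = if (strand == "+")
                      donor_pos + nchar(intron_seq) - 1L
                    else donor_pos - nchar(intron_seq) + 1L)
  )
}

# a df_index built from explicit 12-nt donor windows: one contig per
# donor, window at a fixed position
index_from_windows <- function(windows) {
  contigs <- sprintf("w%03d", seq_along(windows))
  genome <- setNames(paste0(strrep("C", 6), windows, strrep("C", 6)),
                     contigs)
  junctions <- data.frame(contig = contigs, strand = "+",
                          donor_pos = 11L, stringsAsFactors = FALSE)
  build_df_index(junctions, as_genome(genome))
}

# the five-donor toy index: four identical consensus windows, one other
toy_index <- function() {
  index_from_windows(c(rep("CAAGGTAAGTAT", 4), "TTTGGTGAGTCC"))
}

random_window <- function(n = 1L, essential = TRUE) {
  w <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
          collapse = "")
  }, character(1))
  if (essential) {
    substr(w, 5, 6) <- sample(c("GT", "GC"), n, replace = TRUE,
                              prob = c(0.9, 0.1))
  }
  w
}

# genome of i.i.d. uniform-ACGT junction regions (one contig each) with a
# junction table; used for null-model properties
random_junction_set <- function(n, exon_len = 150L, intron_len = 250L,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  flank <- 20L
  contigs <- sprintf("rj%04d", seq_len(n))
  L <- flank + exon_len + intron_len + flank
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = "")
  }, character(1))
  genome <- as_genome(setNames(seqs, contigs))
  junctions <- data.frame(
    transcript_id = paste0("tx", contigs), gene_id = contigs,
    contig = contigs, strand = "+",
    donor_pos = flank + exon_len + 1L,
    acceptor_pos = flank + exon_len + intron_len,
    exon_length = exon_len, intron_length = intron_len,
    donor_dinuc = NA_character_, stringsAsFactors = FALSE)
  list(genome = genome, junctions = junctions)
}

# independent regex-scan oracle for decoy enumeration
regex_decoy_oracle <- function(junction, genome, max_exonic = 250L,
                               max_intronic = 250L, min_intron = 80L) {
  lo <- -min(max_exonic, junction$exon_length)
  hi <- min(max_intronic, junction$intron_length)
  strand_sign <- if (junction$strand == "+") 1L else -1L
  g <- junction$donor_pos + strand_sign * c(lo, hi + 1L)
  g1 <- min(g); g2 <- max(g)
  seq <- substring(genome[[junction$contig]], g1, g2)
  if (junction$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  }
  offs <- integer(0)
  for (pat in c("GT", "GC")) {
    m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1L) offs <- c(offs, lo + as.integer(m) - 1L)
  }
  offs <- offs[offs >= lo & offs <= hi & offs != 0L]
  offs <- offs[!(offs > 0L & junction$intron_length - offs < min_intron)]
  sort(offs)
}

dinuc_multiset <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  sort(paste0(ch[-length(ch)], ch[-1]))
}

# lookup-table scorer for prediction tests
table_scorer <- function(tbl, floor = 0) {
  f <- function(windows) {
    s <- unname(tbl[windows])
    s[is.na(s)] <- floor
    s
  }
  attr(f, "floor") <- floor
  attr(f, "label") <- "table"
  f
}
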