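# a junction with designed decoys for classification tests:
# exon 300 nt, intron 300 nt, annotated donor GT at the boundary
classify_fixture <- function(strand = "+") {
  set.seed(31)
  exon <- paste(sample(c("A", "C", "A", "C"), 300, replace = TRUE),
                collapse = "")  # no G/T: no accidental decoys
  intron <- paste(sample(c("A", "C", "A", "C"), 300, replace = TRUE),
                  collapse = "")
  substr(intron, 1, 8) <- "GTAAGTAC"            # annotated donor
  substr(exon, 280, 281) <- "GT"                # decoy at offset -21
  substr(intron, 30, 31) <- "GC"                # GC decoy at offset +29
  substr(intron, 5, 6) <- "GT"                  # decoy at offset +4
  toy_junction(exon_seq = exon, intron_seq = intron, strand = strand)
}

# genomic position of transcript-oriented offset o
gpos <- function(jn, o) jn$donor_pos + (if (jn$strand == "+") o else -o)

test_that("apply_variant edits sequence and maps coordinates through indels", {
  v <- list(pos = 12L, ref = "T", alt = "A")
  ed <- apply_variant("GGTACGCGGG", 10L, v)
  expect_identical(ed$seq, "GGAACGCGGG")
  expect_identical(ed$map(15L), 15L)

  # 3-nt deletion: downstream positions shift left, deleted bases map to
  # the deletion's left edge
  d <- apply_variant("GGTACGCGGG", 10L, list(pos = 12L, ref = "TACG",
                                             alt = "T"))
  expect_identical(d$seq, "GGTCGGG")
  expect_identical(nchar(d$seq), 10L - 3L)
  expect_identical(d$map(17L), 14L)
  expect_identical(d$map(14L), 12L)
  expect_true(d$deleted(14L))
  expect_false(d$deleted(12L))

  # 2-nt insertion shifts downstream positions right
  ins <- apply_variant("GGTACGCGGG", 10L, list(pos = 12L, ref = "T",
                                               alt = "TCC"))
  expect_identical(ins$seq, "GGTCCACGCGGG")
  expect_identical(ins$map(13L), 15L)
  expect_error(apply_variant("GGTACG", 10L, list(pos = 12L, ref = "A",
                                                 alt = "C")),
               "mismatch")
})

test_that("AM / CM / AM-CM categories follow window intersections", {
  fx <- classify_fixture()
  jn <- fx$junction
  # SNV at the annotated D+2, cryptic observed at -21: AM
  expect_identical(
    classify_variant(list(pos = gpos(jn, 1L), ref = "T", alt = "A"),
                     jn, -21L), "AM")
  # GC->GT at D+2 of the decoy 29 nt into the intron: CM
  expect_identical(
    classify_variant(list(pos = gpos(jn, 30L), ref = "C", alt = "T"),
                     jn, 29L), "CM")
  # SNV at annotated D+5 = D+1 of the +4 cryptic: AM/CM
  expect_identical(
    classify_variant(list(pos = gpos(jn, 4L), ref = "G", alt = "A"),
                     jn, 4L), "AMCM")
  # outside every window
  expect_identical(
    classify_variant(list(pos = gpos(jn, 100L), ref = "A", alt = "C"),
                     jn, -21L), "excluded")
})

test_that("SNV positions partition exhaustively against an interval oracle", {
  fx <- classify_fixture()
  jn <- fx$junction
  cryptics <- c(-21L, 29L)
  in_window <- function(p, o) p >= o - 4L & p <= o + 7L
  for (off in -60:60) {
    p <- gpos(jn, off)
    ref <- genome_seq(fx$genome, jn$contig, p, p)
    cat_got <- classify_variant(list(pos = p, ref = ref, alt = "N"),
                                jn, cryptics)
    am <- in_window(off, 0L)
    cm <- any(in_window(off, cryptics))
    cat_exp <- if (am && cm) "AMCM" else if (am) "AM" else if (cm) "CM"
               else "excluded"
    expect_identical(cat_got, cat_exp)
  }
})

test_that("inclusion criteria produce the right exclusion reasons", {
  fx <- classify_fixture()
  jn <- fx$junction
  g <- fx$genome
  # (a) variant outside all windows
  expect_identical(
    validate_variant_record(list(pos = gpos(jn, 11L), ref = "A",
                                 alt = "C"), jn, -40L, g),
    "outside_windows")
  # (b) cryptic beyond the intron's 3' end
  expect_identical(
    validate_variant_record(list(pos = gpos(jn, 1L), ref = "T",
                                 alt = "A"), jn, 400L, g),
    "cryptic_outside_region")
  # (c) claimed cryptic whose VAR window lacks GT/GC at D+1/D+2
  expect_identical(
    validate_variant_record(list(pos = gpos(jn, 1L), ref = "T",
                                 alt = "A"), jn, -30L, g),
    "no_var_essential_dinuc")
  # a clean AM record passes
  expect_identical(
    validate_variant_record(list(pos = gpos(jn, 1L), ref = "T",
                                 alt = "A"), jn, -21L, g),
    "pass")
})

test_that("variant context reports REF/VAR windows and indel-shifted offsets", {
  fx <- classify_fixture()
  jn <- fx$junction
  g <- fx$genome
  # AM SNV at D+2: annotated windows differ at one position, decoy
  # windows unchanged
  ctx <- build_variant_context(list(pos = gpos(jn, 1L), ref = "T",
                                    alt = "A"), jn, g, -21L)
  expect_identical(ctx$category, "AM")
  d <- which(strsplit(ctx$annotated$ref_window, "")[[1]] !=
               strsplit(ctx$annotated$var_window, "")[[1]])
  expect_identical(d, 6L)  # D+2 is window position 6
  far <- ctx$sites[abs(ctx$sites$offset_ref) > 12L, ]
  expect_identical(far$ref_window, far$var_window)
  expect_identical(ctx$sites$offset_var, ctx$sites$offset_ref)

  # 3-nt deletion between the cryptic and the donor pulls the cryptic
  # 3 nt closer in VAR coordinates
  del_left <- gpos(jn, -16L)
  ref_al <- genome_seq(g, jn$contig, del_left, del_left + 3L)
  v <- list(pos = del_left, ref = ref_al, alt = substring(ref_al, 1, 1))
  ctx2 <- build_variant_context(v, jn, g, -21L)
  cr <- ctx2$sites[ctx2$sites$kind == "cryptic", ]
  expect_identical(cr$offset_ref, -21L)
  expect_identical(cr$offset_var, -18L)
  # intronic decoys are untouched
  intr <- ctx2$sites[ctx2$sites$offset_ref > 0L, ]
  expect_identical(intr$offset_var, intr$offset_ref)
})

test_that("offsets remeasured on the VAR string match the coordinate map", {
  fx <- classify_fixture()
  jn <- fx$junction
  g <- fx$genome
  set.seed(32)
  for (i in 1:100) {
    # random small indel in the exon, away from the donor
    left <- gpos(jn, sample(-120:-30, 1))
    len <- sample(1:5, 1)
    ref_al <- genome_seq(g, jn$contig, left, left + len)
    v <- list(pos = left, ref = ref_al,
              alt = if (runif(1) < 0.5) substring(ref_al, 1, 1)
                    else paste0(ref_al, "ACG"))
    ctx <- build_variant_context(v, jn, g, -21L,
                                 include_decoys = FALSE)
    cr <- ctx$sites[ctx$sites$kind == "cryptic", ]
    if (is.na(cr$offset_var)) next
    # oracle: find the cryptic window on the VAR region directly
    reg <- genome_seq(g, jn$contig, jn$donor_pos - 300L,
                      jn$donor_pos + 300L)
    ed <- apply_variant(reg, jn$donor_pos - 300L, v)
    ann_i <- ed$map(jn$donor_pos) - (jn$donor_pos - 300L) + 1L
    cr_i <- ed$map(gpos(jn, -21L)) - (jn$donor_pos - 300L) + 1L
    expect_identical(cr$offset_var, cr_i - ann_i)
  }
})

test_that("unmodified co-activated cryptics of AM/CM variants are flagged", {
  fx <- classify_fixture()
  jn <- fx$junction
  # variant inside annotated and +4 windows; -21 cryptic also observed
  ctx <- build_variant_context(list(pos = gpos(jn, 4L), ref = "G",
                                    alt = "A"), jn, fx$genome,
                               c(4L, -21L))
  expect_identical(ctx$category, "AMCM")
  s <- ctx$sites
  expect_true(s$excluded_unmodified_cryptic[s$kind == "cryptic" &
                                              s$offset_ref == -21L])
  expect_false(s$excluded_unmodified_cryptic[s$kind == "cryptic" &
                                               s$offset_ref == 4L])
})

test_that("variant tables round-trip through the TSV and VCF readers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\talt\ttranscript_id\tcryptic_offsets",
               "c1\t100\tG\tA\ttx1\t-21,4",
               "c1\t200\tGTA\tG\ttx2\t"), f)
  v <- read_variants(f)
  expect_identical(v$cryptic_offsets[[1]], c(-21L, 4L))
  expect_identical(v$cryptic_offsets[[2]], integer(0))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "c1\t100\ttx1\tG\tA\t.\t.\t."), vcf)
  vv <- read_variants_vcf(vcf)
  expect_identical(vv$pos, 100L)
  expect_identical(vv$transcript_id, "tx1")
})
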