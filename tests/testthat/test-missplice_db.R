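write_star <- function(path, rows) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
}

test_that("STAR SJ.out.tab rows are parsed with the documented semantics", {
  f <- withr::local_tempfile(fileext = ".tab")
  write_star(f, list(
    c("1", "1001", "2000", "1", "1", "0", "5", "2", "30"),
    c("1", "3001", "4000", "2", "2", "0", "7", "0", "25"),
    c("1", "5001", "6000", "1", "1", "0", "0", "9", "12")))
  s <- read_junction_file(f, "star_sj", sample_id = "s1")
  expect_identical(nrow(s$junctions), 2L)  # zero-unique-reads row dropped
  expect_identical(s$junctions$reads[s$junctions$start == 1001], 5L)
  expect_identical(s$junctions$strand, c("+", "-"))

  # undetermined strand dropped with a warning
  f2 <- withr::local_tempfile(fileext = ".tab")
  write_star(f2, list(c("1", "1001", "2000", "0", "0", "0", "5", "0", "30")))
  expect_warning(s2 <- read_junction_file(f2, "star_sj"),
                 "undetermined")
  expect_identical(nrow(s2$junctions), 0L)

  # malformed column count names the line
  f3 <- withr::local_tempfile(fileext = ".tab")
  writeLines("1\t100\t200", f3)
  expect_error(read_junction_file(f3, "star_sj"), "line 1")
})

test_that("the TSV dialect round-trips through the writer", {
  s <- structure(list(sample_id = "sX", junctions = data.frame(
    contig = c("c1", "c2"), start = c(10L, 30L), end = c(20L, 44L),
    strand = c("+", "-"), reads = c(3L, 8L),
    stringsAsFactors = FALSE)), class = "sample_junctions")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_junction_file(s, f)
  s2 <- read_junction_file(f, "tsv", sample_id = "sX")
  expect_identical(s2$junctions, s$junctions)
})

mk_sample <- function(id, ...) {
  rows <- list(...)
  structure(list(sample_id = id, junctions = do.call(rbind, lapply(
    rows, function(r) data.frame(contig = r[[1]],
                                 start = as.integer(r[[2]]),
                                 end = as.integer(r[[3]]),
                                 strand = r[[4]],
                                 reads = as.integer(r[[5]]),
                                 stringsAsFactors = FALSE)))),
    class = "sample_junctions")
}

test_that("aggregation tallies samples, totals and maxima, order-free", {
  a <- mk_sample("A", list("c1", 1001, 2000, "+", 5))
  b <- mk_sample("B", list("c1", 1001, 2000, "+", 2),
                 list("c1", 981, 2000, "+", 1))
  agg <- aggregate_junctions(list(a, b))
  j <- agg[agg$start == 1001, ]
  expect_identical(j$sample_count, 2L)
  expect_identical(j$total_reads, 7L)
  expect_identical(j$max_reads, 5L)
  expect_identical(agg[agg$start == 981, ]$sample_count, 1L)
  expect_identical(aggregate_junctions(list(b, a)), agg)
  expect_error(aggregate_junctions(list(a, a)), "duplicate")
  # conservation: total reads in = total reads out
  expect_identical(sum(agg$total_reads),
                   sum(a$junctions$reads) + sum(b$junctions$reads))
})

# an annotated junction table with one + and one - strand junction
two_junctions <- function() {
  data.frame(
    transcript_id = c("txP", "txM"), gene_id = c("gP", "gM"),
    contig = c("cP", "cM"), strand = c("+", "-"),
    donor_pos = c(1001L, 5000L), acceptor_pos = c(2000L, 4001L),
    exon_length = c(300L, 300L), intron_length = c(1000L, 1000L),
    donor_dinuc = "GT", stringsAsFactors = FALSE)
}

test_that("event extraction enforces acceptor match, bounds and sample floor", {
  jx <- two_junctions()
  samples <- lapply(1:5, function(i) {
    mk_sample(paste0("s", i),
              list("cP", 1001, 2000, "+", 50),   # annotated
              list("cP", 981, 2000, "+", 2),     # cryptic at -20
              list("cP", 981, 1900, "+", 9))     # wrong acceptor
  })
  # a junction seen in only 2 samples
  samples[[1]]$junctions <- rbind(samples[[1]]$junctions,
    data.frame(contig = "cP", start = 1031L, end = 2000L, strand = "+",
               reads = 4L, stringsAsFactors = FALSE))
  samples[[2]]$junctions <- rbind(samples[[2]]$junctions,
    data.frame(contig = "cP", start = 1031L, end = 2000L, strand = "+",
               reads = 1L, stringsAsFactors = FALSE))
  agg <- aggregate_junctions(samples)
  ev <- extract_cryptic_events(agg, jx)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$offset, -20L)
  expect_identical(ev$sample_count, 5L)
  expect_identical(ev$total_reads, 10L)
  # the 2-sample junction and the wrong-acceptor junction are absent
  expect_false(30L %in% ev$offset)
  # the annotated donor itself is never an event
  expect_false(any(ev$cryptic_donor_pos == 1001L))
})

test_that("minus-strand offsets mirror plus-strand ones", {
  jx <- two_junctions()
  # donor at 5000 (-): cryptic donor 20 nt into the exon lies at 5020
  samples <- lapply(1:3, function(i) {
    mk_sample(paste0("s", i), list("cM", 4001, 5020, "-", 3))
  })
  ev <- extract_cryptic_events(aggregate_junctions(samples), jx)
  expect_identical(ev$offset, -20L)
  expect_identical(ev$cryptic_donor_pos, 5020L)
})

test_that("extraction equals a brute-force double loop on random instances", {
  set.seed(51)
  jx <- two_junctions()
  # random aggregated junctions around both annotated junctions
  n <- 400L
  pick <- sample(1:2, n, replace = TRUE)
  base <- jx[pick, ]
  off <- sample(c(-300:-1, 1:300), n, replace = TRUE)
  donor <- base$donor_pos + ifelse(base$strand == "+", 1L, -1L) * off
  agg <- data.frame(
    contig = base$contig,
    start = ifelse(base$strand == "+", donor, base$acceptor_pos),
    end = ifelse(base$strand == "+", base$acceptor_pos, donor),
    strand = base$strand,
    sample_count = sample(1:6, n, replace = TRUE),
    total_reads = sample(1:50, n, replace = TRUE),
    max_reads = 1L, stringsAsFactors = FALSE)
  agg <- agg[!duplicated(agg[, 1:4]), ]
  ev <- extract_cryptic_events(agg, jx, max_dist = 250L,
                               min_samples = 3L)
  # brute force: explicit loops over aggregated x annotated
  brute <- 0L
  for (i in seq_len(nrow(agg))) {
    for (j in seq_len(nrow(jx))) {
      jn <- jx[j, ]
      acc <- if (jn$strand == "+") agg$end[i] else agg$start[i]
      don <- if (jn$strand == "+") agg$start[i] else agg$end[i]
      o <- if (jn$strand == "+") don - jn$donor_pos
           else jn$donor_pos - don
      if (agg$contig[i] == jn$contig && agg$strand[i] == jn$strand &&
          acc == jn$acceptor_pos && don != jn$donor_pos &&
          o >= -jn$exon_length && o <= jn$intron_length - 1L &&
          abs(o) <= 250L && agg$sample_count[i] >= 3L) {
        brute <- brute + 1L
        expect_true(any(ev$transcript_id == jn$transcript_id &
                          ev$offset == o))
      }
    }
  }
  expect_identical(nrow(ev), brute)
})

test_that("ranking is dense per junction with deterministic tie-breaks", {
  ev <- data.frame(
    transcript_id = "t", contig = "c", strand = "+",
    annotated_donor_pos = 100L,
    cryptic_donor_pos = c(80L, 130L, 90L, 124L, 76L),
    offset = c(-20L, 30L, -10L, 24L, -24L),
    sample_count = c(137L, 25L, 25L, 3L, 3L),
    total_reads = c(500L, 90L, 40L, 9L, 9L),
    max_reads = 9L, stringsAsFactors = FALSE)
  r <- rank_events(ev)
  expect_identical(sort(r$rank), 1:5)
  expect_identical(r$offset[r$rank == 1L], -20L)   # highest sample count
  expect_identical(r$offset[r$rank == 2L], 30L)    # more reads at 25
  expect_identical(r$offset[r$rank == 3L], -10L)
  # full tie at 3 samples / 9 reads: exonic (negative) precedes intronic
  expect_identical(r$offset[r$rank == 4L], -24L)
  expect_identical(r$offset[r$rank == 5L], 24L)

  # property: ranks are a dense permutation per junction on random data
  set.seed(52)
  ev2 <- data.frame(
    transcript_id = sample(c("a", "b"), 60, TRUE), contig = "c",
    strand = "+", annotated_donor_pos = sample(c(10L, 20L), 60, TRUE),
    cryptic_donor_pos = 1L, offset = sample(c(-50:-1, 1:50), 60),
    sample_count = sample(1:8, 60, TRUE),
    total_reads = sample(1:20, 60, TRUE), max_reads = 1L,
    stringsAsFactors = FALSE)
  r2 <- rank_events(ev2)
  for (k in split(r2, paste(r2$transcript_id, r2$annotated_donor_pos))) {
    expect_identical(sort(k$rank), seq_len(nrow(k)))
    ord <- order(-k$sample_count, -k$total_reads, abs(k$offset),
                 k$offset >= 0)
    expect_identical(k$rank[ord], seq_len(nrow(k)))
  }
})

test_that("presence fractions hit the degenerate extremes", {
  set.seed(53)
  rj <- random_junction_set(5)
  empty_db <- data.frame(transcript_id = character(0),
                         annotated_donor_pos = integer(0),
                         offset = integer(0))
  pr0 <- presence_profile(empty_db, rj$junctions, rj$genome)
  expect_true(all(pr0$fraction == 0))
  # plant an event for every decoy -> fraction 1 everywhere
  rows <- list()
  for (j in seq_len(nrow(rj$junctions))) {
    jn <- as.list(rj$junctions[j, ])
    dec <- enumerate_decoys(jn, rj$genome)
    rows[[j]] <- data.frame(transcript_id = jn$transcript_id,
                            annotated_donor_pos = jn$donor_pos,
                            offset = dec$offset)
  }
  full_db <- do.call(rbind, rows)
  pr1 <- presence_profile(full_db, rj$junctions, rj$genome)
  expect_true(all(pr1$fraction == 1))
  expect_identical(sum(pr1$n_decoys), nrow(full_db))
})
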