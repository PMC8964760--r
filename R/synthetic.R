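#' Simulation configuration
#'
#' Defines the toy study conditions: gene/exon architecture, the
#' consensus-like donor position-weight matrix, the planted-decoy
#' landscape, the usage kernel turning decoy strength and proximity into
#' per-sample mis-splicing probabilities, and the read-count model.
#'
#' Defaults: 50 genes of 5 exons (two usable middle junctions each after
#' first/last-intron filtering), exons 120-180 nt, introns 300-400 nt,
#' uniform ACGT background, three planted decoys per junction in disjoint
#' offset bands (strong GT at |offset| 16-36, medium GC at 80-112, weak
#' intronic GT at 140-200) so planted windows never overlap each other or
#' the annotated window, usage probability
#' `plogis(alpha * DF - beta * |offset| / 250)` with `alpha = 4`,
#' `beta = 2`, 200 samples, zero-truncated Poisson(2) cryptic reads and
#' log-normal(meanlog 4, sdlog 0.5) annotated junction depth.
#'
#' @param n_genes,exons_per_gene gene architecture.
#' @param exon_length,intron_length integer ranges `c(min, max)`.
#' @param flank contig padding either side of the transcript (nt).
#' @param n_samples number of simulated RNA-seq samples.
#' @param usage_alpha,usage_beta usage-kernel weights on DF percentile
#'   and |offset|/250.
#' @param read_lambda Poisson rate of cryptic-junction reads (zero
#'   truncated).
#' @param depth_meanlog,depth_sdlog log-normal parameters of annotated
#'   junction depth.
#' @param n_am,n_cm,n_amcm variant counts per category for
#'   [generate_variants()].
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return a `dw_sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, exons_per_gene = 5L,
                       exon_length = c(120L, 180L),
                       intron_length = c(300L, 400L), flank = 200L,
                       n_samples = 200L, usage_alpha = 4,
                       usage_beta = 2, read_lambda = 2,
                       depth_meanlog = 4, depth_sdlog = 0.5,
                       n_am = 30L, n_cm = 30L, n_amcm = 10L,
                       seed = 1L) {
  stopifnot(exons_per_gene >= 4L, exon_length[1] >= 120L,
            intron_length[1] >= 220L, n_genes >= 1L)
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length = as.integer(exon_length),
                 intron_length = as.integer(intron_length),
                 flank = as.integer(flank),
                 n_samples = as.integer(n_samples),
                 usage_alpha = usage_alpha, usage_beta = usage_beta,
                 read_lambda = read_lambda,
                 depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog,
                 n_am = as.integer(n_am), n_cm = as.integer(n_cm),
                 n_amcm = as.integer(n_amcm),
                 seed = as.integer(seed)),
            class = "dw_sim_config")
}

# consensus-like donor PWM over the 12-nt E-4..D+8 window
# (rows A,C,G,T; D+1/D+2 fixed to the essential dinucleotide)
donor_pwm <- function(dinuc = "GT") {
  # sharp consensus (cAG|GTrAGTnn): most positions near-fixed, variation
  # concentrated at E-4, D+3, D+7 and D+8 so exact 9-mer repeats are
  # common even in small donor sets, as they are genome-wide
  p <- matrix(c(
    # E-4   E-3   E-2   E-1   D+1  D+2  D+3   D+4   D+5   D+6   D+7   D+8
    0.50, 0.97, 0.97, 0.01, 0,   0,   0.50, 0.97, 0.01, 0.01, 0.50, 0.00,
    0.50, 0.01, 0.01, 0.01, 0,   0,   0.00, 0.01, 0.01, 0.01, 0.00, 0.00,
    0.00, 0.01, 0.01, 0.97, 1,   0,   0.50, 0.01, 0.97, 0.01, 0.00, 0.50,
    0.00, 0.01, 0.01, 0.01, 0,   1,   0.00, 0.01, 0.01, 0.97, 0.50, 0.50
  ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (dinuc == "GC") { p[, 6] <- c(0, 1, 0, 0) }
  p
}

sample_pwm_window <- function(pwm, mix_uniform = 0) {
  vapply(seq_len(ncol(pwm)), function(j) {
    pr <- (1 - mix_uniform) * pwm[, j] + mix_uniform * 0.25
    if (j %in% c(5L, 6L)) pr <- pwm[, j]  # essential dinucleotide fixed
    sample(rownames(pwm), 1L, prob = pr)
  }, character(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# planted decoy tiers: disjoint |offset| bands so no planted window can
# overlap another planted window or the annotated E-4..D+8
decoy_tiers <- function() {
  # bands are disjoint (with >12 nt gaps) so planted windows cannot
  # overlap each other or the annotated window; the GC medium tier scores
  # DF 0 against a GT-donor index, and the weak tier is intronic-only and
  # distal, giving the three tiers well-separated usage probabilities
  data.frame(tier = c("strong", "medium", "weak"),
             dinuc = c("GT", "GC", "GT"),
             mix = c(0, 0.3, 1),
             lo = c(16L, 80L, 140L), hi = c(36L, 112L, 200L),
             side = c("both", "both", "intron"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genome, annotation and planted ground truth
#'
#' One contig per gene (alternating strand), uniform-ACGT background,
#' annotated donors drawn from a sharp consensus-like PWM, and three
#' decoys per usable (middle) junction planted at recorded offsets in
#' distinct strength tiers. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return a `dw_simulation` list: `genome` (`dw_genome`), `transcripts`
#'   (`dw_transcripts`), `truth` (list with `planted` data.frame:
#'   `transcript_id`, `intron_index`, `offset`, `dinuc`, `tier`, and the
#'   config), ready for [simulate_junction_samples()] and
#'   [generate_variants()].
#' @export
generate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  pwm_gt <- donor_pwm("GT")
  genome <- character(config$n_genes)
  contigs <- sprintf("g%03d", seq_len(config$n_genes))
  tx <- vector("list", config$n_genes)
  planted <- list()
  n_introns <- config$exons_per_gene - 1L
  for (g in seq_len(config$n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    ex_len <- sample(config$exon_length[1]:config$exon_length[2],
                     config$exons_per_gene, replace = TRUE)
    in_len <- sample(config$intron_length[1]:config$intron_length[2],
                     n_introns, replace = TRUE)
    # transcript-oriented sequence: flank | exon1 intron1 ... exonN | flank
    parts <- character(0)
    # transcript-oriented start position (1-based) of each exon/intron
    pos <- config$flank + 1L
    ex_start <- integer(config$exons_per_gene)
    in_start <- integer(n_introns)
    parts <- c(parts, random_dna(config$flank))
    for (i in seq_len(config$exons_per_gene)) {
      ex_start[i] <- pos
      parts <- c(parts, random_dna(ex_len[i]))
      pos <- pos + ex_len[i]
      if (i <= n_introns) {
        in_start[i] <- pos
        parts <- c(parts, random_dna(in_len[i]))
        pos <- pos + in_len[i]
      }
    }
    parts <- c(parts, random_dna(config$flank))
    ts <- paste(parts, collapse = "")
    ts_chars <- strsplit(ts, "", fixed = TRUE)[[1]]

    write_window <- function(d1_ts, window) {
      # d1_ts: transcript-oriented position of the site's D+1
      ts_chars[(d1_ts - 4L):(d1_ts + 7L)] <<- window
    }
    # consensus donors at every annotated junction
    for (i in seq_len(n_introns)) {
      write_window(in_start[i], sample_pwm_window(pwm_gt))
    }
    # planted decoys around the usable (middle) junctions
    tiers <- decoy_tiers()
    usable <- setdiff(seq_len(n_introns), c(1L, n_introns))
    for (i in usable) {
      d1_ann <- in_start[i]
      for (t in seq_len(nrow(tiers))) {
        tr <- tiers[t, ]
        side <- if (tr$side == "intron") 1L else sample(c(-1L, 1L), 1L)
        hi <- tr$hi
        if (side < 0L) hi <- min(hi, ex_len[i] - 8L)
        if (side > 0L) hi <- min(hi, in_len[i] - 80L)
        if (hi < tr$lo) {
          stop("infeasible config: exon/intron too short for tier '",
               tr$tier, "' decoys", call. = FALSE)
        }
        off <- side * sample(tr$lo:hi, 1L)
        win <- sample_pwm_window(donor_pwm(tr$dinuc), mix_uniform = tr$mix)
        write_window(d1_ann + off, win)
        planted[[length(planted) + 1L]] <- data.frame(
          transcript_id = paste0("tx", contigs[g]),
          contig = contigs[g], strand = strand, intron_index = i,
          offset = off, dinuc = tr$dinuc, tier = tr$tier,
          stringsAsFactors = FALSE)
      }
    }
    ts <- paste(ts_chars, collapse = "")
    L <- nchar(ts)
    if (strand == "+") {
      genome[g] <- ts
      exons <- cbind(start = ex_start, end = ex_start + ex_len - 1L)
    } else {
      genome[g] <- revcomp(ts)
      exons <- cbind(start = L - (ex_start + ex_len - 1L) + 1L,
                     end = L - ex_start + 1L)
    }
    tx[[g]] <- list(transcript_id = paste0("tx", contigs[g]),
                    gene_id = paste0("gene", contigs[g]),
                    contig = contigs[g], strand = strand,
                    exons = exons,
                    cds = c(min(exons), max(exons)))
  }
  names(genome) <- contigs
  class(genome) <- "dw_genome"
  names(tx) <- vapply(tx, `[[`, character(1), "transcript_id")
  class(tx) <- "dw_transcripts"
  structure(list(genome = genome, transcripts = tx,
                 truth = list(planted = do.call(rbind, planted),
                              config = config)),
            class = "dw_simulation")
}

# planted decoys joined to their junction rows (donor/acceptor coords)
planted_with_junctions <- function(sim, junctions) {
  pl <- sim$truth$planted
  key_j <- paste(junctions$transcript_id)
  out <- list()
  for (i in seq_len(nrow(pl))) {
    tx <- sim$transcripts[[pl$transcript_id[i]]]
    # recompute this intron's donor coordinate from the transcript model
    e1 <- tx$exons[pl$intron_index[i], ]
    donor_pos <- if (tx$strand == "+") e1[["end"]] + 1L else e1[["start"]] - 1L
    j <- which(junctions$transcript_id == pl$transcript_id[i] &
                 junctions$donor_pos == donor_pos)
    if (length(j) != 1L) next  # junction filtered out
    out[[length(out) + 1L]] <- cbind(pl[i, , drop = FALSE],
                                     junction_row = j)
  }
  do.call(rbind, out)
}

# zero-truncated Poisson
rztpois <- function(n, lambda) {
  as.integer(stats::qpois(runif(n, stats::ppois(0, lambda), 1), lambda))
}

#' Simulate per-sample splice-junction sets with planted mis-splicing
#'
#' Every annotated intron of every transcript receives log-normal read
#' depth in every sample. Each planted decoy is used in a sample with
#' probability `plogis(alpha * DF - beta * |offset| / 250)` — DF is the
#' decoy window's percentile on the index built from the simulated
#' genome's own filtered junctions — and, when used, contributes a
#' zero-truncated Poisson read count on the junction (decoy donor ->
#' annotated acceptor).
#'
#' @param sim a `dw_simulation` from [generate_genome()].
#' @param config a [sim_config()] (defaults to the one in `sim`).
#' @return list: `samples` (list of `sample_junctions`), `truth`
#'   (the planted table with `donor_pos`, `acceptor_pos`,
#'   `cryptic_donor_pos`, `df_percentile`, `usage_prob`,
#'   `realized_sample_count`), `junctions` (the filtered junction set),
#'   `index` (the `df_index` used by the kernel).
#' @export
simulate_junction_samples <- function(sim, config = NULL) {
  config <- config %||% sim$truth$config
  set.seed(config$seed + 1L)
  junctions <- enumerate_junctions(sim$transcripts, sim$genome)
  index <- build_df_index(junctions, sim$genome)
  pl <- planted_with_junctions(sim, junctions)
  jn <- junctions[pl$junction_row, ]
  pl$donor_pos <- jn$donor_pos
  pl$acceptor_pos <- jn$acceptor_pos
  pl$cryptic_donor_pos <- offset_to_genomic(jn$donor_pos, jn$strand,
                                            pl$offset)
  wins <- character(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    wins[i] <- donor_window(sim$genome, pl$contig[i],
                            pl$cryptic_donor_pos[i], pl$strand[i])$window
  }
  pl$df_percentile <- df_score(wins, index)$percentile
  pl$usage_prob <- plogis(config$usage_alpha * pl$df_percentile -
                            config$usage_beta * abs(pl$offset) / 250)

  # intron coordinates in plus-strand (STAR-style) convention
  star_coords <- function(donor_pos, acceptor_pos, strand) {
    if (strand == "+") c(donor_pos, acceptor_pos)
    else c(acceptor_pos, donor_pos)
  }
  # all annotated introns (not just filtered ones) get normal splicing
  ann <- list()
  for (tx in sim$transcripts) {
    for (i in seq_len(nrow(tx$exons) - 1L)) {
      if (tx$strand == "+") {
        d <- tx$exons[i, "end"] + 1L; a <- tx$exons[i + 1L, "start"] - 1L
      } else {
        d <- tx$exons[i, "start"] - 1L; a <- tx$exons[i + 1L, "end"] + 1L
      }
      sc <- star_coords(d, a, tx$strand)
      ann[[length(ann) + 1L]] <- data.frame(
        contig = tx$contig, start = sc[1], end = sc[2],
        strand = tx$strand, stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, ann)
  cr_sc <- t(mapply(star_coords, pl$cryptic_donor_pos, pl$acceptor_pos,
                    pl$strand))
  samples <- vector("list", config$n_samples)
  realized <- integer(nrow(pl))
  for (s in seq_len(config$n_samples)) {
    depth <- as.integer(pmax(1, round(rlnorm(nrow(ann),
                                             config$depth_meanlog,
                                             config$depth_sdlog))))
    rows <- data.frame(contig = ann$contig, start = ann$start,
                       end = ann$end, strand = ann$strand,
                       reads = depth, stringsAsFactors = FALSE)
    used <- runif(nrow(pl)) < pl$usage_prob
    if (any(used)) {
      realized <- realized + as.integer(used)
      rows <- rbind(rows, data.frame(
        contig = pl$contig[used], start = cr_sc[used, 1],
        end = cr_sc[used, 2], strand = pl$strand[used],
        reads = rztpois(sum(used), config$read_lambda),
        stringsAsFactors = FALSE))
    }
    samples[[s]] <- structure(
      list(sample_id = sprintf("sample%03d", s), junctions = rows),
      class = "sample_junctions")
  }
  pl$realized_sample_count <- realized
  pl$junction_row <- NULL
  list(samples = samples, truth = pl, junctions = junctions,
       index = index)
}

# transcript-oriented base at a genomic position
tx_base <- function(genome, contig, pos, strand) {
  b <- genome_seq(genome, contig, pos, pos)
  if (strand == "-") b <- revcomp(b)
  b
}

# convert a transcript-oriented allele to plus-strand (VCF) orientation
to_genomic_allele <- function(allele, strand) {
  if (strand == "+") allele else revcomp(allele)
}

#' Generate variants with known AM/CM/AM-CM truth labels
#'
#' AM variants are SNVs at the annotated donor's D+2 (weakening it), with
#' the junction's planted strong decoy recorded as the activated cryptic.
#' CM variants convert a planted GC decoy to GT at its D+2. AM/CM
#' variants mutate a position shared by the annotated window and the
#' window of a background decoy found within 11 nt, avoiding both
#' essential dinucleotides. All planted offsets are >= 16 nt away, so AM
#' and CM footprints provably touch exactly one window.
#'
#' @param sim a `dw_simulation`.
#' @param config a [sim_config()] (defaults to the one in `sim`).
#' @return data.frame: `contig`, `pos`, `ref`, `alt`, `transcript_id`,
#'   `cryptic_offsets` (list column), `truth_category`.
#' @export
generate_variants <- function(sim, config = NULL) {
  config <- config %||% sim$truth$config
  set.seed(config$seed + 2L)
  junctions <- enumerate_junctions(sim$transcripts, sim$genome)
  pl <- planted_with_junctions(sim, junctions)
  rows <- list()
  add <- function(jn, off_var, tx_ref, tx_alt, cryptics, cat) {
    pos <- offset_to_genomic(jn$donor_pos, jn$strand, off_var)
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = jn$contig, pos = pos,
      ref = to_genomic_allele(tx_ref, jn$strand),
      alt = to_genomic_allele(tx_alt, jn$strand),
      transcript_id = jn$transcript_id,
      cryptic_offsets = I(list(as.integer(cryptics))),
      truth_category = cat, stringsAsFactors = FALSE)
  }
  strong <- pl[pl$tier == "strong", ]
  gc_dec <- pl[pl$tier == "medium", ]
  j_am <- sample(strong$junction_row, min(config$n_am, nrow(strong)))
  for (j in j_am) {
    jn <- as.list(junctions[j, ])
    # D+2 T>A kills the annotated donor; strong planted decoy activates
    off <- strong$offset[strong$junction_row == j][1]
    add(jn, 1L, "T", "A", off, "AM")
  }
  j_cm <- sample(gc_dec$junction_row, min(config$n_cm, nrow(gc_dec)))
  for (j in j_cm) {
    jn <- as.list(junctions[j, ])
    off <- gc_dec$offset[gc_dec$junction_row == j][1]
    # GC -> GT at the decoy's D+2 strengthens the cryptic
    add(jn, off + 1L, "C", "T", off, "CM")
  }
  # AM/CM: background GT/GC within 11 nt whose window overlaps the
  # annotated window; mutate a shared, non-essential position
  n_amcm <- 0L
  for (j in sample(seq_len(nrow(junctions)))) {
    if (n_amcm >= config$n_amcm) break
    jn <- as.list(junctions[j, ])
    dec <- enumerate_decoys(jn, sim$genome, max_exonic = 11L,
                            max_intronic = 11L)
    dec <- dec[abs(dec$offset) >= 3L, , drop = FALSE]
    if (nrow(dec) == 0L) next
    o <- dec$offset[1]
    shared <- intersect(seq(-4L, 7L), seq(o - 4L, o + 7L))
    shared <- setdiff(shared, c(0L, 1L, o, o + 1L))
    if (length(shared) == 0L) next
    p_off <- shared[ceiling(length(shared) / 2)]
    ref_b <- tx_base(sim$genome, jn$contig,
                     offset_to_genomic(jn$donor_pos, jn$strand, p_off),
                     jn$strand)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
    add(jn, p_off, ref_b, alt_b, o, "AMCM")
    n_amcm <- n_amcm + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write simulation outputs to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `samples/sampleNNN.tsv` (TSV junction
#' dialect), `variants.tsv` and `truth.json` under `outdir`.
#'
#' @param sim a `dw_simulation`.
#' @param sim_samples result of [simulate_junction_samples()].
#' @param variants result of [generate_variants()] (optional).
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, sim_samples = NULL, variants = NULL,
                             outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(outdir, "genome.fa"))
  write_gtf(sim$transcripts, file.path(outdir, "genes.gtf"))
  truth <- list(planted = sim$truth$planted,
                config = unclass(sim$truth$config))
  if (!is.null(sim_samples)) {
    sdir <- file.path(outdir, "samples")
    dir.create(sdir, showWarnings = FALSE)
    for (s in sim_samples$samples) {
      write_junction_file(s, file.path(sdir, paste0(s$sample_id, ".tsv")))
    }
    truth$planted <- sim_samples$truth
  }
  if (!is.null(variants)) {
    v <- variants
    v$cryptic_offsets <- vapply(v$cryptic_offsets, paste,
                                character(1), collapse = ",")
    write.table(v, file.path(outdir, "variants.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Write a genome as FASTA
#' @param genome a `dw_genome`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write transcript models as GTF
#' @param transcripts a `dw_transcripts`.
#' @param path output path.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    ex <- tx$exons[order(tx$exons[, "start"]), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, paste(tx$contig, "donorwatch", "exon",
                              ex[i, "start"], ex[i, "end"], ".",
                              tx$strand, ".", attrs, sep = "\t"))
    }
    if (!is.null(tx$cds)) {
      for (i in seq_len(nrow(ex))) {
        cs <- max(ex[i, "start"], tx$cds[1])
        ce <- min(ex[i, "end"], tx$cds[2])
        if (cs <= ce) {
          lines <- c(lines, paste(tx$contig, "donorwatch", "CDS",
                                  cs, ce, ".", tx$strand, "0", attrs,
                                  sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
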