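test_that("rDNA reference tiles the unit, is deterministic, 28S is the longest transcribed segment", {
  rdna <- make_rdna_reference(4300, seed = 1)
  seg <- rdna$segments
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], 4300)
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])  # no gaps, no overlap
  expect_equal(nchar(rdna$sequence), 4300)
  expect_equal(sum(seg$end - seg$start), 4300)
  expect_identical(rdna$sequence, make_rdna_reference(4300, seed = 1)$sequence)
  expect_false(identical(rdna$sequence,
                         make_rdna_reference(4300, seed = 2)$sequence))
  transcribed <- seg[seg$label != "IGS", ]
  expect_equal(transcribed$label[which.max(transcribed$end - transcribed$start)],
               "28S")
  expect_equal(rdna$transcribed_end, seg$start[seg$label == "IGS"])
  expect_error(make_rdna_reference(4300, c("5'ETS" = 0.5, IGS = 0.4)),
               "sum to 1")
  expect_error(make_rdna_reference(500), ">= 1000")
})

test_that("planted fragments reproduce the configured identity and orientation", {
  rdna <- make_rdna_reference(seed = 2)
  genome <- sim_genome(c(chr1 = 150000L, chr2 = 150000L), seed = 2)
  genes <- sim_gene_annotation(c(chr1 = 150000L, chr2 = 150000L),
                               n_genes = 14, seed = 2)
  # identity 1, sense only: planted substring equals the source exactly
  p1 <- plant_fragments(genome, genes, rdna, n_fragments = 6, identity = 1,
                        antisense_prob = 0, seed = 3)
  for (i in seq_len(nrow(p1$fragments))) {
    f <- p1$fragments[i, ]
    expect_identical(substring(p1$genome[[f$chrom]], f$start + 1, f$end),
                     substring(rdna$sequence, f$source_start + 1,
                               f$source_end))
  }
  # identity 0.9632: realized mismatch fraction within 3 binomial SDs
  p2 <- plant_fragments(genome, genes, rdna, n_fragments = 10,
                        identity = 0.9632, antisense_prob = 0, seed = 4)
  tot <- 0L; mis <- 0L
  for (i in seq_len(nrow(p2$fragments))) {
    f <- p2$fragments[i, ]
    a <- strsplit(substring(p2$genome[[f$chrom]], f$start + 1, f$end), "")[[1]]
    b <- strsplit(substring(rdna$sequence, f$source_start + 1,
                            f$source_end), "")[[1]]
    tot <- tot + length(a); mis <- mis + sum(a != b)
  }
  expect_gte(tot, 1000)
  p <- 1 - 0.9632
  expect_lt(abs(mis / tot - p), 3 * sqrt(p * (1 - p) / tot))
  # antisense: reverse complement of the planted region matches the source
  p3 <- plant_fragments(genome, genes, rdna, n_fragments = 6,
                        identity = 0.9632, antisense_prob = 1, seed = 5)
  expect_true(all(p3$fragments$orientation == "antisense"))
  for (i in seq_len(nrow(p3$fragments))) {
    f <- p3$fragments[i, ]
    a <- strsplit(rc_chr(substring(p3$genome[[f$chrom]], f$start + 1,
                                   f$end)), "")[[1]]
    b <- strsplit(substring(rdna$sequence, f$source_start + 1,
                            f$source_end), "")[[1]]
    frac <- sum(a != b) / length(a)
    expect_lt(frac, 0.08)  # ~3.7% expected, loose upper bound
    expect_gt(frac, 0)
  }
  expect_error(plant_fragments(genome, genes, rdna, identity = 0.4),
               "identity")
})

test_that("simulated reads match the length, strand and origin model", {
  rdna <- make_rdna_reference(seed = 6)
  sim <- simulate_srrna_reads(rdna, n_reads = 10000, seed = 7)
  len <- nchar(sim$reads$sequence)
  expect_true(all(len >= 19 & len <= 50))
  expect_lt(abs(mean(len) - 29), 0.5)
  sf <- mean(sim$truth$strand == "+")
  expect_lt(abs(sf - 0.995), 2 * sqrt(0.995 * 0.005 / 10000) + 1e-9)
  expect_equal(nchar(sim$reads$quality), len)
  # sense_fraction = 1: no antisense reads
  s2 <- simulate_srrna_reads(rdna, n_reads = 500, sense_fraction = 1,
                             seed = 8)
  expect_true(all(s2$truth$strand == "+"))
  # weight concentrated on one hotspot: reads start inside it
  one <- data.frame(start = 900L, end = 960L, weight = 1, label = "only")
  s3 <- simulate_srrna_reads(rdna, hotspots = one, n_reads = 2000, seed = 9)
  inside <- mean(s3$truth$origin_start >= 900 & s3$truth$origin_start < 960)
  expect_gte(inside, 0.99)
  # determinism and error on empty hotspot list
  s4 <- simulate_srrna_reads(rdna, n_reads = 200, seed = 7)
  s5 <- simulate_srrna_reads(rdna, n_reads = 200, seed = 7)
  expect_identical(s4$reads, s5$reads)
  expect_error(simulate_srrna_reads(rdna, hotspots = data.frame()), "empty")
})

test_that("expression table is zero-inflated log-normal and deterministic", {
  e0 <- simulate_expression_table(1000, zero_fraction = 0, seed = 1)
  expect_true(all(e0$tpm > 0))
  e1 <- simulate_expression_table(1000, zero_fraction = 0.4, seed = 2)
  expect_equal(sum(e1$tpm == 0), 400)
  expect_true(all(e1$tpm >= 0))
  expect_identical(simulate_expression_table(1000, seed = 3),
                   simulate_expression_table(1000, seed = 3))
  expect_error(simulate_expression_table(1000, zero_fraction = 1), "zero_fraction")
  expect_error(simulate_expression_table(1), "n_genes")
})

test_that("state segmentation tiles chromosomes with weight-consistent labels", {
  lens <- c(c1 = 60000L, c2 = 40000L)
  seg <- simulate_state_segmentation(lens, seed = 4)
  for (chrom in names(lens)) {
    s <- seg[seg$chrom == chrom, ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], unname(lens[[chrom]]))
    expect_equal(s$start[-1], s$end[-nrow(s)])
  }
  # one weight = 1 gives a single-state genome
  w <- c(1, rep(0, 14))
  s1 <- simulate_state_segmentation(lens, state_weights = w, seed = 5)
  expect_equal(unique(s1$state), roadmap15_states()[1])
  # empirical bp fractions near the weights (exponential lengths double the
  # binomial variance, hence the factor 2 inside the bound)
  w2 <- rep(1 / 15, 15)
  s2 <- simulate_state_segmentation(c(c1 = 400000L), mean_segment_len = 1000,
                                    state_weights = w2, seed = 6)
  n_seg <- nrow(s2)
  bp <- tapply(s2$end - s2$start, factor(s2$state, roadmap15_states()), sum,
               default = 0)
  frac <- bp / sum(bp)
  # exponential segment lengths double the binomial share variance
  bound <- 4 * sqrt(2 * w2[1] * (1 - w2[1]) / n_seg)
  expect_true(all(abs(frac - w2) < bound))
})

test_that("signal track is a sorted tiling with the configured enrichment", {
  lens <- c(cx = 100000L)
  er <- data.frame(chrom = "cx", start = 20000L, end = 40000L)
  tr <- simulate_signal_track(lens, er, enrichment = 5, seed = 7)
  expect_true(all(tr$start[-1] == tr$end[-nrow(tr)]))  # sorted, bookended
  mid <- (tr$start + tr$end) / 2
  inside <- mid >= 20000 & mid < 40000
  ratio <- mean(rep(tr$value[inside], tr$end[inside] - tr$start[inside])) /
    mean(rep(tr$value[!inside], tr$end[!inside] - tr$start[!inside]))
  expect_lt(abs(ratio - 5) / 5, 0.2)
  # enrichment = 0: flat mean
  tr0 <- simulate_signal_track(lens, er, enrichment = 0, seed = 8)
  m_in <- mean(tr0$value[mid >= 20000 & mid < 40000])
  m_out <- mean(tr0$value[!(mid >= 20000 & mid < 40000)])
  expect_lt(abs(m_in - m_out), 0.1)
  expect_warning(simulate_signal_track(lens,
    data.frame(chrom = "cx", start = c(0L, 100L), end = c(200L, 300L)),
    seed = 9), "merged")
})

test_that("generated FASTQ round-trips through the package reader bit-exactly", {
  rdna <- make_rdna_reference(seed = 10)
  sim <- simulate_srrna_reads(rdna, n_reads = 300, seed = 11)
  path <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_identical(back$read_id, sim$reads$read_id)
  expect_identical(back$sequence, sim$reads$sequence)
  expect_identical(back$quality, sim$reads$quality)
})

test_that("the full study bundle is deterministic and truth-consistent", {
  study <- get_small_study()
  frag <- study$fragments
  hosts <- frag$host_gene_id[!is.na(frag$host_gene_id)]
  expect_setequal(study$truth$true_target_genes, unique(hosts))
  expect_true(all(hosts %in% study$genes$genes$gene_id))
  # fragments land inside their host gene
  g <- study$genes$genes
  for (i in which(!is.na(frag$host_gene_id))) {
    gi <- g[g$gene_id == frag$host_gene_id[i], ]
    expect_true(frag$start[i] >= gi$start && frag$end[i] <= gi$end)
  }
  s2 <- sim_srrna_study(small_study_config(), seed = study$seed)
  expect_identical(s2$reads, study$reads)
  expect_identical(s2$genome, study$genome)
  expect_error(sim_srrna_study(list(bogus_key = 1)), "unknown config key")
})
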