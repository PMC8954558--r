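test_that("shuffle_read conserves (base, quality) pairs and read identity", {
  # homopolymer with uniform quality is invariant
  set.seed(80)
  h <- shuffle_read(strrep("A", 20), qual_str(rep(35, 20)))
  expect_equal(h$sequence, strrep("A", 20))
  expect_equal(h$quality, qual_str(rep(35, 20)))
  # length-1 read unchanged
  expect_equal(shuffle_read("G", "I")$sequence, "G")
  # pairing: each base keeps its quality value
  seq <- "ACGTACGTTT"; qual <- qual_str(c(30:37, 38, 39))
  for (i in 1:20) {
    s <- shuffle_read(seq, qual)
    pairs0 <- sort(paste(strsplit(seq, "")[[1]], utf8ToInt(qual)))
    pairs1 <- sort(paste(strsplit(s$sequence, "")[[1]], utf8ToInt(s$quality)))
    expect_identical(pairs1, pairs0)
  }
  # all six permutations of a 3-mer occur with similar frequency
  out <- replicate(600, shuffle_read("ACG", qual_str(c(1, 2, 3)))$sequence)
  tab <- table(out)
  expect_equal(length(tab), 6)
  expect_true(all(tab > 55))  # expected 100 each
  # shuffle_reads: ids preserved, deterministic under seed
  reads <- uniform_reads(replicate(20, rand_seq(25)))
  s1 <- shuffle_reads(reads, seed = 5)
  s2 <- shuffle_reads(reads, seed = 5)
  expect_identical(s1, s2)
  expect_identical(s1$read_id, reads$read_id)
  expect_false(identical(s1$sequence, reads$sequence))
})

test_that("interval Jaccard is intersection over union after merging", {
  a <- data.frame(chrom = "c", start = 0L, end = 10L)
  b <- data.frame(chrom = "c", start = 5L, end = 15L)
  expect_equal(jaccard_intervals(a, a), 1)
  expect_equal(jaccard_intervals(a, data.frame(chrom = "c", start = 20L,
                                               end = 30L)), 0)
  expect_equal(jaccard_intervals(a, b), 5 / 15)
  # internal merging: split representation of the same set
  a2 <- data.frame(chrom = "c", start = c(0L, 4L), end = c(6L, 10L))
  expect_equal(jaccard_intervals(a2, b), 5 / 15)
  expect_equal(jaccard_intervals(a[0, ], b[0, ]), 0)
})

test_that("hypergeometric overlap tail matches enumeration and phyper", {
  # exact small case: P(X > 2) for sets of 5 and 4 in a universe of 10
  p <- hypergeom_overlap_p(2, 5, 10, 4)
  enum <- (choose(5, 3) * choose(5, 1) + choose(5, 4) * choose(5, 0)) /
    choose(10, 4)
  expect_equal(p, enum, tolerance = 1e-12)
  expect_equal(enum, 55 / 210, tolerance = 1e-12)
  # support bound
  expect_equal(hypergeom_overlap_p(4, 5, 10, 4), 0)
  expect_equal(hypergeom_overlap_p(-1, 5, 10, 4), 1)
  # exhaustive agreement with term-by-term enumeration, universe <= 30
  for (N in c(5, 12, 30)) {
    for (m in unique(c(0, 1, N %/% 3, N %/% 2, N))) {
      for (k in unique(c(0, 1, N %/% 4, N %/% 2, N))) {
        for (q in -1:min(m, k)) {
          lo <- max(q + 1, 0, m + k - N); hi <- min(m, k)
          direct <- if (lo > hi) 0 else
            sum(choose(m, lo:hi) * choose(N - m, k - (lo:hi))) / choose(N, k)
          expect_equal(hypergeom_overlap_p(q, m, N, k), direct,
                       tolerance = 1e-10)
          expect_equal(hypergeom_overlap_p(q, m, N, k),
                       phyper(q, m, N - m, k, lower.tail = FALSE),
                       tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(hypergeom_overlap_p(1, 11, 10, 4), "impossible")
})

test_that("Mann-Whitney U handles symmetry, exact small samples and ties", {
  sym <- mannwhitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$U, 4.5)
  expect_equal(sym$p, 1)
  sep <- mannwhitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 1 / 3)
  expect_equal(sep$method, "exact")
  # agreement with wilcox.test: exact tie-free and tie-corrected normal
  set.seed(81)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(mannwhitney_u(x, y)$p,
                 wilcox.test(x, y)$p.value, tolerance = 1e-12)
  }
  for (i in 1:20) {
    x <- sample(1:8, 30, TRUE); y <- sample(1:8, 25, TRUE)
    expect_equal(mannwhitney_u(x, y)$p,
                 suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
  # p decreases monotonically as a location shift grows
  set.seed(82)
  base <- rlnorm(300)
  ps <- vapply(c(0, 0.3, 0.8, 1.5), function(d)
    mannwhitney_u(base * exp(d), base)$p, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(mannwhitney_u(numeric(0), 1), "empty")
})

test_that("Monte-Carlo type-I calibrations behave at the edges and calibrate", {
  vals <- simulate_expression_table(4000, seed = 83)$tpm
  expect_equal(mc_type1_equal_subsets(vals, 100, 50, alpha = 0,
                                      seed = 1)$rejection_fraction, 0)
  expect_equal(mc_type1_full_vs_subset(vals, 100, 50, alpha = 0,
                                       seed = 1)$rejection_fraction, 0)
  # degenerate all-equal values never reject
  expect_equal(mc_type1_equal_subsets(rep(2, 500), 100, 50,
                                      seed = 2)$rejection_fraction, 0)
  # subset = full set gives p = 1 every repetition
  expect_equal(mc_type1_full_vs_subset(vals, length(vals), 20,
                                       seed = 3)$rejection_fraction, 0)
  # the fast subset-vs-full path equals the direct test
  pre <- srrnascout:::mw_full_precompute(vals)
  set.seed(84)
  for (i in 1:10) {
    sub <- vals[sample.int(length(vals), 150)]
    expect_equal(srrnascout:::mw_subset_vs_full_p(pre, sub),
                 mannwhitney_u(sub, vals)$p, tolerance = 1e-12)
  }
  # calibration on continuous i.i.d. values at reduced repetitions
  cont <- withr::with_seed(85, rnorm(4000))
  cal <- mc_type1_equal_subsets(cont, 400, 2000, alpha = 0.05, seed = 86)
  expect_lt(abs(cal$rejection_fraction - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
  expect_error(mc_type1_equal_subsets(vals, 3000, 10), "2 \\* subset_size")
})

test_that("focal-vs-random Monte-Carlo detects planted shifts and checks inputs", {
  expr <- simulate_expression_table(3000, seed = 87)
  # a uniformly random focal set is not rejected at tiny alpha
  set.seed(88)
  focal_null <- sample(expr$gene_id, 200)
  r0 <- mc_subset_vs_random(expr, focal_null, n_reps = 50, alpha = 1e-4,
                            seed = 89)
  expect_equal(r0$rejection_fraction, 0)
  # the top-expressed genes are rejected in every repetition
  focal_top <- expr$gene_id[order(-expr$tpm)][1:200]
  r1 <- mc_subset_vs_random(expr, focal_top, n_reps = 50, alpha = 1e-4,
                            seed = 90)
  expect_equal(r1$rejection_fraction, 1)
  expect_lt(r1$max_p, 1e-6)
  # reproducible under a fixed seed
  r2 <- mc_subset_vs_random(expr, focal_top, n_reps = 1, seed = 91)
  r3 <- mc_subset_vs_random(expr, focal_top, n_reps = 1, seed = 91)
  expect_equal(r2$max_p, r3$max_p)
  expect_error(mc_subset_vs_random(expr, c("NOT_A_GENE", focal_top)),
               "NOT_A_GENE")
})

test_that("averaged random subsets converge to mean order statistics", {
  expect_equal(averaged_random_subset(rep(3.3, 100), 10, 50, seed = 1),
               rep(3.3, 10))
  set.seed(92)
  vals <- rlnorm(200)
  avg <- averaged_random_subset(vals, 25, 500, seed = 93)
  expect_false(is.unsorted(avg))
  # independent simulation of the same expectation, different rng stream
  ind <- withr::with_seed(94, {
    acc <- numeric(25)
    for (i in 1:4000) acc <- acc + sort(sample(vals, 25))
    acc / 4000
  })
  expect_equal(avg, ind, tolerance = 0.08)
})

test_that("permuted reads collapse while identity comparison is perfect", {
  study <- get_small_study()
  pipe <- run_small_pipeline(study)
  obs_mapped <- unname(pipe$genome$stats["n_aligned"])
  pt <- permutation_trial(study$reads, pipe$rdna_index, pipe$genome_index,
                          study$genes, pipe$table, seed = 95)
  expect_lt(pt$n_mapped_reads, 0.01 * obs_mapped)
  expect_lte(pt$jaccard, 0.01)
  expect_gte(pt$hypergeom_p, 0.05)
  # the observed table against itself: identity "permutation" yields jaccard 1
  obs_regions <- merge_mapping_regions(pipe$table)
  expect_equal(jaccard_intervals(obs_regions, obs_regions), 1)
  # shuffled random reads map nowhere
  rnd <- shuffle_reads(uniform_reads(replicate(100, rand_seq(30))), seed = 96)
  expect_equal(nrow(align_reads(rnd, pipe$rdna_index, 2)$alignments), 0)
})
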