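step_track <- function(chrom, start, end, value) {
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

test_that("metaprofile bins, clips and z-scores as specified", {
  lens <- c(cc = 10000L)
  const <- step_track("cc", 0L, 10000L, 3.5)
  anchors <- data.frame(chrom = "cc", mid = c(3000L, 6000L))
  prof <- metaprofile(const, anchors, chrom_lengths = lens)
  expect_equal(prof$n_bins, 300)  # 2 * 1500 / 10
  expect_true(all(prof$values == 0))        # sd = 0 rule
  expect_true(all(prof$raw_values == 3.5))
  # single anchor over a unit step: raw profile equals manual binning
  tr <- step_track("cc", c(0L, 4000L, 4120L), c(4000L, 4120L, 10000L),
                   c(0, 1, 0))
  one <- data.frame(chrom = "cc", mid = 4000L)
  prof2 <- metaprofile(tr, one, flank = 200, bin = 10, zscore = FALSE,
                       chrom_lengths = lens)
  manual <- vapply(seq_len(40), function(j) {
    lo <- 4000 - 200 + (j - 1) * 10; hi <- lo + 10
    mean(as.numeric(seq(lo, hi - 1) >= 4000 & seq(lo, hi - 1) < 4120))
  }, 0)
  expect_equal(prof2$values, manual)
  # an anchor near the chromosome start is clipped, not dropped
  edge <- metaprofile(const, data.frame(chrom = "cc", mid = 100L),
                      flank = 200, bin = 10, zscore = FALSE,
                      chrom_lengths = lens)
  expect_true(all(is.na(edge$values[1:10])))   # bins fully out of range
  expect_true(all(edge$values[11:40] == 3.5))
  expect_error(metaprofile(const, anchors[0, ], chrom_lengths = lens),
               "no anchors")
  expect_error(metaprofile(const, anchors, flank = 1505, bin = 10,
                           chrom_lengths = lens), "divisible")
})

test_that("metaprofile is linear pre-z-score and affine-invariant post-z-score", {
  set.seed(70)
  lens <- c(cc = 20000L)
  starts <- seq(0L, 19800L, by = 200L)
  tr <- step_track("cc", starts, starts + 200L, runif(length(starts), 0, 4))
  anchors <- data.frame(chrom = "cc", mid = sample(2000:18000, 8))
  raw1 <- metaprofile(tr, anchors, zscore = FALSE, chrom_lengths = lens)
  tr3 <- tr; tr3$value <- 3 * tr3$value
  raw3 <- metaprofile(tr3, anchors, zscore = FALSE, chrom_lengths = lens)
  expect_equal(raw3$values, 3 * raw1$values)
  z1 <- metaprofile(tr, anchors, zscore = TRUE, chrom_lengths = lens)
  tra <- tr; tra$value <- 2.5 * tra$value + 7  # track tiles, so +7 is uniform
  za <- metaprofile(tra, anchors, zscore = TRUE, chrom_lengths = lens)
  expect_equal(za$values, z1$values, tolerance = 1e-12)
  expect_equal(mean(z1$values), 0, tolerance = 1e-12)
  expect_equal(sd(z1$values), 1, tolerance = 1e-12)
})

test_that("anchor midpoints use floor((start + end) / 2)", {
  recs <- data.frame(chrom = c("a", "a", "b"), start = c(100L, 0L, 7L),
                     end = c(130L, 1L, 18L))
  mids <- anchor_midpoints(recs)
  expect_equal(mids$mid, c(115L, 0L, 12L))
  expect_equal(mids$mid, as.integer(floor((recs$start + recs$end) / 2)))
})

test_that("state composition is bp-weighted and sums to one", {
  lens <- c(c1 = 1000L)
  states <- data.frame(chrom = "c1", start = c(0L, 400L), end = c(400L, 1000L),
                       state = c("S1", "S2"), stringsAsFactors = FALSE)
  targets <- data.frame(chrom = "c1", start = c(50L, 100L), end = c(150L, 200L))
  comp <- state_composition(targets, states, lens)
  expect_equal(comp$target_fraction[comp$state == "S1"], 1)  # all inside S1
  expect_equal(sum(comp$target_fraction), 1)
  expect_equal(sum(comp$genome_fraction), 1)
  expect_equal(comp$genome_fraction[comp$state == "S1"], 0.4)
  # single-state genome
  one <- data.frame(chrom = "c1", start = 0L, end = 1000L, state = "only")
  c1 <- state_composition(targets, one, lens)
  expect_equal(c1$target_fraction, 1)
  expect_equal(c1$genome_fraction, 1)
  # random fixture against a brute-force per-bp labelling oracle
  set.seed(71)
  lens2 <- c(cA = 5000L, cB = 4000L)
  seg <- simulate_state_segmentation(lens2, n_states = 4,
                                     mean_segment_len = 300,
                                     state_labels = paste0("st", 1:4),
                                     seed = 72)
  tg <- data.frame(chrom = sample(names(lens2), 30, TRUE),
                   start = sample(0:3500, 30))
  tg$end <- tg$start + sample(20:200, 30, TRUE)
  comp2 <- state_composition(tg, seg, lens2)
  # per-bp oracle
  lab <- list(cA = character(5000), cB = character(4000))
  for (i in seq_len(nrow(seg)))
    lab[[seg$chrom[i]]][(seg$start[i] + 1):seg$end[i]] <- seg$state[i]
  hit <- list(cA = logical(5000), cB = logical(4000))
  for (i in seq_len(nrow(tg)))
    hit[[tg$chrom[i]]][(tg$start[i] + 1):min(tg$end[i], length(hit[[tg$chrom[i]]]))] <- TRUE
  all_lab <- c(lab$cA, lab$cB); all_hit <- c(hit$cA, hit$cB)
  for (stt in paste0("st", 1:4)) {
    expect_equal(comp2$genome_bp[comp2$state == stt], sum(all_lab == stt))
    expect_equal(comp2$target_bp[comp2$state == stt],
                 sum(all_hit & all_lab == stt))
  }
  expect_equal(sum(comp2$target_fraction), 1, tolerance = 1e-9)
})

test_that("the per-state Welch test matches the closed-form statistic", {
  # identical fraction vectors: single-state genome makes target and genome
  # fractions both 1 on every chromosome
  lens <- c(a = 2000L, b = 2000L, c = 2000L)
  one <- data.frame(chrom = rep(c("a", "b", "c")), start = 0L, end = 2000L,
                    state = "only", stringsAsFactors = FALSE)
  tg <- data.frame(chrom = c("a", "b", "c"), start = c(10L, 20L, 30L),
                   end = c(110L, 140L, 160L))
  w1 <- state_welch_test(tg, one, lens)
  expect_equal(w1$t, 0)
  expect_equal(w1$p, 1)
  # two-state genome with known per-chromosome fractions: compare with the
  # closed-form Welch formulas evaluated on those fractions
  cuts <- c(a = 600L, b = 1000L, c = 1400L)
  states <- do.call(rbind, lapply(names(cuts), function(ch)
    data.frame(chrom = ch, start = c(0L, cuts[[ch]]),
               end = c(cuts[[ch]], 2000L), state = c("L", "R"),
               stringsAsFactors = FALSE)))
  tg2 <- data.frame(chrom = c("a", "b", "c"), start = c(0L, 0L, 0L),
                    end = c(100L, 300L, 500L))  # all target bp in state L
  w2 <- state_welch_test(tg2, states, lens)
  x <- c(1, 1, 1)                    # per-chrom target fraction in L
  y <- unname(cuts) / 2000           # per-chrom genome fraction in L
  se <- sqrt(var(x) / 3 + var(y) / 3)
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- (var(x) / 3 + var(y) / 3)^2 /
    ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_manual <- 2 * pt(-abs(t_manual), df_manual)
  row <- w2[w2$state == "L", ]
  expect_equal(row$t, t_manual, tolerance = 1e-12)
  expect_equal(row$df, df_manual, tolerance = 1e-12)
  expect_equal(row$p, p_manual, tolerance = 1e-12)
  expect_error(state_welch_test(tg2, states, lens["a"]), ">= 2 chromosomes")
})

test_that("TSS classification filters minors and pairs divergent promoters", {
  tss <- data.frame(
    chrom = "c1",
    pos = c(1000L, 1500L, 9000L, 10500L, 20000L, 20300L),
    strand = c("-", "+", "-", "+", "+", "+"),
    cage_tpm = c(10, 8, 5, 6, 100, 0.5),
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gE"),
    stringsAsFactors = FALSE)
  cls <- classify_tss(tss)
  # divergent pair 500 bp apart
  expect_equal(cls$class[1:2], c("bidirectional", "bidirectional"))
  # same orientation pair 1500 bp apart
  expect_equal(cls$class[3:4], c("unidirectional", "unidirectional"))
  # minor TSS: 0.5 < 1% of 100 (strict)
  expect_equal(cls$class[6], "filtered_minor")
  expect_equal(cls$class[5], "unidirectional")
  # exactly 1% is kept (strict less-than)
  at <- classify_tss(data.frame(chrom = "c", pos = c(0L, 5000L),
                                strand = "+", cage_tpm = c(100, 1),
                                gene_id = "g"))
  expect_false(any(at$class == "filtered_minor"))
  # convergent pair within 1 kb stays unidirectional
  conv <- classify_tss(data.frame(chrom = "c", pos = c(1000L, 1500L),
                                  strand = c("+", "-"),
                                  cage_tpm = c(5, 5),
                                  gene_id = c("g1", "g2")))
  expect_true(all(conv$class == "unidirectional"))
  expect_error(classify_tss(data.frame(chrom = "c", pos = 1L, strand = "+",
                                       cage_tpm = -1, gene_id = "g")),
               "negative")
})

test_that("TSS metaprofiles use mapping coverage and partition surviving TSSs", {
  lens <- c(cz = 40000L)
  recs <- data.frame(chrom = "cz", start = 19985L, end = 20015L, strand = "+",
                     read_count = 4L, unique_count = 1L, mean_depth = 4,
                     sequence = strrep("A", 30), stringsAsFactors = FALSE)
  tssA <- data.frame(chrom = "cz", pos = c(20000L, 35000L),
                     strand = c("+", "-"), cage_tpm = c(5, 5),
                     gene_id = c("g1", "g2"), stringsAsFactors = FALSE)
  cls <- classify_tss(tssA)
  # no bidirectional TSS in this fixture: skipped with a warning
  expect_warning(tss_metaprofile(recs, cls, flank = 300, bin = 10,
                                 zscore = FALSE, chrom_lengths = lens),
                 "bidirectional")
  profs <- suppressWarnings(
    tss_metaprofile(recs, cls, flank = 300, bin = 10,
                    zscore = FALSE, chrom_lengths = lens))
  expect_named(profs, "unidirectional")
  v <- profs$unidirectional$values
  # one mapping centred on one TSS: symmetric raw profile, all signal central
  expect_equal(v, rev(v), tolerance = 1e-12)
  expect_true(all(v[c(1:25, 36:60)] == 0))
  expect_gt(sum(v), 0)
  # far TSS contributes zeros, halving the central bins' mean
  expect_equal(max(v), 4 * 10 / 10 / 2)
  # every surviving TSS lands in exactly one class
  surv <- cls[cls$class != "filtered_minor", ]
  expect_equal(nrow(surv),
               sum(cls$class == "bidirectional") +
                 sum(cls$class == "unidirectional"))
})
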