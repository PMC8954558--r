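# Statistical validation machinery: within-read shuffling permutation null,
# interval Jaccard, hypergeometric overlap, Mann-Whitney U with Monte-Carlo
# type-I-error calibration, and the averaged random expression subset.

#' Shuffle a read's (base, quality) pairs
#'
#' Permutes the order of the read's letters uniformly at random
#' (Fisher-Yates), moving each base together with its quality value, so the
#' (base, quality) multiset — and hence composition and GC content — is
#' conserved exactly while contiguous homology is destroyed.
#'
#' @param sequence nucleotide string.
#' @param quality Phred+33 string of the same length.
#' @return list `sequence`, `quality`.
#' @export
shuffle_read <- function(sequence, quality) {
  n <- nchar(sequence)
  if (n <= 1) return(list(sequence = sequence, quality = quality))
  perm <- sample.int(n)
  s <- utf8ToInt(sequence)[perm]
  q <- utf8ToInt(quality)[perm]
  list(sequence = intToUtf8(s), quality = intToUtf8(q))
}

#' Shuffle every read in a set
#'
#' @param reads a [small_read_set()].
#' @param seed optional integer seed.
#' @return a [small_read_set()] with identical ids and per-read (base,
#'   quality) multisets, orders permuted.
#' @export
shuffle_reads <- function(reads, seed = NULL) {
  run <- function() {
    n <- nrow(reads)
    seqs <- character(n); quals <- character(n)
    for (i in seq_len(n)) {
      r <- shuffle_read(reads$sequence[i], reads$quality[i])
      seqs[i] <- r$sequence; quals[i] <- r$quality
    }
    small_read_set(reads$read_id, seqs, quals)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Jaccard statistic of two genomic interval sets
#'
#' Total intersection bp over total union bp after merging each set
#' internally; defined as 0 when the union is empty.
#'
#' @param set_a,set_b data.frames chrom/start/end (0-based half-open).
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_intervals <- function(set_a, set_b) {
  to_gr <- function(d) {
    if (!nrow(d)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(GenomicRanges::GRanges(d$chrom,
      IRanges::IRanges(d$start + 1L, d$end)))
  }
  a <- to_gr(set_a); b <- to_gr(set_b)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
  if (uni == 0) 0 else inter / uni
}

#' Hypergeometric tail probability of a gene-set overlap
#'
#' Returns `P(X > overlap_exceeding)` for
#' `X ~ Hypergeometric(universe, set_a_size, set_b_size)` (the number of
#' elements shared by a fixed `set_a_size`-element set and a random
#' `set_b_size`-element set drawn from `universe`), computed by log-space
#' summation of the exact terms.
#'
#' @param overlap_exceeding threshold `q` (>= -1); the upper tail is strict.
#' @param set_a_size,set_b_size the two set sizes.
#' @param universe universe size.
#' @return the tail probability.
#' @export
hypergeom_overlap_p <- function(overlap_exceeding, set_a_size, universe,
                                set_b_size) {
  if (set_a_size > universe || set_b_size > universe || set_a_size < 0 ||
      set_b_size < 0 || universe < 0)
    stop("impossible configuration: set sizes must lie in [0, universe]")
  if (overlap_exceeding < -1) stop("overlap_exceeding must be >= -1")
  hi <- min(set_a_size, set_b_size)
  lo <- max(overlap_exceeding + 1, 0, set_a_size + set_b_size - universe)
  if (lo > hi) return(0)
  x <- seq(lo, hi)
  logp <- lchoose(set_a_size, x) +
    lchoose(universe - set_a_size, set_b_size - x) -
    lchoose(universe, set_b_size)
  m <- max(logp)
  exp(m + log(sum(exp(logp - m))))
}

# Core two-sided Mann-Whitney p from U and sample sizes, normal
# approximation with tie-corrected variance and continuity correction.
mw_normal_p <- function(U, n1, n2, tie_term) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(z = 0, p = 1))
  d <- U - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  list(z = z, p = min(1, 2 * pnorm(-abs(z))))
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties.  The p-value uses the exact null
#' distribution when `n1 + n2 <= exact_max_n` and there are no ties, and the
#' normal approximation with tie-corrected variance and continuity
#' correction otherwise.
#'
#' @param x,y numeric samples (nonempty).
#' @param two_sided two-sided test (default); otherwise the one-sided
#'   p-value for the alternative that `x` is stochastically greater.
#' @param exact_max_n size limit for the exact method (default 12).
#' @return list: `U` (statistic for `x`), `p`, `method`.
#' @export
mannwhitney_u <- function(x, y, two_sided = TRUE, exact_max_n = 12) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tt <- rle(sort(z))$lengths
  has_ties <- any(tt > 1)
  if (!has_ties && n1 + n2 <= exact_max_n) {
    if (two_sided) {
      p <- if (U > n1 * n2 / 2)
        2 * pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      else
        2 * pwilcox(U, n1, n2)
      p <- min(1, p)
    } else {
      p <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    }
    return(list(U = U, p = p, method = "exact"))
  }
  tie_term <- sum(tt^3 - tt)
  if (two_sided) {
    res <- mw_normal_p(U, n1, n2, tie_term)
    return(list(U = U, p = res$p, method = "normal"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  zstat <- (U - mu - 0.5) / sqrt(sigma2)
  list(U = U, p = pnorm(zstat, lower.tail = FALSE), method = "normal")
}

# Precomputed order structure of a fixed reference vector, for fast repeated
# subset-vs-full Mann-Whitney tests without re-ranking the full vector.
mw_full_precompute <- function(values) {
  sv <- sort(values)
  rl <- rle(sv)
  d <- rl$values                      # distinct values, ascending
  b <- rl$lengths                     # tie counts in the full vector
  a <- c(0, cumsum(b))[seq_along(b)]  # #full < d[i]
  list(n = length(values), d = d, b = b, a = a,
       tie_full = sum(b^3 - b))
}

# Two-sided p of subset (values[idx]) vs the full vector, where the subset
# values are drawn from the full vector.  Midranks in the combined sample
# are reconstructed incrementally from the precomputed full-vector order.
mw_subset_vs_full_p <- function(pre, subset_values) {
  m <- length(subset_values)
  ssort <- sort(subset_values)
  rl <- rle(ssort)
  dv <- rl$values; s <- rl$lengths
  i <- findInterval(dv, pre$d)        # exact positions (subset values in full)
  a <- pre$a[i]; b <- pre$b[i]
  As <- c(0, cumsum(s))[seq_along(s)] # #subset < dv[j]
  ranksum <- sum(s * (a + As + (b + s + 1) / 2))
  U <- ranksum - m * (m + 1) / 2
  tie_term <- pre$tie_full + sum((b + s)^3 - (b + s) - (b^3 - b))
  mw_normal_p(U, m, pre$n, tie_term)$p
}

#' Monte-Carlo type-I error of the Mann-Whitney test on two equal subsets
#'
#' Per repetition, the expression vector is shuffled (Fisher-Yates), two
#' disjoint subsets of `subset_size` values are taken, and the two-sided
#' Mann-Whitney U-test is applied; the fraction of repetitions with
#' `p < alpha` estimates the empirical type-I error rate at nominal level
#' `alpha` under a true null.
#'
#' @param values numeric expression vector (length >= `2 * subset_size`).
#' @param subset_size subset size (default 1575).
#' @param n_reps repetitions (default 10000).
#' @param alpha nominal level (default 0.05; strict `<`).
#' @param seed integer seed.
#' @return list: `n_reps`, `alpha`, `rejection_fraction`,
#'   `mode = "equal_subsets"`, `seed`.
#' @export
mc_type1_equal_subsets <- function(values, subset_size = 1575,
                                   n_reps = 10000, alpha = 0.05, seed = 1) {
  if (2 * subset_size > length(values))
    stop("values must contain at least 2 * subset_size elements")
  rej <- withr::with_seed(seed, {
    hits <- 0L
    m <- subset_size
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(length(values), 2L * m)
      z <- values[idx]
      r <- rank(z)
      U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
      tt <- rle(sort(z))$lengths
      p <- mw_normal_p(U, m, m, sum(tt^3 - tt))$p
      if (p < alpha) hits <- hits + 1L
    }
    hits / n_reps
  })
  list(n_reps = n_reps, alpha = alpha, rejection_fraction = rej,
       mode = "equal_subsets", seed = seed)
}

#' Monte-Carlo type-I error of the Mann-Whitney test, full set vs subset
#'
#' Per repetition a `subset_size`-value subset is drawn from the shuffled
#' vector and tested two-sided against the full vector.
#'
#' @inheritParams mc_type1_equal_subsets
#' @return list as in [mc_type1_equal_subsets()] with
#'   `mode = "full_vs_subset"`.
#' @export
mc_type1_full_vs_subset <- function(values, subset_size = 1575,
                                    n_reps = 10000, alpha = 0.05, seed = 1) {
  if (subset_size > length(values))
    stop("subset_size exceeds the number of values")
  pre <- mw_full_precompute(values)
  rej <- withr::with_seed(seed, {
    hits <- 0L
    for (rep in seq_len(n_reps)) {
      idx <- sample.int(length(values), subset_size)
      p <- mw_subset_vs_full_p(pre, values[idx])
      if (p < alpha) hits <- hits + 1L
    }
    hits / n_reps
  })
  list(n_reps = n_reps, alpha = alpha, rejection_fraction = rej,
       mode = "full_vs_subset", seed = seed)
}

#' Monte-Carlo comparison of a focal gene set against random gene sets
#'
#' Per repetition the focal genes' expression values are tested (two-sided
#' Mann-Whitney) against the values of an equal-size uniformly drawn gene
#' set; reports the maximum p over repetitions and the rejection fraction at
#' `alpha`.
#'
#' @param expression data.frame `gene_id`, `tpm`.
#' @param focal_genes character vector of gene ids (all must be present).
#' @param n_reps repetitions (default 10000).
#' @param alpha rejection level (default 1e-4).
#' @param seed integer seed.
#' @return list: `max_p`, `rejection_fraction`, `n_reps`, `alpha`, `seed`.
#' @export
mc_subset_vs_random <- function(expression, focal_genes, n_reps = 10000,
                                alpha = 1e-4, seed = 1) {
  missing <- setdiff(focal_genes, expression$gene_id)
  if (length(missing))
    stop("focal genes missing from the expression table: ",
         paste(missing, collapse = ", "))
  x <- expression$tpm[match(focal_genes, expression$gene_id)]
  m <- length(x)
  res <- withr::with_seed(seed, {
    max_p <- 0; hits <- 0L
    for (rep in seq_len(n_reps)) {
      y <- expression$tpm[sample.int(nrow(expression), m)]
      z <- c(x, y)
      r <- rank(z)
      U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
      tt <- rle(sort(z))$lengths
      p <- mw_normal_p(U, m, m, sum(tt^3 - tt))$p
      if (p > max_p) max_p <- p
      if (p < alpha) hits <- hits + 1L
    }
    list(max_p = max_p, rej = hits / n_reps)
  })
  list(max_p = res$max_p, rejection_fraction = res$rej, n_reps = n_reps,
       alpha = alpha, seed = seed)
}

#' Averaged random expression subset (sorted-mean profile)
#'
#' Per trial a `subset_size`-value subset is drawn, sorted ascending and
#' accumulated element-wise; the accumulator is divided by the number of
#' trials.  The result is the mean order-statistic profile of a random
#' subset and is nondecreasing by construction.
#'
#' @param values numeric vector.
#' @param subset_size subset size (default 1575).
#' @param n_trials number of trials (default 10000).
#' @param seed integer seed.
#' @return nondecreasing numeric vector of length `subset_size`.
#' @export
averaged_random_subset <- function(values, subset_size = 1575,
                                   n_trials = 10000, seed = 1) {
  if (subset_size > length(values))
    stop("subset_size exceeds the number of values")
  withr::with_seed(seed, {
    acc <- numeric(subset_size)
    for (t in seq_len(n_trials))
      acc <- acc + sort(values[sample.int(length(values), subset_size)])
    acc / n_trials
  })
}
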