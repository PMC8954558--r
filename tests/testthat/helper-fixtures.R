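# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (per-position loops, literal rule application) and independent of the
# package implementation paths they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

qual_str <- function(scores) intToUtf8(scores + 33L)

uniform_reads <- function(seqs, q = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  small_read_set(ids, seqs,
                 vapply(nchar(seqs), function(n) qual_str(rep(q, n)), ""))
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Exhaustive Hamming scan over every position and strand of every target.
brute_align_one <- function(seq, refs, max_mm) {
  L <- nchar(seq)
  hits <- list()
  for (tn in sort(names(refs))) {
    ref <- refs[[tn]]
    n <- nchar(ref)
    if (L > n) next
    rv <- strsplit(ref, "")[[1]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else rc_chr(seq)
      qv <- strsplit(q, "")[[1]]
      P <- n - L + 1L
      mm <- integer(P)
      for (i in seq_len(L)) {
        seg <- rv[i:(i + P - 1L)]
        mm <- mm + (seg != qv[i] | seg == "N" | qv[i] == "N")
      }
      ok <- which(mm <= max_mm)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          target = tn, start = ok - 1L, strand = strand, mm = mm[ok],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  h <- do.call(rbind, hits)
  best <- min(h$mm)
  h <- h[h$mm == best, , drop = FALSE]
  h <- h[order(h$target, h$start, factor(h$strand, levels = c("+", "-"))), ,
         drop = FALSE]
  list(target = h$target[1], start = h$start[1], strand = h$strand[1],
       mismatches = best, multiplicity = nrow(h))
}

# Literal step-by-step reference implementation of the trimming rules.
trim_oracle <- function(sequence, quality, leading_q = 18, trailing_q = 18,
                        window = 4, window_q = 22, min_len = 20) {
  q <- utf8ToInt(quality) - 33L
  s <- strsplit(sequence, "")[[1]]
  while (length(q) && q[1] < leading_q) { q <- q[-1]; s <- s[-1] }
  while (length(q) && q[length(q)] < trailing_q) {
    q <- q[-length(q)]; s <- s[-length(s)]
  }
  if (length(q) >= window) {
    for (i in seq_len(length(q) - window + 1L)) {
      if (mean(q[i:(i + window - 1L)]) < window_q) {
        q <- q[seq_len(i - 1L)]; s <- s[seq_len(i - 1L)]
        break
      }
    }
  } else if (length(q) && mean(q) < window_q) {
    q <- integer(0); s <- character(0)
  }
  if (length(q) < min_len) return(NULL)
  list(sequence = paste(s, collapse = ""), quality = qual_str(q))
}

# Sweep-line interval merge oracle.
sweep_merge <- function(df, gap = 0) {
  out <- list()
  for (chrom in sort(unique(df$chrom))) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= ce + gap) ce <- max(ce, d$end[i])
      else {
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = cs,
                                              end = ce)
        cs <- d$start[i]; ce <- d$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = cs, end = ce)
  }
  do.call(rbind, out)
}

# Exact two-sided Mann-Whitney p by exhaustive label enumeration (tie-free).
mw_enum_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x); N <- length(z)
  mu <- n1 * (N - n1) / 2
  obs <- sum(rank(z)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2, function(ix)
    sum(rank(z)[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(obs - mu))
}

# Small, cached study for pipeline-level tests.
.fixture_env <- new.env(parent = emptyenv())
small_study_config <- function() {
  list(chrom_lengths = c(chrA = 100000L, chrB = 100000L, chrC = 100000L),
       n_genes = 15L, n_reads = 4000L, n_fragments = 12L,
       n_expression_genes = 2000L, n_contacting_genes = 10L)
}
get_small_study <- function(seed = 7) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- sim_srrna_study(small_study_config(), seed = seed)
  .fixture_env[[key]]
}

run_small_pipeline <- function(study) {
  key <- paste0("pipe_", study$seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  tr <- trim_reads(study$reads)
  ri <- seq_index(study$rdna)
  sel <- select_rdna_reads(tr$reads, ri, 2)
  gi <- seq_index(study$genome)
  gal <- align_reads(sel$reads, gi, 1)
  tab <- mapping_table(gal$alignments, study$reads)
  out <- list(trimmed = tr, rdna_index = ri, selection = sel,
              genome_index = gi, genome = gal, table = tab)
  .fixture_env[[key]] <- out
  out
}
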