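# Configuration validation and end-to-end execution:
# simulate -> qc -> rDNA pass -> genome pass -> targets -> epigenomics ->
# validation, with a machine-readable run manifest.

default_run_config <- function() {
  list(seed = 1L,
       outdir = NULL,
       simulate = default_study_config(),
       qc = list(leading_q = 18, trailing_q = 18, window = 4, window_q = 22,
                 min_len = 20, end_trim_q = 18),
       align = list(k = 12L, rdna_max_mismatch = 2L, genome_max_mismatch = 1L),
       profile = list(flank = 1500L, bin = 10L),
       tss = list(minor_fraction = 0.01, bidir_max_dist = 1000L),
       permutation = list(n_trials = 10L, cor_bin = 1000L),
       mc = list(n_reps = 0L, subset_size = 1575L, alpha = 0.05))
}

merge_config <- function(defaults, given, path = "") {
  for (key in names(given)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(given[[key]]))
        stop("config key ", full, " must be a block")
      defaults[[key]] <- merge_config(defaults[[key]], given[[key]], full)
    } else {
      defaults[key] <- list(given[[key]])  # keeps explicit NULLs
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Accepts a YAML file path, YAML text, or a named list; missing entries are
#' filled from the defaults (trim 18/18/4:22/20, flank 1500 bp, bin 10 bp,
#' minor-TSS threshold 1%, bidirectional distance 1000 bp), unknown keys are
#' rejected, and invalid thresholds raise an error naming the key.
#'
#' @param config path, YAML string, or named list.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list or YAML")
  cfg <- merge_config(default_run_config(), config)
  cfg$simulate$chrom_lengths <- unlist(cfg$simulate$chrom_lengths)
  check <- function(ok, key) if (!ok) stop("invalid config value: ", key)
  check(cfg$seed >= 0, "seed")
  for (k in c("leading_q", "trailing_q", "window_q"))
    check(cfg$qc[[k]] >= 0, paste0("qc.", k))
  check(cfg$qc$window >= 1, "qc.window")
  check(cfg$qc$min_len >= 1, "qc.min_len")
  check(cfg$align$k >= 8, "align.k")
  check(cfg$align$rdna_max_mismatch >= 0, "align.rdna_max_mismatch")
  check(cfg$align$genome_max_mismatch >= 0, "align.genome_max_mismatch")
  check(cfg$profile$flank %% cfg$profile$bin == 0, "profile.flank")
  check(cfg$tss$minor_fraction >= 0 && cfg$tss$minor_fraction < 1,
        "tss.minor_fraction")
  check(cfg$tss$bidir_max_dist > 0, "tss.bidir_max_dist")
  check(cfg$permutation$n_trials >= 0, "permutation.n_trials")
  check(cfg$mc$n_reps >= 0, "mc.n_reps")
  check(cfg$simulate$identity > 0.5 && cfg$simulate$identity <= 1,
        "simulate.identity")
  structure(cfg, class = c("run_config", "list"))
}

#' Serialise a run configuration as YAML
#'
#' @param config a `run_config`.
#' @return YAML text; re-validating it reproduces the configuration.
#' @export
emit_config <- function(config) {
  cfg <- unclass(config)
  cfg$simulate$chrom_lengths <- as.list(cfg$simulate$chrom_lengths)
  yaml::as.yaml(cfg)
}

#' Run the full analysis end to end
#'
#' Executes the stages in fixed order (simulate, qc, rDNA pass, genome pass,
#' target assignment, epigenomics, validation), writing outputs under
#' `config$outdir` when set, and returns a run manifest with per-stage
#' record counts, derived seeds and wall times.  On stage failure the
#' partial manifest is still written (when an outdir is set) and the error
#' is re-raised with the stage name.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @return list: `manifest` and `results` (all intermediate objects).
#' @export
run_all <- function(config = list()) {
  cfg <- validate_config(config)
  seed <- cfg$seed
  outdir <- cfg$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("srrnascout")),
                   seeds = list(), counts = list(), wall_times = list(),
                   stages = character(), status = "running")
  results <- list()
  write_manifest <- function() {
    if (!is.null(outdir)) {
      m <- manifest
      m$config$simulate$chrom_lengths <-
        as.list(m$config$simulate$chrom_lengths)
      jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
    }
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- paste0("failed at stage ", name, ": ",
                                 conditionMessage(e))
      write_manifest()
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages <<- c(manifest$stages, name)
    manifest$wall_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  manifest$seeds$simulate <- derive_seed(seed, 1)
  results$study <- stage("simulate", {
    sim_srrna_study(cfg$simulate, seed = derive_seed(seed, 1),
                    outdir = if (is.null(outdir)) NULL
                             else file.path(outdir, "inputs"))
  })
  study <- results$study
  manifest$counts$reads_simulated <- nrow(study$reads)

  results$qc <- stage("qc", {
    trimmed <- trim_reads(study$reads, cfg$qc$leading_q, cfg$qc$trailing_q,
                          cfg$qc$window, cfg$qc$window_q, cfg$qc$min_len)
    unique_reads <- dedup_reads(trimmed$reads, cfg$qc$end_trim_q)
    list(trimmed = trimmed, unique_reads = unique_reads,
         lengths = read_length_summary(trimmed$reads))
  })
  manifest$counts$reads_trimmed <- unname(results$qc$trimmed$counts["kept"])
  manifest$counts$reads_unique <- nrow(results$qc$unique_reads)

  results$rdna_pass <- stage("rdna_pass", {
    idx <- seq_index(study$rdna, k = cfg$align$k)
    sel <- select_rdna_reads(results$qc$trimmed$reads, idx,
                             max_mismatch = cfg$align$rdna_max_mismatch)
    list(index = idx, selection = sel,
         coverage = rdna_coverage(sel$alignments, study$rdna),
         sense_fraction = if (nrow(sel$alignments))
           strand_fraction(sel$alignments) else NA_real_)
  })
  manifest$counts$reads_rdna_selected <- nrow(results$rdna_pass$selection$reads)

  results$genome_pass <- stage("genome_pass", {
    idx <- seq_index(study$genome, k = cfg$align$k)
    gal <- align_reads(results$rdna_pass$selection$reads, idx,
                       max_mismatch = cfg$align$genome_max_mismatch)
    tab <- mapping_table(gal$alignments, study$reads)
    regions <- merge_mapping_regions(tab)
    list(index = idx, alignments = gal, table = tab, regions = regions)
  })
  manifest$counts$reads_genome_mapped <-
    unname(results$genome_pass$alignments$stats["n_aligned"])
  manifest$counts$mapping_records <- nrow(results$genome_pass$table)
  manifest$counts$merged_regions <- nrow(results$genome_pass$regions)

  results$targets <- stage("targets", {
    tg <- assign_target_genes(results$genome_pass$table, study$genes)
    target_ids <- exclude_rdna_family(tg$targets$gene_id)
    venn <- overlap_gene_lists(target_ids, study$contacting_genes)
    list(assignment = tg, target_genes = target_ids, venn = venn)
  })
  manifest$counts$target_genes <- length(results$targets$target_genes)

  results$epigenomics <- stage("epigenomics", {
    tab <- results$genome_pass$table
    lens <- cfg$simulate$chrom_lengths
    anchors <- anchor_midpoints(tab)
    prof <- if (nrow(anchors))
      metaprofile(study$track, anchors, flank = cfg$profile$flank,
                  bin = cfg$profile$bin, chrom_lengths = lens) else NULL
    comp <- state_composition(tab, study$states, lens)
    welch <- state_welch_test(tab, study$states, lens)
    cls <- classify_tss(study$tss, cfg$tss$minor_fraction,
                        cfg$tss$bidir_max_dist)
    tssprof <- tss_metaprofile(tab, cls, flank = cfg$profile$flank,
                               bin = cfg$profile$bin, chrom_lengths = lens)
    list(metaprofile = prof, state_composition = comp, state_welch = welch,
         tss_classes = cls, tss_profiles = tssprof)
  })
  manifest$counts$tss_bidirectional <-
    sum(results$epigenomics$tss_classes$class == "bidirectional")
  manifest$counts$tss_unidirectional <-
    sum(results$epigenomics$tss_classes$class == "unidirectional")

  results$validation <- stage("validation", {
    out <- list()
    if (cfg$permutation$n_trials > 0) {
      out$permutation <- run_permutation_trials(
        study$reads, results$rdna_pass$index, results$genome_pass$index,
        study$genes, results$genome_pass$table,
        n_trials = cfg$permutation$n_trials,
        seed = derive_seed(seed, 20),
        trim = cfg$qc[c("leading_q", "trailing_q", "window", "window_q",
                        "min_len")],
        rdna_max_mismatch = cfg$align$rdna_max_mismatch,
        genome_max_mismatch = cfg$align$genome_max_mismatch,
        cor_bin = cfg$permutation$cor_bin)
    } else out$permutation_skipped <- TRUE
    if (cfg$mc$n_reps > 0) {
      out$mc_equal <- mc_type1_equal_subsets(
        study$expression$tpm, cfg$mc$subset_size, cfg$mc$n_reps,
        cfg$mc$alpha, seed = derive_seed(seed, 21))
      out$mc_full <- mc_type1_full_vs_subset(
        study$expression$tpm, cfg$mc$subset_size, cfg$mc$n_reps,
        cfg$mc$alpha, seed = derive_seed(seed, 22))
    } else out$mc_skipped <- TRUE
    out
  })
  manifest$counts$permutation_trials <- cfg$permutation$n_trials
  if (is.data.frame(results$validation[["permutation"]]))
    manifest$counts$permutation_max_mapped_reads <-
      max(results$validation$permutation$n_mapped_reads)

  if (!is.null(outdir)) {
    write_tsv(results$genome_pass$table, file.path(outdir, "mapping_table.tsv"))
    write_tsv(results$genome_pass$regions, file.path(outdir, "regions.tsv"))
    write_tsv(results$targets$assignment$targets,
              file.path(outdir, "target_genes.tsv"))
    cov <- results$rdna_pass$coverage
    write_bedgraph(data.frame(chrom = study$rdna$name,
                              start = seq_along(cov$sense_depth) - 1L,
                              end = seq_along(cov$sense_depth),
                              value = cov$sense_depth),
                   file.path(outdir, "rdna_coverage_sense.bedGraph"))
    write_bedgraph(data.frame(chrom = study$rdna$name,
                              start = seq_along(cov$antisense_depth) - 1L,
                              end = seq_along(cov$antisense_depth),
                              value = cov$antisense_depth),
                   file.path(outdir, "rdna_coverage_antisense.bedGraph"))
    if (is.data.frame(results$validation[["permutation"]]))
      write_tsv(results$validation[["permutation"]],
                file.path(outdir, "permutation_trials.tsv"))
  }
  manifest$status <- "ok"
  write_manifest()
  list(manifest = manifest, results = results)
}
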