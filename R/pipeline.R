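# End-to-end orchestration: simulate -> sequence -> genotype -> model.
#
# A single run config drives every stage; the master seed deterministically
# derives one child seed per stage, so the whole run is bit-reproducible.

run_config_defaults <- function() {
  list(
    array = list(n_units = 14L, unit_length = 2000L, intervening_length = 0L,
                 flank_anchor_length = 1000L, unit_divergence_rate = 0),
    background_length = 32000L,
    n_chromosomes = 2L,
    population = list(p_exp = 0.05, step_mean = 1.5, k = 1e-5,
                      origin_mode = "internal", d_internal_side = 1000,
                      d_external = 10000, population_cap = 500L,
                      n_generations = 30L),
    long_reads = list(length_meanlog = log(35000), length_sdlog = 0.45,
                      n_reads = 80L, substitution_error_rate = 0),
    short_reads = list(read_length = 300L, depth = 10,
                       substitution_error_rate = 0),
    qpcr = list(noise_sd = 1, n_replicates = 3L, g_per_day = 10),
    analysis = list(min_identity = 0.8, min_unit_fraction = 0.6,
                    bin_size = 100L, gain_threshold = 1.25,
                    loss_threshold = 0.75, min_flank_length = 200L,
                    window = 2000L, n_boot = 200L),
    master_seed = 1L
  )
}

check_range <- function(errs, val, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
    c(errs, sprintf("%s: must be a finite number", field))
  } else if (val < lo || val > hi) {
    c(errs, sprintf("%s: must be in [%s, %s], got %s", field, lo, hi, val))
  } else errs
}

#' Validate and normalize a run configuration
#'
#' Accepts a JSON or YAML file (by extension) or an R list. Unknown keys
#' are rejected and all schema violations are reported together, not just
#' the first; missing fields are filled with documented defaults.
#'
#' @param config path to a JSON/YAML config, or a named list.
#' @return a normalized config list of class `run_config`; on invalid
#'   input, an error listing every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- run_config_defaults()
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  for (sec in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(bad)) {
        errs <- c(errs, sprintf("unknown key(s) in %s: %s", sec,
                                paste(bad, collapse = ", ")))
      }
    }
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  errs <- check_range(errs, cfg$array$n_units, "array.n_units", 0)
  errs <- check_range(errs, cfg$array$unit_length, "array.unit_length", 1)
  errs <- check_range(errs, cfg$array$intervening_length,
                      "array.intervening_length", 0)
  errs <- check_range(errs, cfg$array$unit_divergence_rate,
                      "array.unit_divergence_rate", 0, 1)
  errs <- check_range(errs, cfg$background_length, "background_length", 1)
  errs <- check_range(errs, cfg$population$p_exp, "population.p_exp", 0, 1)
  errs <- check_range(errs, cfg$population$step_mean, "population.step_mean", 1)
  errs <- check_range(errs, cfg$population$k, "population.k", 0)
  if (!cfg$population$origin_mode %in% c("internal", "external")) {
    errs <- c(errs, "population.origin_mode: must be 'internal' or 'external'")
  }
  errs <- check_range(errs, cfg$population$population_cap,
                      "population.population_cap", 1)
  errs <- check_range(errs, cfg$population$n_generations,
                      "population.n_generations", 0)
  errs <- check_range(errs, cfg$long_reads$substitution_error_rate,
                      "long_reads.substitution_error_rate", 0, 1)
  errs <- check_range(errs, cfg$short_reads$substitution_error_rate,
                      "short_reads.substitution_error_rate", 0, 1)
  errs <- check_range(errs, cfg$qpcr$noise_sd, "qpcr.noise_sd", 0)
  errs <- check_range(errs, cfg$qpcr$g_per_day, "qpcr.g_per_day", 1e-9)
  errs <- check_range(errs, cfg$master_seed, "master_seed", 0, 2^31 - 1)
  if (length(errs)) {
    stop("invalid run config:\n  ", paste(errs, collapse = "\n  "))
  }
  structure(cfg, class = c("run_config", "list"))
}

log_stage <- function(quiet, stage, msg) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline on synthetic data
#'
#' Executes, in order: genome construction, population simulation and
#' qPCR-like measurement, long-read simulation with spanning-read unit
#' counting, short-read depth with masked normalization and ploidy calls,
#' the split-read rearrangement screen, and the kinetics summary (empirical
#' and model CNA/G, plus a rate-constant fit when the measured series
#' decreases). Every estimate in the report is paired with the truth the
#' generator recorded. Runs are bit-reproducible for a fixed master seed;
#' all intermediate files are written in standard formats (FASTA, FASTQ,
#' BED, TSV, bedGraph, JSON).
#'
#' @param config a [validate_config()]-normalized config (lists and paths
#'   are validated on the fly).
#' @param out_dir output directory for intermediate files and the report;
#'   `NULL` skips file output.
#' @param quiet suppress per-stage progress messages.
#' @return a list of class `run_report`; see the `truth_vs_estimate`
#'   element for the paired summary table.
#' @export
run_end_to_end <- function(config, out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  seed <- config$master_seed
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- synthetic genome -----------------------------------------------
  log_stage(quiet, "genome", "building array genome")
  spec <- array_spec(
    n_units = config$array$n_units,
    unit_length = config$array$unit_length,
    intervening_length = config$array$intervening_length,
    flank_anchor_length = config$array$flank_anchor_length,
    unit_divergence_rate = config$array$unit_divergence_rate
  )
  genome <- run_stage("genome", build_array_genome(
    spec, config$background_length, seed = derive_seed(seed, 1L),
    n_chromosomes = config$n_chromosomes
  ))
  if (!is.null(out_dir)) write_genome(genome, out_dir)

  # --- population dynamics + measurement ------------------------------
  log_stage(quiet, "population", "simulating copy-number dynamics")
  nrep <- config$qpcr$n_replicates
  pops <- run_stage("population", lapply(seq_len(nrep), function(r) {
    p <- sim_params(
      p_exp = config$population$p_exp, step_mean = config$population$step_mean,
      k = config$population$k, origin_mode = config$population$origin_mode,
      d_internal_side = config$population$d_internal_side,
      d_external = config$population$d_external,
      unit_length_bp = config$array$unit_length,
      population_cap = config$population$population_cap,
      seed = derive_seed(seed, 100L + r)
    )
    simulate_population(max(config$array$n_units, 1L), p,
                        config$population$n_generations)
  }))
  series <- run_stage("qpcr", simulate_qpcr_series(
    lapply(pops, `[[`, "trajectory"), config$qpcr$noise_sd,
    seed = derive_seed(seed, 2L)
  ))
  if (!is.null(out_dir)) {
    write_copy_series(series, file.path(out_dir, "copy_number_series.tsv"))
  }

  # --- kinetics summary -----------------------------------------------
  G <- config$population$n_generations
  mean_by_time <- tapply(series$copy_number, series$time, mean)
  times <- as.numeric(names(mean_by_time))
  cna_g_emp <- if (G > 0) {
    cna_g_empirical(mean_by_time[[length(mean_by_time)]],
                    mean_by_time[[1]], G)
  } else 0
  T_days <- G / config$qpcr$g_per_day
  cna_g_mod <- if (G > 0 && T_days > 0) {
    cna_g_model(max(config$array$n_units, 1L), config$population$k,
                T_days, G)
  } else 0
  kfit <- NULL
  if (length(times) >= 3 && mean_by_time[[length(mean_by_time)]] <
      mean_by_time[[1]]) {
    log_stage(quiet, "kinetics", "fitting contraction rate constant")
    traj_days <- trajectory(times / config$qpcr$g_per_day,
                            as.numeric(mean_by_time))
    kfit <- run_stage("kinetics", fit_k(
      traj_days, G_per_day = config$qpcr$g_per_day,
      n_boot = config$analysis$n_boot, seed = derive_seed(seed, 3L)
    ))
    if (!is.null(out_dir)) write_k_fit(kfit, file.path(out_dir, "k_fit.json"))
  }

  # --- long reads + spanning-read genotyping --------------------------
  log_stage(quiet, "spanscan", "simulating long reads and counting units")
  lr_params <- read_sim_params(
    length_distribution = list(type = "lognormal",
                               meanlog = config$long_reads$length_meanlog,
                               sdlog = config$long_reads$length_sdlog),
    n_reads = config$long_reads$n_reads,
    substitution_error_rate = config$long_reads$substitution_error_rate,
    seed = derive_seed(seed, 4L)
  )
  long_reads <- run_stage("spanscan", simulate_reads(genome, lr_params))
  if (!is.null(out_dir)) {
    write_reads_fastq(long_reads, file.path(out_dir, "long_reads.fastq.gz"))
  }
  anchors <- genome$truth$anchors
  seqs1 <- genome_sequences(genome)[[genome$array_locus$chrom]]
  left_anchor <- substring(seqs1, anchors$start[anchors$side == "5prime"] + 1L,
                           anchors$end[anchors$side == "5prime"])
  right_anchor <- substring(seqs1, anchors$start[anchors$side == "3prime"] + 1L,
                            anchors$end[anchors$side == "3prime"])
  span <- run_stage("spanscan", span_count(
    long_reads, left_anchor, right_anchor, genome$unit_sequence,
    min_identity = config$analysis$min_identity,
    min_unit_fraction = config$analysis$min_unit_fraction
  ))
  span_dist <- if (nrow(span) > 0) copy_number_distribution(span) else NULL
  if (!is.null(out_dir)) {
    utils::write.table(span, file.path(out_dir, "spanning_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- short-read depth copy number -----------------------------------
  log_stage(quiet, "depthcn", "short-read depth and masked normalization")
  sr_params <- read_sim_params(
    length_distribution = list(type = "fixed",
                               length = config$short_reads$read_length),
    depth = config$short_reads$depth,
    substitution_error_rate = config$short_reads$substitution_error_rate,
    seed = derive_seed(seed, 5L)
  )
  short_reads <- run_stage("depthcn", simulate_reads(genome, sr_params))
  # reference with a single retained unit copy: same seed, same unit and
  # background, so every unit-derived read piles onto the retained copy
  ref_spec <- array_spec(
    n_units = min(config$array$n_units, 1L),
    unit_length = config$array$unit_length,
    intervening_length = config$array$intervening_length,
    flank_anchor_length = config$array$flank_anchor_length
  )
  reference <- run_stage("depthcn", build_array_genome(
    ref_spec, config$background_length, seed = derive_seed(seed, 1L),
    n_chromosomes = config$n_chromosomes
  ))
  idx <- genome_index(reference, mask = NULL)
  profile <- run_stage("depthcn", compute_depth(
    reads = short_reads, index = idx,
    bin_size = config$analysis$bin_size
  ))
  array_region <- data.frame(
    chrom = reference$array_locus$chrom,
    start = max(reference$array_locus$start -
                  reference$spec$flank_anchor_length, 0L),
    end = reference$array_locus$end + reference$spec$flank_anchor_length
  )
  # exclude the array and the read-length coverage ramp at chromosome ends
  # from the normalization background
  rl <- config$short_reads$read_length
  end_ramps <- do.call(rbind, lapply(names(idx$seqlengths), function(chr) {
    len <- idx$seqlengths[[chr]]
    data.frame(chrom = chr, start = c(0L, max(len - rl, 0L)),
               end = c(min(rl, len), len))
  }))
  profile <- run_stage("depthcn", normalize_depth(
    profile, mask = NULL,
    background = gr_complement(rbind(array_region, end_ramps),
                               idx$seqlengths)
  ))
  depth_cn <- if (config$array$n_units > 0) {
    run_stage("depthcn", region_copy_number(
      profile,
      data.frame(chrom = reference$array_locus$chrom,
                 start = reference$array_locus$start,
                 end = reference$array_locus$end)
    ))
  } else NULL
  ploidy <- chromosome_ploidy(
    profile, gain_threshold = config$analysis$gain_threshold,
    loss_threshold = config$analysis$loss_threshold,
    exclude = array_region
  )
  if (!is.null(out_dir)) {
    write_depth_bedgraph(profile, file.path(out_dir, "depth_normalized.bedgraph"))
  }

  # --- rearrangement screen -------------------------------------------
  log_stage(quiet, "rearrange", "split-read rearrangement screen")
  full_idx <- genome_index(genome)
  screen <- run_stage("rearrange", sv_screen(
    long_reads, full_idx, genome$unit_sequence,
    expected_flank_loci(genome),
    min_flank_length = config$analysis$min_flank_length,
    window = config$analysis$window
  ))
  if (!is.null(out_dir) && nrow(screen$calls) > 0) {
    utils::write.table(screen$calls, file.path(out_dir, "sv_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- consolidated report --------------------------------------------
  truth_vs_estimate <- data.frame(
    quantity = c("initial_copy_number", "spanning_modal_copy_number",
                 "depth_copy_number", "final_population_mean"),
    truth = c(config$array$n_units, config$array$n_units,
              config$array$n_units,
              mean(vapply(pops, function(p) mean(p$final), numeric(1)))),
    estimate = c(config$array$n_units,
                 if (is.null(span_dist)) NA_real_ else span_dist$mode,
                 if (is.null(depth_cn)) NA_real_ else depth_cn$mean,
                 mean_by_time[[length(mean_by_time)]]),
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(
      truth_vs_estimate = truth_vs_estimate,
      cna_g = list(empirical = unname(cna_g_emp), model = unname(cna_g_mod)),
      k_fit = if (is.null(kfit)) NULL else
        list(k = kfit$k, ci = kfit$ci, warning_flag = kfit$warning_flag),
      spanning = list(n_spanning = nrow(span), distribution = span_dist),
      depth = list(copy_number = if (is.null(depth_cn)) NULL else
        list(mean = depth_cn$mean, sd = depth_cn$sd),
        placer_stats = as.list(profile$placer_stats)),
      ploidy = ploidy,
      rearrangements = screen$summary,
      provenance = list(
        package_version = as.character(utils::packageVersion("bitrexkit")),
        master_seed = seed,
        config = unclass(config)
      )
    ),
    class = "run_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      report_to_json(report), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null", null = "null"
    )
  }
  report
}

gr_complement <- function(region, seqlengths) {
  all <- GenomicRanges::GRanges(names(seqlengths),
                                IRanges::IRanges(1L, seqlengths))
  GenomicRanges::setdiff(all, as_granges0(region))
}

report_to_json <- function(report) {
  r <- unclass(report)
  if (!is.null(r$spanning$distribution)) {
    h <- r$spanning$distribution$histogram
    r$spanning$distribution <- list(
      histogram = stats::setNames(as.list(as.integer(h)), names(h)),
      mode = r$spanning$distribution$mode,
      max = r$spanning$distribution$max,
      n = r$spanning$distribution$n
    )
  }
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("bitrexkit run report\n")
  cat("  truth vs estimate:\n")
  print(x$truth_vs_estimate, row.names = FALSE)
  cat(sprintf("  CNA/G: empirical %.4f, model %.4f\n",
              x$cna_g$empirical, x$cna_g$model))
  if (!is.null(x$k_fit)) {
    cat(sprintf("  fitted k: %.3g [%.3g, %.3g]\n", x$k_fit$k,
                x$k_fit$ci[1], x$k_fit$ci[2]))
  }
  cat("  rearrangement calls:\n")
  print(x$rearrangements, row.names = FALSE)
  invisible(x)
}

#' Demo fixture dataset
#'
#' Generates the small demonstration dataset used throughout the examples
#' and tests: a 14-unit array genome, long reads, a three-replicate
#' copy-number series, and the truth tables, written to `dir`.
#'
#' @param dir output directory.
#' @param seed master seed.
#' @return invisibly, the [run_end_to_end()] report.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  cfg <- validate_config(list(master_seed = seed))
  invisible(run_end_to_end(cfg, out_dir = dir, quiet = TRUE))
}
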