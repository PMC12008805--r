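#' Parameters of the stochastic array expansion/contraction process
#'
#' The simulator models a population of cell lineages, each carrying a tandem
#' array of `X` repeat-unit copies. Per division, a break-induced-replication
#' expansion event occurs with probability `p_eff`: the broken fork within
#' the terminal unit can only re-invade in register or upstream, so the array
#' either stays unchanged or grows — it never contracts through this pathway.
#' Expansion requires at least two unit copies (a single copy offers no
#' out-of-register donor). Division is asymmetric: one daughter inherits the
#' donor chromatid with the original array, the other the expanded product.
#' Independently, every lineage contracts each generation through inter-unit
#' homologous recombination with per-generation hazard `1 - exp(-k X^2)`, the
#' discrete-time counterpart of the second-order rate `dX/dt = -k X^2`.
#'
#' `p_eff` depends on where replication initiates relative to the nick:
#' * `origin_mode = "internal"` — an origin inside the repeat unit guarantees
#'   the fork orientation the mechanism needs: `p_eff = p_exp`.
#' * `origin_mode = "external"` — the nick-proximal fork races a fork coming
#'   from beyond the far side of the array; with constant fork speeds the
#'   near fork wins with probability
#'   `d_internal_side / (d_internal_side + d_external + X * unit_length_bp)`,
#'   so expansion slows as the array grows and the copy number plateaus.
#'
#' @param p_exp per-division expansion-event probability when eligible.
#' @param step_mean mean of the geometric expansion step size in copies
#'   (support 1, 2, ...; default 1.5).
#' @param k contraction rate constant, per copy^2 per generation.
#' @param origin_mode `"internal"` or `"external"` replication origin.
#' @param d_internal_side distance (bp) from the nick to the origin on the
#'   nick side (external mode).
#' @param d_external distance (bp) from the far array edge to the opposing
#'   external origin (external mode).
#' @param unit_length_bp repeat unit length in bp, used to convert copy
#'   number to array length in the fork race.
#' @param population_cap population size maintained by dilution; `Inf`
#'   disables resampling (full lineage tree).
#' @param seed integer seed.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(p_exp = 0.05,
                       step_mean = 1.5,
                       k = 0,
                       origin_mode = c("internal", "external"),
                       d_internal_side = 1000,
                       d_external = 10000,
                       unit_length_bp = 2000,
                       population_cap = 1000L,
                       seed = 1L) {
  origin_mode <- match.arg(origin_mode)
  stopifnot(
    p_exp >= 0, p_exp <= 1,
    step_mean >= 1,
    k >= 0,
    d_internal_side > 0, d_external >= 0,
    unit_length_bp > 0,
    population_cap >= 1
  )
  structure(
    list(p_exp = p_exp, step_mean = step_mean, k = k,
         origin_mode = origin_mode,
         d_internal_side = d_internal_side, d_external = d_external,
         unit_length_bp = unit_length_bp,
         population_cap = population_cap, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Effective expansion probability for a given copy number
#'
#' In external-origin mode the probability decays with array length (the
#' fork-race form), producing the plateau in long-term expansion; in internal
#' mode it is constant.
#'
#' @param x copy number (vectorized).
#' @param params a [sim_params()].
#' @return numeric vector of per-division expansion probabilities.
#' @export
effective_p_exp <- function(x, params) {
  if (params$origin_mode == "internal") {
    rep(params$p_exp, length(x))
  } else {
    params$p_exp * params$d_internal_side /
      (params$d_internal_side + params$d_external + x * params$unit_length_bp)
  }
}

geometric_step <- function(n, step_mean) {
  if (step_mean <= 1) return(rep(1L, n))
  stats::rgeom(n, prob = 1 / step_mean) + 1L
}

#' Simulate a population of array-bearing lineages
#'
#' Runs `n_generations` synchronous generations from a clonal population of
#' `x0`-copy lineages. Each generation every cell divides into two daughters:
#' one keeps the parental copy number, the other receives the expansion
#' product `X + step` if an expansion event fired (probability
#' [effective_p_exp()], only when `X >= 2`), otherwise also `X`. Every
#' daughter then contracts with hazard `1 - exp(-k X^2)`; contraction
#' magnitude is uniform on `{1, ..., X-1}`, so copy number never drops below
#' one and a single-copy array is absorbing for contraction. Finally the
#' population is diluted back to `population_cap` lineages by multinomial
#' resampling (skipped when the cap is infinite).
#'
#' @param x0 initial copy number (>= 1).
#' @param params a [sim_params()].
#' @param n_generations number of generations to simulate.
#' @return a list with `trajectory` (a [trajectory()] data frame of
#'   per-generation mean/sd/population size, generation 0 included), `final`
#'   (the final copy-number multiset as an integer vector), and `params`.
#' @export
simulate_population <- function(x0, params, n_generations) {
  stopifnot(inherits(params, "sim_params"), n_generations >= 0)
  if (x0 < 1) stop("x0 must be >= 1")
  x0 <- as.integer(x0)
  with_seed(derive_seed(params$seed, 0L), {
    pop <- rep(x0, if (is.finite(params$population_cap))
      params$population_cap else 1L)
    gens <- 0:n_generations
    means <- numeric(n_generations + 1L)
    sds <- numeric(n_generations + 1L)
    sizes <- integer(n_generations + 1L)
    means[1] <- mean(pop); sds[1] <- stats::sd(pop); sizes[1] <- length(pop)
    if (n_generations > 0) {
      for (g in seq_len(n_generations)) {
        n <- length(pop)
        eligible <- pop >= 2L
        expand <- eligible &
          (stats::runif(n) < effective_p_exp(pop, params))
        step <- integer(n)
        if (any(expand)) {
          step[expand] <- geometric_step(sum(expand), params$step_mean)
        }
        # asymmetric division: donor daughter keeps X, the other gets X+step
        pop <- c(pop, pop + step)
        if (params$k > 0) {
          m <- length(pop)
          hazard <- 1 - exp(-params$k * pop^2)
          contract <- (stats::runif(m) < hazard) & pop >= 2L
          if (any(contract)) {
            idx <- which(contract)
            loss <- vapply(pop[idx],
                           function(x) sample.int(x - 1L, 1L), integer(1))
            pop[idx] <- pop[idx] - loss
          }
        }
        if (is.finite(params$population_cap) &&
            length(pop) > params$population_cap) {
          pop <- pop[sample.int(length(pop), params$population_cap,
                                replace = TRUE)]
        }
        means[g + 1L] <- mean(pop)
        sds[g + 1L] <- stats::sd(pop)
        sizes[g + 1L] <- length(pop)
      }
    }
    list(
      trajectory = trajectory(times = gens, mean_copy = means,
                              sd_copy = ifelse(is.na(sds), 0, sds),
                              n_replicates = sizes),
      final = as.integer(pop),
      params = params
    )
  })
}

#' Measured copy-number time series
#'
#' Container for a (possibly measured) copy-number trajectory: strictly
#' increasing times, per-time mean and standard deviation, and the number of
#' lineages/replicates behind each point.
#'
#' @param times strictly increasing numeric times (generations or days).
#' @param mean_copy non-negative mean copy numbers.
#' @param sd_copy non-negative standard deviations (default 0).
#' @param n_replicates integer count(s) behind each time point.
#' @return a `data.frame` of class `trajectory` with columns `time`,
#'   `mean_copy`, `sd_copy`, `n`.
#' @export
trajectory <- function(times, mean_copy, sd_copy = 0, n_replicates = 1L) {
  stopifnot(length(times) == length(mean_copy))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(mean_copy < 0)) stop("mean_copy must be non-negative")
  df <- data.frame(
    time = as.numeric(times),
    mean_copy = as.numeric(mean_copy),
    sd_copy = rep_len(as.numeric(sd_copy), length(times)),
    n = rep_len(as.integer(n_replicates), length(times))
  )
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Simulate a qPCR-style copy-number measurement series
#'
#' Emulates population-average copy-number quantification by qPCR sampled
#' from replicate cultures: for every time point of every replicate
#' trajectory, the measurement is the population mean copy number plus
#' independent Gaussian noise.
#'
#' @param trajectories a list of [trajectory()] objects, one per replicate.
#' @param noise_sd measurement noise standard deviation (copies; >= 0).
#' @param seed integer seed.
#' @return a `data.frame` with columns `time`, `replicate`, `copy_number`.
#' @export
simulate_qpcr_series <- function(trajectories, noise_sd, seed = 1L) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(noise_sd >= 0)
  if (length(trajectories) == 0 ||
      all(vapply(trajectories, nrow, integer(1)) == 0L)) {
    return(data.frame(time = numeric(0), replicate = integer(0),
                      copy_number = numeric(0)))
  }
  with_seed(derive_seed(seed, 7L), {
    out <- lapply(seq_along(trajectories), function(r) {
      tr <- trajectories[[r]]
      data.frame(
        time = tr$time,
        replicate = r,
        copy_number = tr$mean_copy +
          if (noise_sd > 0) stats::rnorm(nrow(tr), 0, noise_sd) else 0
      )
    })
    do.call(rbind, out)
  })
}

#' Read/write a copy-number series as TSV
#'
#' Columns `time`, `replicate`, `copy_number` (tab-separated, with header).
#'
#' @param series a data frame as returned by [simulate_qpcr_series()].
#' @param path file path.
#' @return `write_copy_series`: invisibly, `path`; `read_copy_series`: the
#'   data frame.
#' @export
write_copy_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_copy_series
#' @export
read_copy_series <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
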