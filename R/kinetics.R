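#' Second-order contraction kinetics of a tandem array
#'
#' Array contraction by homologous recombination between repeat units is
#' modeled as a pairwise (second-order) reaction in the copy number `X`:
#' `dX/dt = -k X^2`, with `k` the rate constant of inter-unit recombination.
#' Solving with initial copy number `X0` gives the rectangular hyperbola
#' `X(t) = X0 / (1 + k X0 t)`.
#'
#' `closed_form_x` evaluates that closed form; it is strictly decreasing in
#' `t` whenever `k > 0` and `X0 > 0`, and reduces to `X0` at `t = 0` or
#' `k = 0`. All arguments are vectorized and recycled.
#'
#' @param X0 initial copy number (>= 0).
#' @param k rate constant, per copy^2 per time unit (>= 0).
#' @param t elapsed time (>= 0), in the same time unit as `k` (days
#'   throughout this package).
#' @return copy number at time `t`.
#' @export
closed_form_x <- function(X0, k, t) {
  if (any(X0 < 0) || any(k < 0) || any(t < 0)) {
    stop("X0, k and t must be non-negative")
  }
  X0 / (1 + k * X0 * t)
}

#' Model-predicted copy-number alteration per generation (CNA/G)
#'
#' Under the second-order contraction model, the copy-number change over an
#' exposure window of duration `T` spanning `G` generations is
#' `X(T) - X0 = -k T X0^2 / (1 + k T X0)`, so
#'
#' `CNA/G = -(1/G) * X0^2 / (X0 + 1/(k T))`
#'
#' which is algebraically identical to `(closed_form_x(X0, k, T) - X0) / G`.
#' As `X0` grows, CNA/G approaches the straight line `-(X0 - 1/(kT))/G`: the
#' contraction rate per generation becomes asymptotically linear in the
#' initial copy number.
#'
#' The `pairwise` flag replaces `X^2` with `X (X - 1)` in the underlying
#' rate, a variant in which a single-copy array (no partner unit) has zero
#' contraction rate; the default follows the plain second-order form.
#'
#' @param X0 initial copy number (>= 1).
#' @param k rate constant (>= 0).
#' @param T_days exposure duration (> 0 unless `k = 0`).
#' @param G number of generations over the window (> 0).
#' @param pairwise use the `k X (X - 1)` rate variant.
#' @return predicted CNA/G (non-positive; 0 when `k = 0`).
#' @export
cna_g_model <- function(X0, k, T_days, G, pairwise = FALSE) {
  if (any(G <= 0)) stop("G must be positive")
  if (any(k < 0) || any(X0 < 0) || any(T_days < 0)) {
    stop("X0, k and T_days must be non-negative")
  }
  if (!pairwise) {
    # -(1/G) * X0^2 / (X0 + 1/(kT)); written via the closed form so k = 0
    # needs no special-casing
    (closed_form_x(X0, k, T_days) - X0) / G
  } else {
    # dX/dt = -k X (X-1) has solution X = X0 / (X0 - (X0-1) exp(-kt))
    xt <- ifelse(k * T_days == 0, X0,
                 X0 / (X0 - (X0 - 1) * exp(-k * T_days)))
    (xt - X0) / G
  }
}

#' Empirical copy-number alteration per generation
#'
#' The measured statistic: the change in population-average copy number
#' between the start and end of the exposure window, divided by the number
#' of cell divisions over that window,
#' `CNA/G = (copy_T - copy_0) / divisions`.
#'
#' @param copy_T copy number at the end of the window.
#' @param copy_0 copy number at the start.
#' @param divisions number of cell divisions (> 0), e.g. from
#'   [divisions_from_od()].
#' @return the empirical CNA/G.
#' @export
cna_g_empirical <- function(copy_T, copy_0, divisions) {
  if (any(divisions <= 0)) stop("divisions must be positive")
  (copy_T - copy_0) / divisions
}

#' Division number from optical density change
#'
#' A batch culture growing from inoculum density `od_inoculum` to final
#' density `od_final` has undergone `log2(od_final / od_inoculum)` doublings;
#' this is the division number used to convert copy-number change into
#' CNA/G.
#'
#' @param od_inoculum optical density at inoculation (> 0).
#' @param od_final optical density at the end of the window (> 0).
#' @return number of divisions (0 when the density did not change).
#' @export
divisions_from_od <- function(od_inoculum, od_final) {
  if (any(od_inoculum <= 0) || any(od_final <= 0)) {
    stop("optical densities must be positive")
  }
  log2(od_final / od_inoculum)
}

#' Fit the contraction rate constant to a copy-number series
#'
#' Least-squares fit of the closed-form decay `X0 / (1 + k X0 t)` to a
#' measured trajectory, with `k` constrained non-negative
#' (Levenberg-Marquardt via \pkg{minpack.lm}). By default `X0` is
#' co-estimated; with `estimate_x0 = FALSE` it is fixed to the day-0
#' measurement. Uncertainty is quantified by case-resampling bootstrap over
#' time points (percentile interval).
#'
#' A series with no net decrease carries no information about `k` under the
#' non-negativity constraint; the fit then returns `k = 0` with
#' `warning_flag = "no_contraction"`.
#'
#' @param traj a [trajectory()] (times in days, `mean_copy > 0`, >= 3
#'   points).
#' @param G_per_day generations per day, recorded in the result so CNA/G
#'   predictions can be made on the fitted scale.
#' @param estimate_x0 co-estimate `X0` (default) or fix it to the first
#'   observation.
#' @param n_boot bootstrap draws (default 1000; 0 skips the bootstrap).
#' @param conf confidence level of the percentile interval.
#' @param seed integer seed for the bootstrap.
#' @return a list of class `k_fit`: `k`, `X0`, `ci` (length-2 or `NA`),
#'   `G_per_day`, `residuals`, `fitted`, `n_boot`, `boot_k`, `warning_flag`.
#' @export
fit_k <- function(traj, G_per_day = 1, estimate_x0 = TRUE,
                  n_boot = 1000L, conf = 0.95, seed = 1L) {
  stopifnot(inherits(traj, "data.frame"), nrow(traj) >= 3)
  t <- traj$time
  y <- traj$mean_copy
  if (any(y <= 0)) stop("mean_copy must be positive to fit the decay model")

  if (y[which.max(t)] >= y[which.min(t)]) {
    # no net decrease: under k >= 0 the series carries no rate information
    warning("series does not decrease; returning k = 0")
    return(structure(
      list(k = 0, X0 = y[which.min(t)], ci = c(NA_real_, NA_real_),
           conf = conf, G_per_day = G_per_day,
           fitted = rep(y[which.min(t)], length(t)),
           residuals = y - y[which.min(t)],
           n_boot = 0L, boot_k = numeric(0),
           warning_flag = "no_contraction"),
      class = "k_fit"
    ))
  }

  fit_once <- function(t, y) {
    x0_start <- max(y[which.min(t)], 1e-6)
    # two-point moment start for k: X_T = X0/(1+k X0 T)
    yT <- y[which.max(t)]
    Tmax <- max(t) - min(t)
    k_start <- if (yT < x0_start && Tmax > 0) {
      (x0_start / yT - 1) / (x0_start * Tmax)
    } else 0
    if (estimate_x0) {
      fit <- try(minpack.lm::nlsLM(
        y ~ X0 / (1 + k * X0 * t),
        start = list(k = max(k_start, 1e-12), X0 = x0_start),
        lower = c(k = 0, X0 = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      co <- stats::coef(fit)
      list(k = unname(co["k"]), X0 = unname(co["X0"]),
           fitted = stats::fitted(fit))
    } else {
      X0 <- y[which.min(t)]
      fit <- try(minpack.lm::nlsLM(
        y ~ X0 / (1 + k * X0 * t),
        start = list(k = max(k_start, 1e-12)),
        lower = c(k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      list(k = unname(stats::coef(fit)["k"]), X0 = X0,
           fitted = stats::fitted(fit))
    }
  }

  base <- fit_once(t, y)
  warning_flag <- NA_character_
  if (is.null(base)) stop("contraction model fit failed to converge")

  boot_k <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot_k <- with_seed(derive_seed(seed, 13L), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(t), replace = TRUE)
        if (length(unique(t[idx])) < 3) return(NA_real_)
        bt <- fit_once(t[idx], y[idx])
        if (is.null(bt)) NA_real_ else bt$k
      }, numeric(1))
    })
    ok <- boot_k[!is.na(boot_k)]
    if (length(ok) >= 10) {
      a <- (1 - conf) / 2
      ci <- unname(stats::quantile(ok, c(a, 1 - a)))
    }
  }

  structure(
    list(k = base$k, X0 = base$X0, ci = ci, conf = conf,
         G_per_day = G_per_day,
         fitted = base$fitted, residuals = y - base$fitted,
         n_boot = n_boot, boot_k = boot_k, warning_flag = warning_flag),
    class = "k_fit"
  )
}

#' @export
print.k_fit <- function(x, ...) {
  cat(sprintf("second-order contraction fit: k = %.6g per copy^2 per day\n",
              x$k))
  cat(sprintf("  X0 = %.3f; %d%% bootstrap CI for k: [%.6g, %.6g] (%d draws)\n",
              x$X0, round(100 * x$conf), x$ci[1], x$ci[2], x$n_boot))
  if (!is.na(x$warning_flag)) cat("  warning:", x$warning_flag, "\n")
  invisible(x)
}

#' Write a `k_fit` report as JSON
#' @param fit a [fit_k()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_k_fit <- function(fit, path) {
  jsonlite::write_json(
    list(k = fit$k, X0 = fit$X0, ci = fit$ci, conf = fit$conf,
         G_per_day = fit$G_per_day, residuals = fit$residuals,
         n_boot = fit$n_boot, warning_flag = fit$warning_flag),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Predicted CNA/G as a function of initial copy number
#'
#' Evaluates [cna_g_model()] over a grid of initial copy numbers, the
#' theoretical counterpart of plotting measured CNA/G against starting array
#' size: for `k > 0` the curve decreases monotonically and approaches a
#' straight line at large `X0`.
#'
#' @param k rate constant.
#' @param T_days exposure duration (days).
#' @param G generations over the window.
#' @param X0_grid positive initial copy numbers.
#' @param pairwise see [cna_g_model()].
#' @return a `data.frame` with columns `X0`, `cna_g` (empty grid gives an
#'   empty table).
#' @export
predict_cna_curve <- function(k, T_days, G, X0_grid, pairwise = FALSE) {
  if (length(X0_grid) == 0) {
    return(data.frame(X0 = numeric(0), cna_g = numeric(0)))
  }
  if (any(X0_grid <= 0)) stop("X0_grid must be positive")
  data.frame(X0 = X0_grid,
             cna_g = cna_g_model(X0_grid, k, T_days, G, pairwise = pairwise))
}

round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Predicted size of the array-containing restriction fragment
#'
#' A restriction enzyme with no site inside the repeat unit releases the
#' whole array on one fragment, so the band size in Mb is simply
#' `(n_units * unit_length_kb + extra_kb) / 1000`, reported rounded
#' half-away-from-zero to one decimal — the precision at which pulsed-field
#' gel band sizes are read.
#'
#' @param n_units number of repeat units on the fragment (>= 0).
#' @param unit_length_kb unit length in kb (default 2.0).
#' @param extra_kb non-repeat sequence on the fragment, in kb.
#' @return fragment size in Mb, one decimal.
#' @export
predict_fragment_size <- function(n_units, unit_length_kb = 2.0, extra_kb = 0) {
  if (any(n_units < 0) || any(unit_length_kb < 0) || any(extra_kb < 0)) {
    stop("inputs must be non-negative")
  }
  round_half_away((n_units * unit_length_kb + extra_kb) / 1000, 1)
}
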