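#' Single-hit multitarget (SHMT) dose-response curve
#'
#' Predicted effect rate (survival or fertility fraction) at absorbed dose
#' `dose` under the single-hit multitarget model
#' \deqn{R(D) = 1 - (1 - e^{-D/D_0})^m}
#' where `d0` is the dose conferring a 37% (\eqn{e^{-1}}) biological effect
#' and `m` is the extrapolation number. The curve equals 1 at dose 0 and is
#' non-increasing in dose; `m > 1` produces the characteristic low-dose
#' shoulder.
#'
#' @param dose Absorbed dose in Gy; non-negative, vectorised.
#' @param d0 Characteristic dose in Gy; must be positive.
#' @param m Extrapolation number; must be >= 1.
#' @return Numeric vector of rates in \[0, 1\].
#' @examples
#' shmt_rate(0, 60, 5)            # 1 at zero dose
#' shmt_rate(60, 60, 1)           # exp(-1), the 37% dose
#' shmt_rate(c(0, 50, 100), 62.3, 6.33)
#' @export
shmt_rate <- function(dose, d0, m) {
  if (any(!is.finite(d0)) || any(d0 <= 0)) {
    stop("`d0` must be a positive dose (Gy).", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 1)) {
    stop("`m` (extrapolation number) must be >= 1.", call. = FALSE)
  }
  if (any(dose < 0)) {
    stop("`dose` must be non-negative.", call. = FALSE)
  }
  1 - (1 - exp(-dose / d0))^m
}

#' Shoulder dose Dq of an SHMT curve
#'
#' The quasi-threshold (shoulder) dose `Dq = d0 * ln(m)`: below it the
#' fitted effect rate stays close to 1. A purely exponential curve
#' (`m = 1`) has no shoulder, so `Dq = 0`.
#'
#' @inheritParams shmt_rate
#' @return Shoulder dose in Gy.
#' @examples
#' shoulder_dose(100, 1)      # 0: no shoulder
#' shoulder_dose(62.3, 6.33)  # approx 115 Gy
#' @export
shoulder_dose <- function(d0, m) {
  if (any(!is.finite(d0)) || any(d0 <= 0)) {
    stop("`d0` must be a positive dose (Gy).", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 1)) {
    stop("`m` (extrapolation number) must be >= 1.", call. = FALSE)
  }
  d0 * log(m)
}

# Average replicate rates per dose and validate the observation table.
# Accepts columns (dose, rate) or (dose, n_effect, n_total).
prepare_observations <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"dose" %in% names(data)) {
    stop("`data` must contain a `dose` column (Gy).", call. = FALSE)
  }
  if (!"rate" %in% names(data)) {
    if (!all(c("n_effect", "n_total") %in% names(data))) {
      stop("`data` needs either a `rate` column or `n_effect` and `n_total`.",
           call. = FALSE)
    }
    if (any(data$n_total <= 0) || any(data$n_effect < 0) ||
        any(data$n_effect > data$n_total)) {
      stop("counts must satisfy 0 <= n_effect <= n_total with n_total > 0.",
           call. = FALSE)
    }
    data$rate <- data$n_effect / data$n_total
  }
  if (any(data$dose < 0)) stop("doses must be non-negative.", call. = FALSE)
  if (any(data$rate < 0 | data$rate > 1)) {
    stop("rates must lie in [0, 1].", call. = FALSE)
  }
  data |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop") |>
    dplyr::arrange(.data$dose)
}

#' Fit the SHMT model to dose-response observations
#'
#' Least-squares fit of [shmt_rate()] on the rate scale. Replicate rates at
#' the same dose are averaged before fitting (the averaged curve is what the
#' shoulder-dose and 50%-effect readouts are taken from). The optimiser is a
#' multi-start Nelder-Mead on the reparameterised surface
#' `(log d0, u)` with `m = 1 + exp(u)`, started from the best cells of a
#' coarse `(d0, m)` grid; the reparameterisation keeps `d0 > 0` and
#' `m >= 1` (hence `Dq >= 0`) without a constrained solver, and the
#' multi-start avoids the local minima that shouldered curves produce.
#'
#' @param data Data frame with columns `dose` and `rate`, or `dose`,
#'   `n_effect`, `n_total` (rates computed as `n_effect / n_total`).
#' @param n_starts Number of grid cells used to seed local optimisations.
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @return An object of class `shmt_fit` with elements `d0`, `m`, `dq`
#'   (`= d0 * log(m)`), `r_squared`, `sse`, `converged` and the averaged
#'   observations in `$data`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] for tibble output and
#'   [autoplot.shmt_fit()] to plot.
#' @examples
#' obs <- tibble::tibble(dose = c(0, 40, 80, 120, 160, 200),
#'                       rate = shmt_rate(c(0, 40, 80, 120, 160, 200), 60, 5))
#' fit <- fit_shmt(obs)
#' glance(fit)
#' @export
fit_shmt <- function(data, n_starts = 6, maxit = 500) {
  obs <- prepare_observations(data)
  if (nrow(obs) < 3) {
    stop("at least 3 distinct doses are required to fit the SHMT model.",
         call. = FALSE)
  }
  if (all(obs$rate > 1 - 1e-9)) {
    stop("degenerate data: no decline in effect rate to fit.", call. = FALSE)
  }

  sse <- function(d0, m) sum((obs$rate - shmt_rate(obs$dose, d0, m))^2)
  dmax <- max(obs$dose)
  grid <- tidyr::expand_grid(
    d0 = seq(dmax / 10, dmax, length.out = 15),
    m  = c(1, 1.5, 2, 3, 4, 6, 9, 13, 20)
  )
  grid$sse <- purrr::map2_dbl(grid$d0, grid$m, sse)
  starts <- grid |> dplyr::arrange(.data$sse) |> utils::head(n_starts)

  obj <- function(par) {
    d0 <- exp(par[1])
    m <- 1 + exp(par[2])
    sum((obs$rate - shmt_rate(obs$dose, d0, m))^2)
  }
  runs <- purrr::map2(starts$d0, starts$m, function(d0, m) {
    par0 <- c(log(d0), log(max(m - 1, 1e-6)))
    stats::optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
  })
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]

  d0_hat <- exp(best$par[1])
  m_hat <- 1 + exp(best$par[2])
  fit <- structure(
    list(
      d0 = d0_hat,
      m = m_hat,
      dq = d0_hat * log(m_hat),
      sse = best$value,
      converged = best$convergence == 0,
      n_obs = nrow(obs),
      data = obs
    ),
    class = "shmt_fit"
  )
  fit$r_squared <- shmt_r_squared(fit)
  fit
}

#' Coefficient of determination for an SHMT fit
#'
#' `1 - SS_residual / SS_total`, computed on the rate scale against the
#' (averaged) observations. When the observed rates have zero variance the
#' statistic is undefined and `NA` is returned with a warning.
#'
#' @param fit An [fit_shmt()] object.
#' @param data Optional observation table to score against; defaults to the
#'   observations the model was fitted to.
#' @return A single numeric value (<= 1), or `NA` if undefined.
#' @export
shmt_r_squared <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "shmt_fit"))
  obs <- if (is.null(data)) fit$data else prepare_observations(data)
  ss_tot <- sum((obs$rate - mean(obs$rate))^2)
  if (ss_tot == 0) {
    warning("observed rates have zero variance; R^2 is undefined.",
            call. = FALSE)
    return(NA_real_)
  }
  ss_res <- sum((obs$rate - shmt_rate(obs$dose, fit$d0, fit$m))^2)
  1 - ss_res / ss_tot
}

#' Dose producing a target effect rate
#'
#' Inverts a fitted SHMT curve: finds the dose `D` with
#' `shmt_rate(D) = target_rate`. The curve is monotone, so the root is
#' bracketed and found by bisection to an absolute dose tolerance
#' (default 0.01 Gy). With `method = "interpolate"` the readout instead
#' comes from linear interpolation of the raw (averaged) observed rates.
#'
#' @param fit An [fit_shmt()] object.
#' @param target_rate Effect rate in (0, 1), e.g. 0.5 for the 50%-effect
#'   dose (LD50 when the endpoint is survival).
#' @param tol Absolute bisection tolerance in Gy.
#' @param method `"fitted"` (default, bisection on the fitted curve) or
#'   `"interpolate"` (linear interpolation of observed rates).
#' @return Dose in Gy.
#' @examples
#' obs <- tibble::tibble(dose = seq(0, 240, 40),
#'                       rate = shmt_rate(seq(0, 240, 40), 60, 5))
#' dose_at_rate(fit_shmt(obs), 0.5)
#' @export
dose_at_rate <- function(fit, target_rate, tol = 0.01,
                         method = c("fitted", "interpolate")) {
  stopifnot(inherits(fit, "shmt_fit"))
  method <- match.arg(method)
  if (!is.numeric(target_rate) || length(target_rate) != 1 ||
      target_rate <= 0 || target_rate >= 1) {
    stop("`target_rate` must be a single value strictly inside (0, 1).",
         call. = FALSE)
  }
  if (method == "interpolate") {
    obs <- fit$data
    return(stats::approx(obs$rate, obs$dose, xout = target_rate,
                         ties = "ordered")$y)
  }
  lo <- 0
  hi <- max(fit$data$dose, fit$d0)
  while (shmt_rate(hi, fit$d0, fit$m) > target_rate) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (shmt_rate(mid, fit$d0, fit$m) > target_rate) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Relative biological effectiveness (RBE)
#'
#' Ratio of the reference-mutagen dose (low LET, e.g. gamma rays) to the
#' test-mutagen dose (high LET, e.g. a carbon-ion beam) that produces the
#' same biological endpoint: `rbe = reference_dose / test_dose`. Reports
#' conventionally round RBE to 2 decimals; the returned value keeps full
#' precision.
#'
#' @param reference_dose Dose of the reference (low-LET) mutagen, Gy; > 0.
#' @param test_dose Dose of the test (high-LET) mutagen, Gy; > 0.
#' @param endpoint_label Text describing the shared endpoint, e.g.
#'   `"Dq of survival"`.
#' @return A tibble with columns `endpoint`, `reference_dose`, `test_dose`,
#'   `rbe`.
#' @examples
#' rbe(343, 115, "Dq of survival")   # approx 2.98
#' @export
rbe <- function(reference_dose, test_dose, endpoint_label = "effect") {
  if (any(!is.finite(reference_dose)) || any(reference_dose <= 0) ||
      any(!is.finite(test_dose)) || any(test_dose <= 0)) {
    stop("doses must be positive.", call. = FALSE)
  }
  tibble::tibble(
    endpoint = endpoint_label,
    reference_dose = reference_dose,
    test_dose = test_dose,
    rbe = reference_dose / test_dose
  )
}

#' Pod-based fertility rate
#'
#' Low-fertility pods are the sterile (seedless) pods plus the single-seed
#' pods; the fertility rate is the fraction of pods that are not
#' low-fertility: `(total - (sterile + single)) / total`.
#'
#' @param total_pods Total pods assayed (> 0).
#' @param sterile_pods Count of seedless pods.
#' @param single_seed_pods Count of one-seed pods.
#' @return Fertility rate in \[0, 1\], vectorised.
#' @examples
#' fertility_rate(100, 30, 20)  # 0.5
#' @export
fertility_rate <- function(total_pods, sterile_pods, single_seed_pods) {
  if (any(total_pods <= 0)) {
    stop("`total_pods` must be positive.", call. = FALSE)
  }
  if (any(sterile_pods < 0) || any(single_seed_pods < 0)) {
    stop("pod counts must be non-negative.", call. = FALSE)
  }
  low <- sterile_pods + single_seed_pods
  if (any(low > total_pods)) {
    stop("sterile + single-seed pods exceed total pods.", call. = FALSE)
  }
  (total_pods - low) / total_pods
}

#' Dose at which relative yield falls to one half
#'
#' Yield dose-response is too shallow for the SHMT model; the half-yield
#' dose is instead read off by linear interpolation between the two doses
#' bracketing the first downward crossing of the threshold (relative yields
#' are normalised so the unirradiated control equals 1).
#'
#' @param data Data frame with columns `dose` and `relative_yield`.
#' @param threshold Crossing level, default 0.5.
#' @return Dose in Gy at the crossing.
#' @examples
#' yield_half_dose(tibble::tibble(dose = c(100, 140),
#'                                relative_yield = c(0.6, 0.4)))  # 120
#' @export
yield_half_dose <- function(data, threshold = 0.5) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("dose", "relative_yield") %in% names(data)))
  data <- dplyr::arrange(data, .data$dose)
  d <- data$dose
  y <- data$relative_yield
  if (!any(y > threshold) || !any(y <= threshold)) {
    stop("relative yield never crosses the threshold; no half-yield dose.",
         call. = FALSE)
  }
  for (i in seq_len(length(d) - 1)) {
    if (y[i] > threshold && y[i + 1] <= threshold) {
      return(d[i] + (threshold - y[i]) * (d[i + 1] - d[i]) / (y[i + 1] - y[i]))
    }
  }
  stop("relative yield never crosses the threshold from above.",
       call. = FALSE)
}

#' @export
print.shmt_fit <- function(x, ...) {
  cat("Single-hit multitarget fit\n")
  cat(sprintf("  D0 = %.2f Gy, m = %.3f, Dq = %.1f Gy\n", x$d0, x$m, x$dq))
  cat(sprintf("  R^2 = %.4f on %d dose points (converged: %s)\n",
              x$r_squared, x$n_obs, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_shmt
#' @param x,object An `shmt_fit` object.
#' @param ... Unused.
#' @export
tidy.shmt_fit <- function(x, ...) {
  tibble::tibble(
    term = c("d0", "m", "dq"),
    estimate = c(x$d0, x$m, x$dq)
  )
}

#' @rdname fit_shmt
#' @export
glance.shmt_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sse = x$sse,
    nobs = x$n_obs,
    converged = x$converged
  )
}

#' @rdname fit_shmt
#' @param newdata Optional data frame with a `dose` column to predict at.
#' @export
predict.shmt_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  shmt_rate(dose, object$d0, object$m)
}
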