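# Binding-model math: Hill-equation fits with bootstrap confidence
# intervals, the co-sedimentation fractional-binding inversion, and the
# Bonferroni helper.

#' Hill equation
#' @param c concentration(s).
#' @param K_D dissociation constant.
#' @param n Hill coefficient.
#' @param I_max saturation intensity.
#' @return `I_max * c^n / (K_D^n + c^n)`.
#' @export
hill_curve <- function(c, K_D, n, I_max) I_max * c^n / (K_D^n + c^n)

#' Fit a Hill equation to a binding curve
#'
#' Least-squares fit of `I = I_max * c^n / (K_D^n + c^n)` (Levenberg-
#' Marquardt). Initialization: `K_D` at the interpolated half-max
#' concentration, `n = 2`, `I_max` at the maximum intensity. 95% confidence
#' intervals come from a seeded residual-resampling bootstrap (percentile
#' method).
#'
#' @param conc concentrations (>= 0, at least 5 points).
#' @param intensity measured intensities.
#' @param n_boot bootstrap replicates (default 1000; 0 disables CIs).
#' @param seed integer seed for the bootstrap.
#' @return list with `K_D`, `hill_n`, `I_max`, `ci_K_D`, `ci_hill_n`
#'   (95% percentile intervals), `residual_norm`, `seed`.
#' @export
fit_hill <- function(conc, intensity, n_boot = 1000, seed = 1) {
  stopifnot(length(conc) >= 5, all(conc >= 0),
            length(conc) == length(intensity))
  fit_once <- function(y) {
    i_max0 <- max(y)
    half <- i_max0 / 2
    above <- which(y >= half)
    kd0 <- if (length(above) > 0 && above[1] > 1) {
      i <- above[1]
      stats::approx(y[c(i - 1, i)], conc[c(i - 1, i)], xout = half,
                    ties = "ordered")$y
    } else stats::median(conc[conc > 0])
    if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
    df <- data.frame(c = conc, I = y)
    fit <- minpack.lm::nlsLM(
      I ~ Imax * c^n / (K^n + c^n), data = df,
      start = list(K = kd0, n = 2, Imax = i_max0),
      lower = c(1e-12, 1e-3, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(fit)
  }
  co <- tryCatch(fit_once(intensity), error = function(e)
    stop("Hill fit did not converge (non-sigmoidal data?): ",
         conditionMessage(e)))
  pred <- hill_curve(conc, co["K"], co["n"], co["Imax"])
  resid <- intensity - pred
  ci_k <- ci_n <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      yb <- pred + sample(resid, replace = TRUE)
      cb <- tryCatch(fit_once(yb), error = function(e) NULL)
      if (!is.null(cb)) boots[b, ] <- cb[c("K", "n")]
    }
    ok <- stats::complete.cases(boots)
    if (sum(ok) >= 10) {
      ci_k <- unname(stats::quantile(boots[ok, 1], c(0.025, 0.975)))
      ci_n <- unname(stats::quantile(boots[ok, 2], c(0.025, 0.975)))
    }
  }
  list(K_D = unname(co["K"]), hill_n = unname(co["n"]),
       I_max = unname(co["Imax"]), ci_K_D = ci_k, ci_hill_n = ci_n,
       residual_norm = sqrt(sum(resid^2)), seed = seed)
}

#' Co-sedimentation dissociation constant
#'
#' Inverts the fractional-binding relation `f = K_A * A / (1 + K_A * A)`
#' (with `A` the accessible F-actin concentration) for the association
#' constant and returns its reciprocal: `K_D = A * (1 - f) / f`, in the
#' units of `A`.
#'
#' @param fraction_bound fraction of protein co-sedimenting, in (0, 1).
#' @param accessible_factin accessible F-actin concentration (> 0).
#' @return `K_D` in the units of `accessible_factin`.
#' @export
cosed_kd <- function(fraction_bound, accessible_factin) {
  if (fraction_bound <= 0 || fraction_bound >= 1)
    stop("fraction_bound must lie strictly between 0 and 1")
  stopifnot(accessible_factin > 0)
  accessible_factin * (1 - fraction_bound) / fraction_bound
}

#' Bonferroni per-comparison threshold
#'
#' @param alpha_total total type-I error (default 0.05).
#' @param m number of comparisons (>= 1).
#' @return list with `threshold` (`alpha_total / m`) and `display` (the
#'   threshold rounded to 3 decimals, matching figure-legend reporting:
#'   0.05 over 8 comparisons gives 0.00625, displayed 0.006).
#' @export
bonferroni <- function(alpha_total = 0.05, m) {
  stopifnot(m >= 1, alpha_total > 0, alpha_total < 1)
  thr <- alpha_total / m
  list(threshold = thr, display = round(thr, 3))
}
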