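# Estimation procedures: single-exponential rise/decay fits, the constant
# fit used for anchor channels, melting-midpoint extraction, and the
# unpaired two-tailed t test used for membrane-binding comparisons.

exp_fit_result <- function(model, pars, se, residual_sd, converged,
                           k_at_bound, start, fit = NULL) {
  structure(list(model = model, y0 = unname(pars[["y0"]]),
                 y_inf = if ("y_inf" %in% names(pars)) unname(pars[["y_inf"]]) else NA_real_,
                 k = unname(pars[["k"]]), se = se, residual_sd = residual_sd,
                 converged = converged, k_at_bound = k_at_bound,
                 start = start, fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> %s: k = %.6g min^-1 (SE %.3g)%s\n", x$model, x$k,
              x$se[["k"]], if (x$k_at_bound) " [k at bound]" else ""))
  cat(sprintf("  y0 = %.6g", x$y0))
  if (!is.na(x$y_inf)) cat(sprintf("  y_inf = %.6g", x$y_inf))
  cat(sprintf("  residual sd = %.3g  converged = %s\n",
              x$residual_sd, x$converged))
  invisible(x)
}

K_UPPER_BOUND <- 1e3 # min^-1

exp_start_k <- function(x, y, y_end) {
  # 1 / time to half range; robust for monotone rise and decay traces
  half <- y[1] + 0.5 * (y_end - y[1])
  idx <- if (y_end >= y[1]) which(y >= half) else which(y <= half)
  t_half <- if (length(idx) > 0) x[idx[1]] else max(x)
  t_half <- max(t_half, diff(range(x)) / 100, .Machine$double.eps)
  log(2) / t_half
}

check_xy <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < min_n) stop(sprintf("need at least %d points", min_n))
  if (any(x < 0)) stop("x (time) must be non-negative")
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  invisible(TRUE)
}

#' Fit a single-exponential rise (or decay to a plateau)
#'
#' Least-squares fit of `y = y0 + (y_inf - y0) * (1 - exp(-k x))`. The same
#' form describes product formation (rise) and signal loss to a plateau
#' (`y_inf < y0`). Initial guesses: `y0` = first point, `y_inf` = last
#' point, `k` = 1/(time to half range); `k` is bounded to [0, 1000] min^-1.
#'
#' @param x Times (min), strictly increasing, non-negative; >= 4 points.
#' @param y Signal values.
#' @return An object of class `exp_fit` with elements `y0`, `y_inf`, `k`,
#'   per-parameter standard errors `se`, `residual_sd`, `converged`, and
#'   `k_at_bound` (TRUE when the rate stuck at a bound, e.g. for constant
#'   input).
#' @export
fit_rise <- function(x, y) {
  check_xy(x, y, 4L)
  if (diff(range(y)) == 0) { # degenerate constant input: rate unidentifiable
    return(exp_fit_result("rise", c(y0 = y[1], y_inf = y[1], k = 0),
                          se = c(y0 = 0, y_inf = 0, k = NA_real_),
                          residual_sd = 0, converged = TRUE, k_at_bound = TRUE,
                          start = list(y0 = y[1], y_inf = y[1], k = 0)))
  }
  start <- list(y0 = y[1], y_inf = y[length(y)], k = exp_start_k(x, y, y[length(y)]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (y_inf - y0) * (1 - exp(-k * x)),
      start = start, lower = c(-Inf, -Inf, 0), upper = c(Inf, Inf, K_UPPER_BOUND),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf("exponential rise fit failed (%s); initial guesses: y0=%g, y_inf=%g, k=%g",
                 conditionMessage(fit), start$y0, start$y_inf, start$k))
  }
  pars <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(pars)))
  exp_fit_result("rise", pars, se,
                 residual_sd = sd(stats::residuals(fit)),
                 converged = fit$convInfo$isConv %||% TRUE,
                 k_at_bound = pars[["k"]] <= 1e-9 ||
                   pars[["k"]] >= K_UPPER_BOUND * (1 - 1e-9),
                 start = start, fit = fit)
}

#' Fit a single-exponential decay to zero
#'
#' Least-squares fit of `y = y0 * exp(-k x)` (the rise form with the
#' asymptote fixed at 0), used for substrate-consumption curves.
#'
#' @inheritParams fit_rise
#' @return An `exp_fit` (with `y_inf` fixed at 0).
#' @export
fit_decay <- function(x, y) {
  check_xy(x, y, 4L)
  if (diff(range(y)) == 0) { # degenerate constant input
    return(exp_fit_result("decay", c(y0 = y[1], y_inf = 0, k = 0),
                          se = c(y0 = 0, k = NA_real_), residual_sd = 0,
                          converged = TRUE, k_at_bound = TRUE,
                          start = list(y0 = y[1], k = 0)))
  }
  start <- list(y0 = y[1], k = exp_start_k(x, y, 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 * exp(-k * x), start = start,
      lower = c(-Inf, 0), upper = c(Inf, K_UPPER_BOUND),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop(sprintf("exponential decay fit failed (%s); initial guesses: y0=%g, k=%g",
                 conditionMessage(fit), start$y0, start$k))
  }
  pars <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 2), names(pars)))
  res <- exp_fit_result("decay", c(pars, y_inf = 0), se,
                        residual_sd = sd(stats::residuals(fit)),
                        converged = fit$convInfo$isConv %||% TRUE,
                        k_at_bound = pars[["k"]] <= 1e-9 ||
                          pars[["k"]] >= K_UPPER_BOUND * (1 - 1e-9),
                        start = start, fit = fit)
  res$y_inf <- 0
  res
}

#' Fit a constant (y = k)
#'
#' The model used for channels expected to be flat, e.g. the membrane
#' anchor's intensity during cargo release. The least-squares constant is
#' the mean.
#'
#' @param x Times (used only for length checking).
#' @param y Signal values; >= 2 points.
#' @return List with `k` (the mean), `se` (standard error of the mean), and
#'   `n`.
#' @export
fit_constant <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(y) < 2L) stop("need at least 2 points")
  list(k = mean(y), se = stats::sd(y) / sqrt(length(y)), n = length(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- melting-midpoint extraction -------------------------------------------

#' Extract the melting temperature from a denaturation curve
#'
#' Locates the thermal transition from the second derivative of the
#' (Savitzky-Golay smoothed) signal: the midpoint between the extrema of
#' d2y/dT2, read as the zero crossing of the second derivative. For
#' bimolecular (dimer) melts that inflection lies systematically above the
#' half-dissociation temperature, so when the curve carries a total
#' concentration (attribute `total_conc_uM`, set by [melt_curve()] and
#' [gen_cd_melt()], or the `total_conc_uM` argument) the estimate is refined
#' by fitting the two-state bimolecular model and the half-folded
#' temperature of the fit is returned.
#'
#' @param curve A [melt_curve()] or data frame with columns `temperature_C`
#'   and `mre222` (or any two first columns temperature, signal); >= 15
#'   points spanning the transition.
#' @param window Odd Savitzky-Golay window length (points); default
#'   auto-scaled to the grid spacing (5-11 points, polynomial order 3).
#' @param total_conc_uM Peptide concentration for bimolecular refinement;
#'   default taken from the curve's attribute, `NULL` to disable refinement.
#' @return Tm in deg C, with attribute `method` (`"bimolecular-midpoint"` or
#'   `"inflection"`); `NA` (no-call) when no transition rises above the
#'   noise floor.
#' @export
tm_second_derivative <- function(curve, window = NULL, total_conc_uM = NULL) {
  if (is.null(total_conc_uM)) total_conc_uM <- attr(curve, "total_conc_uM")
  df <- as.data.frame(curve)
  tcol <- if ("temperature_C" %in% names(df)) "temperature_C" else names(df)[1]
  ycol <- if ("mre222" %in% names(df)) "mre222" else names(df)[2]
  tt <- df[[tcol]]
  yy <- df[[ycol]]
  if (length(tt) < 15L) stop("need >= 15 points spanning the transition")
  if (is.unsorted(tt, strictly = TRUE)) stop("temperatures must be sorted ascending")

  # interpolate to a uniform grid if spacing is uneven
  dts <- diff(tt)
  if (max(dts) / min(dts) > 1.001) {
    g <- approx(tt, yy, n = length(tt))
    tt <- g$x
    yy <- g$y
  }
  dT <- tt[2] - tt[1]

  if (is.null(window)) {
    window <- 2 * floor(2.5 / dT) + 1 # ~5 deg C span
    window <- max(5, min(11, window))
  }
  if (window %% 2 == 0) window <- window + 1
  window <- min(window, length(yy) - (1 - length(yy) %% 2))
  sm <- signal::sgolayfilt(yy, p = min(3, window - 2), n = window)

  noise <- stats::sd(yy - sm)
  amplitude <- diff(range(sm))
  if (amplitude <= max(10 * noise, 1e-12)) {
    warning("no transition detected (signal change below noise floor); no-call")
    return(structure(NA_real_, method = "no-call"))
  }

  d2 <- (sm[-c(1, 2)] - 2 * sm[-c(1, length(sm))] + sm[-c(length(sm) - 1, length(sm))]) / dT^2
  t2 <- tt[-c(1, length(tt))]
  i_lo <- min(which.max(d2), which.min(d2))
  i_hi <- max(which.max(d2), which.min(d2))
  if (i_lo == i_hi) {
    warning("degenerate second derivative; no-call")
    return(structure(NA_real_, method = "no-call"))
  }
  seg <- i_lo:i_hi
  sign_change <- which(d2[seg][-length(seg)] * d2[seg][-1] <= 0)
  if (length(sign_change) == 0) {
    t_inflect <- t2[seg[which.min(abs(d2[seg]))]]
  } else {
    j <- seg[sign_change[1]]
    frac <- d2[j] / (d2[j] - d2[j + 1])
    t_inflect <- t2[j] + frac * dT
  }

  if (is.null(total_conc_uM)) {
    return(structure(t_inflect, method = "inflection"))
  }

  # bimolecular two-state refinement: report the half-folded temperature
  fit <- tryCatch({
    ff <- function(temp, tm, dh) {
      fraction_folded(temp, melt_params(tm = tm, dh = dh,
                                        total_conc_uM = total_conc_uM))
    }
    minpack.lm::nlsLM(
      yy ~ bf + (bu - bf) * (1 - ff(tt, tm, dh)),
      start = list(tm = t_inflect, dh = 40, bf = sm[1], bu = sm[length(sm)]),
      lower = c(min(tt) - 50, 1, -Inf, -Inf),
      upper = c(max(tt) + 50, 500, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(t_inflect, method = "inflection"))
  }
  structure(unname(coef(fit)[["tm"]]), method = "bimolecular-midpoint")
}

# ---- t test -----------------------------------------------------------------

#' Unpaired two-tailed t test
#'
#' Student's two-sample t test with pooled variance by default (Welch's
#' unequal-variance form via `welch = TRUE`), as used for comparing
#' membrane-binding quantitation between conditions. Degenerate zero-variance
#' input is handled explicitly: equal means give `t = 0, p = 1`; unequal
#' means give infinite `t` with `degenerate = TRUE`.
#'
#' @param group1,group2 Numeric vectors, each >= 2 values.
#' @param welch Use Welch's correction instead of pooled variance.
#' @return List of class `t_test_result`: `t`, `p`, `df`, `n1`, `n2`,
#'   `mean_diff` (`mean(group1) - mean(group2)`), `method`, `degenerate`.
#' @export
unpaired_t_test <- function(group1, group2, welch = FALSE) {
  stopifnot(is.numeric(group1), is.numeric(group2))
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least 2 values")
  }
  mean_diff <- mean(group1) - mean(group2)
  v1 <- stats::var(group1)
  v2 <- stats::var(group2)
  out <- if (v1 == 0 && v2 == 0) {
    if (mean_diff == 0) {
      list(t = 0, p = 1, df = length(group1) + length(group2) - 2,
           degenerate = FALSE)
    } else {
      list(t = sign(mean_diff) * Inf, p = 0,
           df = length(group1) + length(group2) - 2, degenerate = TRUE)
    }
  } else {
    ht <- stats::t.test(group1, group2, var.equal = !welch)
    list(t = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter), degenerate = FALSE)
  }
  structure(c(out, list(n1 = length(group1), n2 = length(group2),
                        mean_diff = mean_diff,
                        method = if (welch) "welch" else "pooled")),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.4f, p = %.4g (%s, df = %.3g, n = %d/%d)\n",
              x$t, x$p, x$method, x$df, x$n1, x$n2))
  invisible(x)
}
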