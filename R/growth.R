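# Tumor growth kinetics: exponential fits to volume-vs-time tables and
# doubling times.  The doubling-time constant is 0.69 (as conventionally
# rounded in the preclinical literature), not ln 2, so that reported
# doubling times reproduce the field's arithmetic exactly.

#' Construct a growth series
#'
#' @param times_days numeric, strictly increasing observation times (days).
#' @param volumes_mm3 numeric, positive tumor volumes (mm^3).
#' @return object of class `growth_series`.
#' @export
growth_series <- function(times_days, volumes_mm3) {
  stop_if(length(times_days) != length(volumes_mm3),
          "times and volumes must have equal length")
  stop_if(length(times_days) < 3L, "need at least 3 timepoints")
  stop_if(any(!is.finite(times_days)) || any(!is.finite(volumes_mm3)),
          "times and volumes must be finite")
  stop_if(any(diff(times_days) <= 0), "times must be strictly increasing")
  stop_if(any(volumes_mm3 <= 0), "volumes must be positive")
  structure(list(times_days = as.numeric(times_days),
                 volumes_mm3 = as.numeric(volumes_mm3)),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> %d timepoints, t = %g..%g d, y = %.3g..%.3g mm^3\n",
              length(x$times_days), min(x$times_days), max(x$times_days),
              min(x$volumes_mm3), max(x$volumes_mm3)))
  invisible(x)
}

#' Tumor doubling time from an exponential rate constant
#'
#' Computed as `0.69 / k` (days), keeping the conventional rounded constant
#' rather than `log(2)` so reported values match standard preclinical
#' arithmetic.
#'
#' @param k_per_day exponential rate constant (1/day), must be positive.
#' @return doubling time in days.
#' @export
doubling_time <- function(k_per_day) {
  stop_if(!is.numeric(k_per_day) || length(k_per_day) != 1L ||
            !is.finite(k_per_day), "'k_per_day' must be a finite number")
  stop_if(k_per_day <= 0, "doubling time undefined for k <= 0")
  0.69 / k_per_day
}

#' Fit an exponential growth model
#'
#' Nonlinear least squares on the untransformed model `y = y0 * exp(k t)`
#' (log-linear regression is used only to seed the optimizer), with
#' `r^2 = 1 - SS_res / SS_tot` computed on the original volume scale.
#'
#' @param series a [growth_series()].
#' @return object of class `growth_fit`: list with `y0_mm3`, `k_per_day`,
#'   `r2`, `doubling_days` (`NA` with a `flag` when `k <= 0`).
#' @export
fit_exponential <- function(series) {
  stop_if(!inherits(series, "growth_series"), "'series' must be a growth_series")
  t <- series$times_days
  y <- series$volumes_mm3
  # log-linear initial guess (exact when noise-free)
  init <- lm(log(y) ~ t)
  start <- list(y0 = exp(unname(coef(init)[1])), k = unname(coef(init)[2]))
  fit <- tryCatch(
    nls(y ~ y0 * exp(k * t), start = start,
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # nls rejects zero-residual problems; the log-linear seed is then exact,
    # and a flat series legitimately converges to k = 0.
    pred <- start$y0 * exp(start$k * t)
    if (max(abs(pred - y)) <= 1e-8 * max(y)) {
      y0 <- start$y0; k <- start$k
    } else {
      stop("exponential fit did not converge", call. = FALSE)
    }
  } else {
    cf <- coef(fit)
    y0 <- unname(cf["y0"]); k <- unname(cf["k"])
  }
  resid <- y - y0 * exp(k * t)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  flagged <- k <= 1e-12
  structure(list(
    y0_mm3 = y0, k_per_day = k, r2 = r2,
    doubling_days = if (flagged) NA_real_ else doubling_time(k),
    flag = if (flagged) "nonpositive growth rate; doubling undefined" else NA_character_
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> y0 = %.4g mm^3, k = %.4g /d, r2 = %.3f, Td = %s d\n",
              x$y0_mm3, x$k_per_day,
              if (is.na(x$r2)) NA else x$r2,
              if (is.na(x$doubling_days)) "NA" else sprintf("%.3g", x$doubling_days)))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Fit growth tables per subject or pooled
#'
#' @param table data.frame with columns `subject`, `day`, `volume_mm3`.
#' @param pooled if TRUE (default), one fit on all rows; otherwise one fit
#'   per subject.
#' @return data.frame {subject, y0, k, r2, doubling_days}.
#' @export
fit_growth_table <- function(table, pooled = TRUE) {
  stop_if(!all(c("day", "volume_mm3") %in% names(table)),
          "table needs columns day, volume_mm3")
  if (pooled || is.null(table$subject)) {
    # pooled fit treats the cohort as one trajectory; replicate days are
    # averaged so the series is strictly increasing
    agg <- tapply(table$volume_mm3, table$day, mean)
    f <- fit_exponential(growth_series(as.numeric(names(agg)), as.numeric(agg)))
    return(data.frame(subject = "pooled", y0 = f$y0_mm3, k = f$k_per_day,
                      r2 = f$r2, doubling_days = f$doubling_days))
  }
  do.call(rbind, lapply(split(table, table$subject), function(tb) {
    f <- fit_exponential(growth_series(tb$day, tb$volume_mm3))
    data.frame(subject = tb$subject[1], y0 = f$y0_mm3, k = f$k_per_day,
               r2 = f$r2, doubling_days = f$doubling_days)
  }))
}
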