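#' Melting-curve parameters
#'
#' Constructor and validator for the three-parameter logistic melting model
#' used throughout the package. The soluble fraction of a protein at
#' temperature \eqn{T} is
#' \deqn{f(T) = p + (1 - p) / (1 + \exp(b (T - T_m)))}
#' where \eqn{T_m} is the melting point (the temperature at which half of the
#' denaturable fraction has aggregated), \eqn{b > 0} is the transition slope
#' in 1/degC, and \eqn{p \in [0, 1)} is the non-denaturable plateau fraction.
#'
#' @param tm Melting point in degC; must lie in \[30, 80\].
#' @param slope Positive transition rate in 1/degC.
#' @param plateau Non-denaturable fraction, in \[0, 1).
#' @return An object of class `"melt_params"`: a named list with elements
#'   `tm`, `slope` and `plateau`.
#' @examples
#' p <- melt_params(tm = 53, slope = 1, plateau = 0.1)
#' melt_fraction(p, 53) # midpoint: plateau + (1 - plateau) / 2 = 0.55
#' @export
melt_params <- function(tm, slope, plateau = 0) {
  stopifnot(is.numeric(tm), is.numeric(slope), is.numeric(plateau),
            length(tm) == 1L, length(slope) == 1L, length(plateau) == 1L)
  if (!is.finite(tm) || tm < 30 || tm > 80)
    stop("'tm' must be a finite temperature in [30, 80] degC", call. = FALSE)
  if (!is.finite(slope) || slope <= 0)
    stop("'slope' must be a positive finite rate (1/degC)", call. = FALSE)
  if (!is.finite(plateau) || plateau < 0 || plateau >= 1)
    stop("'plateau' must lie in [0, 1)", call. = FALSE)
  structure(list(tm = tm, slope = slope, plateau = plateau),
            class = "melt_params")
}

#' @export
print.melt_params <- function(x, ...) {
  cat(sprintf("Melting parameters: Tm = %.3f degC, slope = %.4g /degC, plateau = %.4g\n",
              x$tm, x$slope, x$plateau))
  invisible(x)
}

as_melt_params <- function(x) {
  if (inherits(x, "melt_params")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(melt_params(x[[1L]], x[[2L]], x[[3L]]))
  if (is.list(x) && all(c("tm", "slope", "plateau") %in% names(x)))
    return(melt_params(x$tm, x$slope, x$plateau))
  stop("cannot interpret input as melting parameters", call. = FALSE)
}

## bare evaluation of the logistic, vectorized over t (no validation)
.melt_frac <- function(tm, slope, plateau, t) {
  plateau + (1 - plateau) / (1 + exp(slope * (t - tm)))
}

#' Soluble fraction at a temperature
#'
#' Evaluates the logistic melting model. Strictly decreasing in `t` for
#' `slope > 0`; values lie in `(plateau, 1)`.
#'
#' @param params A [melt_params()] object (or coercible list/numeric of
#'   length 3).
#' @param t Temperature(s) in degC; vectorized.
#' @return Numeric vector of soluble fractions, same length as `t`.
#' @export
melt_fraction <- function(params, t) {
  params <- as_melt_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  .melt_frac(params$tm, params$slope, params$plateau, t)
}

#' Pooled-temperature (PISA) soluble signal
#'
#' The integral-solubility readout of a pooled-temperature design: the
#' arithmetic mean of the soluble fraction over the window temperatures.
#' Pooling by mean rather than sum differs only by a constant factor that
#' cancels in log-ratios, and keeps the value interpretable as a fraction.
#'
#' @inheritParams melt_fraction
#' @param temperatures Non-empty numeric vector of window temperatures (degC).
#'   The default is the refined 51-56 degC window.
#' @return A single soluble fraction in `(plateau, 1)`.
#' @examples
#' pisa_value(melt_params(53.5, 1, 0), 51:56)
#' @export
pisa_value <- function(params, temperatures = 51:56) {
  if (length(temperatures) == 0L)
    stop("'temperatures' must be a non-empty set", call. = FALSE)
  mean(melt_fraction(params, temperatures))
}

## least-squares objective and analytic gradient for the logistic fit;
## theta = c(tm, slope, plateau), y observed (fraction scale), t temperatures
.melt_rss <- function(theta, t, y) {
  r <- .melt_frac(theta[1L], theta[2L], theta[3L], t) - y
  sum(r * r)
}

.melt_rss_grad <- function(theta, t, y) {
  tm <- theta[1L]; b <- theta[2L]; p <- theta[3L]
  e <- exp(b * (t - tm))
  d <- 1 + e
  f <- p + (1 - p) / d
  r <- f - y
  common <- (1 - p) * e / (d * d)
  c(sum(2 * r * common * b),          # d/dtm
    sum(2 * r * -common * (t - tm)),  # d/dslope
    sum(2 * r * (1 - 1 / d)))         # d/dplateau
}

#' Fit a logistic melting curve
#'
#' Bounded multi-start least squares of the three-parameter logistic melting
#' model to (temperature, quantity) observations. Starts are laid out on a
#' Tm grid (step 2 degC within the bounds); each start is refined with
#' L-BFGS-B using the analytic gradient. Ties between starts are broken by
#' lowest residual sum of squares, then lowest Tm.
#'
#' Parameter bounds: `tm` in \[35, 75\], `slope` in (0, 5\], `plateau` in
#' \[0, 0.5\].
#'
#' @param temperature Numeric vector of temperatures in degC (>= 3 distinct
#'   values required).
#' @param quantity Non-negative soluble quantities, same length.
#' @param normalize_to_lowest If `TRUE` (default), quantities are first
#'   divided by their mean at the lowest temperature so the fitted curve is
#'   on the fraction scale.
#' @return An object of class `"melt_fit"`: list with `params`
#'   ([melt_params()]), `rss`, `n_obs`, `converged`, `fitted`, `residuals`
#'   and the data used.
#' @examples
#' tr <- melt_params(52, 1.2, 0.05)
#' y <- melt_fraction(tr, 51:56)
#' fit <- fit_melting_curve(51:56, y, normalize_to_lowest = FALSE)
#' coef(fit)
#' @export
fit_melting_curve <- function(temperature, quantity, normalize_to_lowest = TRUE) {
  stopifnot(is.numeric(temperature), is.numeric(quantity),
            length(temperature) == length(quantity))
  if (anyNA(temperature) || anyNA(quantity))
    stop("observations must be complete (no NA)", call. = FALSE)
  if (length(unique(temperature)) < 3L)
    stop("need >= 3 distinct temperatures to fit a melting curve", call. = FALSE)
  if (any(quantity < 0))
    stop("'quantity' must be non-negative", call. = FALSE)
  if (all(quantity == 0))
    stop("degenerate input: all quantities are zero", call. = FALSE)

  y <- quantity
  if (normalize_to_lowest) {
    t0 <- min(temperature)
    ref <- mean(quantity[temperature == t0])
    if (ref <= 0)
      stop("degenerate input: zero mean quantity at the lowest temperature",
           call. = FALSE)
    y <- quantity / ref
  }

  lower <- c(35, 1e-3, 0)
  upper <- c(75, 5, 0.5)
  tm_grid <- seq(35, 75, by = 2)
  best <- NULL
  for (tm0 in tm_grid) {
    start <- c(tm0, 1, min(max(min(y), 0), 0.5))
    fit <- tryCatch(
      stats::optim(start, .melt_rss, gr = .melt_rss_grad, t = temperature,
                   y = y, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e2)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[1L] < best$par[1L])) {
      best <- fit
    }
  }
  if (is.null(best))
    stop("melting-curve fit failed from every start", call. = FALSE)

  params <- melt_params(best$par[1L], max(best$par[2L], 1e-3), best$par[3L])
  fitted <- melt_fraction(params, temperature)
  structure(list(
    params = params,
    rss = best$value,
    n_obs = length(y),
    converged = best$convergence == 0L,
    fitted = fitted,
    residuals = y - fitted,
    temperature = temperature,
    quantity = y
  ), class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Logistic melting-curve fit\n")
  cat(sprintf("  Tm = %.3f degC, slope = %.4g /degC, plateau = %.4g\n",
              x$params$tm, x$params$slope, x$params$plateau))
  cat(sprintf("  n = %d, RSS = %.4g, converged: %s\n",
              x$n_obs, x$rss, x$converged))
  invisible(x)
}

#' @export
coef.melt_fit <- function(object, ...) {
  c(tm = object$params$tm, slope = object$params$slope,
    plateau = object$params$plateau)
}

#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$temperature
       else if (is.numeric(newdata)) newdata
       else newdata$temperature
  melt_fraction(object$params, t)
}

#' @export
residuals.melt_fit <- function(object, ...) object$residuals

#' @export
plot.melt_fit <- function(x, ...) {
  ord <- order(x$temperature)
  plot(x$temperature[ord], x$quantity[ord], xlab = "Temperature (degC)",
       ylab = "Soluble fraction", ...)
  tt <- seq(min(x$temperature), max(x$temperature), length.out = 200L)
  graphics::lines(tt, melt_fraction(x$params, tt))
  invisible(x)
}

#' Two-condition melting-curve comparison (NPARC-style F-test)
#'
#' Nested-model comparison of melting behaviour between two conditions for
#' one protein. The null model fits a single shared logistic curve to all
#' observations (3 parameters); the alternative fits one curve per condition
#' (6 parameters). The statistic is
#' \deqn{F = \frac{(RSS_0 - RSS_1)/(p_1 - p_0)}{RSS_1/(n - p_1)}}
#' with a p-value from the F distribution on \eqn{(p_1 - p_0, n - p_1)}
#' degrees of freedom. Theoretical degrees of freedom are used; empirical
#' moderation of the degrees of freedom is a documented non-goal.
#'
#' @param table Data frame with columns `condition`, `temperature_c` and
#'   `quantity` restricted to one protein and exactly two conditions (extra
#'   columns are ignored). Use [simulate_gradient_dataset()] column names.
#' @param normalize_to_lowest Passed to the underlying curve fits.
#' @return An object of class `"nparc_test"`: list with `rss_null`,
#'   `rss_alt`, `df_num`, `df_den`, `f_stat`, `p_value`, `perfect_fit`
#'   (TRUE when `rss_alt` is numerically zero, in which case `p_value` is 0
#'   and a warning attribute is set), and the per-condition fits.
#' @export
nparc_compare <- function(table, normalize_to_lowest = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("condition", "temperature_c", "quantity") %in% names(table)))
  conds <- unique(as.character(table$condition))
  if (length(conds) != 2L)
    stop("'table' must contain exactly two conditions", call. = FALSE)
  for (cc in conds) {
    if (length(unique(table$temperature_c[table$condition == cc])) < 3L)
      stop("each condition needs >= 3 distinct temperatures", call. = FALSE)
  }

  fit_null <- fit_melting_curve(table$temperature_c, table$quantity,
                                normalize_to_lowest = normalize_to_lowest)
  fits <- lapply(conds, function(cc) {
    sub <- table[table$condition == cc, , drop = FALSE]
    fit_melting_curve(sub$temperature_c, sub$quantity,
                      normalize_to_lowest = normalize_to_lowest)
  })
  names(fits) <- conds

  n <- nrow(table)
  p_null <- 3L
  p_alt <- 6L
  if (n <= p_alt)
    stop("insufficient observations for the nested comparison", call. = FALSE)
  rss_null <- fit_null$rss
  rss_alt <- sum(vapply(fits, `[[`, numeric(1L), "rss"))
  ## the alternative nests the null; guard tiny negative slack from the
  ## numerical optimiser
  if (rss_alt > rss_null) rss_alt <- rss_null
  df_num <- p_alt - p_null
  df_den <- n - p_alt

  perfect <- rss_alt <= 1e-14
  if (perfect && rss_null - rss_alt <= 1e-14) {
    ## both models fit perfectly (e.g. identical noise-free curves):
    ## no evidence of a difference
    perfect <- FALSE
    f_stat <- 0
    p_value <- 1
  } else if (perfect) {
    f_stat <- Inf
    p_value <- 0
    warning("perfect alternative fit (rss_alt = 0); p-value reported as 0",
            call. = FALSE)
  } else {
    f_stat <- ((rss_null - rss_alt) / df_num) / (rss_alt / df_den)
    p_value <- stats::pf(f_stat, df_num, df_den, lower.tail = FALSE)
  }

  structure(list(
    rss_null = rss_null, rss_alt = rss_alt,
    df_num = df_num, df_den = df_den,
    f_stat = f_stat, p_value = p_value,
    perfect_fit = perfect,
    fit_null = fit_null, fits = fits
  ), class = "nparc_test")
}

#' @export
print.nparc_test <- function(x, ...) {
  cat("Melting-curve comparison (nested F-test)\n")
  cat(sprintf("  RSS null = %.4g, RSS alt = %.4g\n", x$rss_null, x$rss_alt))
  cat(sprintf("  F = %.4g on (%d, %d) df, p = %.4g\n",
              x$f_stat, x$df_num, x$df_den, x$p_value))
  if (x$perfect_fit) cat("  note: perfect alternative fit\n")
  invisible(x)
}
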