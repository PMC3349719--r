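#' Steady-state summary of a simulation trace
#'
#' Means of force, available-node fraction and bound-bridge count over the
#' stationary window (the final `window` fraction of the trace), plus a
#' stationarity flag: the window's first- and second-half force means must
#' agree within twice the standard error of the window mean.
#'
#' @param trace A `sim_trace` (or data frame with `t`, `force`,
#'   `frac_avail`, `n_bound`).
#' @param window Fraction of the trace used as the stationary window.
#' @return One-row tibble: `force`, `frac_avail`, `n_bound`, `t_start`,
#'   `stationary`.
#' @export
steady_state <- function(trace, window = 0.5) {
  stopifnot(window > 0, window <= 1)
  n <- nrow(trace)
  i0 <- max(1L, n - floor(window * n) + 1L)
  w <- trace[i0:n, ]
  half <- nrow(w) %/% 2
  f1 <- mean(w$force[seq_len(half)])
  f2 <- mean(w$force[(half + 1):nrow(w)])
  se <- stats::sd(w$force) / sqrt(nrow(w))
  tibble::tibble(
    force = mean(w$force),
    frac_avail = mean(w$frac_avail),
    n_bound = mean(w$n_bound),
    t_start = trace$t[i0],
    stationary = is.na(se) || se == 0 || abs(f1 - f2) <= 2 * se * sqrt(nrow(w) / 2)
  )
}

#' Rate constant from the half-time of a developing quantity
#'
#' Estimates the apparent rate of development of force (`k_dev`) or of
#' thin-filament activation (`k_tf_act`) from a single activation-from-rest
#' trace as `ln(2) / t_half`, where `t_half` is the first time the quantity
#' crosses half of its steady-state mean (linear interpolation between
#' steps). Scale-invariant by construction.
#'
#' Before locating the crossing, the trace is smoothed with a centred
#' moving average of `smooth` points (default 9, i.e. 9 ms at the default
#' time step): the developing force is a sum of ~40 pN single-bridge
#' increments, and the resulting shot noise otherwise dominates the
#' crossing-time jitter.
#'
#' @param trace A `sim_trace`.
#' @param quantity `"force"` or `"frac_avail"`.
#' @param window Stationary-window fraction used for the steady-state mean.
#' @param smooth Width (odd number of samples) of the centred moving
#'   average applied before crossing detection; 1 disables smoothing.
#' @return One-row tibble: `quantity`, `steady`, `t_half`, `rate`
#'   (`NA` with a warning if the quantity never crosses half steady state).
#' @export
rate_from_halftime <- function(trace, quantity = c("force", "frac_avail"),
                               window = 0.5, smooth = 9L) {
  quantity <- match.arg(quantity)
  y <- trace[[quantity]]
  if (smooth > 1 && length(y) > smooth) {
    y <- as.numeric(stats::filter(y, rep(1 / smooth, smooth), sides = 2))
    y[is.na(y)] <- trace[[quantity]][is.na(y)]
  }
  t <- trace$t
  n <- length(y)
  i0 <- max(1L, n - floor(window * n) + 1L)
  steady <- mean(y[i0:n])
  target <- steady / 2
  out <- tibble::tibble(quantity = quantity, steady = steady,
                        t_half = NA_real_, rate = NA_real_)
  if (!is.finite(target) || target <= 0) {
    warning("steady-state level is not positive; rate undefined", call. = FALSE)
    return(out)
  }
  above <- which(y >= target)
  if (length(above) == 0) {
    warning("quantity never crosses half steady state; rate undefined", call. = FALSE)
    return(out)
  }
  i <- above[1]
  if (i == 1L) {
    t_half <- t[1]
    if (t_half <= 0) t_half <- t[2] / 2  # crossed within the first step
  } else {
    t_half <- t[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  out$t_half <- t_half
  out$rate <- log(2) / t_half
  out
}

#' Both half-time rate constants of a trace
#'
#' @param trace A `sim_trace`.
#' @param window Stationary-window fraction.
#' @return Tibble with rows for `force` (k_dev) and `frac_avail`
#'   (k_tf_act).
#' @export
rate_constants <- function(trace, window = 0.5) {
  dplyr::bind_rows(
    suppressWarnings(rate_from_halftime(trace, "force", window)),
    suppressWarnings(rate_from_halftime(trace, "frac_avail", window))
  )
}

#' ATPase rate from a simulation trace
#'
#' Cross-bridge turnover over the stationary window, counted from completed
#' post-stroke detachment events: `(ATP events in window) / (n_myosins *
#' window duration)`, in ATP per myosin per second.
#'
#' @param trace A `sim_trace`.
#' @param n_myosins Number of myosins; taken from the trace by default.
#' @param window Stationary-window fraction.
#' @export
atpase_rate <- function(trace, n_myosins = NULL, window = 0.5) {
  if (is.null(n_myosins)) n_myosins <- attr(trace, "n_myosins")
  stopifnot(!is.null(n_myosins), n_myosins >= 1)
  n <- nrow(trace)
  i0 <- max(1L, n - floor(window * n) + 1L)
  dt_win <- trace$t[n] - trace$t[i0]
  if (dt_win <= 0) stop("stationary window has zero length", call. = FALSE)
  tibble::tibble(
    atpase = (trace$atp[n] - trace$atp[i0]) / (n_myosins * dt_win),
    window = dt_win
  )
}

hill_model <- function(pca, x_max, pca50, n_h) {
  x_max / (1 + 10^(n_h * (pca - pca50)))
}

#' Three-parameter Hill fit of a steady-state versus pCa relationship
#'
#' Fits `y(pCa) = X_max / (1 + 10^(n_H (pCa - pCa50)))`, the three-parameter
#' Hill equation in pCa (log) space: `X_max` is the asymptote as `[Ca2+]`
#' grows without bound, `pCa50` the pCa producing the half-maximal
#' response, and `n_H` the slope at `pCa50` (the cooperativity index).
#' Fitting uses Levenberg-Marquardt least squares seeded by a coarse grid
#' search; 95% confidence intervals come from the linearised parameter
#' covariance, optionally replaced by a nonparametric residual bootstrap.
#' The fit is invariant to the ordering of the points.
#'
#' @param data Data frame holding the points.
#' @param pca,y Column names (tidyselect) of the pCa values and response.
#' @param weights Optional column of per-point standard errors; points are
#'   weighted by `1/se^2`.
#' @param bootstrap Number of bootstrap resamples for the confidence
#'   intervals (0 = use the linearised covariance).
#' @return A `hill_fit` object; see [tidy.hill_fit()] and
#'   [glance.hill_fit()]. If the optimiser cannot converge (e.g. an
#'   all-zero response) the object is returned with `converged = FALSE`
#'   and a warning, never silently.
#' @examples
#' d <- data.frame(pCa = seq(8, 4, by = -0.5),
#'                 f = hill_curve(seq(8, 4, by = -0.5), 900, 6, 3))
#' fit <- hill_fit(d, pCa, f)
#' coef(fit)
#' @export
hill_fit <- function(data, pca, y, weights = NULL, bootstrap = 0) {
  pca_v <- dplyr::pull(data, {{ pca }})
  y_v <- dplyr::pull(data, {{ y }})
  w_q <- rlang::enquo(weights)
  w_v <- if (rlang::quo_is_null(w_q)) NULL else dplyr::pull(data, !!w_q)
  ok <- is.finite(pca_v) & is.finite(y_v)
  pca_v <- pca_v[ok]; y_v <- y_v[ok]
  if (!is.null(w_v)) w_v <- w_v[ok]
  if (length(unique(pca_v)) < 4) {
    stop("need >= 4 distinct pCa points spanning the transition", call. = FALSE)
  }
  df <- data.frame(pca = pca_v, y = y_v)
  wts <- if (is.null(w_v)) rep(1, nrow(df)) else
    1 / pmax(w_v, 1e-7 * max(abs(y_v)), 1e-300)^2

  out <- structure(list(data = df, converged = FALSE, coef = NULL,
                        vcov = NULL, residuals = NULL, boot = NULL),
                   class = "hill_fit")
  if (max(y_v) <= 0 || stats::sd(y_v) == 0) {
    warning("degenerate response (flat or non-positive); Hill fit flagged as non-converged",
            call. = FALSE)
    return(out)
  }

  # coarse grid search for a start (and as a fallback optimum)
  grid <- tidyr::expand_grid(pca50 = seq(min(pca_v), max(pca_v), length.out = 41),
                             n_h = c(0.5, 1, 2, 3, 4, 6))
  sse <- purrr::pmap_dbl(grid, function(pca50, n_h) {
    pred <- hill_model(pca_v, max(y_v), pca50, n_h)
    sum(wts * (y_v - pred)^2)
  })
  start <- as.list(grid[which.min(sse), ])
  start$x_max <- max(y_v)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ hill_model(pca, x_max, pca50, n_h),
                      data = df, weights = wts,
                      start = list(x_max = start$x_max, pca50 = start$pca50,
                                   n_h = start$n_h),
                      lower = c(x_max = 0, pca50 = min(pca_v) - 2, n_h = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Hill fit did not converge; diagnostics in $data and grid start retained",
            call. = FALSE)
    out$coef <- unlist(start)[c("x_max", "pca50", "n_h")]
    return(out)
  }
  out$converged <- TRUE
  out$coef <- stats::coef(fit)
  out$vcov <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  out$residuals <- stats::resid(fit)
  out$df_residual <- stats::df.residual(fit)

  if (bootstrap > 0) {
    cf <- out$coef
    fitted <- hill_model(df$pca, cf["x_max"], cf["pca50"], cf["n_h"])
    res <- df$y - fitted
    boot <- purrr::map_dfr(seq_len(bootstrap), function(b) {
      yb <- fitted + sample(res, replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nlsLM(yb ~ hill_model(pca, x_max, pca50, n_h),
                          data = cbind(df, yb = yb), weights = wts,
                          start = as.list(cf)),
        error = function(e) NULL)
      if (is.null(fb)) return(NULL)
      tibble::as_tibble(as.list(stats::coef(fb)))
    })
    out$boot <- boot
  }
  out
}

#' Hill curve evaluated at given pCa values
#'
#' @param pca pCa values.
#' @param x_max,pca50,n_h Hill parameters.
#' @export
hill_curve <- function(pca, x_max, pca50, n_h) hill_model(pca, x_max, pca50, n_h)

#' @export
coef.hill_fit <- function(object, ...) object$coef

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>", if (!x$converged) "(NOT converged)", "\n")
  if (!is.null(x$coef)) {
    cat(sprintf("  X_max = %.4g, pCa50 = %.4g, n_H = %.4g\n",
                x$coef["x_max"], x$coef["pca50"], x$coef["n_h"]))
  }
  invisible(x)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param conf_level Confidence level for the intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (bootstrap percentiles when the fit carried bootstrap
#'   samples, otherwise linearised t-intervals).
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, conf_level = 0.95, ...) {
  if (is.null(x$coef)) return(tibble::tibble())
  est <- x$coef
  terms <- c("x_max", "pca50", "n_h")
  if (!is.null(x$boot) && nrow(x$boot) > 10) {
    a <- (1 - conf_level) / 2
    tibble::tibble(
      term = terms,
      estimate = unname(est[terms]),
      std.error = vapply(terms, function(tm) stats::sd(x$boot[[tm]]), numeric(1)),
      conf.low = vapply(terms, function(tm) stats::quantile(x$boot[[tm]], a), numeric(1)),
      conf.high = vapply(terms, function(tm) stats::quantile(x$boot[[tm]], 1 - a), numeric(1))
    )
  } else {
    se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, 3)
    tq <- if (!is.null(x$df_residual) && x$df_residual > 0)
      stats::qt(1 - (1 - conf_level) / 2, x$df_residual) else stats::qnorm(0.975)
    tibble::tibble(
      term = terms,
      estimate = unname(est[terms]),
      std.error = unname(se[terms]),
      conf.low = unname(est[terms] - tq * se[terms]),
      conf.high = unname(est[terms] + tq * se[terms])
    )
  }
}

#' Glance at a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  rss <- if (!is.null(x$residuals)) sum(x$residuals^2) else NA_real_
  tss <- sum((x$data$y - mean(x$data$y))^2)
  tibble::tibble(
    converged = x$converged,
    r.squared = if (is.finite(rss) && tss > 0) 1 - rss / tss else NA_real_,
    sigma = if (!is.null(x$df_residual) && x$df_residual > 0)
      sqrt(rss / x$df_residual) else NA_real_,
    nobs = nrow(x$data)
  )
}

#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- data.frame(pca = seq(min(d$pca), max(d$pca), length.out = 200))
  cf <- object$coef
  grid$y <- hill_model(grid$pca, cf["x_max"], cf["pca50"], cf["n_h"])
  ggplot2::ggplot(d, ggplot2::aes(.data$pca, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "pCa", y = "response")
}
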