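#' Read a geological timescale
#'
#' Delimited text with columns \code{stage}, \code{period}, \code{base_ma},
#' \code{top_ma}; stages must be contiguous, non-overlapping and ordered
#' from oldest to youngest.
#'
#' @param path file path; defaults to the packaged stage table
#'   (Carboniferous to Quaternary, ICS/Gradstein-derived ages).
#' @return a \code{"timescale"} data frame.
#' @export
read_timescale <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  names(df)[names(df) == "base_ma"] <- "base"
  names(df)[names(df) == "top_ma"] <- "top"
  if (any(df$base <= df$top)) stop("stage base must be older than top")
  if (any(abs(df$base[-1] - df$top[-nrow(df)]) > 1e-9))
    stop("stages must be contiguous, oldest first")
  structure(df, class = c("timescale", "data.frame"))
}

#' The packaged geological timescale
#'
#' Stage-level divisions from the base of the Carboniferous to the
#' present, with base/top ages in Ma.
#'
#' @return a \code{"timescale"} data frame.
#' @export
geo_timescale <- function() {
  read_timescale(system.file("extdata", "geological_stages.tsv",
                             package = "macrophy", mustWork = TRUE))
}

# stage index containing a date (boundary dates resolve to the younger
# stage; 0 Ma resolves to the youngest stage)
stage_of <- function(date, scale) {
  i <- which(scale$base >= date & scale$top < date)
  if (length(i) == 0 && date == 0) i <- nrow(scale)
  if (length(i) == 0) return(NA_integer_)
  i[1]
}

#' Stage-binned lineage richness series
#'
#' Counts, for every stage, the family lineages whose stratigraphic (or
#' ghost-range-adjusted) interval overlaps the stage, and tallies
#' originations (stage containing the first appearance) and extinctions
#' (stage containing the last appearance, extinct families only).
#'
#' @param ranges a [fossil_ranges()] table.
#' @param scale a [geo_timescale()] table.
#' @param use either \code{"fad"} (fossil-only) or \code{"adjusted_fad"}
#'   (phylogeny-adjusted; requires [adjust_originations()] output).
#' @param source label recorded on the series (e.g. \code{"fossil_only"},
#'   \code{"mrp_adjusted"}).
#' @return an object of class \code{"richness_series"}: data frame with
#'   columns \code{stage}, \code{time_ma} (stage midpoint),
#'   \code{richness}, \code{originations}, \code{extinctions}; ordered
#'   oldest to youngest.
#' @export
lineage_series <- function(ranges, scale, use = c("fad", "adjusted_fad"),
                           source = use) {
  use <- match.arg(use)
  if (use == "adjusted_fad" && is.null(ranges$adjusted_fad))
    stop("ranges have no adjusted_fad; run adjust_originations() first")
  fad <- if (use == "fad") ranges$fad else ranges$adjusted_fad
  lad <- ranges$lad
  ns <- nrow(scale)
  richness <- integer(ns)
  orig <- integer(ns)
  ext <- integer(ns)
  for (i in seq_along(fad)) {
    so <- stage_of(fad[i], scale)
    if (is.na(so))
      stop("date outside timescale for family ", ranges$family[i])
    orig[so] <- orig[so] + 1L
    if (!ranges$extant[i]) {
      se <- stage_of(lad[i], scale)
      if (is.na(se))
        stop("date outside timescale for family ", ranges$family[i])
      ext[se] <- ext[se] + 1L
    }
    hit <- fad[i] >= scale$top & lad[i] <= scale$base
    richness[hit] <- richness[hit] + 1L
  }
  structure(data.frame(stage = scale$stage,
                       time_ma = (scale$base + scale$top) / 2,
                       richness = richness,
                       originations = orig,
                       extinctions = ext,
                       stringsAsFactors = FALSE),
            source = source[1], class = c("richness_series", "data.frame"))
}

#' Resample a series to equal spacing with Akima splines
#'
#' Akima (1970) piecewise-cubic interpolation of richness against time,
#' evaluated at the same number of points equally spaced between the
#' original endpoints. Endpoints are reproduced exactly.
#'
#' @param series a \code{"richness_series"} (or any data frame with
#'   \code{time_ma} and \code{richness}); needs >= 5 points.
#' @return a \code{"richness_series"} data frame with equally spaced
#'   \code{time_ma}.
#' @export
akima_resample <- function(series) {
  if (nrow(series) < 5) stop("Akima interpolation needs at least 5 points")
  t <- -series$time_ma          # increasing towards the present
  ord <- order(t)
  t <- t[ord]
  y <- series$richness[ord]
  ti <- seq(t[1], t[length(t)], length.out = length(t))
  yi <- pracma::akimaInterp(t, y, ti)
  # akimaInterp leaves the last interval unevaluated; Akima's slope rule is
  # symmetric under time reversal, so fill from the reversed series
  if (anyNA(yi)) {
    bad <- which(is.na(yi))
    yi[bad] <- rev(pracma::akimaInterp(-rev(t), rev(y), -rev(ti[bad])))
  }
  if (anyNA(yi)) stop("Akima interpolation failed")
  structure(data.frame(time_ma = -ti, richness = yi),
            source = attr(series, "source"),
            class = c("richness_series", "data.frame"))
}

#' Durbin-Watson statistic
#'
#' d = sum_(t>=2) (e_t - e_(t-1))^2 / sum e_t^2, on a residual series in
#' time order; d near 2 indicates no lag-1 autocorrelation, d < 2 positive
#' autocorrelation.
#'
#' @param residuals numeric vector, length >= 2, not all zero.
#' @return the statistic (in [0, 4]).
#' @export
durbin_watson <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals")
  if (all(residuals == 0)) stop("all-zero residuals")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' AR(1) generalized least-squares fit of log richness against time
#'
#' Models log(richness + 1) = b0 + b1 t (+ b2 t^2) + e with AR(1) errors
#' e_t = phi e_(t-1) + u_t, on an equally spaced series; time is taken as
#' t = -Ma so that "towards the present" is increasing and a decelerating
#' log richness has a negative quadratic coefficient. phi and the
#' coefficients are estimated by maximum likelihood (via
#' \code{nlme::gls} with a \code{corAR1} structure). The Durbin-Watson
#' statistic of the ordinary least-squares \emph{linear} fit is attached
#' as an autocorrelation diagnostic.
#'
#' @param series an equally spaced \code{"richness_series"} (from
#'   [akima_resample()]), length >= 10.
#' @param order \code{"linear"} or \code{"quadratic"}.
#' @param phi optional fixed AR(1) coefficient (e.g. 0 to reproduce
#'   ordinary least squares); default NULL estimates it.
#' @param drop_extant drop the final (youngest) point before fitting --
#'   the "not including extant richness" variant.
#' @return an object of class \code{"growth_fit"}: list with
#'   \code{model}, \code{coefficients}, \code{quad_t} (t statistic of the
#'   quadratic term, NA for linear fits), \code{df} (residual degrees of
#'   freedom), \code{p} (two-sided p of the quadratic term), \code{phi},
#'   \code{dw}, \code{n}, and the underlying \code{gls} fit.
#' @export
fit_gls_ar1 <- function(series, order = c("linear", "quadratic"),
                        phi = NULL, drop_extant = FALSE) {
  order <- match.arg(order)
  if (drop_extant) series <- series[-which.min(series$time_ma), ]
  n <- nrow(series)
  if (n < 10) stop("need at least 10 points")
  t <- -series$time_ma
  ord <- base::order(t)
  t <- t[ord]
  steps <- diff(t)
  if (max(steps) - min(steps) > 1e-6 * mean(steps))
    stop("series is not equally spaced; run akima_resample() first")
  dat <- data.frame(t = t, y = log(series$richness[ord] + 1))

  form <- if (order == "linear") y ~ t else y ~ t + I(t^2)
  ols_same <- stats::lm(form, data = dat)
  np <- length(stats::coef(ols_same))
  df <- n - np
  if (stats::sigma(ols_same)^2 < 1e-18 * max(stats::var(dat$y), 1e-30)) {
    # (numerically) noiseless series: the GLS likelihood is singular, but
    # the coefficients are exactly identified by least squares
    tt <- suppressWarnings(summary(ols_same))$coefficients
    fit <- ols_same
    quad_t <- if (order == "quadratic") {
      b2 <- stats::coef(ols_same)[["I(t^2)"]]
      # a coefficient below roundoff scale is an exact zero, not a signal
      if (abs(b2) < 1e-10 * stats::sd(dat$y) / stats::sd(dat$t^2)) 0
      else tt["I(t^2)", "t value"]
    } else NA_real_
    phi_hat <- 0
  } else {
    corr <- if (is.null(phi)) nlme::corAR1(form = ~1)
            else nlme::corAR1(value = phi, form = ~1, fixed = TRUE)
    fit <- tryCatch(
      nlme::gls(form, data = dat, correlation = corr, method = "ML"),
      error = function(e) stop("GLS did not converge: ", conditionMessage(e),
                               call. = FALSE))
    tt <- summary(fit)$tTable
    quad_t <- if (order == "quadratic") tt["I(t^2)", "t-value"] else NA_real_
    phi_hat <- if (is.null(phi)) {
      as.numeric(stats::coef(fit$modelStruct$corStruct,
                             unconstrained = FALSE))
    } else phi
  }
  p <- if (order == "quadratic") 2 * stats::pt(-abs(quad_t), df) else NA_real_
  ols <- stats::lm(y ~ t, data = dat)
  structure(list(model = order,
                 coefficients = stats::coef(fit),
                 quad_t = quad_t, df = df, p = p,
                 phi = phi_hat,
                 dw = durbin_watson(stats::residuals(ols)),
                 n = n, fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("AR(1)-GLS %s fit: n = %d, phi = %.3f, DW(linear OLS) = %.2f\n",
              x$model, x$n, x$phi, x$dw))
  if (x$model == "quadratic")
    cat(sprintf("  quadratic term: t = %.2f, df = %d, p = %.4g\n",
                x$quad_t, x$df, x$p))
  invisible(x)
}

#' Classify clade growth as exponential- or logistic-consistent
#'
#' Under exponential growth log richness is linear in time; logistic
#' growth decelerates towards the present. The series is called
#' logistic-consistent iff the quadratic term is significant at
#' \code{alpha} and negative (deceleration with t = -Ma); otherwise
#' exponential-consistent.
#'
#' @param linear,quadratic [fit_gls_ar1()] fits of the same series.
#' @param alpha significance level.
#' @return \code{"logistic_consistent"} or \code{"exponential_consistent"}.
#' @export
classify_growth <- function(linear, quadratic, alpha = 0.05) {
  stopifnot(linear$model == "linear", quadratic$model == "quadratic",
            linear$n == quadratic$n)
  b2 <- quadratic$coefficients[["I(t^2)"]]
  if (!is.na(quadratic$p) && quadratic$p < alpha && b2 < 0)
    "logistic_consistent"
  else "exponential_consistent"
}

#' Lineage-through-time plot
#'
#' Plots one or more richness series (e.g. fossil-only, MRP-adjusted,
#' MRC-adjusted) against geological time, oldest on the left.
#'
#' @param series_list a \code{"richness_series"} or list of them.
#' @param col line colours.
#' @param ... further arguments to \code{plot}.
#' @export
plot_ltt <- function(series_list, col = c("black", "firebrick", "steelblue"),
                     ...) {
  if (inherits(series_list, "richness_series"))
    series_list <- list(series_list)
  xr <- range(unlist(lapply(series_list, `[[`, "time_ma")))
  yr <- range(0, unlist(lapply(series_list, `[[`, "richness")))
  graphics::plot(NA, xlim = rev(xr), ylim = yr,
                 xlab = "Time (Ma)", ylab = "Family lineages", ...)
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    graphics::lines(s$time_ma, s$richness, col = col[(i - 1) %% length(col) + 1],
                    lwd = 2)
  }
  labs <- vapply(series_list, function(s) attr(s, "source") %||% "series", "")
  graphics::legend("topleft", legend = labs, bty = "n", lwd = 2,
                   col = col[(seq_along(series_list) - 1) %% length(col) + 1])
  invisible(NULL)
}
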