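# Gaussian additive models for each scaled index over the daily and annual
# cycles: cyclic cubic regression splines for hour (period 24) and day of
# year (period 365) with four basis functions each, plus a site x year factor
# interaction with sum-to-zero contrasts. Fitting is delegated to mgcv, the
# standard engine for these smooths; smoothness is selected by GCV.

#' Cyclic cubic regression spline basis
#'
#' Evaluates a cyclic cubic regression spline basis (evenly spaced knots over
#' one period) and its curvature penalty matrix. The basis is exactly
#' periodic: rows for `x` and `x + period` are identical.
#'
#' @param x Numeric vector (reduced modulo `period` before evaluation).
#' @param period Cycle length (e.g. 24 hours or 365 days).
#' @param k Basis dimension (default 4; must be >= 3).
#' @return List with `design` (length(x) x (k - 1) matrix, the cyclic
#'   constraint absorbing one column), `penalty` (the integrated squared
#'   second-derivative matrix) and `knots`.
#' @export
cyclic_cubic_basis <- function(x, period, k = 4) {
  if (k < 3) stop("cyclic_cubic_basis: k must be >= 3")
  xm <- x %% period
  knots <- seq(0, period, length.out = k)  # endpoints identified by the wrap
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cc", k = k),
                        data = data.frame(x = xm),
                        knots = list(x = knots), absorb.cons = FALSE)[[1]]
  list(design = sm$X, penalty = sm$S[[1]], knots = sm$xp)
}

#' Fit a cyclic-smooth additive model for one index
#'
#' `value ~ s(hour, bs = "cc", k) + s(doy, bs = "cc", k) + site:year`, with
#' a Gaussian response, sum-to-zero contrasts on the site x year factor, knot
#' ranges pinned to the full cycles (hour 0-24, day-of-year 0-365) and
#' smoothing parameters chosen by GCV (or fixed via `sp`).
#'
#' @param data Data frame with columns `hour` (1-24), `doy` (1-365), `site`,
#'   `year` and the response column.
#' @param value Response column name (a scaled index, e.g. `"bi_s"`).
#' @param k Basis dimension for both smooths (default 4).
#' @param sp Optional fixed smoothing parameters (length 2), e.g. `c(0, 0)`
#'   for an unpenalized fit.
#' @return An `index_gam`: the mgcv fit plus metadata.
#' @export
fit_index_gam <- function(data, value, k = 4, sp = NULL) {
  need <- c("hour", "doy", "site", "year", value)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("fit_index_gam: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(data) < 50L) {
    stop("fit_index_gam: need at least 50 observations")
  }
  df <- data.frame(y = data[[value]], hour = data$hour, doy = data$doy,
                   site_year = interaction(data$site, data$year, drop = FALSE,
                                           sep = ":"))
  empty <- table(df$site_year) == 0
  if (any(empty)) {
    stop("fit_index_gam: empty site x year cell(s): ",
         paste(names(which(empty)), collapse = ", "))
  }
  contrasts(df$site_year) <- stats::contr.sum(nlevels(df$site_year))
  fit <- mgcv::gam(
    y ~ site_year + s(hour, bs = "cc", k = k) + s(doy, bs = "cc", k = k),
    data = df, knots = list(hour = c(0, 24), doy = c(0, 365)),
    method = "GCV.Cp", sp = sp
  )
  structure(list(fit = fit, value = value, k = k,
                 levels = levels(df$site_year)),
            class = "index_gam")
}

#' Predict an index over an hour/day grid with standard errors
#'
#' @param object An `index_gam`.
#' @param grid Data frame with `hour`, `doy`, `site`, `year`.
#' @return `grid` with added `mean` and `se` columns.
#' @export
predict_gam <- function(object, grid) {
  stopifnot(inherits(object, "index_gam"))
  sy <- interaction(grid$site, grid$year, sep = ":")
  unseen <- setdiff(unique(as.character(sy)), object$levels)
  if (length(unseen) > 0L) {
    stop("predict_gam: unseen site x year level(s): ",
         paste(unseen, collapse = ", "))
  }
  nd <- data.frame(hour = grid$hour %% 24, doy = grid$doy %% 365,
                   site_year = factor(as.character(sy),
                                      levels = object$levels))
  pr <- mgcv::predict.gam(object$fit, newdata = nd, se.fit = TRUE)
  out <- grid
  out$mean <- as.numeric(pr$fit)
  out$se <- as.numeric(pr$se.fit)
  out
}

#' Fit the per-index phenology GAMs
#'
#' One cyclic-smooth model per scaled index column.
#'
#' @param data Scaled-index data frame with `hour`, `doy`, `site`, `year`.
#' @param indices Scaled index columns (default the five `*_s` columns).
#' @param k Basis dimension (default 4).
#' @return Named list of `index_gam` fits.
#' @export
fit_phenology_gams <- function(data,
                               indices = c("aci_s", "adi_s", "bi_s", "h_s",
                                           "np_s"),
                               k = 4) {
  stats::setNames(lapply(indices, function(ix) fit_index_gam(data, ix, k = k)),
                  indices)
}
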