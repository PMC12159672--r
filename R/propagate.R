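# Chained Monte Carlo uncertainty propagation: GAM predictive normals for the
# five indices feed the calibration model, whose predictive normal is sampled
# in turn. Three steps per iteration and grid point: (i) draw each index from
# Normal(GAM mean, GAM se); (ii) push the drawn indices through the
# calibration prediction; (iii) draw activity from Normal(calibration mean,
# calibration se) on the response scale. Index draws are independent across
# the five indices; quadratic covariates are squared after drawing.

#' Propagate GAM and calibration uncertainty to activity draws
#'
#' @param gam_preds Named list (one entry per scaled index) of prediction
#'   frames aligned row-by-row with `grid`, each with `mean` and `se`
#'   columns, as from [predict_gam()].
#' @param calib A `calib_fit` or `averaged_model` for the activity response.
#' @param grid Data frame of grid points (`hour`, `doy`, `site`, `year`).
#' @param n_iter Number of Monte Carlo iterations (default 1000; >= 2).
#' @param seed Integer seed; draws are bit-reproducible given it.
#' @param index_support Clamp interval for drawn index values (the scaled
#'   support, default `c(0.0001, 0.9999)`).
#' @param response `"coverage"` (draws clamped to \[0, 1\]) or `"sonotypes"`
#'   (draws floored at 0).
#' @param activity_draw `"response"` (default: normal draw on the response
#'   scale, as the three-step procedure states, then clamped to the
#'   support) or `"link"` (normal draw on the link scale, mapped through
#'   the inverse link — respects the support without clamping).
#' @param index_corr Optional 5 x 5 correlation matrix for a joint draw of
#'   the index values (rows/columns in `names(gam_preds)` order); `NULL`
#'   (default) draws the five indices independently.
#' @return An `activity_distribution`: `grid`, `draws` (grid rows x n_iter
#'   matrix), `clamp_count` (number of clamped index draws) and `summary`
#'   (per grid point median, mean, q2.5, q97.5).
#' @export
propagate <- function(gam_preds, calib, grid, n_iter = 1000, seed = 1L,
                      index_support = c(0.0001, 0.9999),
                      response = c("coverage", "sonotypes"),
                      activity_draw = c("response", "link"),
                      index_corr = NULL) {
  response <- match.arg(response)
  activity_draw <- match.arg(activity_draw)
  if (n_iter < 2) stop("propagate: n_iter must be >= 2")
  idx_names <- names(gam_preds)
  if (is.null(idx_names) || length(idx_names) == 0L) {
    stop("propagate: gam_preds must be a named list of index predictions")
  }
  for (nm in idx_names) {
    if (nrow(gam_preds[[nm]]) != nrow(grid)) {
      stop("propagate: prediction frame for ", nm,
           " is not aligned with the grid")
    }
  }
  if (!is.null(index_corr)) {
    if (!all(dim(index_corr) == length(idx_names))) {
      stop("propagate: index_corr must be ", length(idx_names), " x ",
           length(idx_names))
    }
    corr_chol <- chol(index_corr)
  }
  n_grid <- nrow(grid)
  draws <- matrix(NA_real_, n_grid, n_iter)
  clamp_count <- 0L
  set.seed(derive_seed(seed, "propagate"))
  for (g in seq_len(n_grid)) {
    z <- matrix(stats::rnorm(n_iter * length(idx_names)), n_iter)
    if (!is.null(index_corr)) z <- z %*% corr_chol
    nd <- as.data.frame(lapply(seq_along(idx_names), function(j) {
      nm <- idx_names[j]
      x <- gam_preds[[nm]]$mean[g] + gam_preds[[nm]]$se[g] * z[, j]
      clamp_count <<- clamp_count + sum(x < index_support[1] |
                                          x > index_support[2])
      pmin(pmax(x, index_support[1]), index_support[2])
    }))
    names(nd) <- idx_names
    nd$site <- grid$site[g]
    nd$year <- grid$year[g]
    if (activity_draw == "response") {
      pr <- predict_response(calib, nd)
      a <- stats::rnorm(n_iter, pr$mean, pr$se)
      draws[g, ] <- if (response == "coverage") pmin(pmax(a, 0), 1) else
        pmax(a, 0)
    } else {
      lp <- predict_linear(calib, nd)
      eta <- stats::rnorm(n_iter, lp$eta, lp$se)
      draws[g, ] <- if (calib$family == "beta_logit") stats::plogis(eta) else
        exp(eta)
    }
  }
  structure(list(grid = grid, draws = draws, n_iter = n_iter,
                 clamp_count = clamp_count, response = response,
                 summary = summarize_activity_draws(grid, draws)),
            class = "activity_distribution")
}

summarize_activity_draws <- function(grid, draws) {
  qs <- t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7, names = FALSE))
  out <- grid
  out$median <- qs[, 2]
  out$mean <- rowMeans(draws)
  out$q2.5 <- qs[, 1]
  out$q97.5 <- qs[, 3]
  out
}

#' Summarize an activity distribution
#'
#' Median, mean and central 95% interval (type-7 quantiles) per grid point,
#' optionally averaged over sites and years.
#'
#' @param dist An `activity_distribution`.
#' @param by Optional grouping columns to aggregate over (e.g. `"hour"`);
#'   draws are pooled within groups before summarizing.
#' @return Data frame of summaries.
#' @export
summarize_activity <- function(dist, by = NULL) {
  stopifnot(inherits(dist, "activity_distribution"))
  if (is.null(by)) return(dist$summary)
  key <- interaction(dist$grid[by], drop = TRUE, sep = "|")
  res <- lapply(levels(key), function(lv) {
    d <- dist$draws[key == lv, , drop = FALSE]
    q <- stats::quantile(d, probs = c(0.025, 0.5, 0.975), type = 7,
                         names = FALSE)
    cbind(dist$grid[which(key == lv)[1L], by, drop = FALSE],
          data.frame(median = q[2], mean = mean(d), q2.5 = q[1],
                     q97.5 = q[3]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}
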