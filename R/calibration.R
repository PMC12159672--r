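# Calibration of manual insect-activity measures against the scaled acoustic
# indices. Spectrogram coverage (a proportion) is fitted with a beta
# distribution and logit link; sonotype counts with Poisson and log link.
# The candidate set holds each scaled index as a linear and a quadratic term
# plus site and year factors; every subset is fitted, ranked by AICc, and
# models within delta AICc < 2 of the best are averaged with Akaike weights
# (full averaging, zero substitution).

#' Candidate calibration terms
#'
#' The 12 selectable terms: five scaled indices linear, five quadratic,
#' plus `site` and `year` factors. The intercept is always included.
#'
#' @return Character vector of term labels.
#' @export
calibration_terms <- function() {
  idx <- c("aci_s", "adi_s", "bi_s", "h_s", "np_s")
  c(idx, paste0(idx, "_sq"), "site", "year")
}

# Expand one term label into named design columns; `xlevels` carries the
# training factor levels so prediction frames with fewer levels still yield
# the full dummy set.
term_columns <- function(data, term, xlevels = NULL) {
  if (term %in% c("site", "year")) {
    lv <- xlevels[[term]]
    if (is.null(lv)) {
      lv <- sort(unique(as.character(data[[term]])))
      if (length(lv) < 2L) {
        stop("term_columns: factor '", term, "' has a single level")
      }
    }
    f <- factor(as.character(data[[term]]), levels = lv)
    if (anyNA(f)) {
      stop("term_columns: unseen level(s) in '", term, "': ",
           paste(setdiff(unique(as.character(data[[term]])), lv),
                 collapse = ", "))
    }
    mm <- matrix(0, length(f), length(lv) - 1L,
                 dimnames = list(NULL, paste0(term, lv[-1L])))
    for (j in seq_along(lv)[-1L]) mm[f == lv[j], j - 1L] <- 1
    mm
  } else if (grepl("_sq$", term)) {
    base <- sub("_sq$", "", term)
    matrix(data[[base]]^2, ncol = 1L, dimnames = list(NULL, term))
  } else {
    matrix(data[[term]], ncol = 1L, dimnames = list(NULL, term))
  }
}

#' Build a calibration design matrix
#'
#' @param data Data frame with scaled index columns and `site` / `year`.
#' @param terms Character vector of term labels (subset of
#'   [calibration_terms()]).
#' @param xlevels Optional named list of training factor levels for `site` /
#'   `year` (used when predicting on data with fewer levels).
#' @return Numeric design matrix with leading intercept column.
#' @export
build_design <- function(data, terms, xlevels = NULL) {
  cols <- c(list(`(Intercept)` = matrix(1, nrow(data), 1L,
                                        dimnames = list(NULL,
                                                        "(Intercept)"))),
            lapply(terms, function(tm) term_columns(data, tm, xlevels)))
  do.call(cbind, cols)
}

#' Squeeze proportions off the \{0, 1\} boundary
#'
#' Manual coverage quantized to 5% steps can be exactly 0 or 1, outside the
#' beta support; the standard transform `(y (n - 1) + 0.5) / n` pulls values
#' strictly inside (0, 1).
#'
#' @param y Proportions in \[0, 1\].
#' @param n Sample size used for the squeeze (default `length(y)`).
#' @return Proportions in (0, 1).
#' @export
squeeze_proportion <- function(y, n = length(y)) (y * (n - 1) + 0.5) / n

beta_negll <- function(par, X, y) {
  mu <- stats::plogis(X %*% par[seq_len(ncol(X))])
  phi <- exp(par[length(par)])
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
         (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
}

beta_negll_grad <- function(par, X, y) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  mu <- stats::plogis(eta)
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  phi <- exp(par[p + 1L])
  ystar <- log(y / (1 - y))
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  g_beta <- -drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  g_phi <- -phi * sum(digamma(phi) - mu * digamma(mu * phi) -
                        (1 - mu) * digamma((1 - mu) * phi) +
                        mu * log(y) + (1 - mu) * log(1 - y))
  c(g_beta, g_phi)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    aliased <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
}

# Expected (Fisher) information for the beta-logit model in the working
# parameterization (beta, log phi).
beta_fisher <- function(par, X) {
  p <- ncol(X)
  phi <- exp(par[p + 1L])
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  t1 <- trigamma(mu * phi)
  t2 <- trigamma((1 - mu) * phi)
  dmu <- mu * (1 - mu)
  K <- matrix(0, p + 1L, p + 1L)
  K[seq_len(p), seq_len(p)] <- crossprod(X * (phi^2 * (t1 + t2) * dmu^2), X)
  kbp <- drop(crossprod(X, phi^2 * dmu * (t1 * mu - t2 * (1 - mu))))
  K[seq_len(p), p + 1L] <- kbp
  K[p + 1L, seq_len(p)] <- kbp
  K[p + 1L, p + 1L] <- phi^2 * sum(t1 * mu^2 + t2 * (1 - mu)^2 -
                                     trigamma(phi))
  K
}

# ML beta-logit fit on a prepared design matrix: Fisher scoring with
# step-halving (a handful of information-weighted Newton steps), falling
# back to a bounded quasi-Newton search on hard cases. log-phi is bounded
# above so noiseless responses (phi -> Inf) stay numerically well-posed.
fit_beta_core <- function(X, y, start = NULL) {
  p <- ncol(X)
  if (is.null(start)) {
    beta0 <- stats::lm.fit(X, stats::qlogis(y))$coefficients
    mu0 <- stats::plogis(drop(X %*% beta0))
    v <- stats::var(y - mu0)
    phi0 <- max(1, mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1)
    start <- c(beta0, log(phi0))
  }
  start[p + 1L] <- min(max(start[p + 1L], -5), 16)

  theta <- start
  nll <- beta_negll(theta, X, y)
  done <- FALSE
  for (it in seq_len(100L)) {
    score <- -beta_negll_grad(theta, X, y)
    K <- beta_fisher(theta, X)
    delta <- tryCatch(solve(K, score), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    step <- 1
    repeat {
      cand <- theta + step * delta
      cand[p + 1L] <- min(max(cand[p + 1L], -5), 16)
      nll_new <- beta_negll(cand, X, y)
      if (is.finite(nll_new) && nll_new <= nll + 1e-10) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
    improved <- nll - nll_new
    theta <- cand
    nll <- nll_new
    if (improved < 1e-10 * (abs(nll) + 1)) {
      done <- TRUE
      break
    }
  }
  if (!done) {
    nl <- stats::nlminb(theta, beta_negll, beta_negll_grad, X = X, y = y,
                        lower = c(rep(-Inf, p), -5),
                        upper = c(rep(Inf, p), 16),
                        control = list(iter.max = 500, eval.max = 1000,
                                       rel.tol = 1e-9))
    if (!(nl$convergence == 0 || nl$objective <= nll + 1e-6)) {
      stop("beta fit did not converge (code ", nl$convergence, ")")
    }
    if (nl$objective <= nll) {
      theta <- nl$par
      nll <- nl$objective
    }
  }
  coefs <- theta[seq_len(p)]
  names(coefs) <- colnames(X)
  phi <- exp(theta[p + 1L])
  K <- beta_fisher(theta, X)
  vc_beta <- tryCatch(solve(K)[seq_len(p), seq_len(p), drop = FALSE],
                      error = function(e) NULL)
  if (is.null(vc_beta)) {
    # degenerate phi direction (e.g. noiseless responses): condition on phi
    vc_beta <- tryCatch(solve(K[seq_len(p), seq_len(p), drop = FALSE]),
                        error = function(e) {
                          stop("beta fit: singular Fisher information")
                        })
  }
  list(coefficients = coefs, phi = phi,
       vcov = structure(vc_beta,
                        dimnames = list(colnames(X), colnames(X))),
       logLik = -nll, k = p + 1L, n = length(y))
}

# Poisson log-link IRLS on a prepared design matrix (lean .lm.fit loop; a
# warm start cuts it to 2-3 iterations inside the all-subsets enumeration).
fit_poisson_core <- function(X, y, start = NULL) {
  p <- ncol(X)
  beta <- if (is.null(start)) c(log(mean(y) + 0.1), numeric(p - 1L)) else start
  eta <- pmin(drop(X %*% beta), 30)
  kern_old <- -Inf
  fit <- NULL
  for (it in seq_len(50L)) {
    mu <- exp(eta)
    kern <- sum(y * eta - mu)             # log-lik minus the y! constant
    if (!is.finite(kern)) stop("Poisson IRLS diverged")
    if (abs(kern - kern_old) < 1e-9 * (abs(kern) + 0.1) && it > 1L) break
    if (it == 50L) stop("Poisson IRLS did not converge")
    kern_old <- kern
    wsq <- sqrt(mu)
    fit <- stats::.lm.fit(X * wsq, (eta + (y - mu) / mu) * wsq)
    beta[fit$pivot] <- fit$coefficients
    eta <- pmin(drop(X %*% beta), 30)
  }
  R <- fit$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  vc <- matrix(NA_real_, p, p)
  vc[fit$pivot, fit$pivot] <- chol2inv(R)
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(coefficients = beta, phi = NULL, vcov = vc,
       logLik = kern - sum(lgamma(y + 1)),
       k = p, n = length(y))
}

#' Fit a calibration regression
#'
#' Maximum-likelihood fit of either a beta regression with logit link
#' (response in (0, 1); precision parameter `phi` estimated jointly by BFGS
#' with analytic score) or a Poisson regression with log link (nonnegative
#' integer response, via `stats::glm.fit`). The coefficient covariance is the
#' inverse observed information.
#'
#' @param data Data frame with the response, scaled index columns and
#'   `site` / `year`.
#' @param terms Term labels (subset of [calibration_terms()]); may be empty
#'   for an intercept-only model.
#' @param response Response column name.
#' @param family `"beta_logit"` or `"poisson_log"`.
#' @return A `calib_fit`: coefficients, `phi` (beta only), `vcov`, `logLik`,
#'   `k` (parameter count incl. intercept and phi), `n`, `family`, `terms`.
#' @export
fit_calibration <- function(data, terms, response,
                            family = c("beta_logit", "poisson_log"),
                            xlevels = NULL) {
  family <- match.arg(family)
  if (is.null(xlevels)) {
    xlevels <- lapply(stats::setNames(nm = intersect(c("site", "year"),
                                                     names(data))),
                      function(tm) sort(unique(as.character(data[[tm]]))))
  }
  X <- build_design(data, terms, xlevels)
  y <- data[[response]]
  check_full_rank(X)
  if (family == "beta_logit") {
    if (any(y <= 0 | y >= 1)) {
      stop("fit_calibration: beta responses must lie strictly in (0, 1); ",
           "apply squeeze_proportion() first")
    }
    core <- fit_beta_core(X, y)
  } else {
    if (any(y < 0) || any(y != round(y))) {
      stop("fit_calibration: Poisson responses must be nonnegative integers")
    }
    core <- fit_poisson_core(X, y)
  }
  structure(c(list(family = family, terms = terms, xlevels = xlevels), core),
            class = "calib_fit")
}

#' AICc: Akaike information criterion with small-sample correction
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param fit A `calib_fit` (or any list with `logLik`, `k`, `n`).
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  ll <- fit$logLik; k <- fit$k; n <- fit$n
  if (n <= k + 1) stop("aicc: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit and rank every subset of the candidate terms
#'
#' Fits all `2^length(candidates)` submodels (intercept always present),
#' ranks them by AICc ascending with deterministic tie-breaking (fewer terms,
#' then lexicographic term labels) and attaches Akaike weights over the
#' ranked set. Submodels that fail to fit are excluded with a warning count.
#'
#' @param data Calibration data frame.
#' @param response Response column.
#' @param family `"beta_logit"` or `"poisson_log"`.
#' @param candidates Candidate term labels (default [calibration_terms()]).
#' @return A `model_ranking`: `table` (data frame: terms, k, logLik, aicc,
#'   delta, weight), `fits` (per-model coefficients and vcov), `family`,
#'   `candidates`, `n_failed`.
#' @export
enumerate_models <- function(data, response,
                             family = c("beta_logit", "poisson_log"),
                             candidates = calibration_terms()) {
  family <- match.arg(family)
  m <- length(candidates)
  if (m > 14L) stop("enumerate_models: more than 14 candidate terms")
  n_models <- 2L^m
  terms_str <- character(n_models)
  n_terms_v <- k_v <- integer(n_models)
  ll_v <- rep(NA_real_, n_models)
  fits <- vector("list", n_models)
  n_failed <- 0L
  xlevels <- lapply(stats::setNames(nm = intersect(c("site", "year"),
                                                   names(data))),
                    function(tm) sort(unique(as.character(data[[tm]]))))
  # full design built once; each submodel subsets its columns
  X_full <- build_design(data, candidates, xlevels)
  check_full_rank(X_full)
  y <- data[[response]]
  term_cols <- lapply(candidates, function(tm) {
    match(colnames(term_columns(data[seq_len(1L), , drop = FALSE], tm,
                                xlevels)),
          colnames(X_full))
  })
  warm <- if (family == "beta_logit") {
    full <- fit_beta_core(X_full, y)
    c(full$coefficients, log(full$phi))
  } else {
    fit_poisson_core(X_full, y)$coefficients
  }
  bit <- seq_len(m) - 1L
  for (id in seq_len(n_models) - 1L) {
    in_model <- bitwAnd(bitwShiftR(id, bit), 1L) == 1L
    terms <- candidates[in_model]
    cols <- c(1L, unlist(term_cols[in_model]))
    X <- X_full[, cols, drop = FALSE]
    fit <- tryCatch(
      if (family == "beta_logit") {
        fit_beta_core(X, y, start = c(warm[cols],
                                      warm[length(warm)]))
      } else {
        fit_poisson_core(X, y, start = unname(warm[cols]))
      },
      error = function(e) NULL)
    if (is.null(fit)) {
      # the warm start (full-model coefficient subset) can be a poor basin
      # for sparse submodels; retry cold before giving up
      fit <- tryCatch(
        if (family == "beta_logit") fit_beta_core(X, y) else
          fit_poisson_core(X, y),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    terms_str[id + 1L] <- paste(terms, collapse = "+")
    n_terms_v[id + 1L] <- length(terms)
    k_v[id + 1L] <- fit$k
    ll_v[id + 1L] <- fit$logLik
    fits[[id + 1L]] <- list(terms = terms, coefficients = fit$coefficients,
                            vcov = fit$vcov, phi = fit$phi, k = fit$k,
                            logLik = fit$logLik, n = fit$n)
  }
  if (n_failed > 0L) {
    warning("enumerate_models: ", n_failed, " submodel(s) failed and were ",
            "excluded")
  }
  done <- !is.na(ll_v)
  n <- length(y)
  tab <- data.frame(model_id = which(done) - 1L, terms = terms_str[done],
                    n_terms = n_terms_v[done], k = k_v[done],
                    logLik = ll_v[done],
                    aicc = -2 * ll_v[done] + 2 * k_v[done] +
                      2 * k_v[done] * (k_v[done] + 1) / (n - k_v[done] - 1),
                    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$n_terms, tab$terms)
  tab <- tab[ord, , drop = FALSE]
  tab$delta <- tab$aicc - tab$aicc[1L]
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  rownames(tab) <- NULL
  kept <- fits[!vapply(fits, is.null, logical(1))][ord]
  structure(list(table = tab, fits = kept, family = family,
                 candidates = candidates, n = kept[[1L]]$n,
                 xlevels = xlevels, n_failed = n_failed),
            class = "model_ranking")
}

#' Average the models within delta AICc of the best
#'
#' Full (zero-substitution) model averaging: coefficients of the component
#' models are averaged with renormalized Akaike weights, entering 0 where a
#' term is absent; the averaged covariance adds the between-model coefficient
#' spread to the weighted within-model covariances. Per-term inclusion counts
#' over the component set are reported.
#'
#' @param ranking A `model_ranking`.
#' @param delta_max Components are all models with `delta < delta_max`
#'   (default 2).
#' @return An `averaged_model`: coefficients, vcov, phi, component weights
#'   and term sets, inclusion counts, family.
#' @export
average_models <- function(ranking, delta_max = 2) {
  stopifnot(inherits(ranking, "model_ranking"))
  sel <- which(ranking$table$delta < delta_max)
  w <- ranking$table$weight[sel]
  w <- w / sum(w)
  comp <- ranking$fits[sel]
  coef_names <- unique(unlist(lapply(comp, function(f) names(f$coefficients))))
  p <- length(coef_names)
  beta_mat <- matrix(0, length(sel), p, dimnames = list(NULL, coef_names))
  for (i in seq_along(comp)) {
    beta_mat[i, names(comp[[i]]$coefficients)] <- comp[[i]]$coefficients
  }
  beta_bar <- drop(w %*% beta_mat)
  V <- matrix(0, p, p, dimnames = list(coef_names, coef_names))
  for (i in seq_along(comp)) {
    Vi <- matrix(0, p, p, dimnames = list(coef_names, coef_names))
    nm <- rownames(comp[[i]]$vcov)
    Vi[nm, nm] <- comp[[i]]$vcov
    d <- beta_mat[i, ] - beta_bar
    V <- V + w[i] * (Vi + tcrossprod(d))
  }
  inclusion <- table(unlist(lapply(comp, function(f) f$terms)))
  phi <- if (ranking$family == "beta_logit") {
    sum(w * vapply(comp, function(f) f$phi, numeric(1)))
  } else NULL
  structure(list(coefficients = beta_bar, vcov = V, phi = phi,
                 weights = w, component_terms = lapply(comp, `[[`, "terms"),
                 inclusion = inclusion, family = ranking$family,
                 xlevels = ranking$xlevels, n_components = length(sel)),
            class = "averaged_model")
}

inv_link <- function(family) {
  switch(family,
         beta_logit = list(mu = stats::plogis,
                           dmu = function(eta) {
                             m <- stats::plogis(eta); m * (1 - m)
                           }),
         poisson_log = list(mu = exp, dmu = exp))
}

#' Predict insect activity on the response scale
#'
#' `mean = inverse-link(x beta)`; the standard error is delta-method:
#' `|d inverse-link / d eta| * sqrt(x' Sigma x)`.
#'
#' @param model A `calib_fit` or `averaged_model`.
#' @param newdata Data frame with all covariates the model's terms need.
#' @return Data frame with `mean` and `se`.
#' @export
predict_response <- function(model, newdata) {
  lp <- predict_linear(model, newdata)
  il <- inv_link(model$family)
  data.frame(mean = il$mu(lp$eta), se = abs(il$dmu(lp$eta)) * lp$se)
}

# linear-predictor mean and standard error
predict_linear <- function(model, newdata) {
  coefs <- model$coefficients
  terms <- if (inherits(model, "averaged_model")) {
    unique(unlist(model$component_terms))
  } else model$terms
  X <- build_design(newdata, terms, model$xlevels)
  missing_cols <- setdiff(names(coefs), colnames(X))
  if (length(missing_cols) > 0L) {
    stop("predict_response: newdata lacks covariates for: ",
         paste(missing_cols, collapse = ", "))
  }
  X <- X[, names(coefs), drop = FALSE]
  list(eta = drop(X %*% coefs),
       se = sqrt(pmax(rowSums((X %*% model$vcov) * X), 0)))
}

#' Repeated k-fold cross-validation of a calibration model
#'
#' Random (unstratified) fold assignment per repeat; predictions are made on
#' the response scale and scored by RMSE and MAE per repeat. Test rows whose
#' site/year level is absent from the training folds are skipped with a
#' warning.
#'
#' @param data Calibration data frame.
#' @param terms Model terms.
#' @param response Response column.
#' @param family Model family.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed.
#' @return A `cv_metrics` list: `rmse_mean`, `rmse_sd`, `mae_mean`, `mae_sd`,
#'   `per_repeat` data frame, `n_skipped`.
#' @export
cross_validate <- function(data, terms, response, family, folds = 5,
                           repeats = 100, seed = 1L) {
  n <- nrow(data)
  if (n < folds) stop("cross_validate: fewer observations than folds")
  factor_terms <- intersect(terms, c("site", "year"))
  rmse <- mae <- numeric(repeats)
  n_skipped <- 0L
  set.seed(derive_seed(seed, "cv"))
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(folds), n))
    err <- numeric(0)
    for (f in seq_len(folds)) {
      train <- data[fold != f, , drop = FALSE]
      test <- data[fold == f, , drop = FALSE]
      keep <- rep(TRUE, nrow(test))
      for (tm in factor_terms) {
        keep <- keep & test[[tm]] %in% unique(train[[tm]])
      }
      if (!all(keep)) n_skipped <- n_skipped + sum(!keep)
      test <- test[keep, , drop = FALSE]
      if (nrow(test) == 0L) next
      fit <- fit_calibration(train, terms, response, family)
      pred <- predict_response(fit, test)
      err <- c(err, pred$mean - test[[response]])
    }
    rmse[r] <- sqrt(mean(err^2))
    mae[r] <- mean(abs(err))
  }
  if (n_skipped > 0L) {
    warning("cross_validate: ", n_skipped, " test row(s) skipped for unseen ",
            "factor levels")
  }
  structure(list(rmse_mean = mean(rmse), rmse_sd = stats::sd(rmse),
                 mae_mean = mean(mae), mae_sd = stats::sd(mae),
                 per_repeat = data.frame(repeat_id = seq_len(repeats),
                                         rmse = rmse, mae = mae),
                 n_skipped = n_skipped),
            class = "cv_metrics")
}
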