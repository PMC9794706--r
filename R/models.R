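#' Fit a negative-binomial richness GLM
#'
#' NB2 generalized linear model with log link for per-cell species counts:
#' richness is overdispersed relative to Poisson, so the variance is
#' mu + mu^2/theta with the dispersion parameter theta estimated by maximum
#' likelihood alongside the coefficients. The reported AIC is
#' -2 log L + 2 (p + 2), counting the intercept and theta.
#'
#' @param y non-negative integer counts (per-cell richness).
#' @param X data frame or matrix of predictor columns (may have zero
#'   columns for an intercept-only fit).
#' @return An `nb_richness_fit` with coefficients, their standard errors,
#'   `theta`, `aic`, null/residual deviance, adjusted explained deviance
#'   (percent) and the underlying `glm.nb` fit. A response with no variance
#'   yields a degenerate intercept-only fit flagged `degenerate = TRUE`.
#' @seealso [all_subsets()] for model selection over predictor subsets.
#' @export
fit_nb_glm <- function(y, X = NULL) {
  if (any(y < 0) || any(y != round(y))) {
    stop("y must be non-negative integer counts")
  }
  X <- if (is.null(X)) data.frame(row.names = seq_along(y)) else as.data.frame(X)
  p <- ncol(X)
  if (length(y) <= p + 2) stop("need n > p + 2 observations")
  if (stats::var(y) == 0) {
    warning("response has no variance; returning degenerate intercept-only fit")
    co <- c(`(Intercept)` = log(mean(y)))
    return(structure(list(
      variables = character(0), coefficients = co,
      se = c(`(Intercept)` = NA_real_), theta = Inf, aic = NA_real_,
      null_deviance = 0, resid_deviance = 0, adj_d2_pct = NA_real_,
      vif = NULL, n = length(y), p = 0L, degenerate = TRUE, glm = NULL),
      class = "nb_richness_fit"))
  }
  dat <- cbind(data.frame(.y = y), X)
  fit <- withCallingHandlers(
    MASS::glm.nb(.y ~ ., data = dat, control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("iteration limit", conditionMessage(w))) {
        invokeRestart("muffleWarning")   # theta at Poisson-limit boundary
      }
    }
  )
  if (!fit$converged) {
    stop(sprintf("NB-GLM did not converge in %d IWLS iterations", fit$iter))
  }
  sm <- summary(fit)
  n <- length(y)
  adj <- if (p >= 1 && n > p + 1) {
    adjusted_explained_deviance(fit$null.deviance, fit$deviance, n, p)
  } else NA_real_
  structure(list(
    variables = colnames(X) %||% character(0),
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    theta = fit$theta,
    aic = -2 * as.numeric(stats::logLik(fit)) + 2 * (p + 2),
    null_deviance = fit$null.deviance,
    resid_deviance = fit$deviance,
    adj_d2_pct = adj,
    vif = if (p >= 2) vif_screen(X) else NULL,
    n = n, p = p, degenerate = FALSE, glm = fit),
    class = "nb_richness_fit")
}

#' @export
print.nb_richness_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Negative-binomial richness GLM (n = %d, theta = %s)\n",
              x$n, format(signif(x$theta, digits))))
  if (isTRUE(x$degenerate)) cat("  [degenerate: constant response]\n")
  print(signif(x$coefficients, digits))
  if (!is.na(x$aic)) {
    cat(sprintf("  AIC %.1f   adj. explained deviance %s\n", x$aic,
                if (is.na(x$adj_d2_pct)) "-" else sprintf("%.2f%%", x$adj_d2_pct)))
  }
  invisible(x)
}

#' @export
coef.nb_richness_fit <- function(object, ...) object$coefficients

#' @export
predict.nb_richness_fit <- function(object, newdata = NULL,
                                    type = c("response", "link"), ...) {
  if (is.null(object$glm)) stop("degenerate fit has no prediction model")
  stats::predict(object$glm, newdata = newdata, type = match.arg(type))
}

#' Adjusted explained deviance of a GLM
#'
#' The deviance analogue of adjusted R-squared: with explained deviance
#' D2 = 1 - residual/null deviance, the adjusted value is
#' (1 - ((n - 1) / (n - p - 1)) (1 - D2)) * 100, in percent.
#'
#' @param null_deviance,resid_deviance model deviances.
#' @param n observations; must exceed `p + 1`.
#' @param p number of predictors (excluding intercept).
#' @return Adjusted explained deviance in percent (at most 100; can be
#'   negative for models worse than their degrees of freedom warrant).
#' @export
adjusted_explained_deviance <- function(null_deviance, resid_deviance, n, p) {
  if (n <= p + 1) stop("need n > p + 1")
  d2 <- 1 - resid_deviance / null_deviance
  (1 - ((n - 1) / (n - p - 1)) * (1 - d2)) * 100
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j is from the OLS regression of
#' predictor j on the remaining predictors. Values above 5 conventionally
#' flag multicollinearity. Exact collinearity yields `Inf` with attribute
#' `collinear = TRUE`.
#'
#' @param X data frame or matrix with at least two non-constant columns.
#' @return Named numeric vector of VIFs.
#' @export
vif_screen <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("VIF needs at least two predictor columns")
  if (any(apply(X, 2, stats::var) == 0)) stop("constant predictor column")
  out <- vapply(seq_len(ncol(X)), function(j) {
    # collinear columns give a perfect fit whose summary warns; the Inf
    # sentinel below is the intended report for that case
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(is.infinite(out))) attr(out, "collinear") <- TRUE
  out
}

#' All-subsets NB-GLM model selection
#'
#' Fits one negative-binomial GLM per non-empty predictor subset (2^p - 1
#' models; 31 for the five impact variables), ranks them by AIC ascending,
#' and marks as best the lowest-AIC model all of whose predictors pass the
#' VIF screen (VIF < `vif_threshold`). Exhaustive enumeration is
#' deterministic and subsumes stepwise search; an AIC-greedy stepwise mode
#' is available for comparison.
#'
#' @param y per-cell counts.
#' @param X data frame of candidate predictors (typically the standardized
#'   MAT, MAP, PET, HHET, DIST columns).
#' @param vif_threshold multicollinearity cutoff (default 5).
#' @param method `"exhaustive"` (default) or `"stepwise"` (both-direction
#'   AIC-greedy from the full model; returned alongside the full ranking).
#' @return A `model_selection` object: a ranking data frame (`variables`,
#'   `formula`-style signs, `adj_d2_pct`, `aic`, `max_vif`, `vif_ok`), the
#'   list of fits, and `best` (an [fit_nb_glm()] result).
#' @export
all_subsets <- function(y, X, vif_threshold = 5,
                        method = c("exhaustive", "stepwise")) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  p <- ncol(X)
  stopifnot(p >= 1)
  vars <- colnames(X)
  subsets <- unlist(lapply(seq_len(p), function(k) {
    asplit(utils::combn(vars, k), 2)
  }), recursive = FALSE)
  fits <- vector("list", length(subsets))
  failed <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(
      fit_nb_glm(y, X[, subsets[[i]], drop = FALSE]),
      error = function(e) e)
    failed[i] <- inherits(fits[[i]], "error")
  }
  if (any(failed)) {
    warning(sprintf("%d subset model(s) failed to converge and were excluded",
                    sum(failed)))
  }
  ok <- which(!failed)
  tab <- do.call(rbind, lapply(ok, function(i) {
    f <- fits[[i]]
    co <- f$coefficients[-1]
    data.frame(
      variables = paste(sprintf("%s (%+.2f)", names(co), co), collapse = ", "),
      k = f$p,
      adj_d2_pct = f$adj_d2_pct,
      aic = f$aic,
      max_vif = if (is.null(f$vif)) 1 else max(f$vif),
      vif_ok = is.null(f$vif) || all(f$vif < vif_threshold),
      stringsAsFactors = FALSE)
  }))
  ord <- order(tab$aic)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  fits_ranked <- fits[ok][ord]
  best_idx <- which(tab$vif_ok)[1]
  stepwise <- if (method == "stepwise") stepwise_nb(y, X) else NULL
  structure(list(
    ranking = tab[, c("rank", "variables", "k", "adj_d2_pct", "aic",
                      "max_vif", "vif_ok")],
    fits = fits_ranked,
    best = if (!is.na(best_idx)) fits_ranked[[best_idx]],
    n_models = length(ok), n_failed = sum(failed),
    vif_threshold = vif_threshold, stepwise = stepwise),
    class = "model_selection")
}

# Both-direction AIC-greedy stepwise search over single-variable moves.
stepwise_nb <- function(y, X) {
  vars <- colnames(X)
  current <- vars
  fit_aic <- function(v) {
    f <- tryCatch(fit_nb_glm(y, X[, v, drop = FALSE]), error = function(e) NULL)
    if (is.null(f)) Inf else f$aic
  }
  best_aic <- fit_aic(current)
  repeat {
    moves <- c(
      lapply(current, function(v) setdiff(current, v)),
      lapply(setdiff(vars, current), function(v) c(current, v))
    )
    moves <- Filter(length, moves)
    if (!length(moves)) break
    aics <- vapply(moves, fit_aic, numeric(1))
    if (min(aics) >= best_aic - 1e-9) break
    current <- moves[[which.min(aics)]]
    best_aic <- min(aics)
  }
  list(variables = sort(current), aic = best_aic,
       fit = fit_nb_glm(y, X[, current, drop = FALSE]))
}

#' @export
print.model_selection <- function(x, digits = 2, n = 10, ...) {
  cat(sprintf("All-subsets NB-GLM selection: %d models ranked by AIC\n",
              x$n_models))
  if (x$n_failed) cat(sprintf("  (%d failed fits excluded)\n", x$n_failed))
  tab <- utils::head(x$ranking, n)
  tab$adj_d2_pct <- round(tab$adj_d2_pct, digits)
  tab$aic <- round(tab$aic, 1)
  tab$max_vif <- round(tab$max_vif, digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$best)) {
    cat(sprintf("Best model (lowest AIC with all VIF < %g): %s\n",
                x$vif_threshold, paste(x$best$variables, collapse = " + ")))
  }
  invisible(x)
}

#' Standardized path model for richness
#'
#' Path analysis of cell richness on a block of freely covarying exogenous
#' predictors. With a single outcome and a saturated exogenous block, the
#' maximum-likelihood path coefficients coincide with the standardized
#' partial regression coefficients of the multiple regression of richness
#' on the predictors, which is how they are computed here. The total
#' explained variance of the outcome is reported as `r_squared_total`.
#'
#' @param y response (richness); standardized internally.
#' @param X data frame of predictors (conventionally PET, MAP, HHET, DIST);
#'   standardized internally.
#' @return A `path_fit`: standardized `coefficients`, their `se`, and
#'   `r_squared_total`.
#' @export
path_model <- function(y, X) {
  X <- as.data.frame(X)
  Z <- scale(as.matrix(X))
  zy <- as.numeric(scale(y))
  if (qr(Z)$rank < ncol(Z)) stop("singular predictor covariance")
  fit <- stats::lm(zy ~ Z)
  sm <- summary(fit)
  co <- stats::coef(fit)[-1]
  names(co) <- colnames(X)
  se <- sm$coefficients[-1, "Std. Error"]
  names(se) <- colnames(X)
  structure(list(coefficients = co, se = se,
                 r_squared_total = sm$r.squared, model = fit),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, digits = 3, ...) {
  cat("Standardized path model (saturated exogenous block)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  total R-squared: %.*f\n", digits, x$r_squared_total))
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) object$coefficients
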