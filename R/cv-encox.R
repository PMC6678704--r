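# Cross-validated lambda selection for the elastic-net Cox model.
#
# Held-out performance uses the Verweij-van Houwelingen cross-validated
# partial-likelihood deviance: for fold k, D_k(lambda) =
# -2 * [ l_all(beta_{-k}) - l_{-k}(beta_{-k}) ], i.e. the likelihood
# contribution of the held-out subjects evaluated through the full-data
# risk sets. This avoids degenerate fold-wise risk sets at small n.

#' Cross-validated elastic-net Cox fit
#'
#' Event-stratified k-fold cross-validation over the lambda grid of a
#' full-data path fit; chooses the lambda minimizing the mean held-out
#' partial-likelihood deviance. Fold assignment is reproducible from
#' `seed` and stratified on the event flag, so every fold's training set
#' retains events (a training split that still ends up without events is
#' re-folded, at most 10 times).
#'
#' @inheritParams encox
#' @param nfolds number of folds (default 5); at least `nfolds` events are
#'   required.
#' @param seed integer seed controlling fold assignment.
#' @return object of class `cv_encox`: list with `lambda`, `cvm` (mean
#'   held-out deviance), `cvsd` (standard error over folds),
#'   `lambda.min`, `fit` (the full-data `encox` path with
#'   `selected_lambda` set to `lambda.min`), `foldid`, `nfolds`, `seed`.
#' @export
cv_encox <- function(x, time, event, nfolds = 5, alpha = 0.1, seed = 1,
                     nlambda = 100, lambda.min.ratio = NULL, lambda = NULL,
                     thresh = 1e-7, maxit = 1e5) {
  x <- as.matrix(x)
  check_surv(time, event)
  if (sum(event) < nfolds)
    stopf("need at least %d events for %d-fold cross-validation", nfolds,
          nfolds)
  full <- encox(x, time, event, alpha = alpha, nlambda = nlambda,
                lambda.min.ratio = lambda.min.ratio, lambda = lambda,
                thresh = thresh, maxit = maxit)
  lam <- full$lambda
  n <- nrow(x)

  foldid <- NULL
  for (attempt in seq_len(10L)) {
    foldid <- make_folds(event, nfolds, seed + (attempt - 1L) * 1000L)
    ok <- vapply(seq_len(nfolds),
                 function(k) sum(event[foldid != k]) >= 2, logical(1))
    if (all(ok)) break
    warnf("fold split left a training set without events; re-folding")
    foldid <- NULL
  }
  if (is.null(foldid)) stopf("could not build folds with events in every training set")

  prep_all <- cox_prep(time, event)
  dev_fold <- matrix(NA_real_, nfolds, length(lam))
  for (k in seq_len(nfolds)) {
    tr <- foldid != k
    fit_k <- encox(x[tr, , drop = FALSE], time[tr], event[tr], alpha = alpha,
                   lambda = lam, thresh = thresh, maxit = maxit)
    prep_tr <- cox_prep(time[tr], event[tr])
    for (m in seq_along(lam)) {
      bfull <- fit_k$beta[, m]
      eta_all <- drop(x %*% bfull)
      ll_all <- cox_derivs(prep_all, eta_all)$loglik
      ll_tr <- cox_derivs(prep_tr, eta_all[tr])$loglik
      dev_fold[k, m] <- -2 * (ll_all - ll_tr)
    }
  }
  cvm <- colMeans(dev_fold)
  cvsd <- apply(dev_fold, 2, stats::sd) / sqrt(nfolds)
  kmin <- which.min(cvm)
  attr(full, "selected_lambda") <- lam[kmin]
  attr(full, "selected_index") <- kmin
  out <- list(lambda = lam, cvm = cvm, cvsd = cvsd,
              lambda.min = lam[kmin], fit = full, foldid = foldid,
              nfolds = nfolds, seed = seed)
  class(out) <- "cv_encox"
  out
}

# Event-stratified fold labels, reproducible from the seed and independent
# of the caller's RNG state.
#' @keywords internal
#' @noRd
make_folds <- function(event, nfolds, seed) {
  foldid <- integer(length(event))
  with_seed(seed, {
    for (lvl in unique(event)) {
      idx <- which(event == lvl)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
  })
  foldid
}

# Run code under a temporary RNG seed, restoring the caller's state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' @export
print.cv_encox <- function(x, ...) {
  k <- which.min(x$cvm)
  cat(sprintf("%d-fold cross-validated elastic-net Cox (alpha = %g)\n",
              x$nfolds, x$fit$alpha))
  cat(sprintf("lambda.min = %.6g, mean held-out deviance = %.4f (se %.4f), df = %d\n",
              x$lambda.min, x$cvm[k], x$cvsd[k], x$fit$df[k]))
  invisible(x)
}

#' @export
plot.cv_encox <- function(x, ...) {
  graphics::plot(log(x$lambda), x$cvm, type = "l",
                 xlab = "log(lambda)", ylab = "CV partial-likelihood deviance",
                 ...)
  graphics::arrows(log(x$lambda), x$cvm - x$cvsd, log(x$lambda),
                   x$cvm + x$cvsd, angle = 90, code = 3, length = 0.02,
                   col = "grey60")
  graphics::abline(v = log(x$lambda.min), lty = 2)
  invisible(x)
}

#' @export
coef.cv_encox <- function(object, s = NULL, ...) {
  coef.encox(object$fit, s = s %||% object$lambda.min)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
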