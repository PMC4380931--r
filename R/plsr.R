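# Partial least squares regression, single response, NIPALS with
# deflation of both blocks. Weights are unit-norm per component, which is
# what the VIP importance score consumes; the explained response sum of
# squares per component is tracked during deflation.

#' Fit a PLSR model (NIPALS)
#'
#' Centers and unit-variance scales predictors and response, then
#' extracts `n_components` latent components by NIPALS: each weight
#' vector `w_n` (unit norm) maximizes covariance between the deflated
#' predictor block and the deflated response. For a single response this
#' coincides with SIMPLS predictions up to sign. The element of largest
#' magnitude in each weight column is made positive so results are
#' reproducible across platforms.
#'
#' @param X numeric matrix (or `design_matrix`), observations x variables.
#' @param y numeric response vector (or `response_vector`).
#' @param n_components number of latent components; silently truncated
#'   (with a warning) if it exceeds the rank of the centered predictors.
#' @param scale logical; unit-variance scale the columns (default `TRUE`).
#'   Zero-variance columns are never divided.
#' @return object of class `plsr_model`: list with `W` (K x N weights),
#'   `P` (K x N predictor loadings), `q` (length-N response loadings),
#'   `T` (rows x N scores), `B` (length-K regression coefficients on
#'   scaled variables), `ss` (explained response sum of squares per
#'   component, scaled units), `tss` (total response sum of squares),
#'   `r2`, scaling parameters, and `variables`/`n_components`.
#' @export
fit_plsr <- function(X, y, n_components, scale = TRUE) {
  if (inherits(X, "design_matrix")) X <- X$X
  if (inherits(y, "response_vector")) y <- y$y
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  if (sd(y) < .Machine$double.eps^0.5) stop("zero response variance")
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")
  max_comp <- min(nrow(X) - 1L, ncol(X))
  if (n_components > max_comp) {
    warning("n_components truncated to ", max_comp)
    n_components <- max_comp
  }

  x_center <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  x_scale <- if (scale) ifelse(x_sd < .Machine$double.eps^0.5, 1, x_sd)
             else rep(1, ncol(X))
  y_center <- mean(y)
  y_scale <- if (scale) sd(y) else 1

  E <- sweep(sweep(X, 2, x_center, "-"), 2, x_scale, "/")
  f <- (y - y_center) / y_scale
  tss <- sum(f^2)

  K <- ncol(E)
  W <- P <- matrix(0, K, n_components)
  Tm <- matrix(0, nrow(E), n_components)
  q <- ss <- numeric(n_components)
  ncomp <- 0L
  for (n in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      warning("component extraction stopped at ", ncomp,
              ": residual covariance exhausted")
      break
    }
    w <- w / wn
    if (w[which.max(abs(w))] < 0) w <- -w
    tvec <- drop(E %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-12) {
      warning("component extraction stopped at ", ncomp, ": rank exhausted")
      break
    }
    p <- drop(crossprod(E, tvec)) / tt
    qn <- sum(tvec * f) / tt
    E <- E - tcrossprod(tvec, p)
    f <- f - tvec * qn
    ncomp <- n
    W[, n] <- w; P[, n] <- p; Tm[, n] <- tvec
    q[n] <- qn
    ss[n] <- qn^2 * tt
  }
  if (ncomp == 0L) stop("no component could be extracted")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Tm <- Tm[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]; ss <- ss[seq_len(ncomp)]

  B <- drop(W %*% solve(crossprod(P, W), q))

  structure(list(
    n_components = ncomp, W = W, P = P, q = q, T = Tm, B = B,
    ss = ss, tss = tss, r2 = sum(ss) / tss,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    variables = colnames(X) %||% paste0("V", seq_len(K))
  ), class = "plsr_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.plsr_model <- function(x, ...) {
  cat("plsr_model:", x$n_components, "components over",
      length(x$variables), "variables; R2 =", round(x$r2, 4), "\n")
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' @param object a [fit_plsr()] model.
#' @param newdata matrix of predictors with the training columns.
#' @param ... unused.
#' @return numeric vector of predictions on the original response scale.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "design_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  Xs <- sweep(sweep(newdata, 2, object$x_center, "-"), 2,
              object$x_scale, "/")
  drop(Xs %*% object$B) * object$y_scale + object$y_center
}

#' Explained response variance of a PLSR model
#'
#' @param model a [fit_plsr()] model.
#' @return list with `r2` and `ss` (per-component explained response sum
#'   of squares, in scaled-response units; `sum(ss) / tss == r2`), and
#'   `tss`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  list(r2 = model$r2, ss = model$ss, tss = model$tss)
}

#' Seeded k-fold partition
#'
#' @param n number of observations; `n_folds` folds of near-equal size.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..n_folds`.
#' @export
make_folds <- function(n, n_folds, seed) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (n < n_folds) stop("need at least one observation per fold")
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

#' Cross-validated fit metrics (Q2, MSPE, R2)
#'
#' Tenfold (by default) cross-validation with a seeded random partition:
#' each fold is predicted by a model trained on the remaining folds, with
#' centering and scaling re-estimated inside each training split (no
#' leakage). `Q2 = 1 - PRESS / TSS` with TSS about the overall response
#' mean; MSPE is the mean squared prediction error of the unit-variance
#' response, reported as a percentage (`100 * PRESS / TSS`).
#'
#' @inheritParams fit_plsr
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the fold partition (required, logged in
#'   the result).
#' @return object of class `cv_result`: list with `q2`, `mspe_percent`,
#'   `r2` (in-sample, full-data model), `predictions`, `fold_assignment`,
#'   `n_components`, `seed`.
#' @export
cross_validate <- function(X, y, n_components, n_folds = 10, seed) {
  if (inherits(X, "design_matrix")) X <- X$X
  if (inherits(y, "response_vector")) y <- y$y
  X <- as.matrix(X); y <- as.numeric(y)
  folds <- make_folds(length(y), n_folds, seed)
  pred <- numeric(length(y))
  for (k in seq_len(n_folds)) {
    test <- folds == k
    fit_k <- fit_plsr(X[!test, , drop = FALSE], y[!test], n_components)
    pred[test] <- predict(fit_k, X[test, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  full <- fit_plsr(X, y, n_components)
  structure(list(q2 = 1 - press / tss,
                 mspe_percent = 100 * press / tss,
                 r2 = full$r2,
                 predictions = pred, fold_assignment = folds,
                 n_components = full$n_components, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d components, R2 = %.3f, Q2 = %.3f, MSPE = %.1f%% (seed %d)\n",
              x$n_components, x$r2, x$q2, x$mspe_percent, x$seed))
  invisible(x)
}

#' Choose the number of PLSR components by cross-validation
#'
#' Evaluates `1..max_components` with the same seeded fold partition and
#' returns the smallest component count whose Q2 is within `tolerance` of
#' the best, i.e. extra components must improve prediction beyond the
#' tolerance to be kept.
#'
#' @inheritParams cross_validate
#' @param max_components largest component count to consider.
#' @param tolerance Q2 slack (default 0.01); 0 selects the Q2 argmax.
#' @return list with `n_components` (chosen) and `trace` (`data.table` of
#'   n, q2, mspe_percent, r2).
#' @export
select_ncomp <- function(X, y, max_components, n_folds = 10, seed,
                         tolerance = 0.01) {
  if (max_components < 1L) stop("max_components must be >= 1")
  trace <- rbindlist(lapply(seq_len(max_components), function(n) {
    cv <- cross_validate(X, y, n, n_folds, seed)
    data.table(n = n, q2 = cv$q2, mspe_percent = cv$mspe_percent,
               r2 = cv$r2)
  }))
  best <- max(trace$q2)
  chosen <- trace$n[which(trace$q2 >= best - tolerance)[1]]
  list(n_components = chosen, trace = trace[])
}
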