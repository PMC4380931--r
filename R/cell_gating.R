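# Single-cell gating: an automated, reproducible mixture-based threshold
# per marker (fitted on vehicle-control cells and then applied to every
# condition of the same cell line), quadrant fractions over two markers,
# and drug-induced subpopulation shifts.

#' Fit a High/Low gate on log marker intensities
#'
#' Fits a two-component Gaussian mixture (unequal variances,
#' [mclust::Mclust]) to per-cell log2 intensities and places the gate at
#' the intensity where the posterior probabilities of the two components
#' are equal, searched between the component means. If a one-component
#' model fits better (BIC), the sample is flagged degenerate and the
#' threshold is `+Inf` (every cell Low). A fixed `manual` threshold can
#' be supplied to bypass the fit.
#'
#' @param log_intensities numeric vector of per-cell log2 intensities
#'   (>= 100 cells recommended; fewer raises a warning).
#' @param manual optional fixed threshold overriding the mixture fit.
#' @return object of class `gate_fit`: list with `threshold` (log2
#'   scale), `degenerate`, `means`, `sds`, `weights`, `n_cells`,
#'   `method`.
#' @export
fit_gate <- function(log_intensities, manual = NULL) {
  x <- log_intensities[!is.na(log_intensities)]
  if (length(unique(x)) < 2L) stop("need >= 2 distinct intensity values")
  if (length(x) < 100L)
    warning("fewer than 100 cells; gate estimate may be unstable")
  if (!is.null(manual))
    return(structure(list(threshold = manual, degenerate = FALSE,
                          means = NULL, sds = NULL, weights = NULL,
                          n_cells = length(x), method = "manual"),
                     class = "gate_fit"))
  # Mclust evaluates helper calls in the caller's frame, so run it in an
  # environment that can see the mclust namespace without attaching it
  menv <- new.env(parent = asNamespace("mclust"))
  menv$.gate_x <- x
  fit <- eval(quote(Mclust(.gate_x, G = 1:2, modelNames = "V",
                           verbose = FALSE)), menv)
  if (fit$G < 2L) {
    warning("intensity distribution is unimodal; gate set to +Inf")
    return(structure(list(threshold = Inf, degenerate = TRUE,
                          means = fit$parameters$mean,
                          sds = sqrt(fit$parameters$variance$sigmasq),
                          weights = fit$parameters$pro,
                          n_cells = length(x), method = "mixture"),
                     class = "gate_fit"))
  }
  mu <- fit$parameters$mean
  sigma <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sigma) == 1L) sigma <- rep(sigma, 2)
  w <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sigma <- sigma[o]; w <- w[o]
  post_diff <- function(t)
    w[1] * dnorm(t, mu[1], sigma[1]) - w[2] * dnorm(t, mu[2], sigma[2])
  thr <- tryCatch(
    uniroot(post_diff, lower = mu[1], upper = mu[2], tol = 1e-8)$root,
    error = function(e) NA_real_)
  degenerate <- FALSE
  if (is.na(thr)) {
    # posteriors do not cross between the means (extreme weights)
    warning("no posterior crossing between component means; gate set to +Inf")
    thr <- Inf
    degenerate <- TRUE
  }
  structure(list(threshold = thr, degenerate = degenerate, means = mu,
                 sds = sigma, weights = w, n_cells = length(x),
                 method = "mixture"),
            class = "gate_fit")
}

#' @export
print.gate_fit <- function(x, ...) {
  cat(sprintf("gate_fit (%s): threshold %.3f on log2 intensity, %d cells%s\n",
              x$method, x$threshold, x$n_cells,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Two-marker quadrant fractions
#'
#' Assigns each cell to one of four quadrants by strict `>` comparison of
#' its log2 intensities against the per-marker thresholds and returns the
#' fraction of cells in each. Cells with a missing marker value are
#' excluded and counted.
#'
#' @param cells single-cell table with columns `cell_id`, `marker`,
#'   `intensity` (raw scale) for exactly two markers.
#' @param thresholds named numeric vector (or list of `gate_fit`) of log2
#'   thresholds, one per marker; names order defines (marker1, marker2).
#' @return object of class `gate_result`: list with `fractions` (named
#'   numeric over `High/High`, `High/Low`, `Low/High`, `Low/Low`),
#'   `n_cells`, `n_excluded`, `thresholds`, `markers`.
#' @export
quadrant_fractions <- function(cells, thresholds) {
  if (is.list(thresholds) && !is.null(thresholds[[1]]$threshold))
    thresholds <- vapply(thresholds, `[[`, numeric(1), "threshold")
  markers <- names(thresholds)
  if (length(markers) != 2L) stop("exactly two marker thresholds required")
  d <- as.data.table(cells)
  d <- d[d$marker %in% markers]
  wide <- dcast(d, cell_id ~ marker, value.var = "intensity")
  if (!all(markers %in% names(wide)))
    stop("cells table lacks marker(s): ",
         paste(setdiff(markers, names(wide)), collapse = ", "))
  m1 <- log2(wide[[markers[1]]])
  m2 <- log2(wide[[markers[2]]])
  ok <- !is.na(m1) & !is.na(m2)
  n_excl <- sum(!ok)
  m1 <- m1[ok]; m2 <- m2[ok]
  hi1 <- m1 > thresholds[[1]]
  hi2 <- m2 > thresholds[[2]]
  counts <- c("High/High" = sum(hi1 & hi2), "High/Low" = sum(hi1 & !hi2),
              "Low/High" = sum(!hi1 & hi2), "Low/Low" = sum(!hi1 & !hi2))
  structure(list(fractions = counts / sum(counts), n_cells = sum(ok),
                 n_excluded = n_excl, thresholds = thresholds,
                 markers = markers),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat("gate_result over", x$n_cells, "cells (",
      paste(x$markers, collapse = " x "), "):\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Drug-induced subpopulation shifts
#'
#' Per quadrant, the fold change (`after / before`) and absolute
#' difference of the occupied fractions between two gate results computed
#' with the same markers and thresholding policy. A quadrant empty in
#' both conditions has an undefined fold change (`NaN`, flagged).
#'
#' @param before,after `gate_result` objects.
#' @return `data.table` with columns `quadrant`, `before`, `after`,
#'   `fold_change`, `difference`, `defined`.
#' @export
#' @examples
#' # a drop from 35% to 9% of cells is a ~4-fold reduction:
#' 0.09 / 0.35
population_shift <- function(before, after) {
  if (!identical(before$markers, after$markers))
    stop("gate results use different markers")
  q <- names(before$fractions)
  fc <- after$fractions / before$fractions
  data.table(quadrant = q,
             before = as.numeric(before$fractions),
             after = as.numeric(after$fractions),
             fold_change = as.numeric(fc),
             difference = as.numeric(after$fractions - before$fractions),
             defined = !(before$fractions == 0 & after$fractions == 0))
}
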