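# Bliss-independence synergy mapping and the Spearman / partial Spearman
# biomarker screen.

#' Bliss independence prediction
#'
#' Expected combined fractional activity of two independently acting
#' agents: `I_xy = I_x + I_y - I_x * I_y`.
#'
#' @param i_x,i_y single-agent activity fractions in `[0, 1]`
#'   (vectorized).
#' @return predicted combined activity in `[0, 1]`.
#' @export
#' @examples
#' bliss_predict(0.2, 0.3)  # 0.44
bliss_predict <- function(i_x, i_y) {
  if (any(i_x < 0 | i_x > 1 | i_y < 0 | i_y > 1))
    stop("activities must lie in [0, 1]")
  i_x + i_y - i_x * i_y
}

#' Excess over Bliss independence across a dose grid
#'
#' Per dose pair, the observed combination activity minus the Bliss
#' prediction from the single-agent activities; positive excess marks
#' synergy.
#'
#' @param grid table with columns `dose_x`, `dose_y`, `i_x`, `i_y`,
#'   `i_obs` (e.g. [generate_synergy()] output); activities are
#'   apoptotic fractions by default, or `1 - relative viability`
#'   depending on how the grid was built.
#' @return object of class `synergy_grid`: the grid with added `i_pred`
#'   and `eobi` columns plus attributes `max_eobi`, `mean_eobi`.
#' @export
eobi_grid <- function(grid) {
  g <- as.data.table(grid)
  need <- c("dose_x", "dose_y", "i_x", "i_y", "i_obs")
  if (!all(need %in% names(g)))
    stop("grid must have columns: ", paste(need, collapse = ", "))
  if (any(g$i_obs < 0 | g$i_obs > 1)) stop("i_obs must lie in [0, 1]")
  g[, i_pred := bliss_predict(i_x, i_y)]
  g[, eobi := i_obs - i_pred]
  setattr(g, "class", c("synergy_grid", class(g)))
  setattr(g, "max_eobi", max(g$eobi))
  setattr(g, "mean_eobi", mean(g$eobi))
  g[]
}

#' Spearman rank correlation with large-sample p-value
#'
#' Average-rank transform followed by Pearson correlation on the ranks;
#' the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (or an exact permutation p-value for `n <= 10` when
#' `exact = TRUE`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact logical; exact permutation p-value for small n.
#' @return object of class `correlation_result`: list with `rho`,
#'   `p_value`, `n`, `method`, `defined`.
#' @export
#' @examples
#' spearman_cor(1:5, c(1, 3, 2, 5, 4))$rho  # 0.7
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need >= 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "spearman", defined = FALSE),
                     class = "correlation_result"))
  rho <- cor(rank(x), rank(y))
  p <- if (exact && n <= 10L) {
    obs <- abs(rho)
    perms <- combinat_perms(n)
    rx <- rank(x)
    ry <- rank(y)
    stat <- apply(perms, 1, function(ix) abs(cor(rx, ry[ix])))
    mean(stat >= obs - 1e-12)
  } else {
    if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(rho = rho, p_value = p, n = n, method = "spearman",
                 defined = TRUE),
            class = "correlation_result")
}

combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$defined) cat("correlation undefined (constant input), n =", x$n, "\n")
  else cat(sprintf("%s rho = %.3f (p = %.3g, n = %d)\n",
                   x$method, x$rho, x$p_value, x$n))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' First-order partial correlation on Spearman correlations:
#' `rho_xy.z = (rho_xy - rho_xz * rho_yz) /
#' sqrt((1 - rho_xz^2) * (1 - rho_yz^2))`, measuring the monotone
#' association of `x` and `y` after controlling for `z`. The p-value uses
#' the t approximation on `n - 3` degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length >= 4.
#' @return `correlation_result` with `rho` (the partial coefficient),
#'   `rho_xy` (unadjusted), `p_value`, `n`.
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("equal lengths required")
  if (n < 4L) stop("need >= 4 observations")
  r_xy <- cor(rank(x), rank(y))
  r_xz <- cor(rank(x), rank(z))
  r_yz <- cor(rank(y), rank(z))
  denom <- (1 - r_xz^2) * (1 - r_yz^2)
  if (denom <= .Machine$double.eps)
    return(structure(list(rho = NA_real_, rho_xy = r_xy, p_value = NA_real_,
                          n = n, method = "partial spearman",
                          defined = FALSE),
                     class = "correlation_result"))
  rho <- (r_xy - r_xz * r_yz) / sqrt(denom)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 3)
  }
  structure(list(rho = rho, rho_xy = r_xy, p_value = p, n = n,
                 method = "partial spearman", defined = TRUE),
            class = "correlation_result")
}

#' Rank candidate biomarkers by correlation with drug response
#'
#' For each candidate signal, computes the Spearman correlation between
#' its z-scored dose-response AUC and the z-scored viability AUC across
#' all (cell line, drug) pairs, optionally excluding listed cell lines
#' (e.g. lines that do not mount the adaptive response under study).
#' Candidates with fewer than 3 usable pairs are skipped with a warning.
#'
#' @param signal_aucs table with columns `biomarker`, `cell_line`, `drug`,
#'   `auc` (z-scored signal AUC per condition pair).
#' @param viability_aucs table with columns `cell_line`, `drug`, `auc`
#'   (z-scored viability AUC).
#' @param exclude_cell_lines character vector of cell lines to drop.
#' @return `data.table` ranked by decreasing `rho`: `biomarker`, `rho`,
#'   `p_value`, `n`, `excluded`.
#' @export
biomarker_screen <- function(signal_aucs, viability_aucs,
                             exclude_cell_lines = character(0)) {
  s <- as.data.table(signal_aucs)
  v <- as.data.table(viability_aucs)
  if (length(exclude_cell_lines)) {
    s <- s[!s$cell_line %in% exclude_cell_lines]
    v <- v[!v$cell_line %in% exclude_cell_lines]
  }
  mm <- merge(s, v, by = c("cell_line", "drug"),
              suffixes = c("_sig", "_viab"))
  res <- rbindlist(lapply(split(mm, mm$biomarker), function(d) {
    if (nrow(d) < 3L) {
      warning("biomarker ", d$biomarker[1], " skipped: <3 pairs")
      return(NULL)
    }
    r <- spearman_cor(d$auc_sig, d$auc_viab)
    data.table(biomarker = d$biomarker[1], rho = r$rho,
               p_value = r$p_value, n = r$n,
               excluded = paste(exclude_cell_lines, collapse = ";"))
  }))
  setorder(res, -rho)
  res[]
}
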