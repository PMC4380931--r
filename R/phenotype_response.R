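# Phenotype layer: non-apoptotic viability, the PLSR response vector,
# Hill dose-response fits (IC50 / Emax / AUC) and the relative-resistance
# score.

#' Non-apoptotic viability per condition
#'
#' For each (cell line, drug, dose, time) condition, averages
#' `(total_cells - apoptotic_cells)` over replicates and normalizes to the
#' same average in the time-matched vehicle control (`dose == 0`) of the
#' same cell line. Vehicle conditions therefore score exactly 1.
#'
#' @param records phenotype count table (see [generate_phenotype()]);
#'   must contain the vehicle-control rows (`dose == 0`).
#' @return `data.table` with columns `cell_line`, `drug`, `dose`, `time`,
#'   `viability`.
#' @export
#' @examples
#' rec <- data.table::data.table(
#'   cell_line = "A", drug = c("DMSO", "d1"), dose = c(0, 1), time = 48,
#'   replicate = 1, total_cells = c(1000, 800),
#'   apoptotic_cells = c(0, 200))
#' nonapoptotic_viability(rec)  # treated condition -> 0.6
nonapoptotic_viability <- function(records) {
  d <- as.data.table(records)
  if (any(d$apoptotic_cells > d$total_cells) || any(d$apoptotic_cells < 0))
    stop("apoptotic_cells must lie in [0, total_cells]")
  agg <- d[, .(nonapop = mean(total_cells - apoptotic_cells)),
           by = .(cell_line, drug, dose, time)]
  ctrl <- agg[dose == 0, .(ctrl = mean(nonapop)), by = .(cell_line, time)]
  out <- merge(agg, ctrl, by = c("cell_line", "time"), all.x = TRUE)
  if (anyNA(out$ctrl))
    stop("missing vehicle control (dose 0) for some cell line/time")
  if (any(out$ctrl <= 0)) stop("vehicle control has zero mean cell count")
  out[, viability := nonapop / ctrl]
  out[, c("nonapop", "ctrl") := NULL]
  setcolorder(out, c("cell_line", "drug", "dose", "time", "viability"))
  setkey(out, cell_line, drug, dose, time)
  out[]
}

#' Assemble the PLSR response vector
#'
#' Averages 48 h and 72 h non-apoptotic viability per treatment condition
#' into the single response the regression predicts. If 72 h data are
#' absent for a cell line, the 48 h values are used alone (documented
#' fallback for lines whose late phenotypes cannot be scored).
#'
#' @param viab output of [nonapoptotic_viability()] for one cell line.
#' @param cell_line optional cell line to restrict to.
#' @param times the two time points to average (default `c(48, 72)`).
#' @return object of class `response_vector`: list with `y` (named numeric,
#'   ordered by drug then descending dose), `conditions` (`data.table`),
#'   `source_times`.
#' @export
assemble_response <- function(viab, cell_line = NULL, times = c(48, 72)) {
  d <- as.data.table(viab)
  if (!is.null(cell_line)) {
    keep <- d$cell_line == cell_line
    d <- d[keep]
  }
  if (length(unique(d$cell_line)) != 1L)
    stop("viability table must contain exactly one cell line")
  d <- d[dose > 0]
  have <- intersect(times, unique(d$time))
  if (!times[1] %in% have)
    stop("no ", times[1], " h viability data")
  used <- if (length(have) >= 2L) times else times[1]
  resp <- d[time %in% used, .(value = mean(viability)), by = .(drug, dose)]
  setorder(resp, drug, -dose)
  y <- resp$value
  names(y) <- paste(resp$drug, signif(resp$dose, 4), sep = "@")
  structure(list(y = y, conditions = resp[, .(drug, dose)],
                 source_times = used, cell_line = unique(d$cell_line)),
            class = "response_vector")
}

#' Raw phenotype matrix for one cell line
#'
#' The uncollapsed response block: per treatment condition, relative
#' viability and apoptotic fraction at each phenotype time point (e.g.
#' 35 conditions x 6 columns for 3 time points), prior to combining them
#' into non-apoptotic viability.
#'
#' @param records phenotype count table for one cell line.
#' @param cell_line optional cell line to restrict to.
#' @return numeric matrix, rows ordered by (drug, descending dose),
#'   columns `viability@t` and `apoptotic@t` per time point.
#' @export
phenotype_matrix <- function(records, cell_line = NULL) {
  d <- as.data.table(records)
  if (!is.null(cell_line)) {
    keep <- d$cell_line == cell_line
    d <- d[keep]
  }
  if (length(unique(d$cell_line)) != 1L)
    stop("records must contain exactly one cell line")
  viab <- nonapoptotic_viability(d)
  apop <- d[, .(apoptotic = mean(apoptotic_cells / total_cells)),
            by = .(drug, dose, time)]
  v <- dcast(viab[dose > 0], drug + dose ~ time, value.var = "viability")
  a <- dcast(apop[dose > 0], drug + dose ~ time, value.var = "apoptotic")
  setorder(v, drug, -dose); setorder(a, drug, -dose)
  times <- setdiff(names(v), c("drug", "dose"))
  M <- cbind(as.matrix(v[, ..times]), as.matrix(a[, ..times]))
  colnames(M) <- c(paste0("viability@", times), paste0("apoptotic@", times))
  rownames(M) <- paste(v$drug, signif(v$dose, 4), sep = "@")
  M
}

#' Fit a four-parameter Hill dose-response curve
#'
#' Fits `v(d) = E_inf + (1 - E_inf) / (1 + (d / EC50)^h)` to relative
#' viability by least squares on the log10-dose axis
#' ([minpack.lm::nlsLM]). IC50 is the absolute concentration where the
#' fitted curve crosses viability 0.5 (reported `NA` if no crossing occurs
#' within 100x the tested dose range); Emax is the fractional effect at
#' the top tested dose, `1 - v(top)`; `auc` is the span-normalized
#' trapezoidal area of `v` over log10 dose.
#'
#' @param doses positive concentrations, uM (>= 4 points).
#' @param viabilities relative viabilities at `doses`.
#' @return object of class `dose_response_fit`: list with `ec50`,
#'   `hill_slope`, `e_inf`, `ic50`, `emax`, `auc`, `converged`, `fitted`.
#' @export
fit_dose_response <- function(doses, viabilities) {
  if (length(doses) < 4L) stop("need >= 4 dose points")
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(doses) != length(viabilities)) stop("length mismatch")
  o <- order(doses)
  doses <- doses[o]; v <- viabilities[o]
  ld <- log10(doses)

  hill_fn <- function(d, e_inf, lec50, h)
    e_inf + (1 - e_inf) / (1 + (d / 10^lec50)^h)

  # multi-start Levenberg-Marquardt: shallow or right-shifted curves have
  # nearly flat objectives, so a single start can stall in a local minimum
  starts <- expand.grid(
    e_inf = unique(c(max(0, min(v)), max(0, 2 * min(v) - max(v)), 0)),
    lec50 = unique(c(ld[which.min(abs(v - (max(v) + min(v)) / 2))],
                     min(ld) - 1, min(ld), mean(ld), max(ld),
                     max(ld) + 1)),
    h = c(0.25, 0.5, 1, 2, 4, 8))
  fit <- NULL
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(v ~ hill_fn(doses, e_inf, lec50, h),
                        start = as.list(starts[i, ]),
                        lower = c(-0.5, min(ld) - 4, 0.05),
                        upper = c(1.5, max(ld) + 4, 10),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      dev <- sum(residuals(cand)^2)
      if (dev < best - 1e-14) {
        best <- dev
        fit <- cand
      }
      if (best < 1e-24) break
    }
  }

  if (is.null(fit)) {
    # fallback: monotone linear interpolation estimates
    converged <- FALSE
    e_inf <- min(v); h <- NA_real_
    ec50 <- ic50_interp(doses, v, level = (1 + min(v)) / 2)
    ic50 <- ic50_interp(doses, v, level = 0.5)
    vfun <- function(d) approx(ld, v, xout = log10(d), rule = 2)$y
  } else {
    converged <- TRUE
    cf <- coef(fit)
    e_inf <- unname(cf["e_inf"]); h <- unname(cf["h"])
    ec50 <- unname(10^cf["lec50"])
    vfun <- function(d) hill_fn(d, e_inf, log10(ec50), h)
    ic50 <- hill_ic50(e_inf, ec50, h, range(doses))
  }
  top <- max(doses)
  structure(list(ec50 = ec50, hill_slope = h, e_inf = e_inf, ic50 = ic50,
                 emax = 1 - vfun(top),
                 auc = trapz_auc(ld, vfun(doses), normalize = TRUE),
                 converged = converged, fitted = vfun(doses),
                 doses = doses),
            class = "dose_response_fit")
}

# absolute 50%-viability crossing of the fitted Hill curve
hill_ic50 <- function(e_inf, ec50, h, dose_range) {
  # v(d) = 0.5  <=>  (d/ec50)^h = (1 - e_inf) / (0.5 - e_inf) - 1
  if (e_inf >= 0.5) return(NA_real_)  # curve never reaches 0.5
  rhs <- (1 - e_inf) / (0.5 - e_inf) - 1
  if (rhs <= 0) return(NA_real_)
  ic50 <- ec50 * rhs^(1 / h)
  lim <- c(dose_range[1] / 100, dose_range[2] * 100)
  if (ic50 < lim[1] || ic50 > lim[2]) return(NA_real_)
  ic50
}

ic50_interp <- function(doses, v, level) {
  below <- which(v <= level)
  if (length(below) == 0L) return(NA_real_)
  i <- min(below)
  if (i == 1L) return(doses[1])
  10^approx(v[c(i - 1, i)], log10(doses[c(i - 1, i)]), xout = level)$y
}

trapz_auc <- function(x, y, normalize = FALSE) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  a <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  if (normalize) a / (max(x) - min(x)) else a
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose_response_fit: EC50 %.4g uM, slope %.3g, E_inf %.3g, IC50 %s, Emax %.3g, AUC %.3g%s\n",
    x$ec50, x$hill_slope, x$e_inf,
    if (is.na(x$ic50)) "none" else sprintf("%.4g uM", x$ic50),
    x$emax, x$auc, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Classify a cell line as drug-sensitive or resistant
#'
#' Sensitive iff `log10(IC50 [M]) < -6.5` (i.e. IC50 below ~0.32 uM),
#' with a strict inequality, so an IC50 exactly at the cutoff is
#' resistant; an absent IC50 (curve never crosses 50% viability) is
#' resistant.
#'
#' @param fit a [fit_dose_response()] object (IC50 in uM) or a numeric
#'   IC50 in uM.
#' @return `"sensitive"` or `"resistant"`.
#' @export
classify_sensitivity <- function(fit) {
  ic50_um <- if (inherits(fit, "dose_response_fit")) fit$ic50 else fit
  if (is.na(ic50_um)) return("resistant")
  # strict inequality: an IC50 exactly at the cutoff is resistant; a tiny
  # tolerance keeps the boundary decision stable under rounding
  if (log10(ic50_um) - 6 < -6.5 - 1e-9) "sensitive" else "resistant"
}

#' Relative resistance from the time-dose-response surface
#'
#' Span-normalized trapezoidal AUC of non-apoptotic viability over log10
#' dose, averaged over the 48 h and 72 h time points. A fully
#' unresponsive line (viability 1 everywhere) scores 1; complete killing
#' at all doses scores 0.
#'
#' @param viab [nonapoptotic_viability()] table for one cell line and
#'   drug (or restrict via `cell_line`/`drug`).
#' @param cell_line,drug optional restrictions.
#' @param times time points averaged (default `c(48, 72)`; if only the
#'   first is present it is used alone).
#' @return single numeric resistance score.
#' @export
resistance_auc <- function(viab, cell_line = NULL, drug = NULL,
                           times = c(48, 72)) {
  d <- as.data.table(viab)
  if (!is.null(cell_line)) {
    keep <- d$cell_line == cell_line
    d <- d[keep]
  }
  if (!is.null(drug)) {
    keep <- d$drug == drug
    d <- d[keep]
  }
  d <- d[dose > 0]
  have <- intersect(times, unique(d$time))
  if (length(have) == 0L) stop("no viability at the requested times")
  per_time <- vapply(have, function(tt) {
    dd <- d[time == tt]
    if (nrow(dd) < 2L) stop("need >= 2 doses")
    trapz_auc(log10(dd$dose), dd$viability, normalize = TRUE)
  }, numeric(1))
  mean(per_time)
}
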