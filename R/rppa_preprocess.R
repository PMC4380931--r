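# Replicate-level QC and normalization: 1.5 x IQR replicate filtering,
# antibody reproducibility filtering, median collapse with log2
# normalization to vehicle control, and per-column autoscaling into the
# design matrix consumed by PLSR.

#' Remove replicate outliers by the 1.5 x IQR rule
#'
#' Values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are dropped, with
#' quartiles computed by linear interpolation of order statistics
#' (`stats::quantile` type 7). The median always survives, so at least one
#' value is retained.
#'
#' @param x numeric vector of replicate measurements (typically the 4
#'   biological x 2 technical replicates of one condition).
#' @return the retained values, in input order.
#' @export
#' @examples
#' iqr_outlier_filter(c(1, 2, 2, 3, 3, 3, 4, 10))  # drops the 10
iqr_outlier_filter <- function(x) {
  if (length(x) == 0L) stop("empty replicate vector")
  if (anyNA(x)) stop("replicate values must not be NA")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- 1.5 * (q[2] - q[1])
  x[x >= q[1] - fence & x <= q[2] + fence]
}

#' Antibody reproducibility QC
#'
#' For one cell line (and scanner pass), computes per antibody the mean
#' pairwise Pearson correlation between biological-replicate condition
#' profiles (technical replicates averaged first, profiles taken across
#' all drug/dose/time conditions) and drops antibodies below `threshold`.
#' Antibodies with fewer than two complete replicate profiles are flagged
#' `insufficient` and retained with a warning.
#'
#' @param tensor replicate-level measurement table (see [generate_rppa()]).
#' @param cell_line cell line label to evaluate.
#' @param threshold minimum acceptable mean pairwise correlation
#'   (default 0.5).
#' @param scanner optional scanner label to restrict to (default: first).
#' @return list with `retained` (character), `dropped` (character), and
#'   `scores` (`data.table` of antibody, correlation, status).
#' @export
antibody_qc <- function(tensor, cell_line, threshold = 0.5,
                        scanner = NULL) {
  d <- as.data.table(tensor)
  keep <- d$cell_line == cell_line
  d <- d[keep]
  if (nrow(d) == 0L) stop("no records for cell line ", cell_line)
  if (is.null(scanner)) scanner <- sort(unique(d$scanner))[1]
  keep <- d$scanner == scanner
  d <- d[keep]
  if (length(unique(d$bio_rep)) < 2L)
    stop("antibody QC needs >= 2 biological replicates")

  # average technical replicates -> one profile per biological replicate
  prof <- d[, .(value = mean(value)),
            by = .(antibody, drug, dose, time, bio_rep)]
  wide <- dcast(prof, antibody + drug + dose + time ~ bio_rep,
                value.var = "value")
  rep_cols <- setdiff(names(wide), c("antibody", "drug", "dose", "time"))

  scores <- wide[, {
    m <- as.matrix(.SD)
    ok <- colSums(!is.na(m)) == nrow(m)
    if (sum(ok) < 2L) {
      list(correlation = NA_real_, status = "insufficient")
    } else {
      m <- m[, ok, drop = FALSE]
      cm <- suppressWarnings(cor(m))
      vals <- cm[upper.tri(cm)]
      if (all(is.na(vals))) {
        # all replicate profiles constant: identical profiles are perfectly
        # reproducible; otherwise reproducibility is simply undefined
        if (max(abs(m - m[, 1])) == 0)
          list(correlation = 1, status = "ok")
        else list(correlation = NA_real_, status = "insufficient")
      } else {
        list(correlation = mean(vals, na.rm = TRUE), status = "ok")
      }
    }
  }, by = antibody, .SDcols = rep_cols]

  if (any(scores$status == "insufficient"))
    warning("antibodies with <2 complete replicate profiles retained: ",
            paste(scores$antibody[scores$status == "insufficient"],
                  collapse = ", "))
  drop <- scores$status == "ok" & scores$correlation < threshold
  list(retained = scores$antibody[!drop],
       dropped = scores$antibody[drop],
       scores = scores[])
}

#' Collapse replicates to per-condition log2 fold changes
#'
#' Applies the 1.5 x IQR replicate filter within each condition, takes the
#' median of the retained replicates, and log2-normalizes to the median of
#' the (equally filtered) vehicle-control replicates of the same cell
#' line, antibody and time point. Vehicle conditions map to 0 exactly.
#'
#' @param tensor replicate-level table; `dose == 0` rows are the vehicle
#'   control.
#' @param antibodies optional antibody subset (e.g. [antibody_qc()]
#'   `retained`).
#' @param scanner optional scanner label to restrict to.
#' @param apply_iqr_filter logical; set `FALSE` to skip outlier removal.
#' @return `data.table` with columns `cell_line`, `drug`, `dose`, `time`,
#'   `antibody`, `log2fc`.
#' @export
collapse_log2fc <- function(tensor, antibodies = NULL, scanner = NULL,
                            apply_iqr_filter = TRUE) {
  d <- as.data.table(tensor)
  if (!is.null(scanner)) {
    keep <- d$scanner == scanner
    d <- d[keep]
  }
  if (!is.null(antibodies)) {
    keep <- d$antibody %in% antibodies
    d <- d[keep]
  }
  if (nrow(d) == 0L) stop("no measurements after filtering")
  if (any(d$value <= 0)) stop("raw intensities must be strictly positive")

  med <- d[, .(med = median(if (apply_iqr_filter) iqr_outlier_filter(value)
                            else value)),
           by = .(cell_line, drug, dose, time, antibody)]
  ctrl <- med[dose == 0,
              .(ctrl_med = median(med)), by = .(cell_line, time, antibody)]
  out <- merge(med, ctrl, by = c("cell_line", "time", "antibody"),
               all.x = TRUE)
  if (anyNA(out$ctrl_med)) {
    miss <- unique(out[is.na(ctrl_med), .(cell_line, antibody, time)])
    stop("missing vehicle control for: ",
         paste(utils::capture.output(print(miss)), collapse = "\n"))
  }
  out[, log2fc := log2(med / ctrl_med)]
  out[dose == 0, log2fc := 0]
  setcolorder(out, c("cell_line", "drug", "dose", "time", "antibody",
                     "log2fc"))
  out[, c("med", "ctrl_med") := NULL]
  setkey(out, cell_line, drug, dose, time, antibody)
  out[]
}

variable_label <- function(signal, time) paste(signal, time, sep = "@")

#' Assemble the per-cell-line design matrix
#'
#' Reshapes a fold-change table for one cell line into the conditions x
#' variables matrix used by PLSR: rows are (drug, descending dose)
#' treatment conditions (vehicle excluded), columns are (signal, time)
#' variables labelled `signal@time`, and each column is mean-centered and
#' unit-variance scaled across rows. Zero-variance columns are flagged and
#' set to 0 rather than divided.
#'
#' @param fc_table output of [collapse_log2fc()] restricted to (or
#'   containing) one cell line.
#' @param cell_line cell line to assemble (required if the table holds
#'   several).
#' @param signals,times optional orderings; defaults to sorted unique
#'   values found in the table.
#' @param impute if `TRUE`, missing cells are filled with the column mean
#'   (before scaling); otherwise missing cells are an error.
#' @return object of class `design_matrix`: list with `X` (scaled matrix),
#'   `fold_change` (unscaled matrix), `column_means`, `column_sds`,
#'   `zero_variance` (logical), `conditions` (`data.table` of drug, dose).
#' @export
assemble_design <- function(fc_table, cell_line = NULL, signals = NULL,
                            times = NULL, impute = FALSE) {
  d <- as.data.table(fc_table)
  if (!is.null(cell_line)) {
    keep <- d$cell_line == cell_line
    d <- d[keep]
  }
  if (length(unique(d$cell_line)) != 1L)
    stop("fc_table must contain exactly one cell line (use `cell_line=`)")
  d <- d[dose > 0]
  if (is.null(signals)) signals <- sort(unique(d$antibody))
  if (is.null(times)) times <- sort(unique(d$time))

  cond <- unique(d[, .(drug, dose)])
  setorder(cond, drug, -dose)
  vars <- as.vector(t(outer(signals, times, variable_label)))

  d[, variable := variable_label(antibody, time)]
  wide <- dcast(d, drug + dose ~ variable, value.var = "log2fc")
  wide <- wide[cond, on = c("drug", "dose")]
  missing_vars <- setdiff(vars, names(wide))
  if (length(missing_vars))
    stop("variables absent from fold-change table: ",
         paste(head(missing_vars, 10), collapse = ", "))
  M <- as.matrix(wide[, ..vars])
  rownames(M) <- paste(cond$drug, signif(cond$dose, 4), sep = "@")

  if (anyNA(M)) {
    if (!impute) {
      idx <- which(is.na(M), arr.ind = TRUE)
      stop("missing design cells (condition x variable): ",
           paste(rownames(M)[idx[, 1]], colnames(M)[idx[, 2]],
                 sep = " x ", collapse = "; "))
    }
    for (j in seq_len(ncol(M))) {
      nas <- is.na(M[, j])
      if (any(nas)) M[nas, j] <- mean(M[, j], na.rm = TRUE)
    }
  }

  mns <- colMeans(M)
  sds <- apply(M, 2, sd)
  zero_var <- sds < .Machine$double.eps^0.5
  X <- sweep(M, 2, mns, "-")
  X <- sweep(X, 2, ifelse(zero_var, 1, sds), "/")
  X[, zero_var] <- 0

  structure(list(X = X, fold_change = M, column_means = mns,
                 column_sds = sds, zero_variance = zero_var,
                 conditions = cond, signals = signals, times = times,
                 cell_line = unique(d$cell_line)),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "conditions x", ncol(x$X),
      "variables (cell line ", x$cell_line, ")\n", sep = " ")
  invisible(x)
}

#' Invert the autoscaling of a design matrix
#'
#' @param design a [assemble_design()] object.
#' @return the unscaled fold-change matrix reconstructed from `X` and the
#'   stored column means/sds.
#' @export
unscale_design <- function(design) {
  X <- sweep(design$X, 2,
             ifelse(design$zero_variance, 1, design$column_sds), "*")
  sweep(X, 2, design$column_means, "+")
}

#' Dual-analysis consistency mask
#'
#' Keeps a (signal, time) variable iff the sign of its condition-averaged
#' fold change agrees between two independent analyses of the same slides
#' (two scanners / image-analysis passes).
#'
#' @param fc_a,fc_b fold-change tables ([collapse_log2fc()]) over
#'   identical condition and variable keys.
#' @return list with `mask` (`data.table`: variable, kept), `fraction_kept`.
#' @export
consistency_mask <- function(fc_a, fc_b) {
  a <- as.data.table(fc_a)[dose > 0]
  b <- as.data.table(fc_b)[dose > 0]
  keyc <- c("cell_line", "drug", "dose", "time", "antibody")
  setkeyv(a, keyc); setkeyv(b, keyc)
  if (!identical(a[, ..keyc], b[, ..keyc]))
    stop("the two fold-change tables must share identical keys")
  ma <- a[, .(m = mean(log2fc)), by = .(antibody, time)]
  mb <- b[, .(m = mean(log2fc)), by = .(antibody, time)]
  mm <- merge(ma, mb, by = c("antibody", "time"), suffixes = c("_a", "_b"))
  mm[, variable := variable_label(antibody, time)]
  mm[, kept := sign(m_a) == sign(m_b)]
  list(mask = mm[, .(variable, kept)],
       fraction_kept = mean(mm$kept))
}
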