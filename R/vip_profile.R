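# Variable importance in the projection (VIP), the sign / threshold /
# consistency rules applied to it, and hierarchical clustering of cell
# lines on signed VIP signatures.

#' VIP scores of a fitted PLSR model
#'
#' For K predictor variables and N components with unit-norm weight
#' columns `w_n` and explained response sums of squares `SS_n`,
#' `VIP_k = sqrt(K * sum_n(w_nk^2 * SS_n) / sum_n(SS_n))`. Because each
#' weight column has unit norm, `sum_k VIP_k^2 = K` identically; a VIP
#' above 1 marks a variable carrying more than average importance.
#'
#' @param model a [fit_plsr()] model.
#' @return named numeric vector of VIP scores (length K, all >= 0).
#' @export
compute_vip <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  if (sum(model$ss) <= 0) stop("model explains nothing (all SS_n = 0)")
  K <- nrow(model$W)
  vip <- sqrt(K * drop(model$W^2 %*% model$ss) / sum(model$ss))
  names(vip) <- model$variables
  vip
}

#' Sign and threshold VIP scores
#'
#' VIP scores are non-negative; a minus sign is attached to variables
#' whose values anti-correlate with the response (Pearson correlation of
#' the predictor column with `y`; an exactly zero correlation gets +1 by
#' convention). Scores with `vip <= 1` are then set to zero, so only
#' above-average-importance variables survive with their direction.
#'
#' @param vip named VIP vector ([compute_vip()]).
#' @param X predictor matrix (or `design_matrix`) the model was fitted on.
#' @param y response vector (or `response_vector`).
#' @param sign_source `"correlation"` (default) or `"coefficient"` (sign
#'   of the PLSR regression coefficient; requires `model`).
#' @param model needed only for `sign_source = "coefficient"`.
#' @return object of class `vip_profile`: `data.table` with columns
#'   `variable`, `vip`, `sign`, `signed_vip`, `kept`.
#' @export
sign_and_threshold <- function(vip, X, y,
                               sign_source = c("correlation", "coefficient"),
                               model = NULL) {
  sign_source <- match.arg(sign_source)
  if (inherits(X, "design_matrix")) X <- X$X
  if (inherits(y, "response_vector")) y <- y$y
  if (length(vip) != ncol(X)) stop("vip length must match columns of X")
  sgn <- if (sign_source == "correlation") {
    sds <- apply(X, 2, sd)
    r <- rep(0, ncol(X))
    ok <- sds > 0
    r[ok] <- as.numeric(cor(X[, ok, drop = FALSE], y))
    ifelse(r < 0, -1, 1)
  } else {
    if (is.null(model)) stop("sign_source='coefficient' requires `model`")
    ifelse(model$B < 0, -1, 1)
  }
  out <- data.table(
    variable = names(vip) %||% colnames(X) %||% paste0("V", seq_along(vip)),
    vip = as.numeric(vip),
    sign = sgn)
  out[, signed_vip := ifelse(vip > 1, sign * vip, 0)]
  out[, kept := TRUE]
  setattr(out, "class", c("vip_profile", class(out)))
  out[]
}

#' Merge VIP profiles from two independent analyses
#'
#' Applies a dual-analysis [consistency_mask()] (variables whose mean
#' fold change disagreed in direction are removed), then averages the two
#' signed VIP profiles; variables whose thresholded signed scores carry
#' opposite signs in the two analyses are additionally dropped and
#' counted, so only reproducible importance calls survive.
#'
#' @param profile_a,profile_b `vip_profile` objects over identical
#'   variables.
#' @param mask optional [consistency_mask()] result (or its `mask`
#'   table).
#' @return list with `profile` (merged `vip_profile` over the kept
#'   variables), `n_masked` (removed by the mask), `n_sign_conflict`
#'   (removed for conflicting signed scores), `fraction_kept`.
#' @export
merge_consistent_vip <- function(profile_a, profile_b, mask = NULL) {
  a <- as.data.table(profile_a)
  b <- as.data.table(profile_b)
  if (!identical(a$variable, b$variable))
    stop("profiles must cover identical variables in identical order")
  keep <- rep(TRUE, nrow(a))
  if (!is.null(mask)) {
    m <- if (is.list(mask) && !is.data.frame(mask)) mask$mask else
      as.data.table(mask)
    idx <- match(a$variable, m$variable)
    if (anyNA(idx)) stop("mask does not cover all profile variables")
    keep <- m$kept[idx]
  }
  n_masked <- sum(!keep)
  conflict <- a$signed_vip * b$signed_vip < 0
  n_conflict <- sum(conflict & keep)
  keep <- keep & !conflict
  merged <- data.table(
    variable = a$variable[keep],
    vip = (a$vip[keep] + b$vip[keep]) / 2,
    sign = ifelse(a$signed_vip[keep] + b$signed_vip[keep] < 0, -1, 1),
    signed_vip = (a$signed_vip[keep] + b$signed_vip[keep]) / 2)
  merged[, kept := TRUE]
  setattr(merged, "class", c("vip_profile", class(merged)))
  list(profile = merged[], n_masked = n_masked,
       n_sign_conflict = n_conflict,
       fraction_kept = sum(keep) / nrow(a))
}

#' Cluster cell lines on signed VIP signatures
#'
#' Stacks one signed, thresholded VIP profile per cell line into a matrix
#' (cell lines x variables), optionally removes direct drug-target
#' readouts (e.g. pMEK, pERK), and clusters the rows by Euclidean
#' distance with average-linkage agglomeration.
#'
#' @param profiles named list of `vip_profile` objects (names are cell
#'   line labels), or a numeric matrix of signed VIP scores with cell
#'   lines as rows.
#' @param exclude character vector of signal names or full `signal@time`
#'   variable labels to remove before computing distances.
#' @return list with `hclust` (the merge tree), `leaf_order` (cell line
#'   labels in dendrogram order), `matrix` (the clustered matrix),
#'   `newick` (the tree in newick text form).
#' @export
cluster_cell_lines <- function(profiles, exclude = character(0)) {
  if (is.matrix(profiles)) {
    M <- profiles
  } else {
    if (length(profiles) < 2L) stop("need >= 2 profiles")
    vars <- profiles[[1]]$variable
    for (p in profiles) if (!identical(p$variable, vars))
      stop("all profiles must cover identical variables")
    M <- do.call(rbind, lapply(profiles, function(p) p$signed_vip))
    rownames(M) <- names(profiles)
    colnames(M) <- vars
  }
  if (length(exclude)) {
    sig <- sub("@.*$", "", colnames(M))
    M <- M[, !(colnames(M) %in% exclude | sig %in% exclude), drop = FALSE]
  }
  hc <- hclust(dist(M, method = "euclidean"), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, leaf_order = hc$labels[hc$order], matrix = M,
       newick = nwk)
}
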