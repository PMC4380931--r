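# Synthetic study generator: a low-rank latent "pathway activity" model.
# Each latent follows a per-drug Hill dose-response multiplied by a time
# profile that may flip sign after a switch time (early down / late up
# adaptation). Signals are linear combinations of latents plus log2
# Gaussian noise; viability is a clipped linear function of late latent
# activity; phenotype counts are Poisson/binomial around that mean.

#' Ground truth for a synthetic study
#'
#' Draws all latent parameters for a configuration: which (signal, time)
#' variables are informative, latent-to-signal loadings, per-drug Hill
#' dose responses with time switch points, the latent-to-viability link,
#' single-cell mixture parameters and the planted synergy excess. The same
#' truth object is consumed by every generator so that all data layers are
#' mutually consistent.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_truth`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "truth"))
  signals <- sprintf("sig%02d", seq_len(config$n_signals))
  cell_lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  doses <- make_dose_grid(config$top_dose, config$dilution_ratio,
                          config$n_doses)

  n_inf <- max(1L, round(config$informative_fraction * config$n_signals))
  informative_signals <- sort(sample.int(config$n_signals, n_inf))

  # loadings: informative signals are driven by exactly one latent each
  loadings <- matrix(0, config$n_latent, config$n_signals,
                     dimnames = list(NULL, signals))
  lat_of_sig <- rep_len(seq_len(config$n_latent), n_inf)
  for (i in seq_len(n_inf)) {
    loadings[lat_of_sig[i], informative_signals[i]] <-
      config$effect_size * sample(c(-1, 1), 1) * runif(1, 0.8, 1.2)
  }

  # per-latent, per-drug Hill parameters over the tested dose range
  lr <- log10(range(doses))
  hill <- vector("list", config$n_latent)
  for (l in seq_len(config$n_latent)) {
    hill[[l]] <- data.table(
      drug = config$drugs,
      ec50 = 10^runif(length(config$drugs), lr[1] + 0.5, lr[2] - 0.5),
      slope = runif(length(config$drugs), 1, 2.5)
    )
  }

  # time profiles: latent 1 ramps up monotonically; even latents flip sign
  # after a switch time (drug-induced down-regulation that later rebounds)
  switch_time <- ifelse(seq_len(config$n_latent) %% 2 == 0,
                        sort(config$times_signal)[
                          min(3L, length(config$times_signal))], NA_real_)

  # cell-line-specific overall responsiveness
  cell_factor <- setNames(runif(config$n_cell_lines, 0.6, 1.4), cell_lines)

  # viability link: positive coefficients, so latent activation kills
  beta <- if (config$effect_size > 0)
    0.45 / config$n_latent * runif(config$n_latent, 0.9, 1.1)
  else rep(0, config$n_latent)

  baseline <- setNames(2^runif(config$n_signals, 8, 12), signals)

  # condition-level biological random effect, shared by all replicates and
  # scanner passes of a condition; independent of the viability latents
  cond_effect <- CJ(cell_line = cell_lines, antibody = signals,
                    drug = c("DMSO", config$drugs),
                    time = config$times_signal, sorted = FALSE)
  cond_effect[, effect := rnorm(.N, 0, config$cond_noise_sd)]

  # scanner gains: per antibody x scanner log2 offsets (cancel in fold change)
  scanner_gain <- matrix(rnorm(config$n_signals * config$n_scanners, 0, 0.2),
                         config$n_signals, config$n_scanners,
                         dimnames = list(signals,
                                         LETTERS[seq_len(config$n_scanners)]))

  markers <- c("p-cJun", "pRb")
  gate_truth <- data.table(
    marker = markers,
    mu_low = c(2.0, 1.5), mu_high = c(5.0, 4.5),
    sd_low = c(0.5, 0.5), sd_high = c(0.5, 0.5),
    w_high_base = c(0.5, 0.6),
    dose_shift = c(1.5, -1.5)  # logit shift per unit late latent activity
  )

  eps <- matrix(0, config$n_doses, config$n_doses)
  mid <- ceiling(config$n_doses / 2)
  eps[mid, mid] <- config$synergy_eps

  tg <- sort(config$times_signal)
  time_profile <- function(l, t) {
    if (is.na(switch_time[l])) 0.4 + 0.6 * t / max(tg)
    else ifelse(t < switch_time[l], -0.6, 1.0)
  }

  # informative variables: (signal, time) pairs with nonzero expected effect
  inf_vars <- character(0)
  if (config$effect_size > 0) {
    for (i in seq_len(n_inf)) {
      l <- lat_of_sig[i]
      tt <- config$times_signal[abs(time_profile(l, config$times_signal)) > 0]
      inf_vars <- c(inf_vars, paste(signals[informative_signals[i]], tt,
                                    sep = "@"))
    }
  }

  truth <- list(
    config = config,
    fingerprint = config_fingerprint(config),
    signals = signals, cell_lines = cell_lines, doses = doses,
    informative_signals = signals[informative_signals],
    informative_variables = inf_vars,
    latent_loadings = loadings,
    latent_hill = hill,
    switch_time = switch_time,
    cell_factor = cell_factor,
    viability_link = beta,
    baseline = baseline,
    cond_effect = cond_effect,
    scanner_gain = scanner_gain,
    gate_truth = gate_truth,
    synergy_truth = list(eps = eps, planted_pair = c(mid, mid))
  )
  class(truth) <- "synthetic_truth"
  truth
}

check_truth <- function(config, truth) {
  if (!inherits(truth, "synthetic_truth") ||
      !identical(truth$fingerprint, config_fingerprint(config)))
    stop("truth object does not match this configuration")
}

hill_activation <- function(dose, ec50, slope) {
  ifelse(dose <= 0, 0, dose^slope / (dose^slope + ec50^slope))
}

latent_time_profile <- function(truth, l, t) {
  tg <- sort(truth$config$times_signal)
  if (is.na(truth$switch_time[l])) 0.4 + 0.6 * t / max(tg)
  else ifelse(t < truth$switch_time[l], -0.6, 1.0)
}

# latent activity for vectors of (drug, dose, time); returns matrix n x n_latent
latent_activity <- function(truth, drug, dose, time) {
  n <- length(drug)
  act <- matrix(0, n, truth$config$n_latent)
  for (l in seq_len(truth$config$n_latent)) {
    h <- truth$latent_hill[[l]]
    ec50 <- h$ec50[match(drug, h$drug)]
    slope <- h$slope[match(drug, h$drug)]
    hv <- hill_activation(dose, ec50, slope)
    hv[is.na(hv)] <- 0  # vehicle-control "drug" not in table
    act[, l] <- hv * latent_time_profile(truth, l, time)
  }
  act
}

#' Noiseless expected log2 fold change of a signal
#'
#' The deterministic part of the generative model: the log2 fold change of
#' `signal` relative to vehicle control for given conditions.
#'
#' @param truth a [make_truth()] object.
#' @param cell_line,drug,dose,time,signal condition coordinates
#'   (vectorized; recycled to common length).
#' @return numeric vector of expected log2 fold changes.
#' @export
true_log2_signal <- function(truth, cell_line, drug, dose, time, signal) {
  n <- max(lengths(list(cell_line, drug, dose, time, signal)))
  cell_line <- rep_len(cell_line, n); drug <- rep_len(drug, n)
  dose <- rep_len(dose, n); time <- rep_len(time, n)
  signal <- rep_len(signal, n)
  act <- latent_activity(truth, drug, dose, time)
  load <- truth$latent_loadings[, signal, drop = FALSE]
  as.numeric(truth$cell_factor[cell_line] * colSums(t(act) * load))
}

#' Ground-truth non-apoptotic viability
#'
#' Expected viability (fraction of vehicle control) under the generative
#' model: 1 minus a time-ramped linear combination of the late latent
#' activities, clipped to `[0.02, 1]`.
#'
#' @inheritParams true_log2_signal
#' @return numeric vector of viabilities in `[0.02, 1]`.
#' @export
true_viability <- function(truth, cell_line, drug, dose, time) {
  n <- max(lengths(list(cell_line, drug, dose, time)))
  cell_line <- rep_len(cell_line, n); drug <- rep_len(drug, n)
  dose <- rep_len(dose, n); time <- rep_len(time, n)
  kill <- numeric(n)
  for (l in seq_len(truth$config$n_latent)) {
    h <- truth$latent_hill[[l]]
    ec50 <- h$ec50[match(drug, h$drug)]
    slope <- h$slope[match(drug, h$drug)]
    hv <- hill_activation(dose, ec50, slope)
    hv[is.na(hv)] <- 0
    kill <- kill + truth$viability_link[l] * hv
  }
  tmax <- max(truth$config$times_pheno)
  v <- 1 - (time / tmax) * truth$cell_factor[cell_line] * kill
  pmin(pmax(v, 0.02), 1)
}

#' Generate a replicate-level synthetic signaling tensor
#'
#' Produces the long-format RPPA-style measurement table: every cell line,
#' drug x dose condition (plus a DMSO vehicle control), signaling time
#' point, antibody, biological x technical replicate and scanner pass.
#' Raw values are `baseline * 2^(mu + noise)` where `mu` is the latent
#' model's log2 fold change; replicate noise is shared between scanner
#' passes of the same physical sample, and each scanner adds an
#' antibody-specific gain plus readout noise.
#'
#' @param config a [sim_config()].
#' @return list with `tensor` (a `data.table` with columns `cell_line`,
#'   `drug`, `dose`, `time`, `antibody`, `bio_rep`, `tech_rep`, `scanner`,
#'   `value`) and `truth` (the [make_truth()] object used).
#' @export
#' @examples
#' sim <- generate_rppa(sim_config(n_cell_lines = 1, seed = 3))
#' nrow(sim$tensor)
generate_rppa <- function(config) {
  truth <- make_truth(config)
  set.seed(stage_seed(config, "rppa"))

  doses <- truth$doses
  cond <- rbind(
    data.table(drug = "DMSO", dose = 0),
    CJ(drug = config$drugs, dose = doses, sorted = FALSE)
  )
  base <- CJ(cell_line = truth$cell_lines,
             cond_id = seq_len(nrow(cond)),
             time = config$times_signal,
             antibody = truth$signals,
             bio_rep = seq_len(config$n_bio_reps),
             tech_rep = seq_len(config$n_tech_reps),
             sorted = FALSE)
  base[, drug := cond$drug[cond_id]]
  base[, dose := cond$dose[cond_id]]
  base[, cond_id := NULL]

  base[, mu := true_log2_signal(truth, cell_line, drug, dose, time, antibody)]
  base <- merge(base, truth$cond_effect,
                by = c("cell_line", "antibody", "drug", "time"),
                all.x = TRUE, sort = FALSE)
  base[, mu := mu + effect]
  base[, effect := NULL]
  base[, rep_noise := rnorm(.N, 0, config$noise_sd)]

  scanners <- LETTERS[seq_len(config$n_scanners)]
  out <- rbindlist(lapply(scanners, function(sc) {
    d <- copy(base)
    d[, scanner := sc]
    d[, value := truth$baseline[antibody] *
        2^(mu + rep_noise + truth$scanner_gain[antibody, sc] +
           rnorm(.N, 0, config$scanner_noise_sd))]
    d
  }))
  out[, c("mu", "rep_noise") := NULL]
  setcolorder(out, c("cell_line", "drug", "dose", "time", "antibody",
                     "bio_rep", "tech_rep", "scanner", "value"))
  setkey(out, cell_line, drug, dose, time, antibody, bio_rep, tech_rep,
         scanner)
  list(tensor = out[], truth = truth)
}

#' Generate synthetic phenotype (viability/apoptosis) counts
#'
#' Per condition, phenotype time point and replicate: `total_cells` is
#' Poisson with mean `n_cells_pheno`, and `apoptotic_cells` is binomial
#' with success probability `1 - true_viability(...)`, so the expected
#' non-apoptotic cell count normalized to vehicle equals the ground-truth
#' viability.
#'
#' @param config a [sim_config()].
#' @param truth the matching [make_truth()] object (as returned by
#'   [generate_rppa()]).
#' @return `data.table` with columns `cell_line`, `drug`, `dose`, `time`,
#'   `replicate`, `total_cells`, `apoptotic_cells`.
#' @export
generate_phenotype <- function(config, truth) {
  check_truth(config, truth)
  set.seed(stage_seed(config, "pheno"))
  cond <- rbind(
    data.table(drug = "DMSO", dose = 0),
    CJ(drug = config$drugs, dose = truth$doses, sorted = FALSE)
  )
  d <- CJ(cell_line = truth$cell_lines,
          cond_id = seq_len(nrow(cond)),
          time = config$times_pheno,
          replicate = seq_len(config$n_bio_reps),
          sorted = FALSE)
  d[, drug := cond$drug[cond_id]]
  d[, dose := cond$dose[cond_id]]
  d[, cond_id := NULL]
  d[, total_cells := rpois(.N, config$n_cells_pheno)]
  d[, p_apop := 1 - true_viability(truth, cell_line, drug, dose, time)]
  d[, apoptotic_cells := rbinom(.N, total_cells, p_apop)]
  d[, p_apop := NULL]
  setcolorder(d, c("cell_line", "drug", "dose", "time", "replicate",
                   "total_cells", "apoptotic_cells"))
  setkey(d, cell_line, drug, dose, time, replicate)
  d[]
}

#' Ground-truth High-subpopulation fraction for a single-cell marker
#'
#' @inheritParams true_log2_signal
#' @param marker marker label present in `truth$gate_truth`.
#' @return mixing weight of the High component per condition.
#' @export
true_high_fraction <- function(truth, marker, cell_line, drug, dose, time) {
  mi <- match(marker, truth$gate_truth$marker)
  if (anyNA(mi)) stop("unknown marker: ", marker)
  gt <- truth$gate_truth[mi]
  act <- latent_activity(truth, drug, dose, rep_len(time, length(drug)))
  late <- rowSums(abs(act))
  plogis(qlogis(gt$w_high_base) +
           gt$dose_shift * truth$cell_factor[cell_line] * late)
}

#' Generate synthetic single-cell marker intensities
#'
#' Per condition and marker, cells are drawn from a two-component
#' log-normal mixture; the High-component weight shifts with dose through
#' the latent activities ([true_high_fraction()]). Both markers are drawn
#' independently for the same cells.
#'
#' @inheritParams generate_phenotype
#' @param time single measurement time in hours (default 24).
#' @return `data.table` with columns `cell_line`, `condition`, `drug`,
#'   `dose`, `cell_id`, `marker`, `intensity` (raw scale), `component`
#'   (ground-truth Low/High label).
#' @export
generate_single_cell <- function(config, truth, time = 24) {
  check_truth(config, truth)
  set.seed(stage_seed(config, "sc"))
  cond <- rbind(
    data.table(drug = "DMSO", dose = 0),
    CJ(drug = config$drugs, dose = truth$doses, sorted = FALSE)
  )
  n <- config$n_cells_sc
  out <- vector("list", nrow(cond) * config$n_cell_lines *
                  nrow(truth$gate_truth))
  k <- 0L
  for (cl in truth$cell_lines) {
    for (i in seq_len(nrow(cond))) {
      for (m in truth$gate_truth$marker) {
        gt <- truth$gate_truth[marker == m]
        w <- true_high_fraction(truth, m, cl, cond$drug[i], cond$dose[i],
                                time)
        hi <- runif(n) < w
        logI <- ifelse(hi, rnorm(n, gt$mu_high, gt$sd_high),
                       rnorm(n, gt$mu_low, gt$sd_low))
        k <- k + 1L
        out[[k]] <- data.table(
          cell_line = cl,
          condition = paste0(cond$drug[i], "@", signif(cond$dose[i], 4)),
          drug = cond$drug[i], dose = cond$dose[i],
          cell_id = seq_len(n), marker = m,
          intensity = 2^logI,
          component = ifelse(hi, "High", "Low"))
      }
    }
  }
  rbindlist(out)
}

#' Generate a synthetic drug-combination activity grid
#'
#' Single-agent activities (apoptotic fractions at 72 h) come from the
#' ground-truth viability curves; the observed combination activity is the
#' Bliss-independence prediction plus the planted excess
#' `truth$synergy_truth$eps`, clipped to `[0, 1]`.
#'
#' @inheritParams generate_phenotype
#' @param drug_x,drug_y the two combined drugs (defaults: first two in the
#'   configuration).
#' @param time phenotype time in hours used for activity (default 72).
#' @return `data.table` with columns `dose_x`, `dose_y`, `i_x`, `i_y`,
#'   `i_obs` over the full factorial dose grid.
#' @export
generate_synergy <- function(config, truth,
                             drug_x = config$drugs[1],
                             drug_y = config$drugs[2],
                             cell_line = truth$cell_lines[1],
                             time = 72) {
  check_truth(config, truth)
  set.seed(stage_seed(config, "synergy"))
  doses <- truth$doses
  a_x <- 1 - true_viability(truth, cell_line, drug_x, doses, time)
  a_y <- 1 - true_viability(truth, cell_line, drug_y, doses, time)
  g <- CJ(ix = seq_along(doses), iy = seq_along(doses), sorted = FALSE)
  g[, dose_x := doses[ix]]
  g[, dose_y := doses[iy]]
  g[, i_x := a_x[ix]]
  g[, i_y := a_y[iy]]
  g[, i_obs := pmin(pmax(bliss_predict(i_x, i_y) +
                           truth$synergy_truth$eps[cbind(ix, iy)], 0), 1)]
  g[, c("ix", "iy") := NULL]
  g[]
}
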