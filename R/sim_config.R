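#' Simulation configuration for the synthetic study design
#'
#' Builds the configuration object consumed by all synthetic-data
#' generators. Defaults emulate the multiplexed perturbation design the
#' analysis assumes: 10 cell lines treated with 5 RAF/MEK inhibitors at 7
#' doses (1:3.16 dilution from 3.2 uM), 21 (phospho)protein signals read at
#' 1, 5, 10, 24 and 48 h in 4 biological x 2 technical replicates on two
#' scanners, and viability/apoptosis phenotypes scored at 24, 48 and 72 h.
#'
#' @param n_cell_lines number of cell lines.
#' @param drugs character vector of drug labels.
#' @param n_doses number of doses per drug (>= 2).
#' @param top_dose highest dose, uM.
#' @param dilution_ratio serial dilution ratio (> 1).
#' @param times_signal hours at which signaling is measured.
#' @param times_pheno hours at which phenotypes are scored.
#' @param n_signals number of antibodies / signals.
#' @param n_bio_reps,n_tech_reps biological and technical replicates.
#' @param n_scanners number of independent scanner/analysis passes.
#' @param n_latent number of latent adaptive pathway activities.
#' @param informative_fraction fraction of signals coupled to the latent
#'   pathways (and hence to viability).
#' @param noise_sd replicate-level measurement noise sd on the log2 scale.
#' @param cond_noise_sd sd of the condition-level (antibody x drug x time)
#'   biological random effect shared by all replicates of a condition;
#'   this is what makes replicate profiles of viability-unrelated
#'   antibodies reproducible, as they are on real arrays.
#' @param scanner_noise_sd additional per-scanner readout noise sd (log2).
#' @param effect_size latent-to-signal coupling amplitude on the log2
#'   scale; 0 decouples signals and viability from the latents entirely.
#' @param synergy_eps planted excess-over-Bliss at one dose pair of the
#'   combination grid.
#' @param n_cells_pheno expected cells per well in phenotype assays.
#' @param n_cells_sc cells per condition in single-cell tables.
#' @param seed master seed; per-generator streams are split from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_cell_lines = 1, seed = 7)
#' cfg$n_doses
sim_config <- function(n_cell_lines = 10,
                       drugs = c("vemurafenib", "PLX4720", "SB590885",
                                 "selumetinib", "AZ628"),
                       n_doses = 7,
                       top_dose = 3.2,
                       dilution_ratio = 3.16,
                       times_signal = c(1, 5, 10, 24, 48),
                       times_pheno = c(24, 48, 72),
                       n_signals = 21,
                       n_bio_reps = 4,
                       n_tech_reps = 2,
                       n_scanners = 2,
                       n_latent = 2,
                       informative_fraction = 0.3,
                       noise_sd = 0.15,
                       cond_noise_sd = 0.3,
                       scanner_noise_sd = 0.05,
                       effect_size = 1,
                       synergy_eps = 0.1,
                       n_cells_pheno = 2000,
                       n_cells_sc = 1000,
                       seed = 1L) {
  cfg <- list(
    n_cell_lines = as.integer(n_cell_lines), drugs = as.character(drugs),
    n_doses = as.integer(n_doses), top_dose = top_dose,
    dilution_ratio = dilution_ratio, times_signal = times_signal,
    times_pheno = times_pheno, n_signals = as.integer(n_signals),
    n_bio_reps = as.integer(n_bio_reps), n_tech_reps = as.integer(n_tech_reps),
    n_scanners = as.integer(n_scanners), n_latent = as.integer(n_latent),
    informative_fraction = informative_fraction, noise_sd = noise_sd,
    cond_noise_sd = cond_noise_sd,
    scanner_noise_sd = scanner_noise_sd, effect_size = effect_size,
    synergy_eps = synergy_eps, n_cells_pheno = n_cells_pheno,
    n_cells_sc = n_cells_sc, seed = as.integer(seed)
  )
  counts <- c(cfg$n_cell_lines, cfg$n_doses, cfg$n_signals, cfg$n_bio_reps,
              cfg$n_tech_reps, cfg$n_scanners, cfg$n_latent)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (cfg$n_doses < 2L) stop("n_doses must be >= 2")
  if (cfg$dilution_ratio <= 1) stop("dilution_ratio must be > 1")
  if (cfg$top_dose <= 0) stop("top_dose must be positive")
  if (cfg$noise_sd < 0 || cfg$scanner_noise_sd < 0 || cfg$cond_noise_sd < 0)
    stop("noise sds must be >= 0")
  if (cfg$informative_fraction < 0 || cfg$informative_fraction > 1)
    stop("informative_fraction must be in [0, 1]")
  if (length(cfg$drugs) < 1L || anyDuplicated(cfg$drugs))
    stop("drugs must be a non-empty set of distinct labels")
  if (any(diff(make_dose_grid(cfg$top_dose, cfg$dilution_ratio,
                              cfg$n_doses)) >= 0))
    stop("dose grid must be strictly decreasing")
  class(cfg) <- "sim_config"
  cfg
}

#' Serial dose-dilution grid
#'
#' Doses are a geometric series starting at `top_dose` and divided by
#' `ratio` at each step, the way multi-dose drug-response plates are laid
#' out (e.g. seven 1:3.16 dilutions span 3.2 uM down to 3.2 nM).
#'
#' @param top_dose highest dose (any positive concentration unit).
#' @param ratio dilution ratio, > 1.
#' @param n number of doses, >= 1.
#' @return numeric vector of length `n`, strictly decreasing:
#'   `top_dose / ratio^(0:(n-1))`.
#' @export
#' @examples
#' make_dose_grid(3.2, 3.16, 7)  # bottoms out near 0.0032 uM = 3.2 nM
make_dose_grid <- function(top_dose, ratio, n) {
  if (top_dose <= 0) stop("top_dose must be positive")
  if (ratio <= 1) stop("ratio must be > 1")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  top_dose / ratio^(seq_len(n) - 1)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cell_lines, "cell lines x", length(x$drugs),
      "drugs x", x$n_doses, "doses;", x$n_signals, "signals x",
      length(x$times_signal), "time points;",
      x$n_bio_reps, "x", x$n_tech_reps, "replicates; seed", x$seed, "\n")
  invisible(x)
}

# deterministic per-stage seed split from the master seed (kept < 2^31)
stage_seed <- function(config, stage) {
  offsets <- c(truth = 101L, rppa = 211L, pheno = 307L, sc = 401L,
               synergy = 503L)
  (config$seed %% 2000000000L) + offsets[[stage]]
}

config_fingerprint <- function(config) {
  paste(vapply(config[order(names(config))], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";")
}
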