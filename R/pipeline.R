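# End-to-end orchestration: simulate -> preprocess -> respond -> fit ->
# VIP -> cluster -> synergy -> gate, writing plain-text artifacts and a
# run manifest with content digests.

#' Serialize / read a PLSR model as structured text (JSON)
#'
#' @param model a [fit_plsr()] model.
#' @param path output file path.
#' @return `path`, invisibly (writer); a `plsr_model` (reader).
#' @export
write_plsr_model <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  obj <- lapply(model, function(v) if (is.matrix(v)) unclass(v) else v)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_plsr_model
#' @export
read_plsr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "P", "T")) obj[[nm]] <- as.matrix(obj[[nm]])
  structure(obj, class = "plsr_model")
}

digest_files <- function(paths) {
  md5 <- tools::md5sum(paths)
  data.table(file = basename(names(md5)), md5 = unname(md5))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a synthetic study from `config`, then runs every analysis
#' stage: replicate-level preprocessing (per scanner), design matrix and
#' response assembly per cell line, PLSR fitting with tenfold
#' cross-validation, signed VIP profiles with dual-scanner consistency
#' merging, hierarchical clustering of cell lines, excess-over-Bliss
#' synergy mapping, and vehicle-anchored single-cell gating. All outputs
#' are plain-text CSV/JSON under `out_dir`, and a manifest with content
#' digests, per-stage seeds, filter counts and timings is written last.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @param n_components PLSR components per cell-line model (default 3).
#' @param cv_folds cross-validation folds (default 10).
#' @param exclude_signals signals removed before clustering (direct
#'   drug-target readouts; default the first two informative signals are
#'   kept, i.e. nothing is excluded unless requested).
#' @param qc_threshold antibody reproducibility threshold (default 0.5).
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, n_components = 3, cv_folds = 10,
                         exclude_signals = character(0),
                         qc_threshold = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  files <- character(0)
  log <- list()
  tick <- function(stage, start) as.numeric(Sys.time() - start, units = "secs")

  put <- function(obj, name) {
    p <- file.path(out_dir, name)
    fwrite(obj, p)
    files <<- c(files, p)
    p
  }

  # -- simulate ------------------------------------------------------------
  st <- Sys.time()
  sim <- generate_rppa(config)
  tensor <- sim$tensor; truth <- sim$truth
  pheno <- generate_phenotype(config, truth)
  cells <- generate_single_cell(config, truth)
  syn_raw <- generate_synergy(config, truth)
  put(tensor, "rppa.csv"); put(pheno, "phenotype.csv")
  put(cells, "single_cell.csv")
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(informative_variables = truth$informative_variables,
         latent_loadings = unclass(truth$latent_loadings),
         viability_link = truth$viability_link,
         switch_time = truth$switch_time,
         doses = truth$doses,
         synergy_eps = unclass(truth$synergy_truth$eps),
         gate_truth = truth$gate_truth),
    truth_path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  files <- c(files, truth_path)
  timings$simulate <- tick("simulate", st)

  scanners <- sort(unique(tensor$scanner))
  cls <- truth$cell_lines
  profiles <- list()
  metrics <- list()
  filter_log <- list()

  st <- Sys.time()
  viab <- nonapoptotic_viability(pheno)
  put(viab, "viability.csv")
  timings$respond <- tick("respond", st)

  st <- Sys.time()
  for (cl in cls) {
    qc <- antibody_qc(tensor, cl, threshold = qc_threshold,
                      scanner = scanners[1])
    fc_by_scanner <- lapply(scanners, function(sc)
      collapse_log2fc(tensor[tensor$cell_line == cl], antibodies = qc$retained,
                      scanner = sc))
    designs <- lapply(fc_by_scanner, assemble_design, cell_line = cl)
    resp <- assemble_response(viab, cell_line = cl)
    put(data.table(condition = names(resp$y), viability = resp$y),
        paste0("response_", cl, ".csv"))
    put(data.table(condition = rownames(designs[[1]]$X), designs[[1]]$X),
        paste0("design_", cl, ".csv"))
    put(data.table(variable = colnames(designs[[1]]$X),
                   mean = designs[[1]]$column_means,
                   sd = designs[[1]]$column_sds,
                   zero_variance = designs[[1]]$zero_variance),
        paste0("design_scaling_", cl, ".csv"))

    prof_by_scanner <- list()
    cv <- NULL
    for (i in seq_along(scanners)) {
      model <- fit_plsr(designs[[i]], resp, n_components)
      if (i == 1L) {
        cv <- cross_validate(designs[[i]]$X, resp$y, n_components,
                             n_folds = cv_folds, seed = config$seed + 7L)
        write_plsr_model(model, file.path(out_dir,
                                          paste0("model_", cl, ".json")))
        files <- c(files, file.path(out_dir, paste0("model_", cl, ".json")))
      }
      vip <- compute_vip(model)
      prof_by_scanner[[i]] <- sign_and_threshold(vip, designs[[i]], resp)
    }
    if (length(scanners) >= 2L) {
      mask <- consistency_mask(fc_by_scanner[[1]], fc_by_scanner[[2]])
      merged <- merge_consistent_vip(prof_by_scanner[[1]],
                                     prof_by_scanner[[2]], mask)
      profiles[[cl]] <- merged$profile
      filter_log[[cl]] <- list(
        antibodies_dropped = length(qc$dropped),
        mask_fraction_kept = mask$fraction_kept,
        vip_sign_conflicts = merged$n_sign_conflict,
        vip_fraction_kept = merged$fraction_kept)
    } else {
      profiles[[cl]] <- prof_by_scanner[[1]]
      filter_log[[cl]] <- list(antibodies_dropped = length(qc$dropped))
    }
    put(profiles[[cl]], paste0("vip_", cl, ".csv"))
    metrics[[cl]] <- data.table(cell_line = cl, r2 = cv$r2, q2 = cv$q2,
                                mspe_percent = cv$mspe_percent,
                                n_components = cv$n_components)
  }
  put(rbindlist(metrics), "model_metrics.csv")
  timings$model <- tick("model", st)

  # -- cluster -------------------------------------------------------------
  st <- Sys.time()
  if (length(profiles) >= 2L) {
    common <- Reduce(intersect, lapply(profiles, function(p) p$variable))
    mats <- do.call(rbind, lapply(profiles, function(p)
      p$signed_vip[match(common, p$variable)]))
    rownames(mats) <- names(profiles); colnames(mats) <- common
    clu <- cluster_cell_lines(mats, exclude = exclude_signals)
    writeLines(clu$newick, file.path(out_dir, "dendrogram.nwk"))
    files <- c(files, file.path(out_dir, "dendrogram.nwk"))
    put(data.table(step = seq_len(nrow(clu$hclust$merge)),
                   left = clu$hclust$merge[, 1],
                   right = clu$hclust$merge[, 2],
                   height = clu$hclust$height), "cluster_merges.csv")
  }
  timings$cluster <- tick("cluster", st)

  # -- synergy -------------------------------------------------------------
  st <- Sys.time()
  put(eobi_grid(syn_raw), "synergy_eobi.csv")
  timings$synergy <- tick("synergy", st)

  # -- gate ----------------------------------------------------------------
  st <- Sys.time()
  gate_rows <- list()
  for (cl in cls) {
    cl_cells <- cells[cells$cell_line == cl]
    ctrl <- cl_cells[cl_cells$dose == 0]
    thr <- vapply(truth$gate_truth$marker, function(m)
      fit_gate(log2(ctrl$intensity[ctrl$marker == m]))$threshold,
      numeric(1))
    for (cond in unique(cl_cells$condition)) {
      gr <- quadrant_fractions(cl_cells[cl_cells$condition == cond], thr)
      gate_rows[[paste(cl, cond)]] <- data.table(
        cell_line = cl, condition = cond,
        quadrant = names(gr$fractions),
        fraction = as.numeric(gr$fractions), n_cells = gr$n_cells)
    }
  }
  put(rbindlist(gate_rows), "gates.csv")
  timings$gate <- tick("gate", st)

  manifest <- list(
    package_version = as.character(utils::packageVersion("adaptsig")),
    config = unclass(config),
    stage_seeds = lapply(
      setNames(nm = c("truth", "rppa", "pheno", "sc", "synergy")),
      function(s) stage_seed(config, s)),
    filters = filter_log,
    timings_sec = lapply(timings, round, 3),
    total_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 3),
    outputs = digest_files(sort(unique(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
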