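# Shared fixtures: small single-cell-line configurations so generator +
# preprocessing stay fast inside tests.

library(data.table)

small_config <- function(seed = 1, ...) {
  sim_config(n_cell_lines = 1, n_cells_sc = 400, seed = seed, ...)
}

# noiseless configuration: deterministic signal layer
clean_config <- function(seed = 1, ...) {
  small_config(seed = seed, noise_sd = 0, cond_noise_sd = 0,
               scanner_noise_sd = 0, ...)
}

# full single-line preprocessing: tensor -> design + response
prep_one <- function(cfg, scanner = "A") {
  sim <- generate_rppa(cfg)
  fc <- collapse_log2fc(sim$tensor, scanner = scanner)
  des <- assemble_design(fc, cell_line = "CL01")
  viab <- nonapoptotic_viability(generate_phenotype(cfg, sim$truth))
  resp <- assemble_response(viab, cell_line = "CL01")
  list(sim = sim, fc = fc, design = des, viab = viab, resp = resp)
}
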