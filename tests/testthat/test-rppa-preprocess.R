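test_that("IQR filter drops fence-crossing values and is idempotent", {
  expect_equal(iqr_outlier_filter(rep(5, 8)), rep(5, 8))
  # hand oracle (type-7 quantiles): Q1 = 2, Q3 = 3.25, upper fence 5.125
  x <- c(1, 2, 2, 3, 3, 3, 4, 10)
  expect_equal(iqr_outlier_filter(x), c(1, 2, 2, 3, 3, 3, 4))
  expect_equal(iqr_outlier_filter(42), 42)
  expect_error(iqr_outlier_filter(numeric(0)), "empty")
  # structural properties over random replicate sets: output is an
  # order-preserving subset, always contains the median, and consists of
  # exactly the values inside the fences of the original sample
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(8) + sample(c(0, 10), 8, TRUE, prob = c(0.9, 0.1))
    kept <- iqr_outlier_filter(x)
    expect_true(all(kept %in% x))
    expect_true(median(x) >= min(kept) && median(x) <= max(kept))
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    inside <- x >= q[1] - 1.5 * diff(q) & x <= q[2] + 1.5 * diff(q)
    expect_identical(kept, x[inside])
  }
})

test_that("antibody QC keeps reproducible antibodies and drops noise", {
  cfg <- small_config(seed = 3)
  sim <- generate_rppa(cfg)
  qc <- antibody_qc(sim$tensor, "CL01")
  expect_setequal(qc$retained, sim$truth$signals)

  # replace one antibody's values by independent noise across replicates
  tensor <- copy(sim$tensor)
  idx <- tensor$antibody == "sig01"
  set.seed(1)
  tensor$value[idx] <- 2^rnorm(sum(idx), 10, 1)
  qc2 <- antibody_qc(tensor, "CL01")
  expect_true("sig01" %in% qc2$dropped)
  expect_false("sig02" %in% qc2$dropped)

  # threshold 1.0 with any noise drops everything measurable
  qc3 <- antibody_qc(tensor, "CL01", threshold = 1 + 1e-12)
  expect_length(qc3$retained, 0)

  # identical replicates correlate perfectly and are all retained
  cfg0 <- clean_config(seed = 3)
  sim0 <- generate_rppa(cfg0)
  qc0 <- antibody_qc(sim0$tensor, "CL01")
  expect_true(all(abs(qc0$scores$correlation - 1) < 1e-12))
})

test_that("log2 fold-change collapse is exact against the generative truth", {
  cfg <- clean_config(seed = 5)
  sim <- generate_rppa(cfg)
  fc <- collapse_log2fc(sim$tensor, scanner = "A")
  treated <- fc[fc$dose > 0]
  mu <- true_log2_signal(sim$truth, treated$cell_line, treated$drug,
                         treated$dose, treated$time, treated$antibody)
  expect_equal(treated$log2fc, mu, tolerance = 1e-12)
  expect_true(all(fc$log2fc[fc$dose == 0] == 0))
})

test_that("collapse handles simple ratio arithmetic and missing controls", {
  mk <- function(dose, value) data.table::data.table(
    cell_line = "A", drug = ifelse(dose == 0, "DMSO", "d"), dose = dose,
    time = 24, antibody = "ab", bio_rep = rep(1:2, each = 2),
    tech_rep = rep(1:2, 2), scanner = "A", value = value)
  t1 <- rbind(mk(0, rep(100, 4)), mk(1, rep(400, 4)))
  expect_equal(collapse_log2fc(t1)[dose == 1]$log2fc, 2)
  t2 <- rbind(mk(0, rep(100, 4)), mk(1, rep(100, 4)))
  expect_equal(collapse_log2fc(t2)[dose == 1]$log2fc, 0)
  expect_error(collapse_log2fc(mk(1, rep(100, 4))), "control")
})

test_that("design assembly yields 35 x 105 with exact autoscaling", {
  cfg <- small_config(seed = 1)
  pr <- prep_one(cfg)
  X <- pr$design$X
  expect_equal(dim(X), c(35, 105))
  keep <- !pr$design$zero_variance
  expect_true(all(abs(colMeans(X[, keep])) < 1e-9))
  expect_true(all(abs(apply(X[, keep], 2, sd) - 1) < 1e-9))
  # rows ordered by drug then descending dose
  expect_equal(pr$design$conditions$dose[1:7],
               sort(unique(pr$design$conditions$dose), decreasing = TRUE))
  # round trip through stored scaling reproduces the fold changes
  expect_equal(unscale_design(pr$design), pr$design$fold_change,
               tolerance = 1e-12)
})

test_that("zero-variance columns are flagged and zeroed, not divided", {
  cfg <- small_config(seed = 2)
  pr <- prep_one(cfg)
  fc <- copy(pr$fc)
  fc[fc$antibody == "sig03", "log2fc"] <- 0.7
  des <- assemble_design(fc, cell_line = "CL01")
  zcols <- grepl("^sig03@", colnames(des$X))
  expect_true(all(des$zero_variance[zcols]))
  expect_true(all(des$X[, zcols] == 0))
})

test_that("missing design cells error unless imputation is requested", {
  cfg <- small_config(seed = 2)
  pr <- prep_one(cfg)
  fc <- pr$fc[!(pr$fc$antibody == "sig05" & pr$fc$time == 24 &
                  pr$fc$drug == cfg$drugs[1] & pr$fc$dose > 0.1)]
  expect_error(assemble_design(fc, cell_line = "CL01"), "missing")
  des <- assemble_design(fc, cell_line = "CL01", impute = TRUE)
  expect_false(anyNA(des$X))
})

test_that("QC filters commute with restriction to a cell-line subset", {
  cfg <- sim_config(n_cell_lines = 3, n_cells_sc = 100, seed = 13)
  sim <- generate_rppa(cfg)
  sub <- sim$tensor[sim$tensor$cell_line == "CL02"]
  full_qc <- antibody_qc(sim$tensor, "CL02")
  sub_qc <- antibody_qc(sub, "CL02")
  expect_identical(full_qc$retained, sub_qc$retained)
  fc_full <- collapse_log2fc(sim$tensor, scanner = "A")
  fc_sub <- collapse_log2fc(sub, scanner = "A")
  expect_equal(fc_full[fc_full$cell_line == "CL02"]$log2fc, fc_sub$log2fc)
})

test_that("consistency mask keeps sign-concordant variables", {
  cfg <- small_config(seed = 8)
  pr <- prep_one(cfg)
  m_same <- consistency_mask(pr$fc, pr$fc)
  expect_equal(m_same$fraction_kept, 1)
  flipped <- copy(pr$fc)
  flipped[, log2fc := -log2fc]
  m_anti <- consistency_mask(pr$fc, flipped)
  # variables with nonzero condition-mean fold change must all drop
  expect_equal(sum(m_anti$mask$kept), 0)
  # two scanner passes of the same biology agree almost everywhere
  fc_b <- collapse_log2fc(pr$sim$tensor, scanner = "B")
  m_ab <- consistency_mask(pr$fc, fc_b)
  expect_gte(m_ab$fraction_kept, 0.95)
  expect_error(consistency_mask(pr$fc, pr$fc[pr$fc$dose > 0.1]), "keys")
})
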