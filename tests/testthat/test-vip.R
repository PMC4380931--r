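# standalone VIP oracle evaluated from serialized weights and SS only
vip_oracle <- function(W, ss) {
  K <- nrow(W)
  sapply(seq_len(K), function(k)
    sqrt(K * sum(W[k, ]^2 * ss) / sum(ss)))
}

test_that("VIP formula collapses correctly in analytic cases", {
  # one component, all weight on one variable
  m1 <- structure(list(W = matrix(c(1, 0, 0), 3, 1), ss = 2,
                       variables = c("a", "b", "c")),
                  class = "plsr_model")
  expect_equal(unname(compute_vip(m1)), c(sqrt(3), 0, 0))
  # uniform squared weights give VIP = 1 everywhere, for any SS profile
  W <- matrix(1 / sqrt(4), 4, 3)
  m2 <- structure(list(W = W, ss = c(5, 1, 0.2),
                       variables = letters[1:4]), class = "plsr_model")
  expect_equal(unname(compute_vip(m2)), rep(1, 4))
  m0 <- structure(list(W = W, ss = c(0, 0, 0), variables = letters[1:4]),
                  class = "plsr_model")
  expect_error(compute_vip(m0), "explains nothing")
})

test_that("VIP matches the standalone oracle and sums to K on real fits", {
  cfg <- small_config(seed = 17)
  pr <- prep_one(cfg)
  m <- fit_plsr(pr$design, pr$resp, 3)
  vip <- compute_vip(m)
  expect_equal(sum(vip^2), 105, tolerance = 1e-6)
  # round trip through the serialized model, then the independent formula
  path <- tempfile(fileext = ".json")
  write_plsr_model(m, path)
  m2 <- read_plsr_model(path)
  expect_equal(unname(vip), vip_oracle(m2$W, m2$ss), tolerance = 1e-10)
})

test_that("signs follow response correlation and (0,1] scores are zeroed", {
  set.seed(3)
  y <- rnorm(30)
  X <- cbind(a = -y + rnorm(30, 0, 1e-6), b = y, c = rnorm(30))
  vip <- c(a = 2, b = 0.99, c = 1.0)
  prof <- sign_and_threshold(vip, X, y)
  expect_equal(prof$signed_vip[prof$variable == "a"], -2)   # anti-correlated
  expect_equal(prof$signed_vip[prof$variable == "b"], 0)    # vip < 1
  expect_equal(prof$signed_vip[prof$variable == "c"], 0)    # boundary 1.0
  expect_true(all(prof$vip >= 0))
  # zero-variance column gets + sign by convention
  X2 <- cbind(X, d = rep(1, 30))
  prof2 <- sign_and_threshold(c(vip, d = 1.5), X2, y)
  expect_equal(prof2$sign[prof2$variable == "d"], 1)
})

test_that("planted negative couplings receive negative signs", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    cfg <- small_config(seed = 300 + s, informative_fraction = 2 / 21,
                        noise_sd = 0.2)
    pr <- prep_one(cfg)
    m <- fit_plsr(pr$design, pr$resp, 3)
    prof <- sign_and_threshold(compute_vip(m), pr$design, pr$resp)
    tr <- pr$sim$truth
    for (v in tr$informative_variables) {
      sig <- sub("@.*", "", v); tt <- as.numeric(sub(".*@", "", v))
      l <- which(tr$latent_loadings[, sig] != 0)
      g <- if (is.na(tr$switch_time[l])) 0.4 + 0.6 * tt / 48
           else if (tt < tr$switch_time[l]) -0.6 else 1
      # viability drops as latent rises, so X ~ +loading*g implies
      # anti-correlation with y: expected sign = -sign(loading * g)
      expected <- -sign(tr$latent_loadings[l, sig] * g)
      got <- prof$sign[prof$variable == v]
      total <- total + 1
      if (got == expected) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("top VIP variables are the planted informative ones", {
  overlaps <- vapply(1:20, function(s) {
    cfg <- small_config(seed = 400 + s, informative_fraction = 2 / 21,
                        noise_sd = 0.2, effect_size = 1)
    pr <- prep_one(cfg)
    m <- fit_plsr(pr$design, pr$resp, 3)
    vip <- compute_vip(m)
    top10 <- names(sort(vip, decreasing = TRUE))[1:10]
    length(intersect(top10, pr$sim$truth$informative_variables))
  }, numeric(1))
  expect_gte(mean(overlaps), 8)
})

test_that("consistency merging averages concordant scores, drops conflicts", {
  prof <- function(sv) {
    p <- data.table::data.table(
      variable = paste0("v", seq_along(sv)), vip = abs(sv),
      sign = ifelse(sv < 0, -1, 1), signed_vip = sv, kept = TRUE)
    data.table::setattr(p, "class", c("vip_profile", class(p)))
    p
  }
  a <- prof(c(2, -1.5, 1.2, 0))
  same <- merge_consistent_vip(a, a)
  expect_equal(same$profile$signed_vip, a$signed_vip)
  expect_equal(same$fraction_kept, 1)
  # one sign conflict: dropped and counted
  b <- prof(c(2, 1.5, 1.2, 0))
  mg <- merge_consistent_vip(a, b)
  expect_equal(mg$n_sign_conflict, 1)
  expect_false("v2" %in% mg$profile$variable)
  # averaging arithmetic under small perturbation
  eps <- c(0.1, -0.1, 0.05, 0)
  d <- prof(c(2, -1.5, 1.2, 0) + eps)
  mg2 <- merge_consistent_vip(a, d)
  expect_equal(mg2$profile$signed_vip, a$signed_vip + eps / 2,
               tolerance = 1e-12)
  # mask-based removal
  mask <- data.table::data.table(variable = paste0("v", 1:4),
                                 kept = c(TRUE, FALSE, TRUE, TRUE))
  mg3 <- merge_consistent_vip(a, a, mask)
  expect_equal(mg3$n_masked, 1)
  expect_false("v2" %in% mg3$profile$variable)
})

# naive O(n^3) average-linkage agglomeration as an independent oracle
naive_avg_linkage_cophenetic <- function(M) {
  n <- nrow(M)
  D <- as.matrix(dist(M))
  groups <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(groups) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      d <- mean(D[groups[[i]], groups[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[groups[[i]], groups[[j]]] <- best[1]
    coph[groups[[j]], groups[[i]]] <- best[1]
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups[[j]] <- NULL
  }
  coph
}

test_that("clustering matches brute-force average-linkage agglomeration", {
  set.seed(19)
  M <- matrix(rnorm(7 * 12), 7, 12,
              dimnames = list(paste0("CL", 1:7), NULL))
  cl <- cluster_cell_lines(M)
  got <- as.matrix(cophenetic(cl$hclust))[paste0("CL", 1:7),
                                          paste0("CL", 1:7)]
  want <- naive_avg_linkage_cophenetic(M)
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("clustering obeys nearest-pair merging and exclusions", {
  M <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  cl <- cluster_cell_lines(M)
  expect_equal(cl$hclust$height[1], 1)      # a-b merge first at distance 1
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  # identical profiles merge at height zero
  M2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 5))
  expect_equal(cluster_cell_lines(M2)$hclust$height[1], 0)
  # excluded signals are removed by prefix before distances
  M3 <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("x", "y", "z"),
                               c("pERK@1", "pERK@24", "pJNK@1", "pJNK@24")))
  cl3 <- cluster_cell_lines(M3, exclude = "pERK")
  expect_equal(ncol(cl3$matrix), 2)
  expect_match(cl3$newick, "x|y|z")
})
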