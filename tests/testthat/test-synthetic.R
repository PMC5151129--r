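test_that("generator hits planted Spearman targets and leaves background flat", {
  cfg <- synth_config(n_controls = 2000, n_cases = 2000, n_molecules = 10,
                      differential_pairs = data.frame(i = 1L, j = 2L,
                                                      rho1 = 0.9, rho2 = -0.2),
                      mean_shift_molecules = data.frame(molecule = integer(),
                                                        effect = numeric()),
                      seed = 11)
  sim <- simulate_expression(cfg)
  v <- sim$data$values
  ctl <- v[sim$data$class == "control", ]
  cas <- v[sim$data$class == "case", ]
  # planted pair: sample Spearman within Monte-Carlo tolerance of target
  expect_equal(cor(ctl[, 1], ctl[, 2], method = "spearman"), 0.9,
               tolerance = 0.03 / 0.9)
  expect_equal(cor(cas[, 1], cas[, 2], method = "spearman"), -0.2,
               tolerance = 0.03 / 0.2)
  # non-planted pairs stay near zero on average
  S <- cor(ctl, method = "spearman")
  off <- abs(S[upper.tri(S)])
  off <- off[-1]  # drop the planted (1,2) entry, first in upper.tri order
  expect_lt(mean(off), 0.05)
})

test_that("identical config and seed reproduce the draw exactly", {
  cfg <- synth_config(n_molecules = 8, seed = 99)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$data$values, s2$data$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_expression(cfg, seed = 100)
  expect_false(identical(s1$data$values, s3$data$values))
})

test_that("mean shifts are applied to the case class only", {
  cfg <- synth_config(n_controls = 500, n_cases = 500, n_molecules = 6,
                      differential_pairs = data.frame(i = integer(), j = integer(),
                                                      rho1 = numeric(), rho2 = numeric()),
                      mean_shift_molecules = data.frame(molecule = 3L, effect = 1.5),
                      marginal_mean = 0, marginal_sd = 2, seed = 12)
  sim <- simulate_expression(cfg)
  ctl <- sim$data$values[sim$data$class == "control", ]
  cas <- sim$data$values[sim$data$class == "case", ]
  # shifted molecule: case mean ~ effect * sd; others ~ 0
  expect_equal(mean(cas[, 3]) - mean(ctl[, 3]), 1.5 * 2, tolerance = 0.15)
  expect_lt(max(abs(colMeans(cas[, -3]) - colMeans(ctl[, -3]))), 0.4)
})

test_that("config validation rejects degenerate designs", {
  expect_error(synth_config(n_controls = 2), "at least 3")
  expect_error(synth_config(differential_pairs = data.frame(
    i = 1L, j = 1L, rho1 = 0.5, rho2 = 0)), "distinct molecules")
  expect_error(synth_config(differential_pairs = data.frame(
    i = 1L, j = 2L, rho1 = 1.5, rho2 = 0)), "\\[-1, 1\\]")
})

test_that("planted Cp artifacts are removed by preprocessing, and only those", {
  qc <- qc_spec(undetected = data.frame(sample = "ctrl02", assay = "mol001"),
                low_efficiency = data.frame(sample = "case01", assay = "mol004"))
  sim <- simulate_cp_panel(synth_config(n_molecules = 8, seed = 21), qc = qc)
  # planted values carry the advertised failure modes
  pan <- sim$panel
  u <- pan[pan$sample_id == "ctrl02" & pan$assay_id == "mol001", ]
  expect_true(u$cp >= 37 && u$negative_control_cp - u$cp < 3)
  e <- pan[pan$sample_id == "case01" & pan$assay_id == "mol004", ]
  expect_lt(e$efficiency, 1.6)
  es <- preprocess_panel(pan, low_expr_quantile = 0)
  expect_true(is.na(es$values["ctrl02", "mol001"]))
  expect_true(is.na(es$values["case01", "mol004"]))
  expect_identical(sum(is.na(es$values)), 2L)
  # clean panel: every record survives
  clean <- simulate_cp_panel(synth_config(n_molecules = 8, seed = 21))
  es2 <- preprocess_panel(clean$panel, low_expr_quantile = 0)
  expect_identical(sum(is.na(es2$values)), 0L)
  expect_identical(dim(es2$values), c(53L, 8L))
  # unknown IDs in the qc spec are rejected
  expect_error(simulate_cp_panel(synth_config(n_molecules = 8, seed = 21),
                                 qc = qc_spec(undetected = data.frame(
                                   sample = "nope", assay = "mol001"))),
               "unknown sample/assay")
})

test_that("rank statistics are invariant to increasing marginal transforms", {
  sim <- simulate_expression(synth_config(n_molecules = 5, seed = 31))
  v <- sim$data$values
  f1 <- diffcorr(sim$data)
  v2 <- v
  v2[, 1] <- exp(v2[, 1])          # strictly increasing
  v2[, 2] <- v2[, 2]^3             # strictly increasing (signed values)
  f2 <- diffcorr(v2, sim$data$class)
  expect_equal(f1$pairs$score, f2$pairs$score)
  expect_equal(f1$pairs$p_value, f2$pairs$p_value)
})
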