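test_that("all m(m-1)/2 pairs are ranked deterministically", {
  sim <- simulate_expression(synth_config(n_molecules = 20, seed = 61))
  fit <- diffcorr(sim$data)
  expect_identical(nrow(fit$pairs), 190L)
  expect_identical(fit$pairs$rank, seq_len(190L))
  expect_true(all(diff(fit$pairs$score) <= 0))
  # no duplicated pair, (i,j) and (j,i) identified
  key <- paste(pmin(fit$pairs$molecule_a, fit$pairs$molecule_b),
               pmax(fit$pairs$molecule_a, fit$pairs$molecule_b))
  expect_identical(anyDuplicated(key), 0L)
  # deterministic re-fit
  expect_identical(fit$pairs, diffcorr(sim$data)$pairs)
  # two molecules give a single pair
  fit2 <- diffcorr(sim$data$values[, 1:2], sim$data$class)
  expect_identical(nrow(fit2$pairs), 1L)
  # score recomputable from the stored correlations
  expect_equal(fit$pairs$score, abs(fit$pairs$r1 - fit$pairs$r2))
  expect_true(all(fit$pairs$p_value > 0 & fit$pairs$p_value <= 1))
})

test_that("marker selection is strict and warns on an empty set", {
  sim <- simulate_expression(synth_config(n_molecules = 10, seed = 62))
  fit <- diffcorr(sim$data)
  mk <- suppressWarnings(markers(fit, threshold = 0.8))
  expect_true(all(mk$score > 0.8))
  expect_warning(empty <- markers(fit, threshold = 2), "no pair")
  expect_identical(nrow(empty), 0L)
})

test_that("undefined-correlation pairs are excluded with reasons", {
  sim <- simulate_expression(synth_config(n_molecules = 6, seed = 63))
  v <- sim$data$values
  v[, 2] <- 1  # constant molecule: correlations undefined
  fit <- diffcorr(v, sim$data$class)
  expect_equal(nrow(fit$pairs), choose(6, 2) - 5)
  expect_identical(nrow(fit$excluded), 5L)
  expect_true(all(grepl("constant", fit$excluded$reason)))
  expect_true(all(fit$excluded$molecule_a == "mol002" |
                    fit$excluded$molecule_b == "mol002"))
})

test_that("missing entries are handled pairwise-complete with recorded counts", {
  sim <- simulate_expression(synth_config(n_molecules = 4, seed = 64))
  v <- sim$data$values
  v[1:4, 1] <- NA  # four controls undetected for mol001
  fit <- diffcorr(v, sim$data$class)
  p <- fit$pairs
  touched <- p$molecule_a == "mol001" | p$molecule_b == "mol001"
  expect_true(all(p$n1[touched] == 26))
  expect_true(all(p$n1[!touched] == 30))
  expect_true(all(p$n2 == 23))
  # spot-check one pairwise-complete correlation
  k <- which(p$molecule_a == "mol001" & p$molecule_b == "mol002")
  cc <- stats::complete.cases(v[sim$data$class == "control", 1:2])
  expect_equal(p$r1[k],
               cor(v[sim$data$class == "control", 1][cc],
                   v[sim$data$class == "control", 2][cc],
                   method = "spearman"))
})

test_that("fisher p-method is available and matches the standalone test", {
  sim <- simulate_expression(synth_config(n_molecules = 5, seed = 65))
  fit <- diffcorr(sim$data, p_method = "fisher")
  k <- 3
  expect_equal(fit$pairs$p_value[k],
               fisher_z_test(fit$pairs$rn1[k], fit$pairs$n1[k],
                             fit$pairs$rn2[k], fit$pairs$n2[k]))
})

test_that("print, summary and plot methods run quietly", {
  sim <- simulate_expression(synth_config(n_molecules = 6, seed = 66))
  fit <- evaluate_pairs(diffcorr(sim$data), threshold = -Inf)
  expect_output(print(fit), "Differential correlation")
  expect_output(print(summary(fit, threshold = 0.5)), "ranked pairs")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("pair table round-trips through its delimited export", {
  sim <- simulate_expression(synth_config(n_molecules = 5, seed = 67))
  fit <- diffcorr(sim$data)
  path <- tempfile(fileext = ".tsv")
  write_pair_table(fit, path)
  tab <- read.delim(path)
  expect_identical(nrow(tab), nrow(fit$pairs))
  expect_equal(tab$score, fit$pairs$score)
})
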