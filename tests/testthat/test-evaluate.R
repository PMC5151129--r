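test_that("AUC equals the Mann-Whitney concordance", {
  cls4 <- factor(c("case", "case", "ctrl", "ctrl"), levels = c("ctrl", "case"))
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.4), cls4), 1)
  expect_equal(roc_auc(c(0.9, 0.3, 0.5, 0.1), cls4), 0.75)
  expect_equal(roc_auc(rep(0.5, 10), two_class(5, 5)), 0.5)
  expect_error(roc_auc(1:3, factor(rep("a", 3))), "both classes")
})

test_that("AUC agrees with brute-force concordance on random instances", {
  set.seed(71)
  for (i in 1:60) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    s <- c(rnorm(n0), rnorm(n1, mean = runif(1, -1, 1)))
    if (i %% 3 == 0) s <- round(s)  # force ties
    cls <- two_class(n0, n1)
    expect_equal(roc_auc(s, cls), auc_bruteforce(s, cls))
  }
})

test_that("AUC is rank-invariant and complements under label reversal", {
  set.seed(72)
  s <- rnorm(40)
  cls <- two_class(22, 18)
  a <- roc_auc(s, cls)
  expect_equal(roc_auc(exp(s), cls), a)
  expect_equal(roc_auc(s, factor(cls, levels = rev(levels(cls)))), 1 - a)
})

test_that("interaction design has one main effect per molecule, one product per pair", {
  sim <- simulate_expression(synth_config(n_molecules = 6, seed = 73))
  # two pairs sharing a molecule: 3 main effects + 2 interactions (+ intercept)
  pairs <- data.frame(molecule_a = c("mol001", "mol001"),
                      molecule_b = c("mol002", "mol003"))
  X <- dcmarker:::interaction_design(sim$data$values, pairs)
  expect_identical(colnames(X),
                   c("(Intercept)", "mol001", "mol002", "mol003",
                     "mol001:mol002", "mol001:mol003"))
  fit <- fit_interaction_logistic(sim$data, pairs)
  expect_identical(length(fit$coefficients), 6L)
  # duplicated pair: collinear design is refused with the column named
  dup <- data.frame(molecule_a = c("mol001", "mol001"),
                    molecule_b = c("mol002", "mol002"))
  expect_error(fit_interaction_logistic(sim$data, dup), "rank-deficient")
})

test_that("separated fits are flagged and score AUC 1", {
  set.seed(74)
  v <- cbind(mol001 = c(rnorm(10, -3), rnorm(10, 3)), mol002 = rnorm(20))
  rownames(v) <- paste0("s", 1:20)
  cls <- two_class(10, 10)
  fit <- fit_interaction_logistic(v, data.frame(molecule_a = "mol001",
                                                molecule_b = "mol002"), cls)
  expect_true(fit$separated)
  expect_equal(fit$auc, 1)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("permuted labels give chance-level AUC on average", {
  sim <- simulate_expression(synth_config(
    n_molecules = 2,
    differential_pairs = data.frame(i = 1L, j = 2L, rho1 = 0.8, rho2 = -0.2),
    mean_shift_molecules = data.frame(molecule = integer(), effect = numeric()),
    seed = 75))
  set.seed(75)
  aucs <- replicate(100, {
    cls <- sample(sim$data$class)
    fit_interaction_logistic(sim$data$values,
                             data.frame(molecule_a = "mol001",
                                        molecule_b = "mol002"), cls)$auc
  })
  # in-sample fit of 4 parameters at n = 53 sits above 0.5 by overfit alone;
  # the permutation null is stable and well under the planted-signal range
  expect_gt(mean(aucs), 0.5)
  expect_lt(mean(aucs), 0.68)
})

test_that("evaluate_pairs fills AUCs deterministically with a summary", {
  sim <- simulate_expression(synth_config(n_molecules = 8, seed = 76))
  fit <- evaluate_pairs(diffcorr(sim$data), threshold = 0.5)
  idx <- fit$pairs$score > 0.5
  expect_true(all(!is.na(fit$pairs$auc[idx])))
  expect_true(all(is.na(fit$pairs$auc[!idx])))
  expect_equal(fit$auc_summary[["mean"]], mean(fit$pairs$auc[idx]))
  fit2 <- evaluate_pairs(diffcorr(sim$data), threshold = 0.5)
  expect_identical(fit$pairs$auc, fit2$pairs$auc)
})

test_that("combination search enumerates C(k,2) combos with deterministic ties", {
  sim <- simulate_expression(synth_config(n_molecules = 10, seed = 77))
  fit <- evaluate_pairs(diffcorr(sim$data), threshold = -Inf)
  cs <- search_pair_combos(fit, threshold = -Inf, combo_size = 2)
  expect_equal(nrow(cs), choose(45L, 2L))
  expect_identical(cs$rank, seq_len(nrow(cs)))
  ok <- !is.na(cs$auc)
  expect_true(all(diff(cs$auc[ok]) <= 0))
  cs2 <- search_pair_combos(fit, threshold = -Inf, combo_size = 2)
  expect_identical(cs, cs2)
  # two marker pairs give exactly one combination
  fit3 <- evaluate_pairs(diffcorr(sim$data$values[, 1:4], sim$data$class),
                         threshold = -Inf)
  cs3 <- search_pair_combos(fit3, threshold = -Inf, combo_size = 2)
  expect_equal(nrow(cs3), choose(choose(4L, 2L), 2L))
  expect_error(suppressWarnings(search_pair_combos(fit3, threshold = 2)),
               "need at least")
})
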