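test_that("REML equals the balanced-ANOVA closed form on balanced data", {
  set.seed(41)
  for (rep in 1:5) {
    d <- make_condition_table(rnorm(8, 0, 2), rnorm(3), rnorm(24),
                              mu = 10)
    fit <- fit_condition_model(d, "T", "C1")
    oracle <- anova_varcomp(d)
    expect_equal(fit$varcomp[["var_G"]], oracle[["var_G"]],
                 tolerance = 1e-6)
    expect_equal(fit$varcomp[["var_error"]], oracle[["var_error"]],
                 tolerance = 1e-6)
    # the closed-form identity sigma_G^2 = (MS_line - MS_error) / r
    expect_equal(fit$varcomp[["var_G"]],
                 max((oracle[["ms_line"]] - oracle[["ms_error"]]) / 3, 0),
                 tolerance = 1e-6)
  }
})

test_that("identical lines give a zero genetic variance at the boundary", {
  # cyclic residual pattern: every line mean and block mean is zero, so
  # all between-line signal vanishes while the residual variance does not
  e <- outer(1:6, 1:3, function(i, j) c(-1, 0, 1)[((i + j) %% 3) + 1])
  d <- make_condition_table(rep(0, 6), c(0, 1, 2), as.vector(e))
  fit <- fit_condition_model(d, "T", "C1")
  expect_equal(fit$varcomp[["var_G"]], 0, tolerance = 1e-8)
})

test_that("preconditions on lines and blocks are enforced", {
  d <- make_condition_table(rnorm(4), 0, rnorm(4))
  expect_error(fit_condition_model(d, "T", "C1"), "blocks")
  expect_error(fit_condition_model(d, "T", "nope"), "no data")
  d2 <- make_condition_table(0, rnorm(3), rnorm(3))
  expect_error(fit_condition_model(d2, "T", "C1"), "lines")
})

test_that("genotypic values are shrunken line means centred on the grand mean", {
  set.seed(7)
  d <- make_condition_table(rnorm(15, 0, 1.5), rnorm(3), rnorm(45, 0, 2),
                            mu = 50)
  fit <- fit_condition_model(d, "T", "C1")
  gv <- coef(fit)
  expect_length(gv, 15)
  # average equals the fitted grand mean
  expect_equal(mean(gv), fit$grand_mean, tolerance = 1e-8)
  # shrinkage: genotypic values vary less than raw line means
  raw <- tapply(d$value, d$line, mean)
  expect_lte(var(gv), var(raw) + 1e-12)
  # ranking preserved for a balanced single-term model
  expect_equal(order(gv), order(raw[names(gv)]))
})

test_that("combined-model estimates match a direct restricted-likelihood optimizer", {
  sp <- trait_spec("X", mean_AP = 20, reduction_pct = 30,
                   var_G = 2, var_GxP = 1, var_error = 1)
  tab <- simulate_phenotypes(sim_config(n_lines = 8, n_blocks = 2,
                                        traits = list(sp), seed = 13))
  tab$trait <- "X"
  fit <- fit_combined_model(tab, "X")

  d <- tab[!is.na(tab$value), ]
  d$line <- factor(d$line); d$condition <- factor(d$condition)
  d$block <- factor(d$block)
  oracle <- reml_oracle_combined(d)

  # the restricted log-likelihood at lme4's estimate matches the direct
  # matrix formula
  vc <- fit$varcomp
  expect_equal(fit$loglik,
               oracle$loglik_at(vc[["var_G"]], vc[["var_GxP"]],
                                vc[["var_error"]]),
               tolerance = 1e-6)
  # and the independent optimizer finds no better restricted likelihood
  expect_lte(oracle$loglik, fit$loglik + 1e-4)
  expect_equal(unname(vc), unname(oracle$varcomp), tolerance = 1e-3)
})

test_that("simulating without interaction concentrates var_GxP at zero", {
  sp <- trait_spec("X", mean_AP = 10, var_G = 1, var_GxP = 0,
                   var_error = 1)
  ests <- vapply(1:20, function(i) {
    tab <- simulate_phenotypes(sim_config(n_lines = 25, n_blocks = 2,
                                          traits = list(sp),
                                          seed = 1000 + i))
    fit_combined_model(tab, "X")$varcomp[["var_GxP"]]
  }, numeric(1))
  expect_lte(median(ests), 0.05)
})

test_that("one condition missing directs the user to the per-condition model", {
  d <- make_condition_table(rnorm(4), rnorm(3), rnorm(12))
  expect_error(fit_combined_model(d, "T"), "fit_condition_model")
})

test_that("likelihood-ratio deviance, p-values and nesting checks behave", {
  set.seed(3)
  d <- make_condition_table(rnorm(20, 0, 2), rnorm(3), rnorm(60))
  full <- fit_condition_model(d, "T", "C1")
  red <- fit_condition_model(d, "T", "C1", random_line = FALSE)
  lrt <- lrt_random_effect(full, red)
  expect_gte(lrt$deviance, 0)
  expect_equal(lrt$deviance, 2 * (full$loglik - red$loglik),
               tolerance = 1e-10)
  expect_equal(lrt$p_value,
               pchisq(lrt$deviance, 1, lower.tail = FALSE))
  expect_equal(lrt$p_value_mixture, lrt$p_value / 2)
  expect_true(lrt$significant)  # strong line signal

  # identical fits: deviance 0, p = 1
  same <- lrt_random_effect(full, full0 <- local({
    f <- full; f$varcomp <- f$varcomp["var_error"]; f
  }))
  expect_equal(same$deviance, 0)
  expect_equal(same$p_value, 1)

  # non-nested pairs are refused
  expect_error(lrt_random_effect(full, full), "exactly one")
  other <- fit_condition_model(
    make_condition_table(rnorm(20), rnorm(3), rnorm(60), trait = "U"),
    "U", "C1", random_line = FALSE)
  expect_error(lrt_random_effect(full, other), "not nested")
})

test_that("the LRT has power against a real line variance", {
  sp <- trait_spec("X", mean_AP = 10, var_G = 0.5, var_GxP = 0,
                   var_error = 1)
  rej <- vapply(1:40, function(i) {
    tab <- simulate_phenotypes(sim_config(n_lines = 40, traits = list(sp),
                                          seed = 2000 + i))
    full <- fit_condition_model(tab, "X", "NAP")
    red <- fit_condition_model(tab, "X", "NAP", random_line = FALSE)
    lrt_random_effect(full, red)$significant
  }, logical(1))
  expect_gt(mean(rej), 0.5)
})

test_that("full-model restricted likelihood dominates the reduced model's", {
  set.seed(17)
  for (i in 1:5) {
    d <- make_condition_table(rnorm(10), rnorm(3), rnorm(30))
    full <- fit_condition_model(d, "T", "C1")
    red <- fit_condition_model(d, "T", "C1", random_line = FALSE)
    expect_gte(full$loglik, red$loglik - 1e-6)
  }
})

test_that("per-condition genotypic values from the combined fit track the interaction", {
  sp <- trait_spec("X", mean_AP = 10, reduction_pct = 50, var_G = 1,
                   var_GxP = 2, var_error = 0.5)
  tab <- simulate_phenotypes(sim_config(n_lines = 30, traits = list(sp),
                                        seed = 8))
  fit <- fit_combined_model(tab, "X")
  cv <- fit$cond_values
  expect_equal(dim(cv), c(30L, 2L))
  expect_setequal(colnames(cv), c("NAP", "AP"))
  # per-condition columns recentre on the observed condition means
  obs <- tapply(tab$value, tab$condition, mean)
  expect_equal(unname(colMeans(cv)[names(obs)]), as.vector(obs),
               tolerance = 0.05)
  # cross-over interaction: per-condition predictions correlate
  # imperfectly across conditions
  expect_lt(cor(cv[, 1], cv[, 2]), 0.95)
  expect_gt(cor(cv[, 1], cv[, 2]), 0)
})
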