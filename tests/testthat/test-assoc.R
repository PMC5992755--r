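make_cohort_props <- function(effect, n_per_group = 60, sd = 0.05, seed = 1) {
  prof <- simulate_reference_profiles(synthetic_config(n_genes = 16,
                                                       n_markers_per_type = 2,
                                                       n_replicates = 2, seed = 2))
  simulate_bulk_cohort(prof, cohort_spec(
    n_cases = n_per_group, n_controls = n_per_group,
    effect_per_type = effect, proportion_noise_sd = sd,
    expression_noise_sigma = 0, seed = seed
  ))
}

test_that("linear association recovers planted effects and is exact in the no-noise limit", {
  coh <- make_cohort_props(c(neuron = -0.17), seed = 31)
  res <- fit_association(coh$proportions, coh$metadata, predictor = "status")
  neuron <- res[res$cell_type == "neuron", ]
  expect_lt(abs(neuron$estimate - (-0.17)), 0.03)
  expect_lt(neuron$p_value, 1e-6)

  # the two groups holding identical sets of proportion vectors: estimate zero
  v <- seq(0.25, 0.45, length.out = 10)
  props0 <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                           neuron = rep(v, 2), astrocyte = 1 - rep(v, 2))
  md0 <- tibble::tibble(sample_id = props0$sample_id,
                        status = rep(c("control", "case"), each = 10))
  res0 <- fit_association(props0, md0, predictor = "status")
  expect_lt(max(abs(res0$estimate)), 1e-12)

  # unbiasedness: mean estimate over 500 Gaussian replicates within 2 MC SEs
  ests <- withr::with_seed(33, vapply(1:500, function(i) {
    y <- c(rep(0, 30), rep(-0.17, 30)) + rnorm(60, 0, 0.05)
    g <- rep(c(0, 1), each = 30)
    unname(coef(lm(y ~ g))[2])
  }, numeric(1)))
  mc_se <- sd(ests) / sqrt(500)
  expect_lt(abs(mean(ests) - (-0.17)), 2 * mc_se + 1e-12)
})

test_that("linear association rejects degenerate designs", {
  coh <- make_cohort_props(c(neuron = -0.1), seed = 34)
  md <- coh$metadata
  md$dup <- as.numeric(md$status == "case")
  expect_error(
    fit_association(coh$proportions, md, predictor = "status", covariates = "dup"),
    "aliased", class = "cortexmix_model_error"
  )
  md$flat <- 1
  expect_error(
    fit_association(coh$proportions, md, predictor = "flat"),
    "no variation", class = "cortexmix_input_error"
  )
})

test_that("stepwise AIC keeps generating covariates and drops pure noise", {
  # AIC retains an uninformative single-df term with probability
  # P(chi^2_1 > 2) ~ 0.157, so noise exclusion should sit near 84%
  kept_noise <- kept_signal <- logical(100)
  for (i in 1:100) {
    d <- withr::with_seed(40 + i, {
      n <- 500
      rin <- rnorm(n, 7, 1)
      junk <- rnorm(n)
      tibble::tibble(rin = rin, junk = junk,
                     outcome = 0.3 + 0.05 * rin + rnorm(n, 0, 0.05))
    })
    sel <- select_covariates(d, "outcome", c("rin", "junk"))
    kept_noise[i] <- "junk" %in% sel$selected
    kept_signal[i] <- "rin" %in% sel$selected
  }
  expect_true(all(kept_signal))
  expect_gte(mean(!kept_noise), 0.75)
  expect_lte(mean(!kept_noise), 0.95)

  empty <- select_covariates(tibble::tibble(outcome = rnorm(10)), "outcome")
  expect_identical(empty$selected, character())
})

test_that("mixed models recover clustered effects and collapse to OLS when degenerate", {
  # planted effect -0.07 with a donor random intercept across 4 regions
  sim <- withr::with_seed(51, {
    n_donors <- 200
    carrier <- rep(c(0, 1), each = n_donors / 2)
    u <- rnorm(n_donors, 0, 0.05)
    d <- tidyr::expand_grid(donor = seq_len(n_donors), region = 1:4)
    d$carrier <- carrier[d$donor]
    d$neuron <- 0.35 - 0.07 * d$carrier + u[d$donor] + rnorm(nrow(d), 0, 0.05)
    d$sample_id <- paste0("s", seq_len(nrow(d)))
    d$donor_id <- paste0("d", d$donor)
    d
  })
  props <- sim[, c("sample_id", "neuron")]
  res <- fit_mixed_association(props, sim[, c("sample_id", "donor_id", "carrier")],
                               predictor = "carrier")
  expect_lt(abs(res$estimate - (-0.07)), 0.02)

  # one observation per donor, no clustering: matches plain OLS
  coh <- make_cohort_props(c(astrocyte = 0.1), n_per_group = 40, seed = 52)
  mm <- fit_mixed_association(coh$proportions, coh$metadata, predictor = "status",
                              cell_types = "astrocyte")
  ols <- fit_association(coh$proportions, coh$metadata, predictor = "status",
                         cell_types = "astrocyte")
  expect_lt(abs(mm$estimate - ols$estimate), 1e-6)
})

test_that("type-I error of the association fits is calibrated near the nominal level", {
  rej <- withr::with_seed(61, vapply(1:1000, function(i) {
    y <- rnorm(120, 0.3, 0.05)
    g <- rep(c(0, 1), each = 60)
    summary(lm(y ~ g))$coefficients[2, 4] < 0.05
  }, logical(1)))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Monte-Carlo power matches the noncentral-t closed form and is monotone", {
  # closed-form two-sample power oracle
  power_oracle <- function(n1, n2, effect, sd, alpha = 0.05) {
    df <- n1 + n2 - 2
    ncp <- abs(effect) / (sd * sqrt(1 / n1 + 1 / n2))
    crit <- qt(1 - alpha / 2, df)
    pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
  }
  est <- estimate_power(c(20, 16), effect = -0.11, sd = 0.08, n_sims = 2000, seed = 3)
  expect_lt(abs(est$power - power_oracle(20, 16, -0.11, 0.08)), 0.02)

  null <- estimate_power(30, effect = 0, sd = 0.05, n_sims = 2000, seed = 4)
  expect_lt(abs(null$power - 0.05), 0.02)

  big <- estimate_power(20, effect = 0.5, sd = 0.05, n_sims = 500, seed = 5)
  expect_gte(big$power, 0.999)

  p_small <- estimate_power(20, effect = 0.02, sd = 0.05, n_sims = 1000, seed = 6)
  p_large <- estimate_power(20, effect = 0.06, sd = 0.05, n_sims = 1000, seed = 6)
  p_more_n <- estimate_power(80, effect = 0.02, sd = 0.05, n_sims = 1000, seed = 6)
  expect_gte(p_large$power, p_small$power)
  expect_gte(p_more_n$power, p_small$power)

  expect_error(estimate_power(20, 0.1, sd = 0), "sd", class = "cortexmix_config_error")
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  row <- function(beta, se, ct = "neuron") {
    tibble::tibble(cell_type = ct, predictor = "status", term = "status",
                   estimate = beta, std_error = se, statistic = beta / se,
                   p_value = 2 * pnorm(-abs(beta / se)), n = 100L,
                   model = "ols", covariates = "")
  }
  # hand fixture: w = (100, 25) -> pooled 0.24, se = 1/sqrt(125)
  pooled <- meta_analyze(dplyr::bind_rows(row(0.2, 0.1), row(0.4, 0.2)))
  expect_equal(pooled$estimate, 0.24)
  expect_equal(pooled$std_error, 0.0894427191, tolerance = 1e-9)

  # cross-check against metafor's fixed-effect model
  mf <- metafor::rma(yi = c(0.2, 0.4), sei = c(0.1, 0.2), method = "FE")
  expect_equal(pooled$estimate, as.numeric(mf$beta), tolerance = 1e-12)
  expect_equal(pooled$std_error, mf$se, tolerance = 1e-12)

  # k identical studies shrink the standard error by exactly 1/sqrt(k)
  for (k in c(2, 4, 9)) {
    same <- dplyr::bind_rows(replicate(k, row(-0.11, 0.05), simplify = FALSE))
    pk <- meta_analyze(same)
    expect_equal(pk$estimate, -0.11)
    expect_equal(pk$std_error, 0.05 / sqrt(k))
  }

  # infinite standard error carries zero weight
  inf <- meta_analyze(dplyr::bind_rows(row(0.3, 0.1), row(9.9, Inf)))
  expect_equal(inf$estimate, 0.3)
  expect_equal(inf$std_error, 0.1)

  mixed <- dplyr::bind_rows(row(0.2, 0.1), row(0.4, 0.2))
  mixed$predictor[2] <- "braak"
  expect_error(meta_analyze(mixed), "mismatched", class = "cortexmix_input_error")
})
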