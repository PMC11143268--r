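test_that("environment generation is reproducible and spans the MAT range", {
  p <- generator_params(n_plots = 500, seed = 5)
  e1 <- generate_environment(p)
  e2 <- generate_environment(p)
  expect_identical(e1, e2)
  expect_gte(min(e1$mat_c), -2)
  expect_lte(max(e1$mat_c), 23)
  expect_equal(range(e1$mat_c), c(-2, 23), tolerance = 1e-9)
  expect_equal(nrow(generate_environment(generator_params(n_plots = 0))), 0)
  # CLT bound on the PC means at n = 10^4
  big <- generate_environment(generator_params(n_plots = 1e4, seed = 8))
  pcs <- as.matrix(big[, paste0("env_pc", 1:10)])
  expect_true(all(abs(colMeans(pcs)) < 4 / sqrt(1e4)))
})

test_that("zero feedback knobs make the phenologies exchangeable", {
  p <- generator_params(n_plots = 3000, seed = 21,
                        target_survival_advantage_de = 0,
                        target_survival_advantage_ev = 0,
                        target_growth_advantage_ev = 0,
                        target_growth_advantage_de = 0,
                        target_recruitment_ratio = 1)
  inv <- generate_two_census_inventory(generate_environment(p), p)
  tr <- inv$trees[inv$trees$fate != "recruit", ]
  sv <- tapply(tr$fate == "survivor", tr$phenology, mean)
  expect_lt(abs(sv["EV"] - sv["DE"]), 0.01)  # < 1 percentage point
  # calibration mirrors exactly under a label swap
  tv <- calibrate_vital_rates(p)
  expect_equal(unname(tv$survival$EV["intercept"]), unname(tv$survival$DE["intercept"] +
               tv$survival$DE["relev"]))
  expect_equal(unname(tv$recruitment$EV["relev"]), 0)
})

test_that("planted survival advantage shows up as an empirical frequency", {
  acc <- acceptance_fixture()
  d <- build_demography_data(acc$inv$trees, acc$inv$plots)
  tf <- d$tree_frame
  sel <- !is.na(tf$relev) & tf$relev < 0.1
  sv <- tapply(tf$survive[sel], tf$phenology[sel], mean)
  adv <- 100 * (sv["DE"] / sv["EV"] - 1)
  # Monte-Carlo error of the sparse evergreen stratum dominates the tolerance
  expect_equal(unname(adv), 14, tolerance = 6)
  expect_gt(unname(adv), 5)
})

test_that("planted recruitment ratio is an empirical count ratio when the
           con-basal-area term is switched off", {
  p <- generator_params(n_plots = 4000, seed = 31, beta_conba = 0,
                        target_recruitment_ratio = 5)
  inv <- generate_two_census_inventory(generate_environment(p), p)
  d <- build_demography_data(inv$trees, inv$plots)
  pf <- d$plot_frame
  s9 <- !is.na(pf$relev) & abs(pf$relev - 0.9) < 0.07
  s1 <- !is.na(pf$relev) & abs(pf$relev - 0.1) < 0.07
  r9 <- sum(pf$recruits_ev[s9]) / sum(pf$recruits_de[s9])
  r1 <- sum(pf$recruits_de[s1]) / sum(pf$recruits_ev[s1])
  expect_equal(r9, 5, tolerance = 0.25)
  expect_equal(r1, 5, tolerance = 0.25)
})

test_that("infeasible knobs raise calibration errors naming the knob", {
  expect_error(calibrate_vital_rates(generator_params(
    base_survival = 0.9, target_survival_advantage_de = 0,
    target_survival_advantage_ev = 20)),
    "target_survival_advantage_ev")
  expect_error(calibrate_vital_rates(generator_params(
    target_recruitment_ratio = -2)), "target_recruitment_ratio")
})

test_that("abundance tables follow the hurdle marginals and the coupling knob", {
  p <- generator_params(n_plots = 4000, seed = 13)
  p$abundance <- list(pi0_intercept = qlogis(0.3), pi0_slope = 0,
                      mu_intercept = 2.2, mu_slope = 0, rho = 0)
  env <- generate_environment(p)
  ab <- generate_abundance_table(env, p)
  expect_lt(abs(mean(ab$ev_count == 0) - 0.3), 0.02)
  expect_lt(abs(mean(ab$de_count == 0) - 0.3), 0.02)
  # with rho = 0 and flat parameters, EV and DE counts are independent
  expect_lt(abs(cor(ab$ev_count, ab$de_count, method = "spearman")), 0.05)

  # strong negative coupling enriches the outer relEV bins
  outer_frac <- function(rho) {
    p2 <- generator_params(n_plots = 4000, seed = 13)
    p2$abundance$rho <- rho
    a <- generate_abundance_table(env, p2)
    keep <- (a$ev_count + a$de_count) >= 10
    rel <- a$ev_count[keep] / (a$ev_count + a$de_count)[keep]
    mean(rel < 0.05 | rel > 0.95)
  }
  expect_gt(outer_frac(-1.5), outer_frac(0) + 0.1)
})

test_that("relEV beta-mixture presets have the expected shapes", {
  x_sym <- generate_relev_samples("bimodal", 4000, seed = 2)
  expect_lt(abs(sample_skewness(x_sym)), 0.15)
  expect_gt(dip_statistic(x_sym), 0.02)
  x_ev <- generate_relev_samples("unimodal_right", 4000, seed = 3)
  expect_lt(sample_skewness(x_ev), 0)  # evergreen-heavy: left tail
  x_de <- generate_relev_samples("unimodal_left", 4000, seed = 4)
  expect_gt(sample_skewness(x_de), 0)
  expect_error(generate_relev_samples(list(weights = c(0.5, 0.2),
                                           shape1 = c(1, 1), shape2 = c(1, 1)),
                                      10), "sum to 1")
  expect_identical(generate_relev_samples("bimodal", 50, seed = 9),
                   generate_relev_samples("bimodal", 50, seed = 9))
})

test_that("two-census inventories are reproducible and respect the schema", {
  p <- generator_params(n_plots = 120, seed = 17)
  env <- generate_environment(p)
  i1 <- generate_two_census_inventory(env, p)
  i2 <- generate_two_census_inventory(env, p)
  expect_identical(i1$trees, i2$trees)
  expect_silent(phenostate:::validate_trees(i1$trees))
  rec <- i1$trees[i1$trees$fate == "recruit", ]
  expect_true(all(rec$dbh_curr_cm == p$recruit_dbh_cm))
  expect_true(all(is.na(rec$dbh_prev_cm)))
})
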