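test_that("feedback models nest the null models (likelihood ordering)", {
  acc <- acceptance_fixture()
  for (ph in c("EV", "DE")) for (rate in c("survival", "growth", "recruitment")) {
    dev_fb <- deviance(acc$models_fb[[ph]][[rate]]$fit)
    dev_nl <- deviance(acc$models_null[[ph]][[rate]]$fit)
    expect_lte(dev_fb, dev_nl + 1e-6)
  }
})

test_that("zero-feedback data give near-zero contrasts with covering intervals", {
  fx <- cached("nofeedback", {
    p <- generator_params(n_plots = 2500, seed = 23,
                          target_survival_advantage_de = 0,
                          target_survival_advantage_ev = 0,
                          target_growth_advantage_ev = 0,
                          target_growth_advantage_de = 0,
                          target_recruitment_ratio = 1)
    inv <- generate_two_census_inventory(generate_environment(p), p)
    fit_vital_rates(inv$trees, inv$plots, feedback = TRUE)
  })
  s <- predict_survival_growth_contrast(fx, "survival", seed = 1)
  expect_true(all(abs(s$rel_diff_pct) < 6))
  expect_true(all(s$lo95 < 0 & s$hi95 > 0))
  # the relev/conBA partition is collinear (relEV = conBA/plotBA), which
  # inflates the ratio's sampling variance; the tolerance reflects that
  r <- predict_recruitment_ratio(fx, seed = 2)
  expect_true(all(abs(r$ratio - 1) < 0.5))
})

test_that("noiseless linear growth is recovered almost exactly", {
  p <- generator_params(n_plots = 800, seed = 29, sigma_growth = 1e-8)
  inv <- generate_two_census_inventory(generate_environment(p), p)
  d <- build_demography_data(inv$trees, inv$plots)
  f <- fit_growth(d, "EV")
  tv <- calibrate_vital_rates(p)
  nd <- phenostate:::means_newdata(f, 0.5)
  pred_incr <- predict(f, nd) - nd$dbh_prev
  true_incr <- predict_true_rate(tv, "growth", "EV",
    data.frame(dbh_prev = nd$dbh_prev, plot_ba = nd$plot_ba,
               stem_density = nd$stem_density, relev = 0.5,
               env_pc1 = 0, env_pc2 = 0, env_pc3 = 0))
  expect_equal(pred_incr, unname(true_incr), tolerance = 0.02)
  # prediction at the training mean of predictors ~ mean response
  tfr <- d$tree_frame
  tfr <- tfr[tfr$phenology == "EV" & tfr$fate == "survivor", ]
  nd2 <- phenostate:::means_newdata(f, mean(tfr$relev))
  expect_equal(predict(f, nd2), mean(tfr$dbh_curr), tolerance = 0.05)
})

test_that("flat vital rates reduce to the simple MLEs", {
  p <- generator_params(n_plots = 1500, seed = 37,
                        base_survival = 0.9,
                        target_survival_advantage_de = 0,
                        target_survival_advantage_ev = 0,
                        target_recruitment_ratio = 1,
                        beta_env = c(0, 0, 0), beta_dbh = 0, beta_ba = 0,
                        beta_density = 0, beta_conba = 0)
  inv <- generate_two_census_inventory(generate_environment(p), p)
  d <- build_demography_data(inv$trees, inv$plots)
  fs <- fit_survival(d, "DE")
  expect_equal(predict(fs, phenostate:::means_newdata(fs, 0.5)), 0.9,
               tolerance = 0.015)
  fr <- fit_recruitment(d, "DE")
  pf <- d$plot_frame
  expect_equal(predict(fr, phenostate:::means_newdata(fr, mean(pf$relev, na.rm = TRUE))),
               mean(pf$recruits_de), tolerance = 0.1)
})

test_that("planted feedbacks are recovered by the fitted contrasts", {
  acc <- acceptance_fixture()
  s <- predict_survival_growth_contrast(acc$models_fb, "survival", seed = 101)
  g <- predict_survival_growth_contrast(acc$models_fb, "growth", seed = 102)
  expect_equal(s$rel_diff_pct[s$relev == 0], 14, tolerance = 2 / 14)
  expect_equal(s$rel_diff_pct[s$relev == 1], 17, tolerance = 2 / 17)
  expect_equal(g$rel_diff_pct[g$relev == 1], 43, tolerance = 4 / 43)
  expect_equal(g$rel_diff_pct[g$relev == 0], 4, tolerance = 3 / 4)
  # label-symmetric recruitment plant: both con:hetero ratios agree
  r <- predict_recruitment_ratio(acc$models_fb, seed = 103)
  expect_equal(r$ratio[1], r$ratio[2], tolerance = 0.25)
})

test_that("con-phenological survival rises monotonically in relEV", {
  acc <- acceptance_fixture()
  f <- acc$models_fb$EV$survival
  grid <- seq(0, 1, by = 0.1)
  nd <- phenostate:::means_newdata(f, 0)
  nd <- nd[rep(1, length(grid)), ]; nd$relev <- grid
  expect_true(all(diff(predict(f, nd)) >= -1e-10))
})

test_that("contrasts refuse null-variant models", {
  acc <- acceptance_fixture()
  expect_error(predict_survival_growth_contrast(acc$models_null, "survival"),
               "null-variant")
  expect_error(predict_recruitment_ratio(acc$models_null), "null-variant")
})

test_that("95% contrast intervals cover the planted growth advantage", {
  # repeated small-scale simulation study of interval coverage
  cover <- vapply(1:50, function(i) {
    p <- generator_params(n_plots = 500, seed = 2000 + i)
    inv <- generate_two_census_inventory(generate_environment(p), p)
    d <- build_demography_data(inv$trees, inv$plots)
    m <- list(feedback = TRUE,
              EV = list(growth = fit_growth(d, "EV")),
              DE = list(growth = fit_growth(d, "DE")))
    class(m) <- "vital_rate_models"
    g <- predict_survival_growth_contrast(m, "growth", relev_points = 1,
                                          n_draws = 100, seed = i)
    g$lo95 <= 43 && g$hi95 >= 43
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})
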