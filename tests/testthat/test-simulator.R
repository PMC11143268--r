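# frozen-demography truth: certain survival, no recruitment, fixed growth
frozen_rates <- function(g = 1.5) {
  p <- generator_params(base_survival = 1 - 1e-9,
                        target_survival_advantage_de = 0,
                        target_survival_advantage_ev = 0,
                        base_growth = g, target_growth_advantage_ev = 0,
                        target_growth_advantage_de = 0, sigma_growth = 0,
                        base_recruitment = 1e-12, target_recruitment_ratio = 1,
                        beta_env = c(0, 0, 0), beta_dbh = 0, beta_ba = 0,
                        beta_density = 0, beta_conba = 0)
  calibrate_vital_rates(p)
}

test_that("the disturbance constant and its per-step compounding are right", {
  expect_equal(natural_disturbance_rate(), 0.0036, tolerance = 1e-12)
  expect_equal(natural_disturbance_rate(0.009, 0.0054), 0.0036)
  expect_equal(1 - (1 - 0.0036)^5, 0.017871, tolerance = 1e-5)
})

test_that("initialization schemes produce the prescribed compositions", {
  env <- generate_environment(generator_params(n_plots = 50, seed = 2))
  st <- init_sim_state(sim_config(n_plots = 1000, init = "bimodal_half", seed = 4), env)
  expect_equal(sum(st$last_relev == 1), 500)
  expect_equal(sum(st$last_relev == 0), 500)
  st2 <- init_sim_state(sim_config(n_plots = 1000, init = "hysteresis_ev", seed = 4), env)
  expect_equal(sum(st2$last_relev == 1), 800)
  expect_equal(sum(st2$last_relev == 0), 200)
  st3 <- init_sim_state(sim_config(n_plots = 1000, init = "hysteresis_de", seed = 4), env)
  expect_equal(sum(st3$last_relev == 0), 800)
  # uniform targets are uniform
  set.seed(9)
  cfg <- sim_config(n_plots = 5000, init = "uniform", seed = 11)
  tg <- phenostate:::init_targets(cfg)
  expect_gt(stats::ks.test(tg, "punif")$p.value, 0.001)
  expect_error(sim_config(init = "nope"))
  # every plot starts with the configured trees at the entry diameter
  expect_true(all(table(st$trees$plot) == 20))
  expect_true(all(st$trees$dbh == 12.7))
})

test_that("certain disturbance resets every plot each step", {
  env <- generate_environment(generator_params(n_plots = 30, seed = 2))
  cfg <- sim_config(n_plots = 30, horizon_years = 10, step_years = 5,
                    p_disturb_annual = 1, init = "uniform", seed = 5)
  st <- init_sim_state(cfg, env)
  st$trees$dbh <- st$trees$dbh + 17  # will be wiped by the reset
  st2 <- sim_step(st, frozen_rates(), cfg)
  expect_true(all(table(st2$trees$plot) == 20))
  expect_true(all(st2$trees$dbh == 12.7))
})

test_that("frozen demography conserves trees and grows them deterministically", {
  env <- generate_environment(generator_params(n_plots = 20, seed = 2))
  cfg <- sim_config(n_plots = 20, horizon_years = 15, step_years = 5,
                    p_disturb_annual = 0, init = "uniform", seed = 6)
  sim <- run_simulation(cfg, frozen_rates(g = 1.5), env)
  expect_equal(nrow(sim$state$trees), 20 * 20)
  expect_true(all(abs(sim$state$trees$dbh - (12.7 + 3 * 1.5)) < 1e-6))
})

test_that("simulation state stays valid and is seed-deterministic", {
  acc <- acceptance_fixture()
  cfg <- sim_config(n_plots = 60, horizon_years = 100, step_years = 5,
                    init = "uniform", seed = 13)
  s1 <- run_simulation(cfg, acc$models_fb, acc$env)
  s2 <- run_simulation(cfg, acc$models_fb, acc$env)
  expect_identical(s1$final_relev, s2$final_relev)
  expect_true(all(s1$final_relev >= 0 & s1$final_relev <= 1))
  expect_true(all(s1$state$trees$dbh >= 12.7))
  # no tree shrinks within a step
  st <- s1$state
  dbh_before <- st$trees$dbh
  ids <- paste(st$trees$plot, seq_len(nrow(st$trees)))
  st2 <- sim_step(st, compile_rates(acc$models_fb, st$env), cfg)
  # surviving trees can be tracked by plot + dbh ordering: check global minimum growth
  expect_gte(min(st2$trees$dbh), 12.7)
})

test_that("compiled predictors agree with direct model predictions", {
  acc <- acceptance_fixture()
  cr <- compile_rates(acc$models_fb, acc$env[1:40, ])
  nd <- data.frame(dbh_prev = c(15, 25, 40), plot_ba = 0.6, stem_density = 20,
                   relev = c(0.2, 0.5, 0.9), acc$env[c(3, 17, 32),
                   c(paste0("env_pc", 1:10), "mat_c")])
  names(nd)[names(nd) == "mat_c"] <- "mat"
  direct <- predict(acc$models_fb$EV$survival, nd)
  fast <- cr$EV$survival(c(3, 17, 32), dbh = nd$dbh_prev, plot_ba = nd$plot_ba,
                         stem_density = nd$stem_density, relev = nd$relev)
  expect_equal(fast, direct, tolerance = 1e-8)
  dg <- predict(acc$models_fb$DE$growth, nd) - nd$dbh_prev
  fg <- cr$DE$growth(c(3, 17, 32), dbh = nd$dbh_prev, plot_ba = nd$plot_ba,
                     stem_density = nd$stem_density, relev = nd$relev)
  expect_equal(fg, dg, tolerance = 1e-8)
})

test_that("label symmetry: symmetric truth with mirrored inits mirrors relEV", {
  p <- generator_params(n_plots = 400, seed = 41,
                        target_survival_advantage_de = 10,
                        target_survival_advantage_ev = 10,
                        target_growth_advantage_ev = 10,
                        target_growth_advantage_de = 10,
                        target_recruitment_ratio = 3)
  env <- generate_environment(p)
  tv <- calibrate_vital_rates(p)
  cfg <- sim_config(n_plots = 200, horizon_years = 150, step_years = 5,
                    init = "bimodal_half", seed = 51)
  sim <- run_simulation(cfg, tv, env)
  expect_lt(abs(mean(sim$final_relev) - 0.5), 0.12)
})

test_that("an evergreen stand under favorable feedback stays evergreen", {
  acc <- acceptance_fixture()
  cfg <- sim_config(n_plots = 50, horizon_years = 250, step_years = 5,
                    p_disturb_annual = 0, init = "hysteresis_ev", seed = 77)
  cfg$init <- "bimodal_half"  # half pure EV
  sim <- run_simulation(cfg, acc$models_fb, acc$env)
  ev_init <- sim$state$target_relev == 1
  expect_gt(mean(sim$final_relev[ev_init]), 0.9)
})

test_that("trajectories are recorded at the requested thinning", {
  env <- generate_environment(generator_params(n_plots = 20, seed = 2))
  cfg <- sim_config(n_plots = 20, horizon_years = 50, step_years = 5,
                    init = "uniform", record_every = 2, seed = 3)
  sim <- run_simulation(cfg, frozen_rates(), env)
  expect_equal(dim(sim$trajectory), c(6, 20))  # init + 5 recordings
  expect_true(all(!is.na(sim$trajectory)))
})
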