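#!/usr/bin/env Rscript
# Hysteresis along the mean-annual-temperature gradient: refit the
# demographic models with a MAT term on data with a planted temperature
# asymmetry (evergreens favored cold, deciduous warm), then simulate 12 MAT
# sections from evergreen-dominated vs deciduous-dominated starts under both
# model variants and compare the final compositions.
suppressMessages(library(phenostate))

dir.create("results", showWarnings = FALSE)
p <- generator_params(n_plots = 3000, seed = 20240531,
                      mat_survival_asym = 0.6, mat_recruit_asym = 0.6)
env <- generate_environment(p)
inv <- generate_two_census_inventory(env, p)
models_fb <- fit_vital_rates(inv$trees, inv$plots, feedback = TRUE, mat_term = TRUE)
models_null <- fit_vital_rates(inv$trees, inv$plots, feedback = FALSE, mat_term = TRUE)

cfg <- sim_config(n_plots = 100, horizon_years = 500, step_years = 5, seed = 401)
h <- hysteresis_experiment(cfg, models_fb, models_null, env)
write.csv(h, "results/hysteresis.csv", row.names = FALSE)

print(h[, c("variant", "section", "mat_mid", "relev_ev_init", "relev_de_init",
            "gap", "gap_lo95", "gap_hi95")], digits = 2)
fb <- h[h$variant == "feedback", ]
cat(sprintf("feedback: initialization gap excludes 0 in %d of 12 MAT sections\n",
            sum(fb$gap_lo95 > 0)))
nl <- h[h$variant == "null", ]
cat(sprintf("null:     initialization gap excludes 0 in %d of 12 MAT sections\n",
            sum(nl$gap_lo95 > 0)))
cat("mean final relEV declines with MAT (feedback variant):",
    cor(fb$mat_mid, (fb$relev_ev_init + fb$relev_de_init) / 2,
        method = "spearman") < 0, "\n")
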