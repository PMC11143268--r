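#!/usr/bin/env Rscript
# Environmental-filtering null model: fit zero-adjusted Poisson abundance
# models per leaf type on plot counts drawn with a negative EV-DE coupling,
# simulate 1000 environment-only replicates, and compare the observed relEV
# histogram and Spearman coupling against the null envelopes.
suppressMessages(library(phenostate))

dir.create("results", showWarnings = FALSE)
p <- generator_params(n_plots = 3000, seed = 20240531)
p$abundance$rho <- -1.5   # feedback-like coupling beyond the environment
env <- generate_environment(p)
ab <- generate_abundance_table(env, p)
pcs <- env[, paste0("env_pc", 1:10)]

fit_ev <- fit_zap(ab$ev_count, pcs)
fit_de <- fit_zap(ab$de_count, pcs)
ens <- null_relev_ensemble(fit_ev, fit_de, pcs, observed = ab,
                           n_rep = 1000, seed = 101, dip_p_value = TRUE)
sp <- spearman_coupling_test(ab$ev_count, ab$de_count, fit_ev, fit_de, pcs,
                             n_rep = 1000, seed = 102)

write.csv(ens$bins, "results/null_envelope.csv", row.names = FALSE)
jsonlite::write_json(list(rho_obs = sp$rho_obs, p_spearman = sp$p,
                          dip_D = ens$dip$D, dip_p = ens$dip$p,
                          outer_exceedance = ens$outer_exceedance),
                     "results/bimodality_null.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("observed dip D = %.4f (Monte-Carlo p = %.3f)\n", ens$dip$D, ens$dip$p))
cat(sprintf("outer bins exceed the 97.5%% null envelope: %s / %s\n",
            ens$outer_exceedance[1], ens$outer_exceedance[2]))
cat(sprintf("Spearman rho observed %.3f vs null median %.3f; one-sided p = %.3g\n",
            sp$rho_obs, median(sp$rho_null), sp$p))
cat("-> environmental filtering alone does not reproduce the bimodality\n")
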