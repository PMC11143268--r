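#!/usr/bin/env Rscript
# Generate the synthetic two-census forest inventory used by all later
# stages: 3000 plots on a 10-PC environment with the headline con-phenological
# feedbacks planted (14%/17% survival, 43%/4% growth, 5x recruitment), apply
# the inventory inclusion filters, and write the tables under results/.
suppressMessages(library(phenostate))

dir.create("results", showWarnings = FALSE)
p <- generator_params(n_plots = 3000, seed = 20240531)
env <- generate_environment(p)
inv <- generate_two_census_inventory(env, p)
kept <- apply_inclusion_filters(inv$trees, inv$plots)

write.csv(inv$trees, "results/trees.csv", row.names = FALSE)
write.csv(env, "results/plots.csv", row.names = FALSE)
write.csv(kept$audit, "results/filter_audit.csv", row.names = FALSE)
write.csv(kept$summaries, "results/plot_summaries.csv", row.names = FALSE)

cat(sprintf("generated %d trees on %d plots (%d recruits)\n",
            nrow(inv$trees), nrow(env), sum(inv$trees$fate == "recruit")))
cat(sprintf("inclusion filters keep %d plots; exclusions by rule:\n",
            length(kept$kept_ids)))
print(kept$audit)
s <- kept$summaries
cat(sprintf("relEV (area) quartiles among kept plots: %s\n",
            paste(round(quantile(s$relev_area, na.rm = TRUE), 3), collapse = " ")))
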