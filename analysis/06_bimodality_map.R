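#!/usr/bin/env Rscript
# Bimodality mapping and determinant importance: cluster plots spatially
# (10-arc-min fishing net) and environmentally (k-means on 3 leading PCs),
# compute the dip-based bimodality index and its four-way classification per
# cluster, and rank the seven key determinants by bootstrap permutation
# importance for plot-level relEV.
suppressMessages(library(phenostate))

dir.create("results", showWarnings = FALSE)
p <- generator_params(n_plots = 3000, seed = 20240531)
env <- generate_environment(p)
inv <- generate_two_census_inventory(env, p)
s <- plot_summaries(inv$trees)
relev <- stats::setNames(s$relev_area, s$plot_id)

net <- fishing_net_clusters(env, cell_arcmin = 10, min_plots = 10)
bi_net <- cluster_bimodality(net, relev)
km <- kmeans_env_clusters(env, k = 60, seed = 601, min_plots = 10)
bi_km <- cluster_bimodality(km, relev)
write.csv(bi_net, "results/bimodality_fishing_net.csv", row.names = FALSE)
write.csv(bi_km, "results/bimodality_kmeans.csv", row.names = FALSE)

cat(sprintf("fishing net: %d clusters (>=10 plots); label counts:\n", nrow(bi_net)))
print(table(bi_net$label))
cat(sprintf("k-means (k=60): %d clusters; label counts:\n", nrow(bi_km)))
print(table(bi_km$label))

# Driver analysis on the abundance-model composition, whose marginals are
# environment-driven (the demographic inventory above draws composition
# independent of environment by design, so its determinant importances are a
# flat null). Temperature enters the truth through the first environmental
# component, so det_mat should rank first.
p2 <- p; p2$abundance$rho <- -0.8
ab <- generate_abundance_table(env, p2)
keep <- (ab$ev_count + ab$de_count) >= 10
y <- ab$ev_count[keep] / (ab$ev_count + ab$de_count)[keep]
detc <- c("det_mat", "det_precip", "det_tcold", "det_pdry",
          "det_soil_ph", "det_soil_n", "det_soil_cn")
imp <- permutation_importance(env[keep, detc], y, n_boot = 100, frac = 1/3,
                              seed = 602)
write.csv(imp, "results/determinant_importance.csv", row.names = FALSE)
cat("determinant permutation importance (mean +/- sd over 100 bootstraps):\n")
print(imp, digits = 3)
cat("top-ranked driver:", imp$feature[1], "\n")
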