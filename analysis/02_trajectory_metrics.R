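# Ensemble dynamics metrics on the condition-A/B ensembles produced by
# 01_simulate_ensembles.R: superposition, per-residue RMSF, block-averaged
# RMSD with a rank test between conditions, and PCA of the fluctuations.

source("analysis/00_common.R")

load_condition <- function(tag) {
  reps <- lapply(1:3, function(r) {
    ens <- read_pdb_trajectory(res_path(sprintf("condition_%s_rep%d.pdb",
                                                tag, r)),
                               condition_label = paste0("condition_", tag))
    ens$replicates[[1]]
  })
  trajectory_ensemble(reps, condition_label = paste0("condition_", tag))
}
ens_a <- load_condition("A")
ens_b <- load_condition("B")

sup_a <- superpose(ens_a)
sup_b <- superpose(ens_b)

rmsf_a <- rmsf(sup_a$aligned)
write_tsv(rmsf_a, res_path("rmsf_A.tsv"))
halves <- rmsf_region_average(rmsf_a, list(first_half = 1:8,
                                           second_half = 9:16))
write_tsv(data.frame(region = names(halves), rmsf_nm = unname(halves)),
          res_path("rmsf_halves_A.tsv"))

# RMSD block means (400-frame sections, 100-frame gaps) and significance
blocks_a <- block_averages(sup_a$rmsd[[1]], 400, 100)
blocks_b <- block_averages(sup_b$rmsd[[1]], 400, 100)
cmp <- compare_conditions(blocks_a, blocks_b)
message(sprintf("RMSD block means: A %s, B %s; Wilcoxon p = %.3g",
                paste(signif(blocks_a$means, 3), collapse = "/"),
                paste(signif(blocks_b$means, 3), collapse = "/"),
                cmp$p_value))
write_tsv(cmp$boxplot, res_path("rmsd_boxplot.tsv"))
write_tsv(data.frame(p_value = cmp$p_value, method = cmp$method,
                     independence_A = blocks_a$independence,
                     independence_B = blocks_b$independence),
          res_path("rmsd_comparison.tsv"))

# PCA of condition A; condition B projected into the same model
pca <- pca_fit_project(ens_a)
proj_b <- pca_project(pca, superpose(ens_b, reference = NULL)$aligned)
write_tsv(data.frame(
  condition = rep(c("A", "B"), c(sum(lengths(pca$projections)),
                                 sum(lengths(proj_b)))),
  pc1 = c(unlist(pca$projections), unlist(proj_b))),
  res_path("pc1_projections.tsv"))
message(sprintf("PC1 fraction of variance: %.2f (degenerate: %s)",
                pca$eigenvalues[1] / sum(pca$eigenvalues), pca$degenerate))
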