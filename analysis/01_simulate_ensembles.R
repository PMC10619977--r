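# Generate the matched pair of synthetic ensembles: a helix-like elastic
# network ("apo") and the same system with a planted allosteric pathway of
# pre-tensioned springs along residues 4-9-14 ("bound"). Three replicates
# per condition, overdamped Langevin dynamics at 300 K. Writes coordinate
# and pair-force artifacts consumed by scripts 02 and 03.

source("analysis/00_common.R")

system <- make_helix_chain(16, bond_k = 2000, network_k = 1000,
                           temperature = 300, friction = 1)
pair <- make_condition_pair(system, planted_path = c(4, 9, 14),
                            delta_k = 150, rest_scale = 0.5,
                            n_steps = 15000, dt = 2e-4, stride = 10,
                            n_replicates = 3,
                            seed = derive_seed(MASTER_SEED, 1))

print(pair$ensemble_a)
print(pair$ensemble_b)

write_pdb_trajectory(pair$ensemble_a, res_path("condition_A_rep1.pdb"))
write_pdb_trajectory(pair$ensemble_b, res_path("condition_B_rep1.pdb"))
write_force_series(pair$forces_a, res_path("forces_A.tsv"))
write_force_series(pair$forces_b, res_path("forces_B.tsv"))
write_tsv(pair$planted_pairs, res_path("planted_pairs.tsv"))

# replicates 2 and 3 as PDB too, so script 02 can rebuild the full ensembles
for (r in 2:3) {
  write_pdb_trajectory(pair$ensemble_a, res_path(sprintf("condition_A_rep%d.pdb", r)),
                       replicate = r)
  write_pdb_trajectory(pair$ensemble_b, res_path(sprintf("condition_B_rep%d.pdb", r)),
                       replicate = r)
}
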