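#!/usr/bin/env Rscript
# Rank candidates by shortlist consensus, compare the computational
# approaches, and summarise the lattice-energy landscapes.

library(nmrcsp)

rep <- run_pipeline("results/campaigns/default", out_dir = NULL)

message("Consensus ranking (memberships, then mean 1H/13C RMSD):")
print(rep$consensus, row.names = FALSE)
write.table(rep$consensus, "results/consensus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- compare_approaches(rep, approach_a = "static", approach_b = "md")
message("static - md reference-shielding deltas (ppm):")
print(cmp$sigma_ref_delta, row.names = FALSE)

message("Energy landscape (reference method):")
ls <- rep$energy$landscapes$reference
print(head(ls[, c("structure_id", "energy_rel", "density", "rank")], 5),
      row.names = FALSE)
message("rank-1/rank-2 gap: ", round(energy_gap(ls, 1, 2), 3), " kJ/mol")
ffcmp <- rep$energy$ff_vs_reference
message("force field vs reference energy RMSD (offset-corrected): ",
        round(ffcmp$rmsd, 3), " kJ/mol (raw ", round(ffcmp$rmsd_raw, 3), ")")

# the 26-candidate landscape
rep26 <- run_pipeline("results/campaigns/landscape26", out_dir = NULL)
ls26 <- rep26$energy$landscapes$reference
write.table(ls26, "results/energy_landscape_26.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("26-candidate landscape: truth rank ",
        ls26$rank[ls26$structure_id == "cand_00"], ", span ",
        round(max(ls26$energy_rel), 2), " kJ/mol")
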