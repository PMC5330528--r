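#!/usr/bin/env Rscript
# Parameter-recovery study: ten independent campaigns (seeds 0-9) under
# the reference conditions; does the pipeline put the planted truth first,
# and does 1H discriminate more sharply than 13C?

library(nmrcsp)

rows <- list()
for (s in 0:9) {
  dir <- file.path(tempdir(), sprintf("recovery_%d", s))
  man <- make_campaign(dir, campaign_config(), seed = s, overwrite = TRUE)
  rep <- run_pipeline(dir, out_dir = NULL)
  st <- rep$scores[rep$scores$approach == "static" &
                     rep$scores$structure_id == man$truth, ]
  rows[[s + 1]] <- data.frame(
    seed = s,
    consensus_top = rep$consensus$structure_id[1],
    truth_first = rep$consensus$structure_id[1] == man$truth,
    shortlist_1h = sum(rep$scores$shortlisted[rep$scores$element == "H"]),
    shortlist_13c = sum(rep$scores$shortlisted[rep$scores$element == "C"]),
    truth_rmsd_1h = st$rmsd[st$element == "H"],
    truth_rmsd_13c = st$rmsd[st$element == "C"],
    transitions_flagged = sum(rep$phase$flag)
  )
  unlink(dir, recursive = TRUE)
}
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/parameter_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
message("truth consensus-first in ", sum(tab$truth_first), "/10 seeds; ",
        "1H shortlist smaller than 13C in ",
        sum(tab$shortlist_1h < tab$shortlist_13c), "/10")
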