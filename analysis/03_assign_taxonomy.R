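#!/usr/bin/env Rscript
# Consensus taxonomy of OTU seeds (>= 80% best-hit similarity, 75% consensus
# with genus-to-domain walk-up), the major-group rollup and the V9
# resolution-profile experiment on the reference database.

source("analysis/common.R")

study <- get_study(seed = 1)
res <- study$res

asg <- cbind(otu_id = res$otus$otus$otu_id,
             res$assignments[, c("status", "label", "rank",
                                 "best_similarity", "lineage")],
             major_group = res$groups)
write_tsv(asg, "assignments.tsv")
write_tsv(res$table3, "major_groups_by_sample.tsv", rownames_as = "group")

# how deep can the V9 region place a sequence when clustered at decreasing
# similarity levels?
prof <- resolution_profile(study$ref$euk_db,
                           levels = c(0.85, 0.90, 0.95, 0.97, 0.99))
write_tsv(prof, "resolution_profile.tsv")

st <- table(res$assignments$status)
message(sprintf("OTUs: %d assigned, %d undetermined, %d unassigned (<80%%)",
                st[["assigned"]],
                if ("undetermined" %in% names(st)) st[["undetermined"]] else 0,
                st[["unassigned"]]))
genus_frac <- prof$fraction[prof$level == 0.99 & prof$rank == "genus"]
message(sprintf("at the 99%% clustering level, %.0f%% of reference sequences keep genus-level consensus",
                100 * genus_frac))
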