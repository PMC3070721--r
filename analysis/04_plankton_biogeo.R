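#!/usr/bin/env Rscript
# Planktonic-origin classification (phototroph taxon list + >= 90% matches to
# environmental marine-plankton sequences) and the cross-sample occupancy and
# region-sharing summaries, with taxonomy profiles of the shared ("bipolar")
# and endemic OTU sets.

source("analysis/common.R")

study <- get_study(seed = 1)
res <- study$res

plank <- res$plankton$summary
if (!is.null(plank$by_group)) {
  write_tsv(plank$by_group, "plankton_by_group.tsv", rownames_as = "group")
}
write_tsv(plank$summary, "plankton_summary.tsv", rownames_as = "quantity")

write_tsv(res$occupancy, "occupancy.tsv")
write_tsv(res$sharing, "region_sharing.tsv")
write_tsv(res$profiles$profile, "sharing_profile_groups.tsv",
          rownames_as = "group")
write_tsv(res$profiles$percent, "sharing_profile_percent.tsv",
          rownames_as = "quantity")

pct <- plank$summary["pct_of_assigned", ]
message(sprintf("putative planktonic OTUs: %.0f-%.0f%% of assigned OTUs per sample",
                min(pct), max(pct)))
occ1 <- res$occupancy
message(sprintf("%d of %d OTUs (%.0f%%) occur in a single sample; the %d OTUs present in all %d samples hold %.0f%% of reads",
                occ1$otus[1], sum(occ1$otus), 100 * occ1$otus[1] / sum(occ1$otus),
                occ1$otus[nrow(occ1)], nrow(occ1),
                100 * occ1$reads[nrow(occ1)] / sum(occ1$reads)))
bip <- res$sharing
message(sprintf("bipolar (all-sample) OTUs: %d holding %d reads; endemic all-region OTUs: ANT %d / ARC %d",
                bip$otus[bip$set == "all_both"], bip$reads[bip$set == "all_both"],
                bip$otus[bip$set == "all_ANT_only"],
                bip$otus[bip$set == "all_ARC_only"]))
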