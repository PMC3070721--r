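#!/usr/bin/env Rscript
# Primer screening, strict dereplication, domain triage and abundance-greedy
# clustering at k = 3 under the homopolymer-insensitive distance. Writes the
# per-sample read-accounting table (total / archaeal / bacterial / non-rRNA /
# eukaryotic reads, unique tags, OTUs), the OTU table and a saturation curve.

source("analysis/common.R")

study <- get_study(seed = 1)
res <- study$res

write_tsv(res$table2, "read_accounting.tsv", rownames_as = "quantity")

otu_tab <- cbind(res$otus$otus[, c("otu_id", "seed_sequence", "n_members",
                                   "total_reads", "single_singleton")],
                 as.data.frame(res$otus$counts))
write_tsv(otu_tab, "otu_table.tsv")

# saturation of OTU discovery with sequencing depth, with and without
# single-singleton OTUs
read_otu <- rep(res$otus$membership$otu_id[
  match(res$euk_tags$tags$tag_id, res$otus$membership$tag_id)],
  res$euk_tags$tags$abundance)
sc_with <- saturation_curve(read_otu, n_points = 20, n_perm = 50, seed = 1)
ss_ids <- res$otus$otus$otu_id[res$otus$otus$single_singleton]
sc_without <- saturation_curve(read_otu[!read_otu %in% ss_ids],
                               n_points = 20, n_perm = 50, seed = 1)
sc <- rbind(cbind(single_singletons = "kept", sc_with),
            cbind(single_singletons = "dropped", sc_without))
write_tsv(sc, "saturation_curve.tsv")

message(sprintf("kept %d/%d reads; %d unique tags; %d eukaryotic tags; %d OTUs (k = %d)",
                nrow(res$screened$kept),
                nrow(res$screened$kept) + nrow(res$screened$rejected),
                nrow(res$tags$tags), nrow(res$euk_tags$tags),
                nrow(res$otus$otus), res$otus$k))
message(sprintf("%d single-singleton OTUs (kept in the main analysis)",
                sum(res$otus$otus$single_singleton)))
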