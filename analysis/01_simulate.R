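#!/usr/bin/env Rscript
# Build the synthetic two-region study: 6 samples (DSE1-3 Southern Ocean,
# DSE4-6 Arctic) x 10,000 reads, 100 eukaryotic taxa with a 40% planktonic
# fraction, prokaryotic and non-rRNA contamination, and 454-style noise
# dominated by homopolymer run-length miscalls. Emits the read sets and
# databases under scratch/sim/ and a community summary under results/.

source("analysis/common.R")

study <- get_study(seed = 1)
p <- study$p; ref <- study$ref; sim <- study$sim

sim_dir <- file.path(SCRATCH_DIR, "sim")
dir.create(sim_dir, showWarnings = FALSE)
for (smp in p$samples$sample) {
  sel <- sim$reads[sim$reads$sample == smp, ]
  write_fasta(sel, file.path(sim_dir, paste0(smp, ".fa")))
}
write_fasta(data.frame(id = ref$full_db$ids,
                       sequence = unname(ref$full_db$seq)),
            file.path(sim_dir, "reference.fa"))
utils::write.table(
  data.frame(id = ref$full_db$ids,
             lineage = apply(ref$full_db$lineage[, -1], 1, function(r) {
               paste(r[!is.na(r)], collapse = ";")
             })),
  file.path(sim_dir, "reference_tax.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE, col.names = FALSE)
write_fasta(data.frame(id = ref$env$db$ids, sequence = unname(ref$env$db$seq)),
            file.path(sim_dir, "env.fa"))
utils::write.table(
  data.frame(id = names(ref$env$habitat), habitat = unname(ref$env$habitat)),
  file.path(sim_dir, "env_habitat.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(sim$truth$reads, file.path(sim_dir, "truth_reads.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$taxa[, setdiff(names(sim$truth$taxa), "sequence")],
                   file.path(sim_dir, "truth_taxa.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# what the community looks like
taxa <- sim$truth$taxa
summary <- data.frame(
  clade = sort(unique(taxa$clade)),
  taxa = as.integer(table(taxa$clade)),
  phototrophic = vapply(sort(unique(taxa$clade)), function(cl) {
    sum(taxa$phototrophic[taxa$clade == cl])
  }, integer(1)),
  planktonic = vapply(sort(unique(taxa$clade)), function(cl) {
    sum(taxa$planktonic[taxa$clade == cl])
  }, integer(1)))
write_tsv(summary, "sim_community.tsv")

reads_per_sample <- table(sim$reads$sample)
message(sprintf("simulated %d reads over %d samples (%s)",
                nrow(sim$reads), length(reads_per_sample),
                paste(sprintf("%s=%d", names(reads_per_sample),
                              as.integer(reads_per_sample)),
                      collapse = ", ")))
message(sprintf("%d taxa: %d planktonic (%d phototrophic), %d bipolar",
                nrow(taxa), sum(taxa$planktonic), sum(taxa$phototrophic),
                sum(taxa$region_class == "bipolar")))
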