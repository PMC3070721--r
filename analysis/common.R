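# Shared setup for the numbered analysis scripts. Builds (or reloads) the
# default synthetic study and its pipeline run so each script stays a thin
# driver. Heavy intermediates live under scratch/ (not part of the
# deliverable); the tables each script reports go under results/.

library(hpotu)

RESULTS_DIR <- "results"
SCRATCH_DIR <- "scratch"
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create(SCRATCH_DIR, showWarnings = FALSE)

get_study <- function(seed = 1) {
  cache <- file.path(SCRATCH_DIR, sprintf("study_seed%d.rds", seed))
  if (file.exists(cache)) return(readRDS(cache))
  message("building the synthetic study (seed ", seed, ") ...")
  p <- sim_params(seed = seed)
  ref <- make_reference(p)
  sim <- simulate_reads(p, ref)
  cfg <- pipeline_config(p$proximal, p$distal,
                         region_map = stats::setNames(p$samples$region,
                                                      p$samples$sample))
  res <- run_pipeline(sim$reads, cfg, ref$euk_db, ref$full_db, ref$env)
  study <- list(p = p, ref = ref, sim = sim, cfg = cfg, res = res)
  saveRDS(study, cache)
  study
}

write_tsv <- function(x, name, rownames_as = NULL) {
  path <- file.path(RESULTS_DIR, name)
  if (!is.null(rownames_as)) {
    x <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE),
                               rownames_as),
               as.data.frame(x, stringsAsFactors = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
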