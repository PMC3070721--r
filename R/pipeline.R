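#' Pipeline configuration with the study defaults
#'
#' Every threshold of the analysis is a named, defaulted field: clustering
#' radius k = 3, assignment floor 0.80, consensus fraction 0.75,
#' environmental-match threshold 0.90, up to 30 hits per query.
#'
#' @param proximal,distal primer pair (read orientation).
#' @param k clustering radius in counted differences.
#' @param assignment_threshold minimum best-hit similarity for assignment.
#' @param consensus_fraction consensus fraction for the rank walk-up.
#' @param env_threshold similarity threshold for environmental matches.
#' @param max_hits hits retained per query.
#' @param drop_single_singletons drop single-singleton OTUs (default FALSE:
#'   the main analysis keeps them).
#' @param region_map named character vector sample -> region.
#' @param seed seed for the rarefaction subsampling.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(proximal, distal, k = 3L,
                            assignment_threshold = 0.80,
                            consensus_fraction = 0.75,
                            env_threshold = 0.90,
                            max_hits = 30L,
                            drop_single_singletons = FALSE,
                            region_map = NULL,
                            seed = 1L) {
  k <- as.integer(k)
  max_hits <- as.integer(max_hits)
  seed <- as.integer(seed)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; `region_map` is a mapping sample -> region.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$region_map)) y$region_map <- unlist(y$region_map)
  do.call(pipeline_config, y)
}

#' Run the full pipeline on a set of reads
#'
#' filter -> dereplicate -> domain triage -> cluster -> assign -> rollup ->
#' plankton -> occupancy/region sharing. Emits the per-sample read-accounting
#' table, the major-group rollup, the plankton summary, the occupancy and
#' region-sharing tables and the taxonomy profiles of shared/endemic OTU
#' sets, together with the intermediate objects. Deterministic given the
#' inputs and config.
#'
#' @param reads data.frame `id`, `sequence`, `sample` (raw reads with
#'   primers).
#' @param config a [pipeline_config()].
#' @param euk_db eukaryotic reference `ref_db`.
#' @param full_db combined `ref_db` with prokaryotic records for triage;
#'   defaults to `euk_db`.
#' @param env environmental database ([load_env_db()]) or NULL to skip the
#'   plankton stage.
#' @param phototrophs phototroph taxon list (default the shipped table).
#' @param grouping major-group rollup table (default the shipped table).
#' @return list of class `pipeline_result`; see Details.
#' @export
run_pipeline <- function(reads, config, euk_db, full_db = euk_db,
                         env = NULL,
                         phototrophs = load_phototrophs(),
                         grouping = load_grouping()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }
  samples <- sort(unique(reads$sample))

  scr <- screen_primers(reads, config$proximal, config$distal)
  note("filter", input = nrow(reads), kept = nrow(scr$kept),
       rejected = nrow(scr$rejected))

  tags <- dereplicate(scr$kept)
  note("dereplicate", tags = nrow(tags$tags), reads = sum(tags$tags$abundance))

  domain <- triage_domain(tags$tags$sequence, full_db,
                          max_hits = config$max_hits)
  domain_reads <- rowsum(tags$counts, group = domain, reorder = TRUE)
  euk_tags <- subset_tags(tags, which(domain == "eukaryotic"))
  note("triage", counts = table(domain))

  otus <- greedy_cluster(euk_tags, k = config$k)
  if (config$drop_single_singletons) {
    otus <- drop_single_singletons(otus)$kept
  }
  note("cluster", otus = nrow(otus$otus))

  asg <- assign_many(otus$otus$seed_sequence, euk_db,
                     assign_params(
                       assignment_threshold = config$assignment_threshold,
                       consensus_fraction = config$consensus_fraction,
                       max_hits = config$max_hits))
  groups <- rollup_major_group(asg$lineage, asg$status, grouping)
  note("assign", assigned = sum(asg$status == "assigned"),
       unassigned = sum(asg$status == "unassigned"),
       undetermined = sum(asg$status == "undetermined"))

  plank <- NULL
  if (!is.null(env)) {
    photo <- flag_phototrophic(asg$lineage, phototrophs)
    envcl <- env_classify(otus$otus$seed_sequence, env,
                          threshold = config$env_threshold,
                          max_hits = config$max_hits)
    calls <- plankton_calls(photo, envcl)
    plank <- list(calls = calls,
                  summary = summarize_plankton(calls, groups, asg$status,
                                               otus$counts))
  }

  # per-sample read accounting
  dr <- function(cls) {
    if (cls %in% rownames(domain_reads)) domain_reads[cls, samples] else
      stats::setNames(rep(0L, length(samples)), samples)
  }
  present <- otus$counts > 0
  tag_present <- euk_tags$counts > 0
  status_f <- factor(asg$status, levels = c("assigned", "undetermined",
                                            "unassigned"))
  table2 <- rbind(
    total_reads = as.integer(table(factor(scr$kept$sample, levels = samples))),
    archaeal_reads = dr("archaeal"),
    bacterial_reads = dr("bacterial"),
    non_rRNA_reads = dr("non_rRNA"),
    eukaryotic_reads = dr("eukaryotic"),
    unique_tags = colSums(tag_present),
    otus = colSums(present),
    assigned = colSums(present[asg$status != "unassigned", , drop = FALSE]),
    unassigned = colSums(present[asg$status == "unassigned", , drop = FALSE]))
  colnames(table2) <- samples

  glev <- sort(unique(groups[asg$status != "unassigned"]))
  table3 <- do.call(rbind, lapply(glev, function(g) {
    colSums(present[groups == g & asg$status != "unassigned", , drop = FALSE])
  }))
  rownames(table3) <- glev
  table3 <- rbind(table3,
                  Subtotal_assigned = colSums(
                    present[asg$status != "unassigned", , drop = FALSE]),
                  Unassigned = colSums(
                    present[asg$status == "unassigned", , drop = FALSE]),
                  Total = colSums(present))

  occ <- sharing <- profiles <- NULL
  if (!is.null(config$region_map)) {
    itab <- incidence_table(otus, config$region_map)
    occ <- occupancy(itab)
    sharing <- region_sharing(itab)
    if (!is.null(plank)) {
      profiles <- sharing_taxonomy_profile(
        sharing, groups, asg$status, plank$calls$putative_planktonic)
    }
  }

  structure(list(
    config = config, log = log,
    screened = scr, tags = tags, domain = domain, euk_tags = euk_tags,
    otus = otus, assignments = asg, groups = groups,
    plankton = plank,
    table2 = table2, table3 = table3,
    occupancy = occ, sharing = sharing, profiles = profiles),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  reads kept: %d (rejected %d)\n",
              nrow(x$screened$kept), nrow(x$screened$rejected)))
  cat(sprintf("  unique tags: %d; eukaryotic: %d\n",
              nrow(x$tags$tags), nrow(x$euk_tags$tags)))
  cat(sprintf("  OTUs (k = %d): %d; assigned %d / undetermined %d / unassigned %d\n",
              x$otus$k, nrow(x$otus$otus),
              sum(x$assignments$status == "assigned"),
              sum(x$assignments$status == "undetermined"),
              sum(x$assignments$status == "unassigned")))
  invisible(x)
}
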