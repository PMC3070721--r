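#' Load the phototroph / exclusively planktonic taxon list
#'
#' One taxon name per line (single column `name`, TSV). The shipped default
#' lists the phototrophic groups usually taken as allochthonous in deep-sea
#' sediment surveys: the green, red and glaucophyte algae, haptophytes,
#' picobiliphytes, diatoms and the other phototrophic stramenopiles, plus
#' Radiolaria (planktonic hosts of algal symbionts). Phototrophic
#' dinoflagellate genera can be appended by the user.
#'
#' @param path TSV path; default the shipped table.
#' @return character vector of taxon names.
#' @export
load_phototrophs <- function(path = system.file("extdata", "phototrophs.tsv",
                                                package = "hpotu")) {
  p <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  stopifnot("name" %in% names(p))
  p$name
}

#' Load an environmental-sequence database with habitat labels
#'
#' @param fasta_path FASTA of environmental V9 sequences.
#' @param habitat_path TSV with columns `id` and `habitat`; habitat is one of
#'   `marine_plankton`, `marine_sediment`, `freshwater_soil`.
#' @return list with `db` (a `ref_db` with habitat as the domain-level
#'   lineage entry is NOT used; lineages are just the habitat) and `habitat`
#'   (named character vector id -> habitat).
#' @export
load_env_db <- function(fasta_path, habitat_path) {
  fa <- read_fasta(fasta_path)
  hab <- utils::read.delim(habitat_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("id", "habitat") %in% names(hab)))
  bad <- setdiff(hab$habitat,
                 c("marine_plankton", "marine_sediment", "freshwater_soil"))
  if (length(bad) > 0) stop("unknown habitat label(s): ",
                            paste(unique(bad), collapse = ", "))
  missing <- setdiff(fa$id, hab$id)
  if (length(missing) > 0) {
    stop("env record(s) without habitat: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  db <- ref_db(fa$id, fa$sequence, rep("env", nrow(fa)))
  habitat <- hab$habitat[match(fa$id, hab$id)]
  names(habitat) <- fa$id
  list(db = db, habitat = habitat)
}

#' Is an assignment phototrophic / exclusively planktonic?
#'
#' True iff any element of the assignment's lineage (or the label itself)
#' matches an entry of the phototroph table. Unassigned OTUs are never
#' phototrophic.
#'
#' @param lineage semicolon lineage path(s), NA for unassigned.
#' @param phototrophs character vector of taxon names ([load_phototrophs()]).
#' @return logical vector.
#' @export
flag_phototrophic <- function(lineage, phototrophs) {
  vapply(lineage, function(lin) {
    if (is.na(lin)) return(FALSE)
    any(strsplit(lin, ";", fixed = TRUE)[[1]] %in% phototrophs)
  }, logical(1), USE.NAMES = FALSE)
}

#' Classify an OTU against the environmental-sequence database
#'
#' Searches the OTU seed sequence against the environmental database with the
#' same machinery as taxonomic assignment and collects the habitats of all
#' hits with similarity at or above the threshold. `env_plankton` is true iff
#' any such hit is from marine plankton; `env_sediment_only` iff hits exist,
#' none is marine plankton and at least one is marine sediment;
#' `env_freshwater_soil` iff any hit is from freshwater or soil.
#'
#' @param seeds character vector of OTU seed sequences.
#' @param env an environmental database from [load_env_db()].
#' @param threshold similarity threshold (default 0.90, boundary inclusive).
#' @param ... passed to [search_db()].
#' @return data.frame `env_plankton`, `env_sediment_only`,
#'   `env_freshwater_soil`, one row per seed.
#' @export
env_classify <- function(seeds, env, threshold = 0.90, ...) {
  hits <- search_db(seeds, env$db, ...)
  hits <- hits[hits$similarity >= threshold, , drop = FALSE]
  hab <- env$habitat[hits$ref_id]
  res <- data.frame(env_plankton = logical(length(seeds)),
                    env_sediment_only = logical(length(seeds)),
                    env_freshwater_soil = logical(length(seeds)))
  for (q in unique(hits$query)) {
    h <- hab[hits$query == q]
    res$env_plankton[q] <- any(h == "marine_plankton")
    res$env_sediment_only[q] <- !any(h == "marine_plankton") &&
      any(h == "marine_sediment")
    res$env_freshwater_soil[q] <- any(h == "freshwater_soil")
  }
  res
}

#' Combine phototroph and environmental evidence per OTU
#'
#' @param phototrophic logical vector from [flag_phototrophic()].
#' @param env data.frame from [env_classify()].
#' @return data.frame with the inputs plus `putative_planktonic`
#'   (`phototrophic | env_plankton`).
#' @export
plankton_calls <- function(phototrophic, env) {
  stopifnot(length(phototrophic) == nrow(env))
  cbind(data.frame(phototrophic = phototrophic), env,
        data.frame(putative_planktonic = phototrophic | env$env_plankton))
}

#' Per-sample plankton summary
#'
#' For each sample: OTU counts per phototrophic group, environmental
#' categories with phototrophic OTUs excluded from the marine-plankton row
#' (so no OTU is double-counted), the putative planktonic total
#' (phototrophic + non-phototrophic marine-plankton matches) and its
#' percentage of all assigned OTUs in the sample.
#'
#' @param calls data.frame from [plankton_calls()], one row per OTU.
#' @param groups major-group label per OTU (phototroph rows are reported by
#'   this label).
#' @param status assignment status per OTU.
#' @param counts OTU x sample incidence/count matrix.
#' @return list with `by_group` (phototroph group x sample OTU counts) and
#'   `summary` (rows marine_plankton, marine_sediment_only, freshwater_soil,
#'   total_phototrophic, putative_planktonic, assigned_otus,
#'   pct_of_assigned x samples).
#' @export
summarize_plankton <- function(calls, groups, status, counts) {
  stopifnot(nrow(calls) == nrow(counts), length(groups) == nrow(counts),
            length(status) == nrow(counts))
  samples <- colnames(counts)
  present <- counts > 0
  photo <- calls$phototrophic
  by_group <- NULL
  if (any(photo)) {
    by_group <- do.call(rbind, lapply(
      sort(unique(groups[photo])), function(g) {
        colSums(present[photo & groups == g, , drop = FALSE])
      }))
    rownames(by_group) <- sort(unique(groups[photo]))
  }
  assigned <- status == "assigned"
  mk <- function(sel) colSums(present[sel, , drop = FALSE])
  summary <- rbind(
    marine_plankton = mk(!photo & calls$env_plankton),
    marine_sediment_only = mk(calls$env_sediment_only),
    freshwater_soil = mk(calls$env_freshwater_soil),
    total_phototrophic = mk(photo),
    putative_planktonic = mk(calls$putative_planktonic),
    assigned_otus = mk(assigned))
  pct <- 100 * summary["putative_planktonic", ] / summary["assigned_otus", ]
  pct[!is.finite(pct)] <- 0
  summary <- rbind(summary, pct_of_assigned = pct)
  colnames(summary) <- samples
  list(by_group = by_group, summary = summary)
}
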