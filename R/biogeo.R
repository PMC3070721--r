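#' Build an incidence table from an otu_set and a region map
#'
#' @param otus an `otu_set`.
#' @param region_map named character vector sample -> region label
#'   (e.g. `c(DSE1 = "ANT", ..., DSE4 = "ARC", ...)`).
#' @return list of class `incidence_table` with `counts` (OTU x sample read
#'   counts) and `region` (per-sample region labels, aligned with columns).
#' @export
incidence_table <- function(otus, region_map) {
  counts <- if (inherits(otus, "otu_set")) otus$counts else otus
  stopifnot(is.matrix(counts), all(counts >= 0))
  missing <- setdiff(colnames(counts), names(region_map))
  if (length(missing) > 0) {
    stop("sample(s) without region: ", paste(missing, collapse = ", "))
  }
  structure(list(counts = counts,
                 region = region_map[colnames(counts)]),
            class = "incidence_table")
}

#' OTU and read counts by number of samples occupied
#'
#' An OTU occupies a sample when its read count there is at least 1. OTUs are
#' classed by their occupancy n = 1..S and reads summed per class, so the
#' classes partition both OTUs and reads exactly.
#'
#' @param tab an `incidence_table` (or bare count matrix).
#' @return data.frame `samples` (n), `otus`, `reads`.
#' @export
occupancy <- function(tab) {
  counts <- if (inherits(tab, "incidence_table")) tab$counts else tab
  S <- ncol(counts)
  if (S < 1) stop("need at least one sample")
  if (nrow(counts) == 0) {
    return(data.frame(samples = seq_len(S), otus = 0L, reads = 0L))
  }
  occ <- rowSums(counts > 0)
  reads <- rowSums(counts)
  data.frame(
    samples = seq_len(S),
    otus = vapply(seq_len(S), function(n) sum(occ == n), integer(1)),
    reads = vapply(seq_len(S), function(n) sum(reads[occ == n]), numeric(1)))
}

#' Region-sharing summary for a two-region design
#'
#' Computes, with both OTU and read totals:
#' * `all_both`: OTUs present in every sample of both regions;
#' * `all_<region>_only`: present in all samples of that region, absent from
#'   the other region entirely;
#' * `min1_both`: present in at least one sample of each region;
#' * `min1_<region>_only`: present in at least one sample of that region and
#'   absent from the other.
#' The min-1 categories partition all OTUs.
#'
#' @param tab an `incidence_table` with exactly two regions.
#' @return data.frame `set`, `otus`, `reads`.
#' @export
region_sharing <- function(tab) {
  stopifnot(inherits(tab, "incidence_table"))
  regions <- sort(unique(tab$region))
  if (length(regions) != 2) stop("region_sharing needs exactly 2 regions")
  if (any(table(factor(tab$region, levels = regions)) == 0)) {
    stop("a region has no samples")
  }
  pres <- tab$counts > 0
  reads <- rowSums(tab$counts)
  r1 <- tab$region == regions[1]
  r2 <- tab$region == regions[2]
  in_all_r1 <- rowSums(pres[, r1, drop = FALSE]) == sum(r1)
  in_all_r2 <- rowSums(pres[, r2, drop = FALSE]) == sum(r2)
  in_any_r1 <- rowSums(pres[, r1, drop = FALSE]) > 0
  in_any_r2 <- rowSums(pres[, r2, drop = FALSE]) > 0
  sets <- list(
    all_both = in_all_r1 & in_all_r2,
    min1_both = in_any_r1 & in_any_r2)
  sets[[paste0("all_", regions[1], "_only")]] <- in_all_r1 & !in_any_r2
  sets[[paste0("all_", regions[2], "_only")]] <- in_all_r2 & !in_any_r1
  sets[[paste0("min1_", regions[1], "_only")]] <- in_any_r1 & !in_any_r2
  sets[[paste0("min1_", regions[2], "_only")]] <- in_any_r2 & !in_any_r1
  out <- data.frame(
    set = names(sets),
    otus = vapply(sets, sum, integer(1)),
    reads = vapply(sets, function(s) sum(reads[s]), numeric(1)))
  rownames(out) <- NULL
  attr(out, "membership") <- sets
  out
}

#' Taxonomy profile of shared and endemic OTU sets
#'
#' For each OTU set from [region_sharing()]: OTU counts per major group,
#' percent putatively planktonic and percent unassigned.
#'
#' @param sharing output of [region_sharing()] (carries set membership).
#' @param groups major-group label per OTU.
#' @param status assignment status per OTU.
#' @param planktonic logical per OTU.
#' @param sets which sets to profile (default the all-samples sets).
#' @return list with `profile` (group x set OTU counts) and `percent`
#'   (rows pct_planktonic, pct_unassigned, n_otus x sets).
#' @export
sharing_taxonomy_profile <- function(sharing, groups, status, planktonic,
                                     sets = grep("^all_",
                                                 sharing$set, value = TRUE)) {
  membership <- attr(sharing, "membership")
  stopifnot(!is.null(membership))
  glev <- sort(unique(groups))
  prof <- sapply(sets, function(s) {
    sel <- membership[[s]]
    vapply(glev, function(g) sum(sel & groups == g), integer(1))
  })
  prof <- matrix(prof, nrow = length(glev), dimnames = list(glev, sets))
  pct <- sapply(sets, function(s) {
    sel <- membership[[s]]
    n <- sum(sel)
    c(pct_planktonic = if (n > 0) 100 * sum(planktonic & sel) / n else 0,
      pct_unassigned = if (n > 0) 100 * sum(status[sel] == "unassigned") / n else 0,
      n_otus = n)
  })
  list(profile = prof, percent = pct)
}
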