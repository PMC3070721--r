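#' Strict dereplication of primer-trimmed reads
#'
#' Exactly identical sequences are grouped as one unique tag carrying its
#' total occurrence count and per-sample counts. Tags are sorted by decreasing
#' abundance, ties broken lexicographically by sequence so the ordering is a
#' total order and the whole pipeline is deterministic.
#'
#' @param reads data.frame with `id`, `sequence`, `sample` (primer-trimmed).
#' @return An object of class `tag_table`: a list with
#'   * `tags`: data.frame `tag_id`, `sequence`, `abundance`, `rep_id`
#'     (id of the first read observed for the tag, in input order);
#'   * `counts`: integer matrix tags x samples of read counts.
#' @export
dereplicate <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence", "sample") %in% names(reads)))
  if (nrow(reads) == 0) {
    return(structure(list(
      tags = data.frame(tag_id = character(), sequence = character(),
                        abundance = integer(), rep_id = character(),
                        stringsAsFactors = FALSE),
      counts = matrix(0L, 0, 0)), class = "tag_table"))
  }
  seqf <- factor(reads$sequence)
  ab <- as.integer(table(seqf))
  uniq <- levels(seqf)
  ord <- order(-ab, uniq)
  uniq <- uniq[ord]
  ab <- ab[ord]
  first_idx <- tapply(seq_len(nrow(reads)), seqf, min)
  rep_id <- reads$id[first_idx[uniq]]
  samples <- sort(unique(reads$sample))
  counts <- table(seqf, factor(reads$sample, levels = samples))
  counts <- matrix(as.integer(counts), nrow = nlevels(seqf),
                   dimnames = list(levels(seqf), samples))[uniq, , drop = FALSE]
  tag_id <- sprintf("tag%06d", seq_along(uniq))
  rownames(counts) <- tag_id
  structure(list(
    tags = data.frame(tag_id = tag_id, sequence = uniq, abundance = ab,
                      rep_id = rep_id, stringsAsFactors = FALSE),
    counts = counts), class = "tag_table")
}

#' @export
print.tag_table <- function(x, ...) {
  cat(sprintf("tag_table: %d unique tags, %d reads, %d sample(s)\n",
              nrow(x$tags), sum(x$tags$abundance), ncol(x$counts)))
  invisible(x)
}

#' Subset a tag_table by tag index or tag_id
#'
#' @param x a `tag_table`.
#' @param i integer or character index into the tags.
#' @return A `tag_table` with the selected tags, order preserved.
#' @export
subset_tags <- function(x, i) {
  stopifnot(inherits(x, "tag_table"))
  if (is.character(i)) i <- match(i, x$tags$tag_id)
  structure(list(tags = x$tags[i, , drop = FALSE],
                 counts = x$counts[i, , drop = FALSE]),
            class = "tag_table")
}

#' Abundance-greedy OTU clustering at k differences
#'
#' Single pass in decreasing-abundance order: the most abundant unassigned tag
#' becomes a seed; every later unassigned tag within `k` counted differences
#' of that seed (under [hp_distance()]) joins it; then the next most abundant
#' unassigned tag seeds the next OTU, until all tags are assigned. Tags join
#' the first seed they are within `k` of and are never re-assigned to a closer
#' later seed.
#'
#' @param tags a `tag_table` as produced by [dereplicate()] (sorted by
#'   decreasing abundance, ties lexicographic).
#' @param k non-negative integer radius (default 3).
#' @return An object of class `otu_set`: a list with
#'   * `otus`: data.frame `otu_id`, `seed_tag`, `seed_sequence`, `n_members`,
#'     `total_reads`, `single_singleton`;
#'   * `counts`: integer matrix OTUs x samples of read counts;
#'   * `membership`: data.frame `tag_id`, `otu_id`;
#'   * `k`: the radius used.
#' @export
greedy_cluster <- function(tags, k = 3L) {
  stopifnot(inherits(tags, "tag_table"), k >= 0)
  tg <- tags$tags
  if (nrow(tg) == 0) {
    return(structure(list(
      otus = data.frame(otu_id = character(), seed_tag = character(),
                        seed_sequence = character(), n_members = integer(),
                        total_reads = integer(), single_singleton = logical(),
                        stringsAsFactors = FALSE),
      counts = tags$counts, membership = data.frame(tag_id = character(),
                                                    otu_id = character()),
      k = as.integer(k)), class = "otu_set"))
  }
  if (is.unsorted(rev(tg$abundance)) ||
      any(diff(tg$abundance) == 0 &
          utils::head(tg$sequence, -1) > utils::tail(tg$sequence, -1))) {
    stop("tags must be sorted by decreasing abundance (ties lexicographic); ",
         "use dereplicate()")
  }
  assign <- .greedy_cluster_cpp(tg$sequence, as.integer(k))
  n_otu <- max(assign)
  otu_id <- sprintf("otu%05d", seq_len(n_otu))
  seed_idx <- match(seq_len(n_otu), assign)  # first tag of each OTU is its seed
  total_reads <- as.integer(tapply(tg$abundance, assign, sum))
  n_members <- as.integer(table(assign))
  counts <- rowsum(tags$counts, group = assign, reorder = TRUE)
  rownames(counts) <- otu_id
  structure(list(
    otus = data.frame(
      otu_id = otu_id,
      seed_tag = tg$tag_id[seed_idx],
      seed_sequence = tg$sequence[seed_idx],
      n_members = n_members,
      total_reads = total_reads,
      single_singleton = n_members == 1L & total_reads == 1L,
      stringsAsFactors = FALSE),
    counts = counts,
    membership = data.frame(tag_id = tg$tag_id, otu_id = otu_id[assign],
                            stringsAsFactors = FALSE),
    k = as.integer(k)), class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  cat(sprintf("otu_set: %d OTUs (k = %d), %d reads, %d sample(s); %d single-singletons\n",
              nrow(x$otus), x$k, sum(x$otus$total_reads), ncol(x$counts),
              sum(x$otus$single_singleton)))
  invisible(x)
}

#' Partition OTUs into single-singletons and the rest
#'
#' A single-singleton is an OTU consisting of exactly one unique sequence
#' observed exactly once; such clusters often reflect large sequencing
#' errors. The pipeline's default is to KEEP them (rare tags are of genuine
#' interest in under-sampled habitats); this helper exposes the filtered
#' variant for sensitivity analyses.
#'
#' @param otus an `otu_set`.
#' @return list with `kept` and `dropped` `otu_set`s partitioning the input.
#' @export
drop_single_singletons <- function(otus) {
  stopifnot(inherits(otus, "otu_set"))
  ss <- otus$otus$single_singleton
  pick <- function(keep) {
    ids <- otus$otus$otu_id[keep]
    structure(list(
      otus = otus$otus[keep, , drop = FALSE],
      counts = otus$counts[keep, , drop = FALSE],
      membership = otus$membership[otus$membership$otu_id %in% ids, , drop = FALSE],
      k = otus$k), class = "otu_set")
  }
  list(kept = pick(!ss), dropped = pick(ss))
}

#' OTU saturation (rarefaction) curve
#'
#' Expected number of distinct OTUs observed as a function of the number of
#' reads subsampled without replacement, averaged over `n_perm` seeded
#' permutations.
#'
#' @param read_otu character vector: the OTU id of every read.
#' @param n_points number of subsample sizes (evenly spaced up to the read
#'   count); clipped with a warning if it exceeds the read count.
#' @param n_perm number of random subsamples per size (default 100).
#' @param seed RNG seed (default 1).
#' @return data.frame `reads`, `mean_otus`, `sd_otus`.
#' @export
saturation_curve <- function(read_otu, n_points = 20L, n_perm = 100L, seed = 1L) {
  stopifnot(n_perm >= 1)
  n <- length(read_otu)
  if (n == 0) stop("no reads")
  if (n_points > n) {
    warning("n_points exceeds read count; clipped to ", n)
    n_points <- n
  }
  sizes <- unique(round(seq(1, n, length.out = n_points)))
  f <- as.integer(factor(read_otu))
  set.seed(seed)
  # nested subsamples: one permutation per replicate, prefix counts; this
  # makes every replicate (and hence the mean) monotone in subsample size
  per_perm <- vapply(seq_len(n_perm), function(p) {
    perm <- f[sample.int(n, n)]
    cum_new <- cumsum(!duplicated(perm))
    cum_new[sizes]
  }, numeric(length(sizes)))
  per_perm <- matrix(per_perm, nrow = length(sizes))
  data.frame(reads = sizes,
             mean_otus = rowMeans(per_perm),
             sd_otus = apply(per_perm, 1, function(v) {
               if (length(v) > 1) stats::sd(v) else 0
             }))
}
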