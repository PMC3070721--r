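#' Taxonomic ranks used by the pipeline, deepest last
#' @export
TAX_RANKS <- c("domain", "kingdom", "phylum", "class", "order", "family",
               "genus", "species")

#' Load a reference database (FASTA + taxonomy TSV)
#'
#' The taxonomy TSV has two tab-separated columns: the record id and the
#' ranked lineage `domain;kingdom;phylum;class;order;family;genus[;species]`.
#' Lineages may be ragged (missing deep ranks); missing ranks are NA.
#'
#' @param fasta_path FASTA of reference sequences (V9 region).
#' @param tax_path taxonomy TSV; every FASTA id must have a row.
#' @return An object of class `ref_db`: list with `ids`, `seq` (named
#'   character) and `lineage` (data.frame, one column per rank in
#'   [TAX_RANKS]).
#' @export
load_reference <- function(fasta_path, tax_path) {
  fa <- read_fasta(fasta_path)
  tax <- utils::read.delim(tax_path, header = FALSE, sep = "\t",
                           col.names = c("id", "lineage"),
                           stringsAsFactors = FALSE, quote = "")
  if (anyDuplicated(fa$id)) stop("duplicate reference ids in FASTA")
  if (anyDuplicated(tax$id)) stop("duplicate ids in taxonomy table")
  missing <- setdiff(fa$id, tax$id)
  if (length(missing) > 0) {
    stop("reference id(s) without lineage: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  tax <- tax[match(fa$id, tax$id), ]
  ref_db(fa$id, fa$sequence, tax$lineage)
}

#' Construct a reference database from vectors
#'
#' @param ids,sequences,lineages parallel character vectors; lineages are
#'   semicolon-separated ranked paths (domain first).
#' @return A `ref_db` object; see [load_reference()].
#' @export
ref_db <- function(ids, sequences, lineages) {
  stopifnot(length(ids) == length(sequences), length(ids) == length(lineages))
  if (anyDuplicated(ids)) stop("duplicate reference ids")
  parts <- strsplit(lineages, ";", fixed = TRUE)
  if (any(lengths(parts) > length(TAX_RANKS))) {
    stop("lineage deeper than ", length(TAX_RANKS), " ranks")
  }
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    c(p, rep(NA_character_, length(TAX_RANKS) - length(p)))
  })
  lin <- as.data.frame(
    matrix(as.character(unlist(rows)), nrow = length(rows),
           ncol = length(TAX_RANKS), byrow = TRUE,
           dimnames = list(NULL, TAX_RANKS)),
    stringsAsFactors = FALSE)
  lin <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), lin)
  seqs <- toupper(sequences)
  names(seqs) <- ids
  structure(list(ids = ids, seq = seqs, lineage = lin), class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("ref_db: %d sequences, %d with genus-level lineage\n",
              length(x$ids), sum(!is.na(x$lineage$genus))))
  invisible(x)
}

#' Excise the V9 region from full-length SSU reference sequences
#'
#' For each record where both primers match (IUPAC-aware; first proximal
#' match, last distal match after it), the between-primer region is emitted.
#' Records without both sites are skipped and counted.
#'
#' @param records data.frame with `id`, `sequence` (full-length SSU).
#' @param proximal,distal primer sequences, distal in the sense of the
#'   emitted region's orientation.
#' @return list with `v9` (data.frame `id`, `sequence`) and `n_skipped`.
#' @export
extract_v9 <- function(records, proximal, distal) {
  re_p <- iupac_regex(proximal)
  re_d <- iupac_regex(distal)
  out_id <- character(0); out_seq <- character(0); skipped <- 0L
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    mp <- regexpr(re_p, s)
    if (mp == -1) { skipped <- skipped + 1L; next }
    start <- mp + attr(mp, "match.length")
    md <- gregexpr(re_d, s)[[1]]
    md <- md[md >= start]
    if (length(md) == 0 || md[1] == -1) { skipped <- skipped + 1L; next }
    end <- md[length(md)]
    if (end <= start) { skipped <- skipped + 1L; next }
    out_id <- c(out_id, records$id[i])
    out_seq <- c(out_seq, substr(s, start, end - 1))
  }
  list(v9 = data.frame(id = out_id, sequence = out_seq,
                       stringsAsFactors = FALSE),
       n_skipped = skipped)
}

#' Similarity of a hit from its High Scoring Pairs
#'
#' `sum(identities - gaps) / query_length`, summed over a maximal-score set
#' of HSPs that do not overlap on query coordinates (greedy by descending
#' score, skipping any HSP that overlaps an already accepted one), floored at
#' 0 and capped at 1. Summing over non-overlapping HSPs and dividing by the
#' full query length is deliberately stringent: a hit covering only a
#' conserved fragment of the query cannot reach a high similarity.
#'
#' @param hsps data.frame with columns `q_start`, `q_end` (0-based half-open
#'   query coordinates), `identities`, `gaps`, `score`.
#' @param query_length length of the query sequence (> 0).
#' @return fraction in `[0, 1]`.
#' @export
hit_similarity <- function(hsps, query_length) {
  stopifnot(query_length > 0)
  if (nrow(hsps) == 0) return(0)
  stopifnot(all(hsps$q_end > hsps$q_start))
  ord <- order(-hsps$score)
  acc <- integer(0)
  for (i in ord) {
    overlaps <- any(hsps$q_start[i] < hsps$q_end[acc] &
                    hsps$q_end[i] > hsps$q_start[acc])
    if (!overlaps) acc <- c(acc, i)
  }
  s <- sum(hsps$identities[acc] - hsps$gaps[acc]) / query_length
  min(max(s, 0), 1)
}

#' Search query sequences against a reference database
#'
#' A built-in seeded local aligner: references sharing at least
#' `min_shared_words` words of length `word_size` with the query are aligned
#' by affine-gap Smith-Waterman with BLAST-like scoring (match +5, mismatch
#' -4, gap open 8, gap extend 6); each alignment yields one HSP, whose
#' similarity is `(identities - gaps) / query length` as in
#' [hit_similarity()]. Hits below `min_similarity` are not reported (the
#' aligner's analogue of an E-value cutoff). Parsed external BLAST XML
#' ([read_blast_xml()]) flows into the same Hit structure.
#'
#' @param queries character vector of query sequences (names optional).
#' @param db a `ref_db`.
#' @param max_hits retain at most this many hits per query (default 30).
#' @param min_similarity do not report hits below this similarity.
#' @param word_size seed word length (default 7).
#' @param min_shared_words minimum shared word count to trigger an alignment.
#' @return data.frame with `query` (index into `queries`), `ref_id`,
#'   `similarity`, `score`, `identities`, `gaps`, `q_start`, `q_end`, ordered
#'   by query then decreasing similarity.
#' @export
search_db <- function(queries, db, max_hits = 30L, min_similarity = 0.30,
                      word_size = 7L, min_shared_words = 4L) {
  stopifnot(inherits(db, "ref_db"))
  if (length(db$ids) == 0) stop("reference database is empty")
  raw <- .search_many_cpp(queries, unname(db$seq),
                          as.integer(word_size), as.integer(min_shared_words))
  hits <- data.frame(query = raw$query,
                     ref_id = db$ids[raw$ref],
                     score = raw$score,
                     identities = raw$identities,
                     gaps = raw$gaps,
                     q_start = raw$q_start,
                     q_end = raw$q_end,
                     stringsAsFactors = FALSE)
  qlen <- nchar(queries)[hits$query]
  hits$similarity <- pmin(pmax((hits$identities - hits$gaps) / qlen, 0), 1)
  hits <- hits[hits$similarity >= min_similarity, , drop = FALSE]
  hits <- hits[order(hits$query, -hits$similarity, hits$ref_id), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query), function(ix) {
    utils::head(ix, max_hits)
  }), use.names = FALSE)
  hits <- hits[sort(keep), c("query", "ref_id", "similarity", "score",
                             "identities", "gaps", "q_start", "q_end")]
  rownames(hits) <- NULL
  hits
}

#' Assignment parameter defaults
#'
#' @param assignment_threshold minimum best-hit similarity for a sequence to
#'   be assigned at all (default 0.80).
#' @param consensus_fraction fraction of good hits that must share a name at
#'   a rank for consensus (default 0.75).
#' @param max_hits hits retained per query (default 30).
#' @param threshold_ladder similarity thresholds explored when profiling
#'   assignment depth.
#' @param use_species include the species rank in the walk-up (default off;
#'   the V9 region rarely resolves below genus).
#' @return list of parameters.
#' @export
assign_params <- function(assignment_threshold = 0.80,
                          consensus_fraction = 0.75,
                          max_hits = 30L,
                          threshold_ladder = c(0.70, 0.75, 0.80, 0.85, 0.90,
                                               0.92, 0.95, 0.96, 0.97, 0.98,
                                               0.99, 1.00),
                          use_species = FALSE) {
  stopifnot(assignment_threshold > 0, assignment_threshold <= 1,
            consensus_fraction > 0, consensus_fraction <= 1,
            !is.unsorted(threshold_ladder, strictly = TRUE))
  list(assignment_threshold = assignment_threshold,
       consensus_fraction = consensus_fraction,
       max_hits = as.integer(max_hits),
       threshold_ladder = threshold_ladder,
       use_species = use_species)
}

#' Consensus taxonomic assignment with rank walk-up
#'
#' Good hits are the retained hits with similarity at or above the assignment
#' threshold. If there are none the query is `unassigned`. Otherwise ranks
#' are walked genus, family, order, class, phylum, kingdom, domain: at the
#' first rank where at least `consensus_fraction` of the good hits that carry
#' a name at that rank share one name, that name and rank are returned. If no
#' rank reaches consensus the query is `undetermined`.
#'
#' @param hits data.frame of hits for ONE query (`ref_id`, `similarity`),
#'   sorted by decreasing similarity.
#' @param db the `ref_db` the hits refer to.
#' @param params an [assign_params()] list.
#' @return list with `status` (assigned/unassigned/undetermined), `label`,
#'   `rank`, `best_similarity`, `threshold_used`, `lineage` (semicolon path
#'   down to the assigned rank, or NA).
#' @export
assign_consensus <- function(hits, db, params = assign_params()) {
  stopifnot(inherits(db, "ref_db"))
  out <- list(status = "unassigned", label = NA_character_,
              rank = NA_character_, best_similarity = 0,
              threshold_used = params$assignment_threshold,
              lineage = NA_character_)
  if (is.null(hits) || nrow(hits) == 0) return(out)
  out$best_similarity <- max(hits$similarity)
  good <- hits[hits$similarity >= params$assignment_threshold, , drop = FALSE]
  if (nrow(good) == 0) return(out)
  lin <- db$lineage[match(good$ref_id, db$ids), , drop = FALSE]
  deepest <- if (params$use_species) "species" else "genus"
  walk <- rev(TAX_RANKS[seq_len(match(deepest, TAX_RANKS))])
  for (rk in walk) {
    nm <- lin[[rk]]
    nm <- nm[!is.na(nm)]
    if (length(nm) == 0) next
    tab <- sort(table(nm), decreasing = TRUE)
    if (tab[1] / length(nm) >= params$consensus_fraction) {
      label <- names(tab)[1]
      # lineage path of the consensus taxon, taken from the first good hit
      # that carries it
      ri <- which(lin[[rk]] %in% label)[1]
      path <- unlist(lin[ri, TAX_RANKS[seq_len(match(rk, TAX_RANKS))]])
      out$status <- "assigned"
      out$label <- label
      out$rank <- rk
      out$lineage <- paste(path, collapse = ";")
      return(out)
    }
  }
  out$status <- "undetermined"
  out
}

#' Assign many queries at once
#'
#' Runs [search_db()] and [assign_consensus()] for each query.
#'
#' @param queries character vector of sequences.
#' @param db a `ref_db`.
#' @param params an [assign_params()] list.
#' @param hits optional precomputed hit table from [search_db()] or
#'   [read_blast_xml()]; if supplied the search is skipped.
#' @return data.frame with one row per query: `query`, `status`, `label`,
#'   `rank`, `best_similarity`, `lineage`.
#' @export
assign_many <- function(queries, db, params = assign_params(), hits = NULL) {
  if (is.null(hits)) {
    hits <- search_db(queries, db, max_hits = params$max_hits)
  }
  byq <- split(hits, hits$query)
  res <- lapply(seq_along(queries), function(i) {
    a <- assign_consensus(byq[[as.character(i)]], db, params)
    data.frame(query = i, status = a$status, label = a$label, rank = a$rank,
               best_similarity = a$best_similarity, lineage = a$lineage,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Domain-level triage of unique tags
#'
#' Each tag is classed by the domain of its best hit against a combined
#' (eukaryote + prokaryote) reference database; tags with no reported hit at
#' all are counted as non-rRNA. Only eukaryotic tags proceed downstream.
#'
#' @param sequences character vector of tag sequences.
#' @param db combined `ref_db` whose lineages carry `Eukaryota`, `Archaea` or
#'   `Bacteria` at the domain rank.
#' @param ... passed to [search_db()].
#' @return character vector over
#'   `c("eukaryotic", "archaeal", "bacterial", "non_rRNA")`, one per input.
#' @export
triage_domain <- function(sequences, db, ...) {
  hits <- search_db(sequences, db, ...)
  cls <- rep("non_rRNA", length(sequences))
  if (nrow(hits) > 0) {
    best <- hits[!duplicated(hits$query), ]  # hits are sorted by similarity
    dom <- db$lineage$domain[match(best$ref_id, db$ids)]
    cls[best$query] <- c(Eukaryota = "eukaryotic", Archaea = "archaeal",
                         Bacteria = "bacterial")[dom]
    cls[is.na(cls)] <- "non_rRNA"
  }
  cls
}

#' Load a major-group rollup table
#'
#' Two tab-separated columns: a lineage name and the major group it maps to.
#' Overlapping rules (the same name twice) are a load error. The package
#' ships a default table reproducing the standard major eukaryotic groups
#' (Ciliophora, Dinophyceae, other Alveolata, ..., CCTH, other Eukarya).
#'
#' @param path TSV path; default the shipped table.
#' @return data.frame `name`, `group`.
#' @export
load_grouping <- function(path = system.file("extdata", "major_groups.tsv",
                                             package = "hpotu")) {
  g <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("name", "group") %in% names(g)))
  if (anyDuplicated(g$name)) {
    stop("overlapping rollup rules for: ",
         paste(unique(g$name[duplicated(g$name)]), collapse = ", "))
  }
  g
}

#' Roll an assignment up to its major eukaryotic group
#'
#' The deepest lineage component present in the grouping table wins;
#' assignments matching no rule map to `Undetermined`; unassigned stay
#' `Unassigned`; status `undetermined` maps to `Undetermined`.
#'
#' @param lineage semicolon lineage path (or NA).
#' @param status assignment status.
#' @param grouping data.frame from [load_grouping()].
#' @return major-group label (character).
#' @export
rollup_major_group <- function(lineage, status, grouping) {
  mapply(function(lin, st) {
    if (st == "unassigned") return("Unassigned")
    if (st == "undetermined" || is.na(lin)) return("Undetermined")
    parts <- rev(strsplit(lin, ";", fixed = TRUE)[[1]])
    hit <- match(parts, grouping$name)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) "Undetermined" else grouping$group[hit[1]]
  }, lineage, status, USE.NAMES = FALSE)
}

#' Taxonomic resolution profile of a reference database
#'
#' Clusters the reference V9 sequences greedily at each similarity level and
#' scores, per cluster, the deepest rank at which all members agree. Reports,
#' for each level and rank, the fraction of sequences lying in clusters whose
#' consensus is at that rank or deeper. Two clustering criteria are exposed:
#' `identity` (global-alignment identity fraction at or above the level) and
#' `hp` (within k counted differences under the homopolymer-insensitive
#' distance, k = round((1 - level) * median sequence length)).
#'
#' @param db a `ref_db`.
#' @param levels similarity levels (default 0.85-0.99).
#' @param method `"identity"` or `"hp"`.
#' @return data.frame `level`, `rank`, `fraction` (of sequences in clusters
#'   with consensus at that rank or deeper).
#' @export
resolution_profile <- function(db, levels = c(0.85, 0.90, 0.95, 0.97, 0.99),
                               method = c("identity", "hp")) {
  stopifnot(inherits(db, "ref_db"))
  if (length(db$ids) == 0) stop("reference database is empty")
  method <- match.arg(method)
  seqs <- unname(db$seq)
  med_len <- stats::median(nchar(seqs))
  walk_ranks <- TAX_RANKS[TAX_RANKS != "species"]
  out <- list()
  for (lev in levels) {
    k <- as.integer(round((1 - lev) * med_len))
    centroids <- integer(0)
    member_of <- integer(length(seqs))
    for (i in seq_along(seqs)) {
      placed <- FALSE
      for (ci in centroids) {
        ok <- if (method == "identity") {
          global_identity(seqs[ci], seqs[i]) >= lev
        } else {
          within_k(seqs[ci], seqs[i], k)
        }
        if (ok) { member_of[i] <- member_of[ci]; placed <- TRUE; break }
      }
      if (!placed) {
        centroids <- c(centroids, i)
        member_of[i] <- length(centroids)
      }
    }
    # deepest unanimous rank per cluster
    depth <- vapply(split(seq_along(seqs), member_of), function(ix) {
      lin <- db$lineage[ix, , drop = FALSE]
      d <- 0L
      for (r in seq_along(walk_ranks)) {
        nm <- lin[[walk_ranks[r]]]
        if (any(is.na(nm)) || length(unique(nm)) != 1) break
        d <- r
      }
      d
    }, integer(1))
    sizes <- as.integer(table(member_of))
    for (r in seq_along(walk_ranks)) {
      out[[length(out) + 1]] <- data.frame(
        level = lev, rank = walk_ranks[r],
        fraction = sum(sizes[depth >= r]) / length(seqs))
    }
  }
  do.call(rbind, out)
}
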