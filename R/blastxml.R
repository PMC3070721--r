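#' Read NCBI BLAST XML output into the pipeline's Hit structure
#'
#' Parses the XML produced by `blastn ... -outfmt 5` (or legacy `-m 7`) and
#' returns the same hit table as [search_db()]: one row per query/reference pair
#' with a similarity computed by [hit_similarity()] over the pair's
#' non-overlapping HSPs. Query coordinates are converted to 0-based
#' half-open.
#'
#' @param path BLAST XML file.
#' @param max_hits retain at most this many hits per query (default 30).
#' @param min_similarity drop hits below this similarity (default 0; BLAST
#'   already applied its own E-value cutoff).
#' @return data.frame `query` (query definition line), `ref_id`,
#'   `similarity`, `score`, `identities`, `gaps`, `q_start`, `q_end`
#'   (the span and HSP stats of the best-scoring HSP; `similarity` uses all
#'   non-overlapping HSPs), ordered by query then decreasing similarity.
#' @export
read_blast_xml <- function(path, max_hits = 30L, min_similarity = 0) {
  doc <- xml2::read_xml(path)
  iters <- xml2::xml_find_all(doc, ".//Iteration")
  rows <- list()
  for (it in iters) {
    qdef <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-def"))
    qlen <- as.integer(xml2::xml_text(
      xml2::xml_find_first(it, "./Iteration_query-len")))
    for (hit in xml2::xml_find_all(it, ".//Hit")) {
      rid <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_def"))
      if (is.na(rid) || !nzchar(rid)) {
        rid <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_accession"))
      }
      hsp_nodes <- xml2::xml_find_all(hit, ".//Hsp")
      num <- function(node, field) {
        as.numeric(xml2::xml_text(xml2::xml_find_first(node, field)))
      }
      hsps <- do.call(rbind, lapply(hsp_nodes, function(h) {
        qf <- num(h, "./Hsp_query-from"); qt <- num(h, "./Hsp_query-to")
        data.frame(q_start = min(qf, qt) - 1, q_end = max(qf, qt),
                   identities = num(h, "./Hsp_identity"),
                   gaps = num(h, "./Hsp_gaps"),
                   score = num(h, "./Hsp_score"))
      }))
      if (is.null(hsps) || nrow(hsps) == 0) next
      hsps$gaps[is.na(hsps$gaps)] <- 0
      sim <- hit_similarity(hsps, qlen)
      best <- hsps[which.max(hsps$score), ]
      rows[[length(rows) + 1]] <- data.frame(
        query = qdef, ref_id = rid, similarity = sim, score = best$score,
        identities = best$identities, gaps = best$gaps,
        q_start = best$q_start, q_end = best$q_end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(query = character(), ref_id = character(),
                      similarity = numeric(), score = numeric(),
                      identities = numeric(), gaps = numeric(),
                      q_start = numeric(), q_end = numeric(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[hits$similarity >= min_similarity, , drop = FALSE]
  hits <- hits[order(hits$query, -hits$similarity, hits$ref_id), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query), function(ix) {
    utils::head(ix, max_hits)
  }), use.names = FALSE)
  hits <- hits[sort(keep), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
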