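IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_regex <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in primer: ", paste(unique(bad), collapse = ", "))
  }
  paste0(vapply(chars, function(ch) {
    alt <- IUPAC_MAP[[ch]]
    if (nchar(alt) == 1) alt else paste0("[", alt, "]")
  }, character(1)), collapse = "")
}

#' Read a FASTA file of amplicon reads
#'
#' Sequences are uppercased and U is mapped to T. Each record becomes one row
#' labelled with the supplied sample name.
#'
#' @param path FASTA file.
#' @param sample sample label attached to every read in the file.
#' @return A data.frame with columns `id`, `sequence`, `sample`.
#' @export
read_fasta <- function(path, sample = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(ss) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      sample = character(), stringsAsFactors = FALSE))
  }
  seqs <- chartr("u", "t", as.character(ss))
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), sample = sample,
             stringsAsFactors = FALSE)
}

#' Write reads or tags to FASTA
#'
#' When `sizes` is supplied, headers follow the usual dereplication dialect
#' `id;size=N`.
#'
#' @param x data.frame with columns `id` and `sequence`.
#' @param path output file.
#' @param sizes optional integer abundances, one per record.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, sizes = NULL) {
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  if (anyDuplicated(x$id)) stop("record ids must be unique")
  ids <- x$id
  if (!is.null(sizes)) {
    stopifnot(length(sizes) == nrow(x))
    ids <- paste0(ids, ";size=", as.integer(sizes))
  }
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  ss <- Biostrings::BStringSet(x$sequence)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Screen reads for exact primer matches and trim the primers
#'
#' A read is kept iff its sequence starts with a (IUPAC-aware, zero-mismatch)
#' match to the proximal primer and ends with a match to the distal primer
#' given in read orientation; both primers are trimmed from kept reads. The
#' presence of both exact primer matches is the pipeline's only sequencing
#' quality filter. Reads whose trimmed insert contains N (or any non-ACGT
#' character) are rejected, because the downstream distance is defined over
#' A, C, G, T only.
#'
#' @param reads data.frame with `id`, `sequence`, `sample`.
#' @param proximal,distal primer sequences; IUPAC ambiguity codes allowed.
#'   `distal` is expected in read orientation; set `distal_revcomp = TRUE` to
#'   search its reverse complement instead.
#' @param distal_revcomp search the reverse complement of `distal`.
#' @return A list with `kept` (primer-trimmed reads) and `rejected`
#'   (untouched input rows); the two partition the input.
#' @export
screen_primers <- function(reads, proximal, distal, distal_revcomp = FALSE) {
  stopifnot(nzchar(proximal), nzchar(distal))
  if (distal_revcomp) {
    distal <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(distal)))
  }
  re <- paste0("^(", iupac_regex(proximal), ")(.*)(", iupac_regex(distal), ")$")
  if (nrow(reads) == 0) {
    return(list(kept = reads, rejected = reads))
  }
  m <- regexec(re, reads$sequence)
  insert <- vapply(seq_len(nrow(reads)), function(i) {
    mi <- m[[i]]
    if (mi[1] == -1) NA_character_ else {
      substr(reads$sequence[i], mi[3], mi[3] + attr(mi, "match.length")[3] - 1)
    }
  }, character(1))
  ok <- !is.na(insert) & nchar(insert) >= 1 & !grepl("[^ACGT]", insert)
  kept <- reads[ok, , drop = FALSE]
  kept$sequence <- insert[ok]
  rownames(kept) <- NULL
  rejected <- reads[!ok, , drop = FALSE]
  rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}
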