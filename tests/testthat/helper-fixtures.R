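rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# homopolymer-rich sequences: short alphabet, biased run lengths
rand_hp_dna <- function(n) {
  out <- character(0)
  while (sum(nchar(out)) < n) {
    out <- c(out, strrep(sample(c("A", "C", "G", "T"), 1), sample(1:4, 1)))
  }
  substr(paste(out, collapse = ""), 1, n)
}

# reads data.frame from a named vector sequence -> count
reads_from_counts <- function(counts, sample = "S1") {
  seqs <- rep(names(counts), counts)
  data.frame(id = sprintf("%s_r%04d", sample, seq_along(seqs)),
             sequence = seqs, sample = sample, stringsAsFactors = FALSE)
}

# recompute the counted-difference cost of a reported alignment under the
# column-costing rule (independent of the DP's own bookkeeping)
alignment_cost <- function(ga, gb) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  stopifnot(length(a) == length(b))
  cost <- 0L
  last_a <- NA_character_  # most recently consumed base of each sequence
  last_b <- NA_character_
  for (i in seq_along(a)) {
    if (a[i] != "-" && b[i] != "-") {
      cost <- cost + (a[i] != b[i])
      last_a <- a[i]; last_b <- b[i]
    } else if (b[i] == "-") {        # deletion of a[i]
      if (is.na(last_b) || a[i] != last_b) cost <- cost + 1L
      last_a <- a[i]
    } else {                         # insertion of b[i]
      if (is.na(last_a) || b[i] != last_a) cost <- cost + 1L
      last_b <- b[i]
    }
  }
  cost
}

# small reference database with two families of two genera each
toy_ref_db <- function() {
  ref_db(
    ids = c("g1s1", "g1s2", "g2s1", "g3s1", "arc1", "bac1"),
    sequences = c(
      "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC",
      "ACGTACGTACGTACGTACGTAGGTACGTACGTACGTACGTACGTACGTAC",
      "TGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATGCATG",
      "GGATCCGGATCCGGATCCGGATCCGGATCCGGATCCGGATCCGGATCCGG",
      "TTAACCGGTTAACCGGTTAACCGGTTAACCGGTTAACCGGTTAACCGGTT",
      "CCGGAATTCCGGAATTCCGGAATTCCGGAATTCCGGAATTCCGGAATTCC"),
    lineages = c(
      "Eukaryota;SAR;Alveolata;Ciliophora;ord1;fam1;GenA",
      "Eukaryota;SAR;Alveolata;Ciliophora;ord1;fam1;GenA",
      "Eukaryota;SAR;Alveolata;Ciliophora;ord1;fam1;GenB",
      "Eukaryota;Hacrobia;Haptophyta;Prymnesiophyceae;ord2;fam2;GenC",
      "Archaea;Archaea_kingdom;Archaea_ph",
      "Bacteria;Bacteria_kingdom;Bacteria_ph"))
}
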