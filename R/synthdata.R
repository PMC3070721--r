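#  Synthetic communities with full ground truth: a hierarchical reference
#  taxonomy with V9-like sequences, an environmental database with habitat
#  labels, and 454-style per-sample read sets whose dominant error mode is
#  homopolymer run-length miscalling.

CLADES <- data.frame(
  name = c("Ciliophora", "Dinophyceae", "Cercozoa", "Radiolaria",
           "Bacillariophyta", "Chrysophyceae", "Labyrinthulea",
           "Pelagophyceae", "Euglenozoa", "Amoebozoa", "Fungi", "Metazoa",
           "Choanoflagellata", "Chlorophyta", "Haptophyta", "Picobiliphyta"),
  kingdom = c("SAR", "SAR", "SAR", "SAR", "SAR", "SAR", "SAR", "SAR",
              "Excavata", "Amoebozoa", "Opisthokonta", "Opisthokonta",
              "Opisthokonta", "Archaeplastida", "Hacrobia", "Hacrobia"),
  phylum = c("Alveolata", "Alveolata", "Rhizaria", "Rhizaria",
             "Stramenopiles", "Stramenopiles", "Stramenopiles",
             "Stramenopiles", "Euglenozoa", "Lobosa", "Fungi", "Metazoa",
             "Choanoflagellata", "Chlorophyta", "Haptophyta", "Picobiliphyta"),
  class = c("Ciliophora", "Dinophyceae", "Cercozoa", "Radiolaria",
            "Bacillariophyta", "Chrysophyceae", "Labyrinthulea",
            "Pelagophyceae", "Kinetoplastea", "Tubulinea", "Ascomycota",
            "Nematoda", "Craspedida", "Mamiellophyceae", "Prymnesiophyceae",
            "Picomonadea"),
  phototrophic = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE,
                   FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_subs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

# 454-style noise: homopolymer runs of length >= 2 have their length
# miscalled (+/-1) with probability min(cap, hp_rate * (len - 1)), emulating
# the light-intensity miscalibration that grows with run length; independent
# substitutions at sub_rate come on top.
mutate_454 <- function(seq, hp_rate, sub_rate, cap = 0.5) {
  if (hp_rate > 0) {
    r <- rle(strsplit(seq, "")[[1]])
    p <- pmin(cap, hp_rate * (r$lengths - 1))
    flip <- stats::runif(length(p)) < p
    if (any(flip)) {
      delta <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
      r$lengths[flip] <- pmax(1L, r$lengths[flip] + delta)
      seq <- paste(rep(r$values, r$lengths), collapse = "")
    }
  }
  mutate_subs(seq, sub_rate)
}

#' Default parameters of the synthetic study
#'
#' The defaults emulate the shape of a two-region, six-sample deep-sea
#' amplicon survey: ~10^4 reads per sample of ~110-150 bp flanked by exact
#' primer sequences, lognormal taxon abundances with many rare taxa, a
#' bipolar/endemic region structure, prokaryotic and non-rRNA contamination,
#' and 454-style noise dominated by homopolymer run-length miscalls.
#'
#' @param n_taxa number of eukaryotic taxa (genus-level leaves).
#' @param v9_length_mean,v9_length_sd V9 insert length distribution.
#' @param divergence named substitution fractions: `species` (between
#'   reference sequences within a genus), `genus` (between sister genera),
#'   `family` (between families of a clade). Chosen large enough that
#'   distinct taxa stay resolvable by both the clustering radius and the
#'   assignment thresholds, which keeps the ground truth unambiguous.
#' @param min_taxon_dist minimum pairwise counted-difference distance
#'   enforced between taxon sequences (well-posedness of the k = 3 truth).
#' @param refs_per_taxon reference sequences (species) per genus.
#' @param samples data.frame `sample`, `region` (default DSE1-3 = ANT,
#'   DSE4-6 = ARC).
#' @param reads_per_sample total reads per sample.
#' @param lognormal_mu,lognormal_sigma lognormal abundance parameters.
#' @param shared_fraction fraction of taxa present in both regions.
#' @param planktonic_fraction fraction of taxa that are planktonic (half
#'   phototrophic, half via environmental marine-plankton records).
#' @param arch_rate,bact_rate,junk_rate read contamination rates (archaeal,
#'   bacterial, non-rRNA).
#' @param hp_indel_rate per-run homopolymer miscall coefficient; a run of
#'   length L is miscalled with probability `min(0.5, hp_indel_rate*(L-1))`.
#' @param sub_rate per-base substitution error rate.
#' @param n_rate per-read probability of an N in the insert.
#' @param primer_defect_rate per-read probability of a truncated distal
#'   primer (such reads fail the exact-primer screen).
#' @param proximal,distal primer pair added to every read.
#' @param n_prok prokaryotic reference sequences per domain.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return list of parameters.
#' @export
sim_params <- function(n_taxa = 100L,
                       v9_length_mean = 130, v9_length_sd = 10,
                       divergence = c(species = 0.02, genus = 0.25,
                                      family = 0.35),
                       min_taxon_dist = 10L,
                       refs_per_taxon = 2L,
                       samples = data.frame(
                         sample = paste0("DSE", 1:6),
                         region = rep(c("ANT", "ARC"), each = 3),
                         stringsAsFactors = FALSE),
                       reads_per_sample = 10000L,
                       lognormal_mu = 0, lognormal_sigma = 2,
                       shared_fraction = 0.30,
                       planktonic_fraction = 0.40,
                       arch_rate = 0.035, bact_rate = 0.09,
                       junk_rate = 0.0025,
                       hp_indel_rate = 0.01, sub_rate = 0.002,
                       n_rate = 0.002, primer_defect_rate = 0.01,
                       proximal = "TTGTACACACCGCCC",
                       distal = "GTAGGTGAACCTGCAGAAGG",
                       n_prok = 10L,
                       seed = 1L) {
  stopifnot(n_taxa >= 2, reads_per_sample >= 1,
            all(divergence >= 0), all(divergence <= 1),
            divergence["species"] <= divergence["genus"],
            divergence["genus"] <= divergence["family"],
            all(c(arch_rate, bact_rate, junk_rate, hp_indel_rate, sub_rate,
                  n_rate, primer_defect_rate) >= 0),
            shared_fraction >= 0, shared_fraction <= 1,
            planktonic_fraction >= 0, planktonic_fraction <= 1)
  as.list(environment())
}

#' Generate the synthetic reference databases
#'
#' Builds a hierarchical taxonomy over a fixed set of real major-group names
#' (so the shipped rollup and phototroph tables apply), draws V9-like
#' sequences whose divergence grows with rank distance, marks a known
#' fraction of taxa as planktonic (phototrophic clades or environmental
#' marine-plankton records), and emits a prokaryotic reference set and an
#' environmental database with habitat labels.
#'
#' @param params a [sim_params()] list.
#' @return list with
#'   * `taxa`: data.frame `taxon_id`, `genus`, `clade`, `lineage`, `sequence`,
#'     `phototrophic`, `env_planktonic`, `planktonic`;
#'   * `euk_db`: `ref_db` of eukaryotic reference sequences
#'     (`refs_per_taxon` per taxon);
#'   * `full_db`: `euk_db` plus archaeal and bacterial references;
#'   * `env`: environmental database as from [load_env_db()];
#'   * `phototrophs`: the phototroph taxon list used.
#' @export
make_reference <- function(params = sim_params()) {
  set.seed(params$seed)
  photo_clades <- CLADES[CLADES$phototrophic, ]
  benthic_clades <- CLADES[!CLADES$phototrophic, ]
  n_photo <- round(0.5 * params$planktonic_fraction * params$n_taxa)
  n_benthic <- params$n_taxa - n_photo
  clade_of <- c(sample(photo_clades$name, n_photo, replace = TRUE),
                sample(benthic_clades$name, n_benthic, replace = TRUE))

  # per-clade root sequences, then family ancestors, then genus leaves
  clade_root <- vapply(CLADES$name, function(cl) {
    n <- max(60, round(stats::rnorm(1, params$v9_length_mean,
                                    params$v9_length_sd)))
    random_dna(n)
  }, character(1))

  taxa_seq <- character(params$n_taxa)
  fam_of <- character(params$n_taxa)
  fam_anc <- list()
  for (i in seq_len(params$n_taxa)) {
    cl <- clade_of[i]
    fam_idx <- 1 + (sum(clade_of[seq_len(i)] == cl) - 1) %/% 3
    fam <- sprintf("%s_fam%02d", cl, fam_idx)
    if (is.null(fam_anc[[fam]])) {
      fam_anc[[fam]] <- mutate_subs(clade_root[[cl]],
                                    params$divergence[["family"]])
    }
    fam_of[i] <- fam
    for (try in 1:100) {
      cand <- mutate_subs(fam_anc[[fam]], params$divergence[["genus"]])
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (.hp_bounded_cpp(cand, taxa_seq[j], params$min_taxon_dist) <=
            params$min_taxon_dist) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("could not place taxon ", i,
                  " at the required minimum distance")
    taxa_seq[i] <- cand
  }

  genus <- sprintf("%s_gen%03d", clade_of, seq_len(params$n_taxa))
  ci <- match(clade_of, CLADES$name)
  lineage <- paste("Eukaryota", CLADES$kingdom[ci], CLADES$phylum[ci],
                   CLADES$class[ci], paste0(clade_of, "_ord01"), fam_of,
                   genus, sep = ";")
  phototrophic <- CLADES$phototrophic[ci]
  n_envp <- round(0.5 * params$planktonic_fraction * params$n_taxa)
  env_planktonic <- rep(FALSE, params$n_taxa)
  env_planktonic[sample(which(!phototrophic), min(n_envp, sum(!phototrophic)))] <- TRUE
  taxa <- data.frame(
    taxon_id = sprintf("tax%03d", seq_len(params$n_taxa)),
    genus = genus, clade = clade_of, lineage = lineage,
    sequence = taxa_seq, phototrophic = phototrophic,
    env_planktonic = env_planktonic,
    planktonic = phototrophic | env_planktonic,
    stringsAsFactors = FALSE)

  # reference species per genus: the canonical sequence plus close relatives
  ref_ids <- character(0); ref_seqs <- character(0); ref_lins <- character(0)
  for (i in seq_len(params$n_taxa)) {
    for (s in seq_len(params$refs_per_taxon)) {
      sq <- if (s == 1) taxa_seq[i] else {
        mutate_subs(taxa_seq[i], params$divergence[["species"]])
      }
      ref_ids <- c(ref_ids, sprintf("%s_sp%d", taxa$taxon_id[i], s))
      ref_seqs <- c(ref_seqs, sq)
      ref_lins <- c(ref_lins, paste0(lineage[i], ";",
                                     sprintf("%s_sp%d", genus[i], s)))
    }
  }
  euk_db <- ref_db(ref_ids, ref_seqs, ref_lins)

  prok <- function(domain, n) {
    ids <- sprintf("%s%03d", tolower(domain), seq_len(n))
    seqs <- vapply(seq_len(n), function(i) {
      random_dna(max(60, round(stats::rnorm(1, params$v9_length_mean,
                                            params$v9_length_sd))))
    }, character(1))
    lin <- paste(domain, paste0(domain, "_kingdom"), paste0(domain, "_ph"),
                 sep = ";")
    list(ids = ids, seqs = seqs, lins = rep(lin, n))
  }
  ar <- prok("Archaea", params$n_prok)
  ba <- prok("Bacteria", params$n_prok)
  full_db <- ref_db(c(ref_ids, ar$ids, ba$ids),
                    c(ref_seqs, ar$seqs, ba$seqs),
                    c(ref_lins, ar$lins, ba$lins))

  # environmental database: planktonic taxa leave marine-plankton records,
  # a fraction of benthic taxa leave sediment or freshwater/soil records
  env_ids <- character(0); env_seqs <- character(0); env_hab <- character(0)
  add_env <- function(i, habitat, tag) {
    env_ids <<- c(env_ids, sprintf("env_%s_%s", taxa$taxon_id[i], tag))
    env_seqs <<- c(env_seqs, mutate_subs(taxa_seq[i], 0.03))
    env_hab <<- c(env_hab, habitat)
  }
  for (i in seq_len(params$n_taxa)) {
    if (taxa$env_planktonic[i]) {
      add_env(i, "marine_plankton", "p1")
      add_env(i, "marine_plankton", "p2")
    } else if (taxa$phototrophic[i]) {
      if (stats::runif(1) < 0.5) add_env(i, "marine_plankton", "p1")
    } else {
      u <- stats::runif(1)
      if (u < 0.3) add_env(i, "marine_sediment", "s1")
      else if (u < 0.4) add_env(i, "freshwater_soil", "f1")
    }
  }
  env_db_obj <- ref_db(env_ids, env_seqs, rep("env", length(env_ids)))
  names(env_hab) <- env_ids
  phototroph_list <- c("Chlorophyta", "Rhodophyta", "Glaucophyta",
                       "Haptophyta", "Picobiliphyta", "Radiolaria",
                       "Bacillariophyta", "Bolidophyceae", "Dictyochophyceae",
                       "Pelagophyceae", "Phaeophyceae", "Phaeothamniophyceae",
                       "Pinguiophyceae", "Raphidophyceae")
  list(taxa = taxa, euk_db = euk_db, full_db = full_db,
       env = list(db = env_db_obj, habitat = env_hab),
       phototrophs = phototroph_list)
}

#' Simulate 454-style amplicon reads with ground truth
#'
#' Draws per-sample taxon abundances from a lognormal distribution with the
#' configured region-sharing structure, adds archaeal, bacterial and
#' non-rRNA contaminant reads, applies the homopolymer-dominated error model
#' and flanks every read with the primer pair. A small fraction of reads
#' carries an N or a truncated distal primer and is expected to fail the
#' primer screen.
#'
#' @param params a [sim_params()] list.
#' @param reference output of [make_reference()] under the same params.
#' @return list with
#'   * `reads`: data.frame `id`, `sequence`, `sample`;
#'   * `truth`: list with `reads` (per-read class, source taxon and
#'     clean/defect flag) and `taxa` (the reference taxa table plus
#'     `region_class` and the true per-sample read counts).
#' @export
simulate_reads <- function(params = sim_params(), reference = make_reference(params)) {
  set.seed(params$seed + 1L)
  taxa <- reference$taxa
  n_taxa <- nrow(taxa)
  n_bipolar <- round(params$shared_fraction * n_taxa)
  regions <- unique(params$samples$region)
  stopifnot(length(regions) == 2)
  shuffled <- sample.int(n_taxa)
  region_class <- character(n_taxa)
  region_class[shuffled[seq_len(n_bipolar)]] <- "bipolar"
  rest <- shuffled[-seq_len(n_bipolar)]
  half <- length(rest) %/% 2
  region_class[rest[seq_len(half)]] <- regions[1]
  region_class[rest[-seq_len(half)]] <- regions[2]
  taxa$region_class <- region_class

  prok_ids <- setdiff(reference$full_db$ids, reference$euk_db$ids)
  prok_dom <- reference$full_db$lineage$domain[match(prok_ids,
                                                     reference$full_db$ids)]
  arch_seqs <- reference$full_db$seq[prok_ids[prok_dom == "Archaea"]]
  bact_seqs <- reference$full_db$seq[prok_ids[prok_dom == "Bacteria"]]

  all_reads <- list()
  truth_reads <- list()
  true_counts <- matrix(0L, n_taxa, nrow(params$samples),
                        dimnames = list(taxa$taxon_id, params$samples$sample))
  for (si in seq_len(nrow(params$samples))) {
    smp <- params$samples$sample[si]
    reg <- params$samples$region[si]
    avail <- which(taxa$region_class %in% c("bipolar", reg))
    w <- stats::rlnorm(length(avail), params$lognormal_mu,
                       params$lognormal_sigma)
    n_reads <- params$reads_per_sample
    cls <- sample(c("euk", "archaeal", "bacterial", "junk"), n_reads,
                  replace = TRUE,
                  prob = c(1 - params$arch_rate - params$bact_rate -
                             params$junk_rate,
                           params$arch_rate, params$bact_rate,
                           params$junk_rate))
    src_taxon <- rep(NA_character_, n_reads)
    insert <- character(n_reads)
    is_euk <- cls == "euk"
    tx <- sample(avail, sum(is_euk), replace = TRUE, prob = w)
    src_taxon[is_euk] <- taxa$taxon_id[tx]
    true_counts[, si] <- true_counts[, si] +
      as.integer(table(factor(taxa$taxon_id[tx], levels = taxa$taxon_id)))
    base_seq <- character(n_reads)
    base_seq[is_euk] <- taxa$sequence[tx]
    n_arch <- sum(cls == "archaeal"); n_bact <- sum(cls == "bacterial")
    if (n_arch > 0) base_seq[cls == "archaeal"] <-
        sample(unname(arch_seqs), n_arch, replace = TRUE)
    if (n_bact > 0) base_seq[cls == "bacterial"] <-
        sample(unname(bact_seqs), n_bact, replace = TRUE)
    n_junk <- sum(cls == "junk")
    if (n_junk > 0) base_seq[cls == "junk"] <- vapply(seq_len(n_junk),
        function(i) random_dna(round(params$v9_length_mean)), character(1))

    mutated <- vapply(base_seq, mutate_454, character(1),
                      hp_rate = params$hp_indel_rate,
                      sub_rate = params$sub_rate, USE.NAMES = FALSE)
    # defects: N in the insert / truncated distal primer
    has_n <- stats::runif(n_reads) < params$n_rate
    for (i in which(has_n)) {
      pos <- sample.int(nchar(mutated[i]), 1)
      substr(mutated[i], pos, pos) <- "N"
    }
    defect <- stats::runif(n_reads) < params$primer_defect_rate
    dist_primer <- ifelse(defect,
                          substr(params$distal, 1, nchar(params$distal) - 1),
                          params$distal)
    seqs <- paste0(params$proximal, mutated, dist_primer)
    ids <- sprintf("%s_r%05d", smp, seq_len(n_reads))
    all_reads[[si]] <- data.frame(id = ids, sequence = seqs, sample = smp,
                                  stringsAsFactors = FALSE)
    truth_reads[[si]] <- data.frame(
      id = ids, sample = smp, class = cls, taxon_id = src_taxon,
      clean = !has_n & !defect, stringsAsFactors = FALSE)
  }
  taxa_out <- cbind(taxa, as.data.frame(true_counts))
  list(reads = do.call(rbind, all_reads),
       truth = list(reads = do.call(rbind, truth_reads), taxa = taxa_out))
}
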