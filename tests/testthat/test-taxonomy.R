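test_that("reference databases load from FASTA plus taxonomy TSV", {
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(data.frame(id = c("a", "b", "c"),
                         sequence = c("ACGT", "GGGG", "TTTT")), fa)
  writeLines(c("a\tEukaryota;SAR;Alveolata;Ciliophora;o;f;GenA",
               "b\tEukaryota;SAR",
               "c\tEukaryota;Opisthokonta;Metazoa;Nematoda;o2;f2;GenB;SpX"), tsv)
  db <- load_reference(fa, tsv)
  expect_identical(length(db$ids), 3L)
  expect_identical(db$lineage$genus[1], "GenA")
  expect_true(is.na(db$lineage$phylum[2]))
  expect_identical(db$lineage$species[3], "SpX")

  writeLines(c("a\tEukaryota"), tsv)
  expect_error(load_reference(fa, tsv), "without lineage")
  expect_error(ref_db(c("x", "x"), c("A", "A"), c("E", "E")), "duplicate")
})

test_that("V9 extraction emits the between-primer region and counts skips", {
  prox <- "GTACA"; dist <- "TGGAC"
  recs <- data.frame(
    id = c("full", "no_distal", "also_full"),
    sequence = c(paste0("AAAA", prox, "CCGGTT", dist, "AAAA"),
                 paste0("AAAA", prox, "CCGGTT"),
                 paste0(prox, "TTTT", dist)),
    stringsAsFactors = FALSE)
  out <- extract_v9(recs, prox, dist)
  expect_identical(out$v9$id, c("full", "also_full"))
  expect_identical(out$v9$sequence, c("CCGGTT", "TTTT"))
  expect_identical(out$n_skipped, 1L)
})

test_that("hit similarity implements sum(identities - gaps) / query length", {
  one <- data.frame(q_start = 0, q_end = 100, identities = 95, gaps = 2,
                    score = 100)
  expect_equal(hit_similarity(one, 100), 0.93)
  two <- data.frame(q_start = c(0, 60), q_end = c(50, 95),
                    identities = c(49, 30), gaps = c(1, 0),
                    score = c(200, 120))
  expect_equal(hit_similarity(two, 100), 0.78)
  # fully overlapping HSPs: only the higher-scoring one contributes
  ovl <- data.frame(q_start = c(0, 0), q_end = c(50, 50),
                    identities = c(45, 50), gaps = c(0, 0),
                    score = c(50, 40))
  expect_equal(hit_similarity(ovl, 100), 0.45)
  expect_equal(hit_similarity(one[0, ], 100), 0)
  # pathological gap excess floors at zero
  bad <- data.frame(q_start = 0, q_end = 10, identities = 2, gaps = 8,
                    score = 5)
  expect_equal(hit_similarity(bad, 10), 0)
})

test_that("greedy HSP selection is feasible and matches brute force on disjoint sets", {
  brute_best <- function(hsps, qlen) {
    n <- nrow(hsps)
    best_score <- -Inf; best_sim <- 0
    for (mask in 0:(2^n - 1)) {
      sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(sel) > 1) {
        o <- FALSE
        for (i in sel) for (j in sel) if (i < j) {
          if (hsps$q_start[i] < hsps$q_end[j] &&
              hsps$q_end[i] > hsps$q_start[j]) o <- TRUE
        }
        if (o) next
      }
      sc <- sum(hsps$score[sel])
      if (sc > best_score) {
        best_score <- sc
        best_sim <- min(max(sum(hsps$identities[sel] - hsps$gaps[sel]) /
                              qlen, 0), 1)
      }
    }
    best_sim
  }
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(1:5, 1)
    st <- sample(0:80, n)
    hsps <- data.frame(q_start = st, q_end = st + sample(5:30, n, TRUE),
                       identities = sample(5:30, n, TRUE),
                       gaps = sample(0:3, n, TRUE),
                       score = sample(10:200, n))
    g <- hit_similarity(hsps, 100)
    b <- brute_best(hsps, 100)
    # greedy by score is exactly optimal when no two HSPs overlap, and never
    # exceeds the brute-force optimum otherwise
    disjoint <- all(outer(hsps$q_start, hsps$q_end, ">=") |
                    outer(hsps$q_end, hsps$q_start, "<=") | diag(n) == 1)
    if (disjoint) expect_equal(g, b) else expect_lte(g, b + 1e-12)
    expect_gte(g, 0); expect_lte(g, 1)
  }
})

test_that("the seeded aligner finds identical and near-identical references", {
  db <- toy_ref_db()
  q <- unname(db$seq["g1s1"])
  hits <- search_db(q, db)
  expect_identical(hits$ref_id[1], "g1s1")
  expect_equal(hits$similarity[1], 1.0)

  # one substitution in the middle: similarity (L-1)/L from one
  # full-length HSP
  q2 <- q
  substr(q2, 25, 25) <- ifelse(substr(q, 25, 25) == "A", "C", "A")
  hits2 <- search_db(q2, db)
  expect_identical(hits2$ref_id[1], "g1s1")
  expect_equal(hits2$similarity[1], (nchar(q) - 1) / nchar(q))

  # nothing shares a 7-word with an alien query
  none <- search_db(strrep("AC", 25), db)
  expect_identical(nrow(none), 0L)
  expect_error(search_db("ACGT", ref_db(character(), character(),
                                        character())), "empty")
})

test_that("consensus assignment walks up the ranks exactly as specified", {
  db <- ref_db(
    ids = sprintf("r%02d", 1:10),
    sequences = rep("ACGT", 10),
    lineages = c(rep("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenX", 6),
                 rep("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenY", 4)))
  hits <- data.frame(query = 1, ref_id = sprintf("r%02d", 1:10),
                     similarity = seq(0.99, 0.90, by = -0.01))
  # 6/10 at genus is below 0.75; family is unanimous
  a <- assign_consensus(hits, db, assign_params())
  expect_identical(a$status, "assigned")
  expect_identical(a$rank, "family")
  expect_identical(a$label, "f")
  expect_identical(a$lineage, "Eukaryota;SAR;Alveolata;Ciliophora;o;f")

  # 8/10 sharing a genus reaches consensus at genus
  db2 <- ref_db(sprintf("r%02d", 1:10), rep("ACGT", 10),
                c(rep("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenX", 8),
                  rep("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenY", 2)))
  a2 <- assign_consensus(hits, db2, assign_params())
  expect_identical(a2$rank, "genus")
  expect_identical(a2$label, "GenX")

  # best hit below the assignment floor
  low <- data.frame(query = 1, ref_id = "r01", similarity = 0.79)
  a3 <- assign_consensus(low, db, assign_params())
  expect_identical(a3$status, "unassigned")
  expect_equal(a3$best_similarity, 0.79)

  # no hits at all
  a4 <- assign_consensus(low[0, ], db, assign_params())
  expect_identical(a4$status, "unassigned")
  expect_equal(a4$best_similarity, 0)

  # irreconcilable split at every rank, including domain
  db3 <- ref_db(c("e1", "b1"), c("ACGT", "ACGT"),
                c("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenX",
                  "Bacteria;Bk;Bp;Bc;Bo;Bf;Bg"))
  a5 <- assign_consensus(
    data.frame(query = 1, ref_id = c("e1", "b1"),
               similarity = c(0.95, 0.94)), db3, assign_params())
  expect_identical(a5$status, "undetermined")
})

test_that("hits without a name at a rank are excluded from that denominator", {
  db <- ref_db(c("r1", "r2", "r3"), rep("ACGT", 3),
               c("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenX",
                 "Eukaryota;SAR;Alveolata;Ciliophora",   # no genus
                 "Eukaryota;SAR;Alveolata;Ciliophora"))  # no genus
  hits <- data.frame(query = 1, ref_id = c("r1", "r2", "r3"),
                     similarity = c(0.95, 0.94, 0.93))
  a <- assign_consensus(hits, db, assign_params())
  # only r1 carries a genus name, so genus consensus is 1/1
  expect_identical(a$rank, "genus")
  expect_identical(a$label, "GenX")
})

test_that("consensus never lands deeper than the shallowest qualifying rank", {
  set.seed(23)
  ranks_no_sp <- setdiff(TAX_RANKS, "species")
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    lins <- vapply(1:n, function(i) {
      paste(vapply(seq_along(ranks_no_sp), function(r) {
        sprintf("%s%d", substr(ranks_no_sp[r], 1, 2), sample(1:2, 1))
      }, character(1)), collapse = ";")
    }, character(1))
    db <- ref_db(sprintf("r%02d", 1:n), rep("ACGT", n), lins)
    hits <- data.frame(query = 1, ref_id = db$ids,
                       similarity = runif(n, 0.85, 1))
    hits <- hits[order(-hits$similarity), ]
    a <- assign_consensus(hits, db, assign_params())
    if (a$status == "assigned") {
      depth <- match(a$rank, TAX_RANKS)
      # brute force: every rank deeper than the assigned one fails consensus
      for (r in TAX_RANKS[seq_along(ranks_no_sp)]) {
        if (match(r, TAX_RANKS) <= depth) next
        if (r == "species") next
        nm <- db$lineage[[r]][match(hits$ref_id, db$ids)]
        nm <- nm[!is.na(nm)]
        if (length(nm) > 0) {
          expect_lt(max(table(nm)) / length(nm), 0.75)
        }
      }
    }
  }
})

test_that("raising the assignment threshold never turns unassigned into assigned", {
  set.seed(29)
  db <- toy_ref_db()
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    hits <- data.frame(query = 1,
                       ref_id = sample(db$ids[1:4], n, replace = TRUE),
                       similarity = round(runif(n, 0.6, 1), 2))
    hits <- hits[order(-hits$similarity), ]
    prev_assigned <- TRUE
    for (th in assign_params()$threshold_ladder) {
      a <- assign_consensus(hits, db, assign_params(assignment_threshold = th))
      now <- a$status != "unassigned"
      if (!prev_assigned) expect_false(now)
      prev_assigned <- now
    }
  }
})

test_that("domain triage classes tags by their best hit and non-hits as non-rRNA", {
  db <- toy_ref_db()
  seqs <- c(unname(db$seq["arc1"]),            # archaeal
            unname(db$seq["bac1"]),            # bacterial
            unname(db$seq["g2s1"]),            # eukaryotic
            strrep("AC", 25))                  # matches nothing
  cls <- triage_domain(seqs, db)
  expect_identical(cls, c("archaeal", "bacterial", "eukaryotic", "non_rRNA"))
})

test_that("major-group rollup maps by the deepest matching lineage name", {
  g <- load_grouping()
  expect_identical(
    rollup_major_group("Eukaryota;SAR;Alveolata;Ciliophora;o;f;GenA",
                       "assigned", g), "Ciliophora")
  expect_identical(
    rollup_major_group("Eukaryota;Hacrobia;Haptophyta;Prym;o;f;G",
                       "assigned", g), "CCTH")
  # deeper rules shadow shallower ones: Dinophyceae, not "other Alveolata"
  expect_identical(
    rollup_major_group("Eukaryota;SAR;Alveolata;Dinophyceae;o;f;G",
                       "assigned", g), "Dinophyceae")
  expect_identical(
    rollup_major_group("Eukaryota;SAR;Alveolata;SomethingElse",
                       "assigned", g), "other Alveolata")
  expect_identical(rollup_major_group("Weird;Lineage", "assigned", g),
                   "Undetermined")
  expect_identical(rollup_major_group(NA, "unassigned", g), "Unassigned")
  expect_identical(rollup_major_group(NA, "undetermined", g), "Undetermined")

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tgroup", "X\tA", "X\tB"), tmp)
  expect_error(load_grouping(tmp), "overlapping")
})

test_that("resolution profile scores cluster consensus depth per level", {
  # every sequence its own genus, all mutually distinct: full genus consensus
  set.seed(31)
  seqs <- replicate(6, rand_dna(60))
  db <- ref_db(sprintf("r%d", 1:6), seqs,
               sprintf("Eukaryota;SAR;Alveolata;Ciliophora;o;f;Gen%d", 1:6))
  prof <- resolution_profile(db, levels = 0.85)
  expect_equal(prof$fraction[prof$rank == "genus"], 1)

  # identical sequences from different kingdoms: consensus stops at domain
  db2 <- ref_db(c("a", "b"), c(seqs[1], seqs[1]),
                c("Eukaryota;SAR;Alveolata;Ciliophora;o;f;G1",
                  "Eukaryota;Opisthokonta;Metazoa;Nematoda;o;f;G2"))
  prof2 <- resolution_profile(db2, levels = 0.90)
  expect_equal(prof2$fraction[prof2$rank == "domain"], 1)
  expect_equal(prof2$fraction[prof2$rank == "kingdom"], 0)
  expect_error(resolution_profile(ref_db(character(), character(),
                                         character())), "empty")
})

test_that("a 2%-within-genus database keeps genus consensus at the 99% level", {
  set.seed(37)
  base <- replicate(5, rand_dna(150))
  ids <- character(0); seqs <- character(0); lins <- character(0)
  mut <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  for (gfam in 1:5) for (g in 1:2) {
    anc <- mut(base[gfam], 0.10)          # genera 10% apart within a family
    for (s in 1:3) {
      ids <- c(ids, sprintf("f%dg%ds%d", gfam, g, s))
      seqs <- c(seqs, mut(anc, 0.02))     # species 2% within the genus
      lins <- c(lins, sprintf("Eukaryota;K;P;C;O;Fam%d;Gen%d_%d",
                              gfam, gfam, g))
    }
  }
  db <- ref_db(ids, seqs, lins)
  prof <- resolution_profile(db, levels = 0.99, method = "identity")
  expect_gte(prof$fraction[prof$rank == "genus"], 0.90)
  # the homopolymer-distance variant runs under the same contract
  prof_hp <- resolution_profile(db, levels = 0.99, method = "hp")
  expect_gte(prof_hp$fraction[prof_hp$rank == "genus"], 0.90)
})
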