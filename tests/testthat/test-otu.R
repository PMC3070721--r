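test_that("dereplication counts occurrences and orders by abundance then sequence", {
  reads <- reads_from_counts(c(ACGT = 2, AAAA = 1))
  tags <- dereplicate(reads)
  expect_identical(tags$tags$sequence, c("ACGT", "AAAA"))
  expect_identical(tags$tags$abundance, c(2L, 1L))
  expect_identical(tags$tags$rep_id, c("S1_r0001", "S1_r0003"))

  reads <- reads_from_counts(c(TTTT = 4, GGGG = 3, CCCC = 2, AAAA = 1))
  tags <- dereplicate(reads)
  expect_identical(tags$tags$sequence, c("TTTT", "GGGG", "CCCC", "AAAA"))
  expect_identical(sum(tags$tags$abundance), nrow(reads))

  # abundance ties broken lexicographically by sequence
  tags <- dereplicate(reads_from_counts(c(TTTT = 2, AAAA = 2, CCCC = 2)))
  expect_identical(tags$tags$sequence, c("AAAA", "CCCC", "TTTT"))

  one <- dereplicate(reads_from_counts(c(ACGT = 1)))
  expect_identical(one$tags$abundance, 1L)
})

test_that("dereplication keeps per-sample counts consistent with totals", {
  set.seed(3)
  reads <- rbind(reads_from_counts(c(ACGT = 3, TTAA = 1), "A"),
                 reads_from_counts(c(ACGT = 2, GGCC = 4), "B"))
  tags <- dereplicate(reads)
  expect_identical(unname(rowSums(tags$counts)),
                   as.numeric(tags$tags$abundance))
  expect_identical(sum(tags$counts), nrow(reads))
  expect_identical(tags$counts[tags$tags$sequence == "ACGT", ],
                   c(A = 3L, B = 2L))
})

test_that("tags within k of the seed are merged with their reads", {
  # the printed homopolymer pair clusters together even at k = 0
  reads <- reads_from_counts(c(ATGTGGGGTAT = 5, ATGTGGGTAT = 2))
  otus <- greedy_cluster(dereplicate(reads), k = 0)
  expect_identical(nrow(otus$otus), 1L)
  expect_identical(otus$otus$total_reads, 7L)
  expect_identical(otus$otus$seed_sequence, "ATGTGGGGTAT")

  single <- greedy_cluster(dereplicate(reads_from_counts(c(ACGT = 4))), k = 5)
  expect_identical(nrow(single$otus), 1L)
  expect_identical(single$otus$n_members, 1L)
})

test_that("members join the first seed only; near-members of non-seeds stay out", {
  # A (abundance 5), B = A + 1 substitution (3), C = B + 1 substitution (2):
  # d(A,B) = 1, d(B,C) = 1, d(A,C) = 2
  A <- "ACGTACGTACGTACGTACGT"
  B <- sub("^ACGTA", "ACGTT", A)
  C <- sub("GT$", "GG", B)
  expect_identical(hp_distance_oracle(substr(A, 11, 20), substr(C, 11, 20)), 1L)
  expect_identical(hp_distance(A, B)$distance, 1L)
  expect_identical(hp_distance(B, C)$distance, 1L)
  expect_identical(hp_distance(A, C)$distance, 2L)
  reads <- reads_from_counts(setNames(c(5, 3, 2), c(A, B, C)))
  otus <- greedy_cluster(dereplicate(reads), k = 1)
  # B joins seed A; C is within 1 of member B but is never compared to it,
  # so C seeds its own OTU
  expect_identical(nrow(otus$otus), 2L)
  expect_identical(otus$otus$seed_sequence, c(A, C))
  expect_identical(otus$membership$otu_id,
                   c("otu00001", "otu00001", "otu00002"))
})

test_that("clustering partitions tags, separates seeds and conserves reads", {
  set.seed(13)
  pool <- replicate(8, rand_hp_dna(30))
  seqs <- vapply(1:300, function(i) {
    x <- pool[sample(8, 1)]
    if (runif(1) < 0.5) x <- paste0(substr(x, 1, 10), rand_dna(2),
                                    substr(x, 13, 30))
    x
  }, character(1))
  reads <- reads_from_counts(table(seqs))
  tags <- dereplicate(reads)
  prev <- Inf
  for (k in 0:8) {
    otus <- greedy_cluster(tags, k)
    expect_identical(sum(otus$otus$total_reads), sum(tags$tags$abundance))
    expect_identical(sort(otus$membership$tag_id), sort(tags$tags$tag_id))
    seeds <- otus$otus$seed_sequence
    if (length(seeds) > 1) {
      for (i in 2:length(seeds)) for (j in 1:(i - 1)) {
        expect_false(within_k(seeds[i], seeds[j], k))
      }
    }
    # OTU count is non-increasing in k
    expect_lte(nrow(otus$otus), prev)
    prev <- nrow(otus$otus)
  }
  # identical input gives identical output
  expect_identical(greedy_cluster(tags, 3), greedy_cluster(tags, 3))
})

test_that("clustering refuses unsorted tag tables", {
  tags <- dereplicate(reads_from_counts(c(ACGT = 1, TTTT = 5)))
  bad <- tags
  bad$tags <- bad$tags[2:1, ]
  bad$counts <- bad$counts[2:1, , drop = FALSE]
  expect_error(greedy_cluster(bad, 3), "sorted")
})

test_that("single-singletons are exactly the one-member one-read OTUs", {
  reads <- rbind(
    reads_from_counts(c(AAAATTTTCCCCGGGGAAAA = 1)),                # single-singleton
    reads_from_counts(c(TTTTAAAAGGGGCCCCTTTT = 2)),                # singleton tag, 2 reads
    reads_from_counts(c(CCCCAAAATTTTGGGGCCCA = 1,
                        CCCCAAAATTTTGGGGCCCT = 1)))                # 2 members, 1 read each
  otus <- greedy_cluster(dereplicate(reads), k = 1)
  parts <- drop_single_singletons(otus)
  expect_identical(sum(parts$dropped$otus$n_members == 1 &
                       parts$dropped$otus$total_reads == 1),
                   nrow(parts$dropped$otus))
  expect_identical(nrow(parts$dropped$otus), 1L)
  expect_identical(nrow(parts$kept$otus) + nrow(parts$dropped$otus),
                   nrow(otus$otus))
  expect_identical(parts$dropped$otus$seed_sequence, "AAAATTTTCCCCGGGGAAAA")
})

test_that("saturation curves hit the exact endpoints and are monotone", {
  read_otu <- rep(c("o1", "o2", "o3"), c(10, 5, 1))
  sc <- saturation_curve(read_otu, n_points = 16, n_perm = 20, seed = 2)
  expect_identical(sc$mean_otus[1], 1)          # one read -> one OTU
  expect_identical(sc$mean_otus[nrow(sc)], 3)   # full depth -> all OTUs
  expect_true(all(diff(sc$mean_otus) >= 0))
  expect_warning(saturation_curve(read_otu, n_points = 100, n_perm = 2),
                 "clipped")
})

test_that("saturation mean matches the hypergeometric expectation on a uniform set", {
  # 100 reads over 10 equal OTUs, subsample 50: per OTU the inclusion
  # probability is 1 - C(90,50)/C(100,50)
  read_otu <- rep(paste0("o", 1:10), each = 10)
  expected <- 10 * (1 - choose(90, 50) / choose(100, 50))
  sc <- saturation_curve(read_otu, n_points = 99, n_perm = 1000, seed = 5)
  got <- sc[sc$reads == 50, ]
  expect_lt(abs(got$mean_otus - expected), 3 * got$sd_otus / sqrt(1000))
})
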