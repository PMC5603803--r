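ref <- default_ref()

test_that("UMI extraction trims the tag and matches truth on clean reads", {
  reads <- data.frame(read_id = "r1",
                      r1_seq = paste0(strrep("A", 13), "GCTAGCC", "TTTGGG"),
                      r1_qual = strrep("?", 26), r2_seq = "ACGT",
                      r2_qual = "????", stringsAsFactors = FALSE)
  ex <- extract_umi(reads, umi_spec())
  expect_equal(ex$reads$umi, strrep("A", 13))
  expect_equal(ex$reads$r1_seq, "TTTGGG")
  expect_equal(ex$n_discarded, 0)

  sim <- sim_library(n_cells = 30, depth = 5, error_rate = 0, seed = 71)
  ex <- extract_umi(sim$reads)
  expect_equal(ex$n_discarded, 0)
  expect_identical(ex$reads$umi, ex$reads$true_umi)
})

test_that("UMI extraction error fraction follows the closed form", {
  sim <- sim_library(n_cells = 100, depth = 20, error_rate = 0.003, seed = 72)
  ex <- extract_umi(sim$reads)
  frac <- mean(ex$reads$umi != ex$reads$true_umi)
  expected <- mean(1 - (1 - 0.003)^nchar(ex$reads$true_umi))
  expect_gt(frac, expected * 0.5)
  expect_lt(frac, expected * 1.6)
  # reads losing the spacer are discarded, roughly 1-(1-e)^7 of them
  expect_lt(ex$n_discarded / nrow(sim$reads), 3 * (1 - (1 - 0.003)^7))
})

test_that("single-error UMI clustering merges errors into the dominant tag", {
  two <- cluster_umis(rep("ACGTACGTACGTA", 2))
  expect_equal(nrow(two$groups), 1)
  expect_equal(two$groups$n_reads, 2)

  umis <- c(rep("AAAAAAAAAAAAA", 10), "AAAAAAAAAAAAT")
  cl <- cluster_umis(umis, max_errors = 1)
  expect_equal(nrow(cl$groups), 1)
  expect_equal(cl$groups$canonical_umi, "AAAAAAAAAAAAA")
  # identity-only mode keeps them apart
  cl0 <- cluster_umis(umis, max_errors = 0)
  expect_equal(nrow(cl0$groups), 2)
  # length mismatch never merges
  lm <- cluster_umis(c(rep("AAAAAAAAAAAAA", 5), "AAAAAAAAAAAAAA"))
  expect_equal(nrow(lm$groups), 2)
})

test_that("clustering matches the brute-force greedy oracle", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n_tags <- sample(4:10, 1)
      # short alphabet-limited tags force near-collisions
      tags <- unique(replicate(n_tags, paste(sample(c("A", "C"), 8,
                                                    replace = TRUE),
                                             collapse = "")))
      umis <- rep(tags, sample(1:5, length(tags), replace = TRUE))
    })
    got <- cluster_umis(umis, max_errors = 1)
    want <- oracle_cluster_umis(umis, max_errors = 1)
    expect_true(same_partition(got$assignment, want$assignment))
    expect_setequal(got$groups$canonical_umi, want$seeds)
  }
})

test_that("identity sub-clustering separates unrelated molecules under one UMI", {
  expect_equal(subcluster_by_identity(rep("ACGTACGT", 4), rep(1L, 4),
                                      window = 8),
               rep(1L, 4))
  withr::with_seed(5, {
    a <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  })
  sub <- subcluster_by_identity(c(a, a, a, b, b), rep(1L, 5))
  expect_equal(length(unique(sub)), 2)
  expect_true(all(sub[1:3] == sub[1]) && all(sub[4:5] == sub[4]))
  # 85% identity over the window splits at the default 90% threshold
  ab <- a
  substring(ab, 1, 22) <- chartr("ACGT", "CATG", substr(a, 1, 22))
  ident <- sum(charToRaw(ab) == charToRaw(a)) / 150
  expect_equal(ident, 128 / 150)
  expect_lt(ident, 0.9)
  sub2 <- subcluster_by_identity(c(a, a, ab), rep(1L, 3))
  expect_equal(length(unique(sub2)), 2)
})

test_that("sub-clustering matches the brute-force oracle and partitions reads", {
  for (s in 1:15) {
    withr::with_seed(100 + s, {
      k <- sample(3:15, 1)
      base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                    collapse = "")
      r1 <- vapply(seq_len(k), function(i) {
        x <- base
        nmut <- sample(0:20, 1)
        if (nmut > 0) x <- igumi:::mutate_fixed_count(x, nmut)
        x
      }, character(1))
    })
    got <- subcluster_by_identity(r1, rep(1L, k), window = 60)
    want <- oracle_subcluster(r1, window = 60)
    expect_true(same_partition(got, want))
    expect_true(all(got >= 1))
  }
})

test_that("consensus calls strict majority and N on ties", {
  expect_equal(build_consensus(rep("ACGT", 3)),
               list(sequence = "ACGT", read_count = 3L, n_count = 0L))
  tie <- build_consensus(c("AAAA", "AAAA", "ACAA", "ACAA"))
  expect_equal(tie$sequence, "ANAA")
  expect_equal(tie$n_count, 1L)
})

test_that("consensus matches the brute-force per-column majority oracle", {
  for (s in 1:30) {
    withr::with_seed(200 + s, {
      k <- sample(1:6, 1)
      L <- sample(5:30, 1)
      base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
      seqs <- vapply(seq_len(k), function(i) {
        x <- igumi:::mutate_fixed_count(base, sample(0:3, 1))
        if (runif(1) < 0.3) x <- substr(x, 1, L - sample(1:3, 1))
        x
      }, character(1))
    })
    got <- build_consensus(seqs)
    expect_equal(got$sequence, oracle_consensus(seqs))
    expect_equal(got$n_count,
                 sum(strsplit(got$sequence, "")[[1]] == "N"))
  }
})

test_that("the junction must be present on both mate consensus sequences", {
  sim <- sim_library(n_cells = 20, depth = 5, error_rate = 0, seed = 81)
  ex <- extract_umi(sim$reads)
  cl <- cluster_umis(ex$reads$umi)
  sub <- subcluster_by_identity(ex$reads$r1_seq, cl$assignment)
  c1 <- igumi:::consensus_by_subgroup(ex$reads$r1_seq, sub)
  c2 <- igumi:::consensus_by_subgroup(ex$reads$r2_seq, sub)
  ok <- require_cdr3_on_both_mates(c1$sequence, c2$sequence,
                                   ref$anchor_5p, ref$anchor_3p)
  expect_true(all(ok))
  # truncating read 2 before the junction fails the filter
  trunc <- substr(c2$sequence, 1, 30)
  ok2 <- require_cdr3_on_both_mates(c1$sequence, trunc,
                                    ref$anchor_5p, ref$anchor_3p)
  expect_false(any(ok2))
})

test_that("paired-end assembly reconstructs the template over the overlap", {
  withr::with_seed(9, {
    template <- paste(sample(c("A", "C", "G", "T"), 450, replace = TRUE),
                      collapse = "")
  })
  r1 <- substr(template, 1, 300)
  r2 <- igumi:::revcomp(substr(template, 151, 450))
  asm <- assemble_pairs(r1, r2)
  expect_true(asm$assembled)
  expect_equal(asm$sequence, template)
  # a 10 nt overlap is below the 20 nt minimum
  r2short <- igumi:::revcomp(substr(template, 291, 450))
  asm2 <- assemble_pairs(substr(template, 1, 300), r2short, min_overlap = 20)
  expect_false(asm2$assembled)
  # an N on one mate takes the other mate's base
  r1n <- r1
  substring(r1n, 200, 200) <- "N"
  asm3 <- assemble_pairs(r1n, r2)
  expect_equal(asm3$sequence, template)
})

test_that("error-free libraries assemble to the exact source transcripts", {
  sim <- sim_library(n_cells = 25, depth = 6, error_rate = 0, seed = 91)
  res <- process_reads(sim$reads, ref)
  rec <- res$records[res$records$assembled, ]
  expect_true(all(rec$sequence %in% sim$pool$transcript))
  expect_equal(sum(res$records$read_count), res$log[["n_reads_kept"]])
})

test_that("the pass filter keeps >=3 reads or >=3 identical UMIGs and collapses", {
  records <- data.frame(
    sequence = c("SEQA", "SEQA", "SEQA", "SEQB", "SEQC"),
    read_count = c(1L, 1L, 1L, 2L, 5L))
  ur <- filter_and_collapse(records, min_reads = 3, min_umigs = 3)
  expect_equal(nrow(ur), 2)
  a <- ur[ur$sequence == "SEQA", ]
  expect_equal(a$umig_count, 3L)
  expect_equal(a$read_count, 3L)
  expect_equal(ur[ur$sequence == "SEQC", ]$umig_count, 1L)
  # exactly three reads passes
  expect_equal(nrow(filter_and_collapse(data.frame(sequence = "S",
                                                   read_count = 3L))), 1)
  expect_equal(nrow(filter_and_collapse(data.frame(sequence = "S",
                                                   read_count = 2L))), 0)
})

test_that("raising min_reads never increases passing rearrangements", {
  withr::with_seed(7, {
    records <- data.frame(
      sequence = sample(sprintf("SEQ%02d", 1:30), 120, replace = TRUE),
      read_count = sample(1:8, 120, replace = TRUE))
  })
  n <- vapply(1:9, function(t)
    nrow(filter_and_collapse(records, min_reads = t)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("every UMI-bearing read lands in exactly one subgroup of one group", {
  sim <- sim_library(n_cells = 40, depth = 10, error_rate = 0.005, seed = 95)
  ex <- extract_umi(sim$reads)
  cl <- cluster_umis(ex$reads$umi)
  expect_equal(length(cl$assignment), nrow(ex$reads))
  expect_false(any(is.na(cl$assignment)))
  expect_equal(sum(cl$groups$n_reads), nrow(ex$reads))
  sub <- subcluster_by_identity(ex$reads$r1_seq, cl$assignment)
  expect_false(any(sub == 0L))
  # each subgroup belongs to a single group
  expect_true(all(tapply(cl$assignment, sub,
                         function(g) length(unique(g))) == 1))
})
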