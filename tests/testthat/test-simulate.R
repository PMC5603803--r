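ref <- default_ref()
prof <- gene_frequency_profile(ref)

test_that("repertoire cells carry their junction uniquely at the recorded offset", {
  cells <- generate_repertoire(50, prof, ref, seed = 3)
  expect_equal(nrow(cells), 50)
  expect_false(anyDuplicated(cells$junction) > 0)
  expect_identical(substring(cells$full_transcript, cells$junction_start + 1,
                             cells$junction_end),
                   cells$junction)
  # single-cell case
  one <- generate_repertoire(1, prof, ref, seed = 4)
  expect_true(grepl(one$junction, one$full_transcript, fixed = TRUE))
})

test_that("gene sampling follows the frequency profile within binomial error", {
  p <- rep((1 - 0.5) / (length(ref$genes) - 1), length(ref$genes))
  p[1] <- 0.5
  names(p) <- names(ref$genes)
  skew <- gene_frequency_profile(ref, p)
  cells <- generate_repertoire(5000, skew, ref, seed = 11)
  n_a <- sum(cells$v_gene == names(ref$genes)[1])
  expect_gte(n_a, qbinom(1e-6, 5000, 0.5))
  expect_lte(n_a, qbinom(1 - 1e-6, 5000, 0.5))
})

test_that("junction uniqueness failure and empty reference are explicit errors", {
  tiny <- c(1, 1)
  expect_error(generate_repertoire(10, prof, ref, junction_length_range = tiny),
               "junction space")
  broken <- ref
  broken$genes <- broken$genes[0]
  expect_error(gene_frequency_profile(broken), "no genes")
})

test_that("spike-in panel mirrors the 58/21 design with 1-10% divergence", {
  panel <- generate_spikein_panel(58, 21, ref, seed = 7)
  expect_equal(nrow(panel), 58)
  expect_equal(sum(panel$mutated), 21)
  expect_false(anyDuplicated(panel$junction) > 0)
  expect_true(all(panel$percent_divergence[panel$mutated] >= 1 - 0.3))
  expect_true(all(panel$percent_divergence[panel$mutated] <= 10 + 0.3))
  expect_true(all(panel$percent_divergence[!panel$mutated] == 0))
  # realized divergence equals the mismatch count against germline
  mm <- mapply(function(v, g) sum(charToRaw(v) != charToRaw(g)),
               panel$v_sequence, ref$genes[panel$v_gene])
  expect_equal(unname(mm), panel$n_mutations)
  expect_equal(generate_spikein_panel(0, 0, ref, seed = 1) |> nrow(), 0)
})

test_that("a 5% divergence over a 300 nt region yields 15 mismatches", {
  withr::with_seed(42, {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    m <- igumi:::mutate_fixed_count(s, round(0.05 * 300))
  })
  expect_equal(sum(charToRaw(s) != charToRaw(m)), 15)
})

test_that("transcription yields Poisson copy numbers with population scaling", {
  cells <- generate_repertoire(1, prof, ref, seed = 5)
  pool <- transcribe_and_tag(cells, copies_mean = 2, seed = 1,
                             deterministic = TRUE)
  expect_equal(nrow(pool), 2)
  mem <- cells
  mem$population <- "memory"
  expect_equal(nrow(transcribe_and_tag(mem, 2, seed = 1, deterministic = TRUE)), 5)
  pla <- cells
  pla$population <- "plasma"
  expect_equal(nrow(transcribe_and_tag(pla, 2, seed = 1, deterministic = TRUE)), 500)

  big <- generate_repertoire(1000, prof, ref, seed = 6)
  bp <- transcribe_and_tag(big, copies_mean = 2, seed = 2)
  expect_gte(nrow(bp), qpois(1e-6, 2000))
  expect_lte(nrow(bp), qpois(1 - 1e-6, 2000))
  expect_true(all(nchar(bp$umi) >= 13 & nchar(bp$umi) <= 16))
})

test_that("UMI composition is uniform and copy counts look Poisson at n = 10^4", {
  cells <- generate_repertoire(5000, prof, ref, seed = 8)
  pool <- transcribe_and_tag(cells, copies_mean = 2, seed = 9)
  expect_gt(nrow(pool), 9000)
  tab <- table(strsplit(paste(pool$umi, collapse = ""), "")[[1]])
  chi <- chisq.test(tab)
  expect_gt(chi$p.value, 1e-6)
  # per-cell molecule counts (including zeros) against Poisson(2)
  counts <- tabulate(factor(pool$cell_id, levels = cells$cell_id), nbins = 5000)
  obs <- table(factor(pmin(counts, 6), levels = 0:6))
  expected <- c(dpois(0:5, 2), ppois(5, 2, lower.tail = FALSE)) * 5000
  chi2 <- sum((as.integer(obs) - expected)^2 / expected)
  expect_lt(chi2, qchisq(1 - 1e-6, df = 6))
})

test_that("dilution is conservative binomial thinning", {
  cells <- generate_repertoire(200, prof, ref, seed = 10)
  pool <- transcribe_and_tag(cells, seed = 11)
  same <- dilute_pool(pool, 1.0, seed = 1)
  expect_equal(nrow(same), nrow(pool))
  half <- dilute_pool(pool, 0.5, seed = 2)
  expect_equal(nrow(half) + attr(half, "n_discarded"), nrow(pool))
  expect_true(all(half$molecule_id %in% pool$molecule_id))
  tot <- sum(vapply(1:100, function(s) nrow(dilute_pool(pool, 0.5, seed = s)),
                    numeric(1)))
  n <- 100 * nrow(pool)
  expect_gte(tot, qbinom(1e-6, n, 0.5))
  expect_lte(tot, qbinom(1 - 1e-6, n, 0.5))
  expect_error(dilute_pool(pool, 0), "fraction")
  expect_error(dilute_pool(pool, 1.2), "fraction")
})

test_that("sequencing honours the depth contract and truth-tag integrity", {
  sim <- sim_library(n_cells = 77, depth = 1.5, error_rate = 0, seed = 21)
  expect_equal(nrow(sim$reads), round(1.5 * 77))
  expect_true(all(sim$reads$molecule_id %in% sim$pool$molecule_id))
  expect_true(all(sim$reads$cell_id %in% sim$cells$cell_id))
  m <- match(sim$reads$molecule_id, sim$pool$molecule_id)
  expect_identical(sim$reads$true_umi, sim$pool$umi[m])
})

test_that("error-free reads reproduce their source molecule exactly", {
  sim <- sim_library(n_cells = 40, depth = 5, error_rate = 0, seed = 31)
  m <- match(sim$reads$molecule_id, sim$pool$molecule_id)
  tr <- sim$pool$transcript[m]
  expected_r1 <- paste0(sim$pool$umi[m], "GCTAGCC",
                        substr(tr, 1, 300 - nchar(sim$pool$umi[m]) - 7))
  expect_identical(sim$reads$r1_seq, expected_r1)
  tlen <- nchar(tr)
  expected_r2 <- igumi:::revcomp(substring(tr, pmax(1, tlen - 299), tlen))
  expect_identical(sim$reads$r2_seq, expected_r2)
})

test_that("substitution errors occur at the configured rate", {
  sim <- sim_library(n_cells = 60, depth = 40, error_rate = 0.003, seed = 41)
  m <- match(sim$reads$molecule_id, sim$pool$molecule_id)
  tr <- sim$pool$transcript[m]
  expected_r1 <- paste0(sim$pool$umi[m], "GCTAGCC",
                        substr(tr, 1, 300 - nchar(sim$pool$umi[m]) - 7))
  nb <- sum(nchar(expected_r1))
  expect_gt(nb, 1e5)
  mm <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                   sim$reads$r1_seq, expected_r1))
  expect_gte(mm, qbinom(1e-6, nb, 0.003))
  expect_lte(mm, qbinom(1 - 1e-6, nb, 0.003))
})

test_that("a read length too short to span the junction is a configuration error", {
  cells <- generate_repertoire(5, prof, ref, seed = 51)
  pool <- transcribe_and_tag(cells, seed = 52)
  expect_error(amplify_and_sequence(pool, depth_multiplier = 2,
                                    read_length = 150, seed = 1),
               "junction")
})

test_that("spike-in pools hold the expected clone molecule yield", {
  panel <- generate_spikein_panel(5, 2, ref, seed = 61)
  pool <- build_spikein_experiment(panel, cells_per_clone_equivalent = 2,
                                   background_cells = 20, reference = ref,
                                   clone_copies_mean = 2, seed = 62,
                                   deterministic = TRUE)
  # expectation: equivalents x copies = 4 molecules per clone, exactly in
  # deterministic mode
  sp <- pool[startsWith(pool$molecule_id, "sp_"), ]
  # 5 clones x 100 lysate cells x 2 copies, thinned by 2/100: 20 molecules,
  # i.e. a mean of 4 per clone
  expect_equal(nrow(sp), 20)
  clone_of <- sub("_c[0-9]+$", "", sp$cell_id)
  expect_equal(mean(table(factor(clone_of, levels = panel$clone_id))), 4)
  expect_equal(attr(pool, "n_source_cells"), 20 + round(5 * 2))
  # vanishing input -> no clone molecules
  none <- build_spikein_experiment(panel, cells_per_clone_equivalent = 1e-3,
                                   background_cells = 20, reference = ref,
                                   clone_copies_mean = 2, seed = 63,
                                   deterministic = TRUE)
  expect_equal(sum(startsWith(none$molecule_id, "sp_")), 0)
})
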