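test_that("quantile vectors use 0..99% quantiles and the 100-point rule", {
  expect_equal(quantile_vector(rep(5, 100)), rep(5, 100))
  expect_null(quantile_vector(1:99))
  expect_equal(length(quantile_vector(1:100)), 100)
  # brute-force order-statistic oracle
  x <- 1:200
  probs <- (0:99) / 100
  expect_equal(quantile_vector(x), oracle_quantile(x, probs))
  withr::with_seed(3, y <- rnbinom(150, mu = 8, size = 2))
  expect_equal(quantile_vector(y), oracle_quantile(y, probs))
})

test_that("relative efficiency recovers identity and planted scale factors", {
  withr::with_seed(10, base <- rnbinom(1000, mu = 20, size = 5) + 1)
  expect_equal(relative_efficiency(base, base), 1)
  for (s in c(0.5, 1, 2, 4)) {
    withr::with_seed(round(100 * s), {
      gene <- s * (rnbinom(1000, mu = 20, size = 5) + 1)
    })
    slope <- relative_efficiency(gene, base)
    expect_lt(abs(slope - s) / s, 0.05)
  }
  # the 100-point rule is exact
  expect_true(is.na(relative_efficiency(base[1:99], base)))
  expect_false(is.na(relative_efficiency(base[1:100], base)))
})

test_that("a uniform subsample of the overall distribution has slope ~1", {
  withr::with_seed(21, {
    all_counts <- rnbinom(5000, mu = 15, size = 3) + 1
    gene <- sample(all_counts, 1000)
  })
  expect_lt(abs(relative_efficiency(gene, all_counts) - 1), 0.05)
})

test_that("slopes are scale-equivariant and scaled efficiencies invariant", {
  withr::with_seed(31, {
    base <- rnbinom(800, mu = 10, size = 4) + 1
    gene <- 2 * (rnbinom(800, mu = 10, size = 4) + 1)
  })
  s1 <- relative_efficiency(gene, base)
  s3 <- relative_efficiency(3 * gene, base)
  expect_equal(s3, 3 * s1, tolerance = 1e-12)
})

make_samples <- function(scales, n_per_gene = 1000, n_samples = 3, seed = 1) {
  lapply(seq_len(n_samples), function(s) {
    withr::with_seed(seed + s, {
      do.call(rbind, lapply(names(scales), function(g) {
        data.frame(v_call = g,
                   umig_count = scales[[g]] *
                     (rnbinom(n_per_gene, mu = 12, size = 4) + 1))
      }))
    })
  })
}

test_that("detectability tables recover planted gene scales and pin the minimum to 1", {
  single <- list(s1 = data.frame(v_call = "G1",
                                 umig_count = rpois(200, 8) + 1))
  dt1 <- detectability_table(single)
  expect_equal(dt1$table$scaled_efficiency, 1)

  samples <- make_samples(c(G1 = 1, G2 = 2, G3 = 4))
  dt <- detectability_table(samples)
  expect_equal(min(dt$table$scaled_efficiency), 1)
  got <- dt$table$scaled_efficiency[match(c("G1", "G2", "G3"), dt$table$gene)]
  expect_true(all(abs(got - c(1, 2, 4)) / c(1, 2, 4) < 0.05))
  # a high vs low detectable gene keeps its ordering in every sample
  per <- dt$per_sample
  for (s in unique(per$sample))
    expect_gt(per$slope[per$sample == s & per$gene == "G3"],
              per$slope[per$sample == s & per$gene == "G1"])
})

test_that("genes below 100 observations contribute no slope for that sample", {
  s1 <- data.frame(v_call = c(rep("G1", 99), rep("G2", 300)),
                   umig_count = c(rpois(99, 5) + 1, rpois(300, 5) + 1))
  s2 <- data.frame(v_call = c(rep("G1", 150), rep("G2", 300)),
                   umig_count = c(rpois(150, 5) + 1, rpois(300, 5) + 1))
  dt <- detectability_table(list(a = s1, b = s2))
  expect_equal(dt$table$n_samples[dt$table$gene == "G1"], 1L)
  expect_equal(dt$table$n_samples[dt$table$gene == "G2"], 2L)
  tiny <- list(a = data.frame(v_call = "G1", umig_count = rpois(50, 5) + 1))
  expect_warning(detectability_table(tiny), "100-point")
})

test_that("efficiency-frequency correlation matches its construction", {
  samples <- make_samples(c(G1 = 1, G2 = 2, G3 = 3, G4 = 4))
  dt <- detectability_table(samples)
  eff <- dt$table$scaled_efficiency
  names(eff) <- dt$table$gene
  # frequencies exactly proportional to efficiency -> R^2 = 1, positive
  prop <- eff / sum(eff)
  r <- suppressWarnings(detectability_frequency_correlation(dt, prop))
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$slope_sign, 1L)
})

test_that("independent frequencies give an R^2 typical of the permutation baseline", {
  scales <- stats::setNames(as.list(seq(1, 3, length.out = 12)),
                            sprintf("G%02d", 1:12))
  samples <- make_samples(scales, n_per_gene = 150, n_samples = 2)
  dt <- detectability_table(samples)
  eff <- dt$table$scaled_efficiency
  withr::with_seed(77, freqs <- stats::setNames(runif(12), dt$table$gene))
  obs <- detectability_frequency_correlation(dt, freqs)$r_squared
  perm <- withr::with_seed(78, {
    vapply(1:200, function(i) {
      f <- stats::setNames(sample(unname(freqs)), names(freqs))
      detectability_frequency_correlation(dt, f)$r_squared
    }, numeric(1))
  })
  expect_lte(obs, max(perm))
  expect_lt(median(perm), 0.5)
})

test_that("coupling gene abundance with mRNA content yields a positive correlation", {
  # genes sampled more often also carry more molecules per rearrangement
  scales <- stats::setNames(as.list(c(1, 1.5, 2, 3, 4)), sprintf("G%d", 1:5))
  samples <- make_samples(scales, n_per_gene = 400, n_samples = 2, seed = 41)
  dt <- detectability_table(samples)
  freqs <- stats::setNames(unlist(scales) / sum(unlist(scales)),
                           names(scales))
  r <- detectability_frequency_correlation(dt, freqs)
  expect_equal(r$slope_sign, 1L)
  expect_gt(r$r_squared, 0.5)
})
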