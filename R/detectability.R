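#' Fine-grained quantile encoding of a count distribution
#'
#' Encodes a UMIG-count distribution as the vector of its 0%, 1%, ...,
#' 99% empirical quantiles (for the default `n_quantiles = 100`), using
#' linear interpolation between order statistics (type 7; configurable).
#' Distributions with fewer than `min_points` observations carry too
#' little quantile resolution and are excluded.
#'
#' @param counts numeric vector of observations.
#' @param n_quantiles number of evenly spaced quantiles (default 100).
#' @param min_points minimum observations required (default 100).
#' @param type quantile interpolation type passed to [stats::quantile()].
#' @return numeric vector of length `n_quantiles`, or `NULL` when the
#'   distribution is excluded.
#' @export
quantile_vector <- function(counts, n_quantiles = 100, min_points = 100,
                            type = 7) {
  stopifnot(n_quantiles >= 2)
  if (length(counts) < min_points) return(NULL)
  unname(stats::quantile(counts, probs = seq(0, n_quantiles - 1) / n_quantiles,
                         type = type, names = FALSE))
}

#' Relative efficiency of one distribution against another
#'
#' The relative shift of a gene's UMIG-count distribution against the
#' all-genes distribution of the same sample: both distributions are
#' encoded as paired quantile vectors and a least-squares line is fitted
#' through the origin; its slope is the relative efficiency. Identical
#' distributions give slope 1, and a distribution scaled by a constant c
#' gives slope c.
#'
#' @param gene_counts,all_counts numeric vectors of UMIG counts; both
#'   must pass the `min_points` rule.
#' @param n_quantiles,min_points,type see [quantile_vector()].
#' @param with_intercept fit an ordinary intercept model instead of
#'   regression through the origin.
#' @return the slope (numeric scalar), or `NA` when either distribution
#'   is excluded.
#' @export
relative_efficiency <- function(gene_counts, all_counts, n_quantiles = 100,
                                min_points = 100, type = 7,
                                with_intercept = FALSE) {
  qy <- quantile_vector(gene_counts, n_quantiles, min_points, type)
  qx <- quantile_vector(all_counts, n_quantiles, min_points, type)
  if (is.null(qy) || is.null(qx)) return(NA_real_)
  if (all(qx == 0)) stop("all-genes quantile vector is identically zero",
                         call. = FALSE)
  if (with_intercept) unname(stats::coef(stats::lm(qy ~ qx))[2L])
  else sum(qx * qy) / sum(qx * qx)
}

#' Per-gene relative detectability across samples
#'
#' For every sample, the UMIG-count distribution of each V gene is
#' compared to the all-genes distribution of that sample (the focal gene
#' included) via [relative_efficiency()]; genes with fewer than
#' `min_points` unique rearrangements in a sample contribute no slope for
#' that sample. Per gene, the median slope over contributing samples is
#' taken and the medians are scaled so the least detectable gene equals
#' exactly 1.
#'
#' @param samples a named list of unique-rearrangement data frames (each
#'   with columns `v_call` and `umig_count`), one per sample.
#' @param n_quantiles,min_points,type,with_intercept passed through.
#' @return list of class `detectability_table` with `per_sample` (sample,
#'   gene, slope, n_obs) and `table` (gene, n_samples, median_slope,
#'   scaled_efficiency).
#' @export
detectability_table <- function(samples, n_quantiles = 100, min_points = 100,
                                type = 7, with_intercept = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (is.null(names(samples)))
    names(samples) <- sprintf("sample%02d", seq_along(samples))
  per_sample <- do.call(rbind, lapply(names(samples), function(s) {
    d <- samples[[s]]
    d <- d[!is.na(d$v_call), , drop = FALSE]
    genes <- sort(unique(d$v_call))
    if (!length(genes)) return(NULL)
    slope <- vapply(genes, function(g)
      relative_efficiency(d$umig_count[d$v_call == g], d$umig_count,
                          n_quantiles, min_points, type, with_intercept),
      numeric(1))
    n_obs <- vapply(genes, function(g) sum(d$v_call == g), integer(1))
    data.frame(sample = s, gene = genes, slope = unname(slope),
               n_obs = unname(n_obs), stringsAsFactors = FALSE)
  }))
  valid <- per_sample[!is.na(per_sample$slope), , drop = FALSE]
  if (is.null(valid) || !nrow(valid)) {
    warning("no gene passes the ", min_points, "-point rule in any sample")
    tab <- data.frame(gene = character(), n_samples = integer(),
                      median_slope = numeric(), scaled_efficiency = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    med <- tapply(valid$slope, valid$gene, stats::median)
    tab <- data.frame(gene = names(med),
                      n_samples = as.integer(table(valid$gene)[names(med)]),
                      median_slope = unname(med),
                      scaled_efficiency = unname(med) / min(med),
                      stringsAsFactors = FALSE)
    tab <- tab[order(tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(per_sample = per_sample, table = tab),
            class = "detectability_table")
}

#' @export
print.detectability_table <- function(x, ...) {
  cat(sprintf("Relative detectability over %d sample(s), %d gene(s)\n",
              length(unique(x$per_sample$sample)), nrow(x$table)))
  print(x$table, ...)
  invisible(x)
}

#' Correlation of detectability with gene-use frequency
#'
#' Simple linear fit of scaled efficiency on per-gene unique-sequence
#' frequency, reporting the coefficient of determination and the sign of
#' the fitted slope.
#'
#' @param table a [detectability_table()] result.
#' @param frequencies named numeric vector of per-gene frequencies.
#' @return list with `r_squared`, `slope_sign`, `slope` and `n_genes`.
#' @export
detectability_frequency_correlation <- function(table, frequencies) {
  tab <- table$table
  shared <- intersect(tab$gene, names(frequencies))
  if (length(shared) < 3)
    stop("need at least 3 genes shared between inputs", call. = FALSE)
  x <- unname(frequencies[shared])
  y <- tab$scaled_efficiency[match(shared, tab$gene)]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance in one of the variables; correlation undefined")
    return(list(r_squared = NA_real_, slope_sign = NA_integer_,
                slope = NA_real_, n_genes = length(shared)))
  }
  fit <- stats::lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope_sign = as.integer(sign(stats::coef(fit)[2L])),
       slope = unname(stats::coef(fit)[2L]), n_genes = length(shared))
}
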