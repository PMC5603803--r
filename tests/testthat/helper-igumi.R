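# shared fixtures and independent brute-force oracles

small_ref <- function(seed = 101, n_genes = 6)
  germline_reference(n_genes = n_genes, v_length = 120, j_length = 30,
                     c_length = 60, seed = seed)

default_ref <- function(seed = 101) germline_reference(seed = seed)

# simulate a small library in one call
sim_library <- function(n_cells = 100, depth = 20, error_rate = 0.003,
                        seed = 1, ref = default_ref(), copies_mean = 2) {
  prof <- gene_frequency_profile(ref)
  cells <- generate_repertoire(n_cells, prof, ref, seed = seed)
  pool <- transcribe_and_tag(cells, copies_mean = copies_mean, seed = seed + 1)
  reads <- amplify_and_sequence(pool, depth_multiplier = depth,
                                error_rate = error_rate, seed = seed + 2)
  list(cells = cells, pool = pool, reads = reads)
}

# brute-force greedy directional UMI clustering: scan existing seeds in
# creation order, merge into the first within max_errors (equal length)
oracle_cluster_umis <- function(umis, max_errors) {
  cnt <- table(umis)
  uniq <- names(cnt)
  ord <- order(-as.integer(cnt), uniq)
  uniq <- uniq[ord]
  seeds <- character()
  grp <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    g <- 0L
    for (j in seq_along(seeds)) {
      if (nchar(uniq[i]) != nchar(seeds[j])) next
      d <- sum(strsplit(uniq[i], "")[[1]] != strsplit(seeds[j], "")[[1]])
      if (d <= max_errors) { g <- j; break }
    }
    if (g == 0L) { seeds <- c(seeds, uniq[i]); g <- length(seeds) }
    grp[i] <- g
  }
  list(assignment = grp[match(umis, uniq)], seeds = seeds)
}

# brute-force per-column strict-majority consensus
oracle_consensus <- function(seqs) {
  lens <- nchar(seqs)
  lt <- table(lens)
  modal <- max(as.integer(names(lt)[lt == max(lt)]))
  out <- character(modal)
  for (p in seq_len(modal)) {
    covering <- seqs[lens >= p]
    ch <- substring(covering, p, p)
    tab <- table(ch)
    best <- names(tab)[which.max(tab)]
    out[p] <- if (max(tab) > length(covering) / 2) best else "N"
  }
  paste(out, collapse = "")
}

# brute-force greedy identity sub-clustering within one group
oracle_subcluster <- function(r1, threshold = 0.9, window = 150) {
  win <- substr(r1, 1, window)
  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    m <- min(length(ca), length(cb))
    if (m == 0) return(0)
    sum(ca[seq_len(m)] == cb[seq_len(m)]) / m
  }
  sub <- integer(length(r1))
  nid <- 0L
  remaining <- seq_along(r1)
  while (length(remaining)) {
    tab <- sort(table(win[remaining]), decreasing = TRUE)
    centroid <- names(tab)[1]
    member <- vapply(win[remaining], function(w) ident(w, centroid) >= threshold,
                     logical(1))
    nid <- nid + 1L
    sub[remaining[member]] <- nid
    remaining <- remaining[!member]
  }
  sub
}

# type-7 quantile by direct order-statistic interpolation
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, n)] - x[lo + 1])
}

# partitions equal up to relabelling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}
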