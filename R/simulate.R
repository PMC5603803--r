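#' Simulate a polyclonal B-cell repertoire
#'
#' Draws `n_cells` B cells, each with a V gene sampled from `profile` and
#' a random junction (HCDR3) of configurable length. Junctions are
#' pairwise distinct across naive cells — the modelling assumption that a
#' unique IGHV-D-J rearrangement marks a single cell — and each cell's
#' full transcript is leader+V, junction, J and constant segment, with the
#' junction flanked by the reference's anchor motifs and occurring exactly
#' once.
#'
#' @param n_cells number of cells (>= 1).
#' @param profile a [gene_frequency_profile()] (names subset of reference
#'   genes).
#' @param reference a [germline_reference()].
#' @param junction_length_range integer pair, junction length bounds in nt
#'   (default 30-60).
#' @param population cell population label, one of `"naive"`, `"memory"`,
#'   `"plasma"` (affects mRNA copy scaling in [transcribe_and_tag()]).
#' @param seed integer RNG seed.
#' @return a `simulated_cells` data frame with columns `cell_id`,
#'   `v_gene`, `junction`, `full_transcript`, `junction_start`,
#'   `junction_end` (0-based half-open), `n_mutations`, `population`.
#' @export
generate_repertoire <- function(n_cells, profile, reference,
                                junction_length_range = c(30, 60),
                                population = c("naive", "memory", "plasma"),
                                seed = 1) {
  validate_reference(reference)
  population <- match.arg(population)
  stopifnot(n_cells >= 1, length(junction_length_range) == 2,
            junction_length_range[1] >= 1,
            junction_length_range[1] <= junction_length_range[2])
  if (!all(names(profile) %in% names(reference$genes)))
    stop("profile genes must exist in the reference", call. = FALSE)
  space <- sum(4^pmin(junction_length_range[1]:junction_length_range[2], 30))
  if (n_cells > space)
    stop("junction space too small for ", n_cells, " distinct junctions",
         call. = FALSE)
  withr::with_seed(stage_seed(seed, "repertoire"), {
    v_gene <- sample(names(profile), n_cells, replace = TRUE, prob = profile)
    junctions <- draw_distinct_junctions(n_cells, junction_length_range,
                                         c(reference$anchor_5p, reference$anchor_3p))
  })
  cells <- assemble_cells(sprintf("cell%06d", seq_len(n_cells)), v_gene,
                          junctions, reference, population)
  cells
}

# distinct random junctions avoiding the anchor motifs
draw_distinct_junctions <- function(n, len_range, avoid) {
  lens <- if (len_range[1] == len_range[2]) rep.int(len_range[1], n) else
    sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  junc <- random_dna(n, lens, avoid = avoid)
  for (i in 1:100) {
    dup <- duplicated(junc)
    if (!any(dup)) return(junc)
    junc[dup] <- random_dna(sum(dup), lens[dup], avoid = avoid)
  }
  stop("could not draw pairwise distinct junctions", call. = FALSE)
}

# build transcripts and verify the junction occurs exactly once at its offset
assemble_cells <- function(cell_id, v_gene, junction, reference, population,
                           v_sequence = NULL, n_mutations = 0L) {
  genes <- if (is.null(v_sequence)) unname(reference$genes[v_gene]) else v_sequence
  transcript <- paste0(genes, junction, reference$j_segment,
                       reference$constant[[1]])
  junction_start <- nchar(genes)
  junction_end <- junction_start + nchar(junction)
  first <- vapply(seq_along(transcript), function(i)
    regexpr(junction[i], transcript[i], fixed = TRUE)[[1]], integer(1))
  again <- vapply(seq_along(transcript), function(i)
    regexpr(junction[i],
            substring(transcript[i], junction_start[i] + 2L),
            fixed = TRUE)[[1]], integer(1))
  ok <- first == junction_start + 1L & again == -1L
  if (!all(ok))
    stop("junction does not occur uniquely at its recorded offset for ",
         sum(!ok), " cell(s)", call. = FALSE)
  structure(
    data.frame(cell_id = cell_id, v_gene = v_gene, junction = junction,
               full_transcript = transcript, junction_start = junction_start,
               junction_end = junction_end,
               n_mutations = rep_len(n_mutations, length(cell_id)),
               population = rep_len(population, length(cell_id)),
               stringsAsFactors = FALSE),
    class = c("simulated_cells", "data.frame"))
}

#' Simulate a panel of clone spike-in signatures
#'
#' Builds a leukemic (CLL-like) clone panel: `n_clones` clones with
#' pairwise distinct junctions, of which `n_mutated` carry uniform random
#' substitutions in the V region at a divergence drawn uniformly from 1 to
#' 10 percent of the mutable V length (the anchor motif is left intact so
#' the junction stays locatable). The default design mirrors a 58-clone
#' panel with 21 mutated members.
#'
#' @param n_clones number of clones (default 58).
#' @param n_mutated number of clones carrying somatic-style V mutations
#'   (default 21; must not exceed `n_clones`).
#' @param reference a [germline_reference()].
#' @param junction_length_range junction length bounds.
#' @param seed integer RNG seed.
#' @return a `clone_panel` data frame with columns `clone_id`, `v_gene`,
#'   `junction`, `mutated`, `percent_divergence`, `n_mutations`,
#'   `v_sequence`, plus transcript geometry columns.
#' @export
generate_spikein_panel <- function(n_clones = 58, n_mutated = 21, reference,
                                   junction_length_range = c(30, 60),
                                   seed = 1) {
  validate_reference(reference)
  stopifnot(n_clones >= 0, n_mutated >= 0, n_mutated <= n_clones)
  if (n_clones == 0L) {
    return(structure(data.frame(clone_id = character(), v_gene = character(),
                                junction = character(), mutated = logical(),
                                percent_divergence = numeric(),
                                n_mutations = integer(),
                                v_sequence = character(),
                                stringsAsFactors = FALSE),
                     class = c("clone_panel", "data.frame")))
  }
  space <- sum(4^pmin(junction_length_range[1]:junction_length_range[2], 30))
  if (n_clones > space)
    stop("junction space too small for ", n_clones, " distinct clones",
         call. = FALSE)
  anchor_len <- nchar(reference$anchor_5p)
  withr::with_seed(stage_seed(seed, "spikein_panel"), {
    v_gene <- sample(names(reference$genes), n_clones, replace = TRUE)
    junction <- draw_distinct_junctions(n_clones, junction_length_range,
                                        c(reference$anchor_5p, reference$anchor_3p))
    mutated <- seq_len(n_clones) %in% sample.int(n_clones, n_mutated)
    v_sequence <- unname(reference$genes[v_gene])
    mutable_len <- nchar(v_sequence) - anchor_len
    pct <- ifelse(mutated, stats::runif(n_clones, 1, 10), 0)
    n_mut <- ifelse(mutated, pmax(1L, round(pct / 100 * mutable_len)), 0L)
    for (i in which(mutated)) {
      v_sequence[i] <- mutate_fixed_count(v_sequence[i], n_mut[i],
                                          region = c(1L, mutable_len[i]))
    }
  })
  realized <- ifelse(mutated, 100 * n_mut / mutable_len, 0)
  cells <- assemble_cells(sprintf("CLL%03d", seq_len(n_clones)), v_gene,
                          junction, reference, "spikein",
                          v_sequence = v_sequence,
                          n_mutations = as.integer(n_mut))
  panel <- data.frame(clone_id = cells$cell_id, v_gene = v_gene,
                      junction = junction, mutated = mutated,
                      percent_divergence = realized,
                      n_mutations = as.integer(n_mut),
                      v_sequence = v_sequence,
                      full_transcript = cells$full_transcript,
                      junction_start = cells$junction_start,
                      junction_end = cells$junction_end,
                      stringsAsFactors = FALSE)
  structure(panel, class = c("clone_panel", "data.frame"))
}

# per-population scaling of the mRNA copy mean, relative to the naive
# baseline: plasma:memory:naive = 500:5:2; spike-in clones are handled
# explicitly by build_spikein_experiment()
population_copy_scale <- c(naive = 1, memory = 2.5, plasma = 250, spikein = 1)

#' Reverse-transcribe cells into a UMI-tagged molecule pool
#'
#' Each cell yields a Poisson number of ds-cDNA molecules with mean
#' `copies_mean` scaled by its population (naive x1, memory x2.5, plasma
#' x250, i.e. the 500:5:2 plasma:memory:naive mRNA ratio when
#' `copies_mean = 2`). Every molecule receives an independent random UMI
#' whose length is uniform over `umi_length_range`.
#'
#' @param cells a `simulated_cells` data frame (or `clone_panel`-derived
#'   cells).
#' @param copies_mean naive-baseline mean mRNA copies per cell (default 2).
#' @param umi_length_range integer pair of UMI lengths (default 13-16).
#' @param seed integer RNG seed.
#' @param deterministic if `TRUE`, each cell yields exactly
#'   `round(copies_mean * scale)` molecules (for exact tests).
#' @return a `molecule_pool` data frame with columns `molecule_id`,
#'   `cell_id`, `umi`, `transcript`, `v_gene`, `junction`,
#'   `junction_start`, `junction_end`; attribute `n_source_cells`.
#' @export
transcribe_and_tag <- function(cells, copies_mean = 2,
                               umi_length_range = c(13, 16), seed = 1,
                               deterministic = FALSE) {
  stopifnot(copies_mean > 0, length(umi_length_range) == 2,
            umi_length_range[1] >= 1,
            umi_length_range[1] <= umi_length_range[2])
  mu <- copies_mean * unname(population_copy_scale[cells$population])
  withr::with_seed(stage_seed(seed, "transcribe"), {
    n_mol <- if (deterministic) as.integer(round(mu)) else stats::rpois(nrow(cells), mu)
    idx <- rep.int(seq_len(nrow(cells)), n_mol)
    total <- length(idx)
    umi_len <- if (umi_length_range[1] == umi_length_range[2])
      rep.int(umi_length_range[1], total) else
      sample(seq(umi_length_range[1], umi_length_range[2]), total, replace = TRUE)
    umis <- random_dna(total, umi_len)
  })
  pool <- data.frame(molecule_id = sprintf("mol%07d", seq_len(total)),
                     cell_id = cells$cell_id[idx],
                     umi = umis,
                     transcript = cells$full_transcript[idx],
                     v_gene = cells$v_gene[idx],
                     junction = cells$junction[idx],
                     junction_start = cells$junction_start[idx],
                     junction_end = cells$junction_end[idx],
                     stringsAsFactors = FALSE)
  structure(pool, class = c("molecule_pool", "data.frame"),
            n_source_cells = nrow(cells))
}

#' Binomially dilute a molecule pool
#'
#' Models splitting ds-cDNA into an aliquot: each molecule is retained
#' independently with probability `fraction` (binomial thinning). Truth
#' links to cells are preserved. The five dilution levels of the bench
#' design (1:1 ... 1:16) correspond to fractions 1, 1/2, 1/4, 1/8, 1/16.
#'
#' @param pool a `molecule_pool`.
#' @param fraction retention probability in (0, 1].
#' @param seed integer RNG seed.
#' @param deterministic if `TRUE`, retain a uniform random subset of
#'   exactly `round(n * fraction)` molecules.
#' @return the thinned `molecule_pool`; attribute `n_discarded` records
#'   the complement so that retained + discarded equals the input exactly.
#' @export
dilute_pool <- function(pool, fraction, seed = 1, deterministic = FALSE) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]", call. = FALSE)
  withr::with_seed(stage_seed(seed, "dilute"), {
    keep <- if (deterministic)
      seq_len(nrow(pool)) %in% sample.int(nrow(pool), round(nrow(pool) * fraction))
    else stats::runif(nrow(pool)) < fraction
  })
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(pool),
            n_source_cells = attr(pool, "n_source_cells"),
            n_discarded = sum(!keep))
}

#' Amplify a molecule pool and sequence paired-end reads
#'
#' PCR amplification is modelled as a per-molecule lognormal weight
#' (dispersion `pcr_sigma`); the source molecule of each read pair is then
#' drawn multinomially with probability proportional to its weight.
#' Exactly `round(depth_multiplier * n_starting_cells)` pairs are emitted,
#' in a deterministic shuffled order given the seed. Read 1 covers the 5'
#' end of the transcript with the molecule's UMI and a constant spacer
#' (partial adaptor) prepended; read 2 covers the 3' end
#' reverse-complemented. Independent per-base substitution errors at
#' `error_rate` are applied to both mates, UMI and spacer included.
#' Quality strings are a constant Q30 placeholder (consensus calling is
#' count-based).
#'
#' @param pool a `molecule_pool` (non-empty).
#' @param n_starting_cells cell count the depth multiplier refers to;
#'   defaults to the pool's `n_source_cells` attribute.
#' @param depth_multiplier raw read pairs per starting cell (e.g. 40
#'   means 5,000 cells yield 200,000 pairs).
#' @param error_rate per-base substitution probability in `[0, 0.25)`.
#' @param read_length maximum mate length (default 300).
#' @param pcr_sigma lognormal sdlog of amplification weights (default 0.5).
#' @param umi_spacer constant spacer between UMI and insert on read 1.
#' @param seed integer RNG seed.
#' @return a `read_pairs` data frame with columns `read_id`, `r1_seq`,
#'   `r1_qual`, `r2_seq`, `r2_qual` and truth columns `cell_id`,
#'   `molecule_id`, `true_umi`.
#' @export
amplify_and_sequence <- function(pool, n_starting_cells = attr(pool, "n_source_cells"),
                                 depth_multiplier, error_rate = 0.003,
                                 read_length = 300, pcr_sigma = 0.5,
                                 umi_spacer = "GCTAGCC", seed = 1) {
  stopifnot(nrow(pool) > 0, depth_multiplier > 0,
            error_rate >= 0, error_rate < 0.25, read_length >= 50,
            !is.null(n_starting_cells))
  umi_len <- nchar(pool$umi)
  spacer_len <- nchar(umi_spacer)
  tlen <- nchar(pool$transcript)
  r1_bio_len <- read_length - umi_len - spacer_len
  if (any(pool$junction_end > r1_bio_len))
    stop("read_length too short: the junction is not covered by read 1 ",
         "after the UMI and spacer", call. = FALSE)
  if (any(pool$junction_start < tlen - read_length))
    stop("read_length too short: the junction is not covered by read 2",
         call. = FALSE)
  n_pairs <- round(depth_multiplier * n_starting_cells)
  withr::with_seed(stage_seed(seed, "amplify"), {
    w <- stats::rlnorm(nrow(pool), 0, pcr_sigma)
    counts <- as.vector(stats::rmultinom(1, n_pairs, w))
    src <- sample(rep.int(seq_len(nrow(pool)), counts))
    r1 <- paste0(pool$umi[src], umi_spacer,
                 substr(pool$transcript[src], 1L, pmin(r1_bio_len[src], tlen[src])))
    r2 <- revcomp(substring(pool$transcript[src],
                            pmax(1L, tlen[src] - read_length + 1L), tlen[src]))
    e1 <- add_substitution_errors(r1, error_rate)
    e2 <- add_substitution_errors(r2, error_rate)
  })
  structure(
    data.frame(read_id = sprintf("sim%07d", seq_len(n_pairs)),
               r1_seq = e1$seqs, r1_qual = strrep("?", nchar(r1)),
               r2_seq = e2$seqs, r2_qual = strrep("?", nchar(r2)),
               cell_id = pool$cell_id[src], molecule_id = pool$molecule_id[src],
               true_umi = pool$umi[src], stringsAsFactors = FALSE),
    class = c("read_pairs", "data.frame"),
    umi_spacer = umi_spacer, error_rate = error_rate,
    n_starting_cells = n_starting_cells)
}

#' Build a clone spike-in molecule pool
#'
#' Emulates spiking clone lysates into a polyclonal background: for each
#' panel clone, a lysate of `lysate_cells` clonal cells is transcribed and
#' then binomially thinned by `cells_per_clone_equivalent / lysate_cells`
#' (the 1/200, 1/100, 1/50 lysate fractions for 0.5, 1, 2
#' cell-equivalents), and the result is merged with a freshly simulated
#' naive background repertoire.
#'
#' The expected molecule yield per clone is
#' `cells_per_clone_equivalent * clone_copies_mean`. The default
#' `clone_copies_mean = 5` models the memory-like mRNA content of mature
#' leukemic B cells; background naive cells use `copies_mean` (default 2).
#'
#' @param panel a [generate_spikein_panel()] result.
#' @param cells_per_clone_equivalent cell-equivalents of genetic material
#'   per clone (0.5, 1 or 2 in the bench design; must be in
#'   `(0, lysate_cells]`).
#' @param background_cells number of polyclonal naive background cells.
#' @param reference a [germline_reference()].
#' @param profile optional background gene profile (default uniform).
#' @param clone_copies_mean mean mRNA copies per spiked clone cell.
#' @param copies_mean naive-baseline copies for the background.
#' @param lysate_cells clonal cells per lysate tube (default 100).
#' @param umi_length_range UMI length bounds.
#' @param seed integer RNG seed.
#' @param deterministic exact copy counts and thinning (for tests).
#' @return a `molecule_pool`; attribute `n_source_cells` equals
#'   `background_cells + round(n_clones * cells_per_clone_equivalent)`.
#' @export
build_spikein_experiment <- function(panel, cells_per_clone_equivalent,
                                     background_cells, reference,
                                     profile = NULL, clone_copies_mean = 5,
                                     copies_mean = 2, lysate_cells = 100,
                                     umi_length_range = c(13, 16), seed = 1,
                                     deterministic = FALSE) {
  stopifnot(cells_per_clone_equivalent > 0,
            cells_per_clone_equivalent <= lysate_cells,
            background_cells >= 1)
  validate_reference(reference)
  profile <- profile %||% gene_frequency_profile(reference)
  clone_cells <- panel_to_cells(panel, lysate_cells)
  cpool <- transcribe_and_tag(clone_cells, copies_mean = clone_copies_mean,
                              umi_length_range = umi_length_range,
                              seed = stage_seed(seed, "clone_transcribe"),
                              deterministic = deterministic)
  if (nrow(cpool))
    cpool <- dilute_pool(cpool, cells_per_clone_equivalent / lysate_cells,
                         seed = stage_seed(seed, "lysate_thin"),
                         deterministic = deterministic)
  bg_cells <- generate_repertoire(background_cells, profile, reference,
                                  seed = stage_seed(seed, "background"))
  bpool <- transcribe_and_tag(bg_cells, copies_mean = copies_mean,
                              umi_length_range = umi_length_range,
                              seed = stage_seed(seed, "background_transcribe"),
                              deterministic = deterministic)
  if (nrow(cpool)) cpool$molecule_id <- paste0("sp_", cpool$molecule_id)
  if (nrow(bpool)) bpool$molecule_id <- paste0("bg_", bpool$molecule_id)
  pool <- rbind(cpool, bpool)
  rownames(pool) <- NULL
  structure(pool, class = c("molecule_pool", "data.frame"),
            n_source_cells = background_cells +
              round(nrow(panel) * cells_per_clone_equivalent))
}

# expand a clone panel into clonal cells (one lysate tube per clone)
panel_to_cells <- function(panel, lysate_cells) {
  if (!nrow(panel)) {
    return(structure(data.frame(cell_id = character(), v_gene = character(),
                                junction = character(),
                                full_transcript = character(),
                                junction_start = integer(),
                                junction_end = integer(),
                                n_mutations = integer(),
                                population = character(),
                                stringsAsFactors = FALSE),
                     class = c("simulated_cells", "data.frame")))
  }
  idx <- rep(seq_len(nrow(panel)), each = lysate_cells)
  structure(
    data.frame(cell_id = paste0(panel$clone_id[idx], "_",
                                sprintf("c%03d", sequence(rep(lysate_cells, nrow(panel))))),
               v_gene = panel$v_gene[idx], junction = panel$junction[idx],
               full_transcript = panel$full_transcript[idx],
               junction_start = panel$junction_start[idx],
               junction_end = panel$junction_end[idx],
               n_mutations = panel$n_mutations[idx],
               population = "spikein", stringsAsFactors = FALSE),
    class = c("simulated_cells", "data.frame"))
}
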