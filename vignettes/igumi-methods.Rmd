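---
title: "UMI-based error correction for Ig-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI-based error correction for Ig-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igumi)
```

## The problem

High-throughput sequencing of immunoglobulin heavy-chain rearrangements
(Ig-seq) aims to report which IGHV-D-J clones are present in a B-cell
sample and in what amounts. Two obstacles stand between raw MiSeq reads
and that answer: amplification noise (PCR favours some molecules over
others) and sequencing errors (which inflate diversity and corrupt clone
signatures). Tagging every ds-cDNA molecule with a unique molecular
identifier (UMI) before amplification makes both tractable: reads sharing
a UMI derive from one molecule, so a per-molecule consensus removes
sequencing errors, and the number of UMI groups (UMIGs) per unique
sequence — rather than the raw read count — proxies the number of mRNA
molecules observed.

`igumi` implements the complete computational side of such a protocol:

* a truth-tagged generative model of library preparation (`igsim`
  functions: `generate_repertoire()`, `transcribe_and_tag()`,
  `dilute_pool()`, `amplify_and_sequence()`,
  `build_spikein_experiment()`);
* UMI-based error correction (`extract_umi()`, `cluster_umis()`,
  `subcluster_by_identity()`, `build_consensus()`, `assemble_pairs()`,
  `filter_and_collapse()`, orchestrated by `process_reads()`);
* junction annotation (`locate_junction()`, `assign_gene()`);
* a quantile-regression estimate of per-gene relative detectability
  (`relative_efficiency()`, `detectability_table()`);
* spike-in sensitivity analysis across depth, input amount, filtering
  threshold and dilution (`detect_signatures()`, `sensitivity_grid()`,
  `threshold_sweep()`, `dilution_experiment()`).

Because every simulated read carries its source cell, molecule and UMI in
the FASTQ header, every downstream stage can be tested against a known
answer without any external data.

## The generative model

A **germline reference** is synthesized once (`germline_reference()`):
by default 20 leader+V segments of 200 nt, one J segment and one constant
segment. Two conserved 6-mers anchor the junction: every leader+V ends
with `TGTGCG` (echoing the conserved Cys codon that opens the CDR3) and
the J segment starts with `TGGGGC` (the conserved Trp-Gly motif that
closes it). Random segments are drawn rejecting these motifs, so each
anchor occurs exactly once per unmutated transcript and the HCDR3 can be
located by motif match, standing in for full V(D)J annotation. The
default leader+V length of 200 nt is chosen so that, with a 13–16 nt UMI
and spacer on read 1 of a 2×300 run, the junction (30–60 nt) is covered
by both mates — a geometric requirement of the filtering rules below;
`amplify_and_sequence()` raises a configuration error for geometries
that violate it. Real IGHV sequences can be supplied via
`read_germline_fasta()` provided they end with the configured 5' anchor.

A **repertoire** (`generate_repertoire()`) draws one V gene per cell from
a configurable frequency profile and one random junction per cell,
pairwise distinct — the modelling assumption that a naive B cell is
unexpanded, so a unique rearrangement marks a single cell.

**Transcription and tagging** (`transcribe_and_tag()`) gives each cell a
Poisson number of UMI-tagged ds-cDNA molecules. The naive baseline mean
is 2 copies per cell, and populations scale it as plasma : memory :
naive = 500 : 5 : 2. The absolute naive copy number is a modelling
choice — only the ratio is established — and 2 is taken as the baseline
consistent with that ratio; a `deterministic` mode gives exact counts for
tests. UMIs are uniform random sequences of length uniform on 13–16 nt.

**Amplification and sequencing** (`amplify_and_sequence()`) draws a
lognormal weight per molecule (sdlog 0.5 by default; the protocol itself
does not constrain amplification noise, so this is a dispersion knob) and
samples the source molecule of each read pair multinomially. Exactly
`round(depth_multiplier * n_starting_cells)` pairs are emitted — the
depth bookkeeping used throughout: 5,000 cells at 40× is 200,000 raw
pairs. Read 1 carries the UMI, then a constant 7 nt spacer, then the 5'
end of the transcript; read 2 is the reverse-complemented 3' end.
Substitution errors hit every base independently (default rate 0.003),
UMI and spacer included. Qualities are a constant Q30 placeholder: the
consensus caller is count-based, not quality-weighted.

The spacer deserves a note. UMI lengths vary per molecule (13–16 nt), so
a fixed-width extraction window cannot be declared. In the emulated
protocol the tagging primer leaves a constant partial-adaptor remnant
between the UMI and the insert; `extract_umi()` finds it at one of the
four allowed offsets and splits there. Reads whose spacer is destroyed by
an error (about `1-(1-e)^7` of reads) are discarded and counted.

**Spike-ins** (`generate_spikein_panel()`,
`build_spikein_experiment()`) model adding leukemic (CLL-like) clone
lysates to a polyclonal background. The default panel holds 58 clones, 21
of which carry uniform random V-region substitutions at a divergence
drawn from 1–10%; anchors are left intact so the junction stays
locatable. Each clone lysate contains 100 clonal cells; spiking `q`
cell-equivalents thins the clone's molecules binomially by `q/100`, so
the expected molecule yield per clone is `q * clone_copies_mean`.
`clone_copies_mean` defaults to 5: leukemic CLL cells are
antigen-experienced mature B cells, and a memory-like mRNA content (5
copies, versus the naive 2) is the realistic choice; it also reproduces
the qualitative sensitivity pattern of the bench experiments (complete
coverage of the panel at 2 cell-equivalents and 10× depth, with 0.5–1
cell-equivalents requiring deeper sequencing). Callers can set any other
value, including the naive baseline.

**Dilution** (`dilute_pool()`) is binomial thinning of the tagged
molecule pool — the in-silico analogue of splitting ds-cDNA into
aliquots — and is applied after tagging, matching the bench design where
aliquots of tagged ds-cDNA are diluted 1:1 … 1:16 while sequencing
effort per aliquot is held constant.

## Error correction

1. **UMI clustering** (`cluster_umis()`): observed UMIs are sorted by
   descending read support (ties broken lexicographically) and processed
   greedily: each UMI merges into the earliest-created seed within one
   substitution, or seeds a new group. The greedy directional order
   prevents single-linkage chaining; UMIs of different length never
   merge, because length is primer-determined and a cross-length merge
   would conflate molecules. `max_errors = 0` recovers plain grouping by
   identity.
2. **Identity sub-clustering** (`subcluster_by_identity()`): within each
   UMI group, reads are partitioned by ≥90% identity over the first
   150 nt of read 1 (the high-quality region), separating independent
   molecules that were tagged with the same or a near-identical UMI. The
   centroid of each subgroup is the most frequent exact window string
   (ties lexicographic), making the partition deterministic; reads
   shorter than the window are compared over the shared prefix rather
   than discarded. The window is evaluated on read 1 only — its start is
   the best-quality stretch of the pair — and both threshold and window
   are configurable.
3. **Consensus** (`build_consensus()`): per position, the strict-majority
   base over covering reads; no majority means `N`. The consensus length
   is the modal read length of the subgroup. No quality weighting is
   used anywhere.
4. **Junction-on-both-mates filter** (`require_cdr3_on_both_mates()`):
   a subgroup is usable only if the junction anchors are found on the
   read-1 consensus and on the reverse-complemented read-2 consensus.
5. **Assembly** (`assemble_pairs()`): maximal-scoring ungapped overlap of
   at least 20 nt with at most 10% mismatches, seeded by exact 20-mers
   with a full scan fallback. Within the overlap, an `N` on one mate
   yields to the other mate's base; a hard disagreement takes the read-1
   base and is counted — a deterministic rule that is rare at default
   error rates.
6. **Pass filter and collapse** (`filter_and_collapse()`): a record
   passes with ≥3 reads, or is rescued when its exact full-length
   sequence recurs in ≥3 distinct subgroups. The rescue is applied after
   assembly on full-length sequences — exact full-length identity is the
   stronger condition — and both thresholds are configurable
   (`min_reads` drives the threshold sweeps). Passing records with
   identical sequences collapse into unique rearrangements accumulating
   UMIG and read counts.

`locate_junction()` then delimits the HCDR3 between the anchor motifs and
`assign_gene()` assigns the V gene by alignment-free positional identity
of the pre-junction region (the simulator's sequences are co-linear;
a user aligner can replace this step for real data). One subtlety: the
junction is taken between the *last* occurrence of each anchor — the
pair closest to the junction — not the first. On unmutated transcripts,
where each anchor occurs exactly once by construction, the two rules
coincide; but a somatic mutation in a spike-in clone can recreate an
anchor motif upstream in V, and a first-occurrence rule would then
systematically mislocate the junction of that clone in every replicate.

## Relative detectability

For a gene's UMIG-count distribution within a sample, the distribution is
encoded as the vector of its 0%, 1%, …, 99% empirical quantiles and
paired with the same encoding of the sample's all-genes distribution
(focal gene included — the literal "all genes"). The slope of the
least-squares line through the origin fitted to these pairs is the
gene's relative efficiency: identical distributions give slope 1 and a
distribution scaled by `c` gives slope `c`. The regression is through
the origin because the slope is interpreted as a pure relative shift and
because an intercept would break the identity-slope property; a
`with_intercept` switch is provided since the alternative reading is
defensible. Quantiles use linear interpolation between order statistics
(type 7), a convention the protocol does not fix; it is configurable.
Distributions with fewer than 100 points carry less resolution than the
quantile grid and are excluded (the cut is exact: 99 observations are
always excluded, 100 always eligible). Per gene, the median slope across
contributing samples is scaled so the least detectable gene equals
exactly 1.

## Spike-in evaluation

`detect_signatures()` calls a clone detected when a passing unique
rearrangement's junction matches the clone junction, exactly by default:
junctions are the discriminative signature, and the consensus machinery
is expected to deliver them error-free; a mismatch allowance exists for
noisy settings. "Complete coverage" of a condition means every panel
clone detected in every replicate. `sensitivity_grid()` simulates fresh
lysate pools per replicate and input amount and sequences each at every
depth; `threshold_sweep()` re-applies the pass filter at `min_reads`
2–10 on retained records; `dilution_experiment()` thins each tube's
tagged pool to each fraction at constant sequencing effort and relates
undiluted UMIG counts to detection after the strongest dilution by
Spearman rank correlation. Per-clone copy-number heterogeneity beyond
the lognormal amplification dispersion is deliberately off by default,
for reproducibility.

## What the simulator does and does not emulate

Emulated: polyclonal naive repertoires with configurable gene
frequencies and unique junctions; Poisson mRNA copy numbers with
population scaling; 13–16 nt UMIs attached once per molecule; lognormal
PCR weight dispersion; uniform substitution sequencing errors; clone
lysate spike-ins at fractional cell-equivalents; binomial ds-cDNA
dilution; exact depth bookkeeping.

Not emulated: indels and cycle-dependent quality decay; somatic
hypermutation hotspots (spike-in mutations are uniform); isotype
switching and allele-level variation; chimeric reads; primer-specific
amplification bias beyond the lognormal knob; real IMGT germline
sequences (synthetic by default). Passing tests therefore demonstrate
the correctness and calibration of the algorithms under this model, not
performance on any particular real dataset — in particular, real data
would add indel errors the UMI matcher ignores and quality information
the consensus caller does not use.

## Numerical and scale choices in the test-suite

The packaged checks run the full pipeline at desk scale: the depth
contract at 5,000 cells × 40× (200,000 pairs); end-to-end recovery on a
500-cell, 40×, 0.3%-error library (≥95% of represented junctions,
unique-rearrangement count within 5% of the represented cell count); the
58-clone panel at 2 cell-equivalents, 5,000-cell background and 10×
depth in triplicate (complete coverage); monotonicity of detection in
depth, input, threshold and dilution on a 6-clone, 80-cell design over
10 seeds; and brute-force oracle equivalence for clustering,
sub-clustering, consensus and quantiles on instances of ≤15 reads or
≤200 counts. The grouping-mode comparison (single-error clustering
versus identity-only) is run at ~6 reads per molecule — the
reads-per-UMIG regime of the bench data (mean read count ~30 against
mean UMIG count ~5–8 per unique sequence) — because at the simulator's
naive yield a nominal 40× depth leaves every group far above the 3-read
filter and the comparison degenerates; directions, not magnitudes, are
asserted.

## Known limitations

* The greedy directional UMI merge is order-dependent by design;
  pathological support ties are resolved lexicographically, which is
  deterministic but arbitrary.
* `assign_gene()` assumes co-linearity and will not handle real indels;
  it is a stand-in for proper V(D)J alignment.
* The detectability slope assumes the two quantile vectors are
  comparable encodings; with fewer than 100 observations this breaks
  down, hence the hard exclusion rather than a small-sample correction.
* Junction uniqueness per naive cell is enforced within a sample, so
  cross-sample clone tracking is out of scope.
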