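# igumi

UMI-based error correction, detectability estimation and spike-in
sensitivity analysis for immunoglobulin heavy-chain repertoire
sequencing (Ig-seq) — together with a truth-tagged simulator of the
entire library-preparation protocol, so that every stage of the analysis
can be validated against a known answer without any external data.

## Who this is for

Ig-seq quantifies which IGHV-D-J rearrangements (B-cell clones) are
present in a sample and in what amounts. Protocols that tag each ds-cDNA
molecule with a unique molecular identifier (UMI, here 13–16 random nt)
before PCR can correct sequencing errors by per-molecule consensus and
use the number of UMI groups (UMIGs) per unique sequence as a proxy for
mRNA molecules observed. `igumi` is for method developers and analysts
who need the computational half of such a protocol: read grouping and
consensus calling, filtering, junction annotation, per-gene
detectability metrics, and sensitivity evaluation against spiked-in
clone signatures — plus a generative model to test all of it.

## The method in brief

Raw paired reads are transformed into error-corrected unique
rearrangements by:

1. **UMI extraction** from the read-1 prefix;
2. **UMI clustering** allowing one substitution in the UMI, by greedy
   directional merge (descending read support);
3. **identity sub-clustering** within each UMI group: ≥90% identity over
   the first 150 nt, separating distinct molecules that share a UMI;
4. **strict-majority consensus** per subgroup and mate (no majority →
   `N`), requiring the HCDR3 junction on *both* mates;
5. **paired-end assembly** (ungapped overlap ≥20 nt, ≤10% mismatch);
6. **pass filter**: ≥3 reads, or the same full-length sequence from ≥3
   distinct UMIGs; passing records collapse into unique rearrangements
   with UMIG and read counts.

Per-gene **relative detectability** compares a gene's UMIG-count
distribution with the sample's all-genes distribution: both are encoded
as vectors of 100 quantiles (0%…99%; distributions with <100 points are
excluded) and the slope of the least-squares line through the origin on
the paired quantiles is the gene's relative efficiency. Gene medians
across samples are scaled so the least detectable gene is exactly 1.

**Spike-in evaluation** detects known clone junctions among passing
rearrangements and maps sensitivity across sequencing depth (raw pairs
per starting cell), input amount (cell-equivalents per clone), read-count
threshold, and ds-cDNA dilution.

## Worked example

```r
library(igumi)

reference <- germline_reference(seed = 101)       # synthetic germline locus
profile   <- gene_frequency_profile(reference)    # uniform gene usage
cells     <- generate_repertoire(500, profile, reference, seed = 1)
pool      <- transcribe_and_tag(cells, copies_mean = 2, seed = 2)
reads     <- amplify_and_sequence(pool, depth_multiplier = 40,
                                  error_rate = 0.003, seed = 3)
result    <- process_reads(reads, reference)
result$log
```

```
             n_reads_in              n_umi_fail            n_reads_kept
                  20000                     390                   19610
           n_umi_groups             n_subgroups             n_cdr3_fail
                   1017                    1017                       1
          n_unassembled        n_records_usable n_unique_rearrangements
                      0                    1016                     427
```

500 cells at 40× depth give exactly 20,000 raw pairs; 390 reads lose
their UMI to spacer errors; the 19,610 survivors form 1,017 UMI groups
(the pool held 1,017 tagged molecules), and after consensus, assembly
and filtering, 427 unique rearrangements remain. The simulation's truth
tags show what that means: 428 of the 500 cells yielded at least one
molecule, and 427 of their junctions are recovered exactly:

```r
head(result$rearrangements[, c("umig_count", "read_count", "v_call", "junction")], 3)
```

```
  umig_count read_count     v_call                                           junction
1          8        159 IGHV-SIM07    CGCAAACGCGGGGGGGGAAGCGGTAGAGGGTTGGTGTTCTGCCAGCCTAG
2          7        147 IGHV-SIM14            CCACCCGCGACTCACAGGTTTTAGAACAGTGAGGATTAGGAC
3          6        126 IGHV-SIM07 TCCAAACAAAATAGAGGGCAGTCACCCCGCCACAGTCGGTATAACTAAAAACG
```

Here `umig_count` is the molecule proxy: the top clone was observed as 8
independent ds-cDNA molecules totalling 159 reads.

A thin command-line wrapper is provided in `exec/igumi` with subcommands
`simulate`, `process`, `detectability`, `spikein-eval` and `report`, all
driven by a YAML configuration (see `read_run_config()`).

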