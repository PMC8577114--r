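# cleavemap

Locate protease cleavage sites from label-free quantitative proteomics of
active-versus-inactive enzyme digests.

## The problem

Protease substrate discovery by "degradomics" compares two parallel digests
of a candidate substrate: one with the active wild-type (WT) enzyme and one
with its catalytically dead active-site mutant (EQ). After trypsinisation
and a semi-tryptic LC-MS/MS search, peptides with one terminus that trypsin
could not have made mark protease cleavage events: a semi-tryptic
N-terminal peptide starting at residue *i* exposes P1′ = *i* of a scissile
bond, a semi-tryptic C-terminal peptide ending at *j* exposes P1 = *j*
(Schechter–Berger nomenclature). `cleavemap` turns a search-engine peptide
export plus the protein FASTA into a deduplicated, domain-annotated table
of scissile-bond calls with supporting and spanning (bridging) peptide
evidence. It is aimed at protease biologists and proteomics analysts who
have peptide-level quantitation in hand and want reproducible site calls
rather than spreadsheet arithmetic.

## The statistic

Per peptide, replicate abundances are aggregated (mean of observed
replicates), converted to a condition ratio — peptides seen in only one
condition receive a scaled fold-change of 100 (log2 = 6.64) so they remain
scorable — log2-transformed, and standardised within each peptide class:

    z_i = (x_i − mean(x)) / sd(x),   x_i = log2(ratio_i)

with moments over the same class population: semi-tryptic peptides on the
WT/EQ orientation, fully tryptic peptides on the EQ/WT orientation (their
informative direction is elevated abundance in the control, which supports
cleavage of the stretch they bridge). Significance is strict, `z > 2`.
Significant semi-tryptic termini are collapsed into per-bond calls, with
modification forms, opposite-side evidence and time points merged, and
every call annotated with its protein domain and any spanning peptides.

A seeded synthetic-experiment generator (`simulate_experiment()`) emulates
the full data structure — tryptic background, WT-only products at planted
sites, condition-balanced contaminant cleavages, log-normal noise,
abundance-dependent dropout — so the entire chain is testable by parameter
recovery. Two deterministic synthetic stand-in constructs
(`synthetic_adamts8()`, `synthetic_opn_b()`) carry the documented sequence
landmarks of an ADAMTS-family protease and of osteopontin isoform b for
worked examples; they are engineered sequences, not the real UniProt
entries.

## Worked example

```r
library(cleavemap)

sim <- simulate_experiment(simulation_config(seed = 42))
res <- run_pipeline(run_config(fasta = sim$proteins,
                               tables = list(run1 = sim$table)))
#> [cleavemap] run1: read 2344, located 2344 (unmatched 0, ambiguous 0),
#>             quantified 2344, significant 48, calls 23

head(res$report[, c("protein", "p1", "site", "domain", "best_z",
                    "n_supporting", "n_spanning")], 5)
#> # A tibble: 5 x 7
#>   protein           p1 site            domain       best_z n_supporting n_spanning
#> 1 SYN_BACKGROUND  1552 Asp1552-Lys1553 inter-domain    2.5            1          3
#> 2 SYN_BACKGROUND  4627 Val4627-Arg4628 inter-domain    2.5            1          4
#> 3 SYN_SUBSTRATE     12 Pro12-Phe13     inter-domain    2.5            1          3
#> 4 SYN_SUBSTRATE     23 Met23-Phe24     inter-domain    2.5            1          5
#> 5 SYN_SUBSTRATE     58 Ala58-Ser59     inter-domain    2.5            1          6

sc <- score_calls(res$calls, sim$truth)
sprintf("recall %.2f  precision %.2f  (%d calls)", sc$recall, sc$precision,
        sc$n_calls)
#> [1] "recall 1.00  precision 0.87  (23 calls)"
```

The log line is the pipeline's stage accounting: 2,344 peptides read and
located, 48 significant at `z > 2`, collapsing to 23 scissile-bond calls.
Each report row is one bond: `Asp1552-Lys1553` means cleavage between
Asp 1552 (P1) and Lys 1553 (P1′); `best_z` is the strongest evidence
peptide's z; `n_spanning` counts fully tryptic peptides bridging the bond.
Scored against the simulation truth, all 20 planted sites were recovered
(recall 1.00) along with 3 false calls (precision 0.87) — balanced
background peptides that happened to drop out of both control replicates,
the generator's dominant false-positive mechanism.

For file-based work there is a thin command-line wrapper at
`inst/scripts/cleavemap.R` with `simulate` and `run` subcommands (YAML run
config; FASTA, TSV tables and domain-interval YAML in; TSV reports and a
JSON run summary out). `inst/extdata/synthetic_domains.yaml` shows the
domain-config format.

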