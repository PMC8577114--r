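---
title: "Mapping protease cleavage sites from semi-tryptic peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping protease cleavage sites from semi-tryptic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The experimental design this package analyses

A protease of interest is incubated with a candidate substrate (or with
itself, to probe autolysis) in two parallel digests: one with the active
wild-type (WT) enzyme and one with a catalytically inactive active-site
mutant (EQ, a Glu-to-Gln substitution). Both digests are trypsinised and
analysed by label-free quantitative LC-MS/MS with a *semi-tryptic* search.
Trypsin cleaves after Lys/Arg; a peptide whose one terminus does not follow
that rule must have been created by another protease. Under the
Schechter–Berger nomenclature the residues flanking the scissile bond are P1
(N-terminal side) and P1′ (C-terminal side):

* a **semi-tryptic N-terminal** peptide starting at residue *i* exposes
  P1′ = *i*, i.e. the bond (*i* − 1, *i*);
* a **semi-tryptic C-terminal** peptide ending at residue *j* exposes
  P1 = *j*, i.e. the bond (*j*, *j* + 1).

Semi-tryptic peptides that are much more abundant in the WT digest than in
the EQ control are evidence for a protease-specific cleavage; fully tryptic
peptides *bridging* (spanning) a candidate bond at higher abundance in the
EQ control corroborate the call, because the stretch stays intact when the
enzyme is dead.

`cleavemap` implements this whole chain: peptide-table parsing, exact
localisation against the protein FASTA, terminus classification, condition
comparison, a per-class z statistic, scissile-bond calling with evidence
merging across modification forms and time points, spanning-peptide
cross-checks, and domain annotation.

## Terminus classification

Against each located peptide's parent protein, with digestion rules
(cleave after K/R, no cleavage before Pro, at most 2 missed cleavages —
all configurable via `digestion_rules()`):

* the N terminus is *tryptic* if the preceding residue is K/R and the
  peptide does not start with Pro (when the proline block is on);
* the C terminus is *tryptic* if the last residue is K/R and the following
  residue is not Pro;
* termini at the protein ends, at position 2 (initiator-Met removal) or at
  an annotated mature-form start (e.g. the furin-processing site of a
  zymogen) are *protein-terminal*: real termini, but never cleavage
  evidence;
* exactly one non-tryptic terminus makes the peptide semi-tryptic (N or C);
  two make it non-tryptic, and such peptides never drive a site call on
  their own.

Classification depends only on the peptide's position and flanking
residues, never on its modifications, so modified and unmodified forms of
one peptide always agree.

A structural blind spot follows from the design: a protease cleavage after
K/R (not followed by Pro) produces termini indistinguishable from trypsin's
own, so the method cannot see such sites. The simulator warns when asked to
plant one, and recovery metrics exclude them by default.

## The quantitative statistic

Per condition, replicate abundances are aggregated as the mean of
*observed* replicates (missing replicates are absent, not zero; `sum` is
available). The ratio is then:

* both conditions observed: plain ratio;
* observed only in the numerator (WT for semi-tryptic peptides): the
  **scaled fold-change**, default 100 (log2 ratio 6.64);
* observed only in the denominator: its reciprocal (0.01);
* observed in neither: the peptide is dropped. A present-but-zero
  denominator is treated as absent (and logged via the `scaled` flag).

Ratios are log2-transformed and standardised *within each peptide class*:

$$ z_i = \frac{x_i - \bar{x}}{s_x}, \qquad x_i = \log_2(\text{ratio}_i) $$

with the mean and standard deviation taken over the same class population —
semi-tryptic peptides (scored on the WT/EQ orientation) separately from
fully tryptic peptides (scored on the EQ/WT orientation, where elevated
abundance in the control is the informative direction). Significance is the
strict inequality `z > 2`. Scaled peptides are included in the moment pool
by default (`include_scaled_in_moments = FALSE` excludes them) and receive
exactly the same z as an unscaled peptide with the same log2 ratio. The
standard deviation uses the sample (n − 1) form by default.

Two deliberate choices deserve a note:

* **z on log2 ratios, not raw ratios.** The transform symmetrises up- and
  down-regulation and keeps the scaled fold-change from dominating the
  variance; it is also what makes the "population mean 0 / sd 1" invariant
  hold exactly.
* **Why the statistic has power at all.** In real semi-tryptic searches the
  large majority of semi-tryptic identifications are condition-balanced
  background (in-source fragmentation, contaminating proteases acting on
  both digests). Protease products are scored as outliers against that
  majority. If protease products dominated the population the z score would
  saturate below any threshold — a structural property of the statistic,
  not an implementation detail — which is why the simulator's defaults
  produce a realistic excess of balanced background (below).

**Degenerate dispersion.** With fewer than two class members, or a class
whose log2 ratios are all equal, the z score is undefined and
`compute_zscores()` raises an error. The pipeline (`run_pipeline()`)
instead falls back, with a warning, to a documented rule: numerator-only
(scaled) peptides are significant, everything else is not. The fallback
matters only in degenerate limits — most prominently the noise-free
simulation limit, where every semi-tryptic peptide sits at exactly the
scaled fold-change; in the limit of an arbitrarily large threshold-free
population those peptides are the ones whose ratios exceed any finite
threshold, which is what the rule encodes.

## Site calling, merging, and spanning evidence

Significant semi-tryptic peptides are converted to scissile bonds as above,
and bonds are deduplicated: opposite-side evidence (an N-exposing and a
C-exposing peptide of the same bond) and different modification forms merge
into one call whose `best_z` is the maximum over its evidence.
`merge_evidence()` extends the same rule across runs or time points; time
point labels are free strings and merging across them is always explicit.
Merging is idempotent and order-independent, and a bond never merges across
proteins.

`spanning_support()` attaches every fully tryptic peptide covering both P1
and P1′ (`start ≤ P1` and `end ≥ P1′`; a peptide starting exactly at P1′
does not span). Each spanning peptide is labelled *supportive* (tryptic
orientation z above threshold, i.e. enriched in the control), *contrary*
(below the negative threshold) or *neutral*. Contrary evidence is reported
but never vetoes a call — distinguishing artefacts from genuine partial
proteolysis is the analyst's judgement, not the pipeline's.

Denominator-only semi-tryptic peptides (found exclusively in the EQ
control) are not cleavage evidence for the active enzyme; they are reported
in a separate table with a flag when they span a called bond, which — like
a supportive spanning tryptic peptide — indicates the region stayed intact
in the control.

## Sequence-level utilities

* `scan_motif()` scans X/B patterns such as the heparin-binding consensus
  XBBXBX (B = K/R). "X" is permissive by default — it may itself match a
  basic residue — because the stricter reading ("any *other* amino acid")
  is ambiguous in common usage; `x_excludes_basic = TRUE` selects it.
* `scan_sequons()` reports all N-X-S/T sequons (X ≠ P) at the Asn position.
  This is the plain consensus; neural-network glycosylation predictors
  score context and typically return a subset.
* `extinction_coefficient()` implements the ProtParam composition rule
  (5500·nW + 1490·nY + 125·⌊nC/2⌋ with paired cysteines) and
  `average_mass()` sums average residue masses plus one water.
* `map_isoform_coord()` maps osteopontin isoform-b positions to isoform a
  (+14 from residue 58, where b lacks residues 58–71 of a).
* `percent_identity()` consumes a supplied alignment and counts identical
  columns over columns where at least one sequence is ungapped. This
  denominator is stated because published identity figures are
  aligner-dependent and not reproducible from sequences alone; the function
  never produces an alignment.
* `annotate_position()` uses 1-based inclusive intervals; overlaps resolve
  to the first-listed interval; positions outside all intervals are
  "inter-domain".

## Synthetic stand-in sequences

The two bundled constructs, `synthetic_adamts8()` and `synthetic_opn_b()`,
are *synthetic*: deterministic random sequences into which the documented
landmarks of the two study proteins are engineered — cleavage-site residue
pairs at the published coordinates, the GRRAKY heparin-binding stretch at
567, five N-glycosylation sequons, a furin site, tryptic anchors around
each site, domain layouts, and (for the protease construct) a Trp/Tyr/Cys
composition whose FLAG-tagged extinction coefficient is 95,195 M⁻¹cm⁻¹ and
whose precursor/mature masses calibrate to ≈95/70 kDa. They exercise every
sequence-level computation at realistic scale, but they share no identity
with the real UniProt entries, and results on them validate the *code*, not
the biology of the real proteins.

## The synthetic experiment generator

`simulate_experiment()` emulates the structure of the deposited dataset:
two conditions (WT/EQ), two technical replicates, a tryptic background with
up to two missed cleavages, semi-tryptic products at planted sites present
only in the WT condition, and condition-balanced contaminant cleavages.
Defaults, chosen once as a realistic experiment and fixed:

| parameter | default | rationale |
|---|---|---|
| substrate length | 1000 aa | a large secreted glycoprotein |
| background protein | 8000 aa | co-purifying conditioned-medium proteins, concatenated; real searches run against the whole proteome |
| planted sites | 20, efficiency U(0.5, 1) | efficiency scales product abundance |
| replicates | 2 per condition | technical duplicates |
| baseline log2 abundance | N(20, 1) | narrow range of a purified digest |
| replicate CV | 0.2 | multiplicative log-normal noise |
| dropout | 0.1 at the baseline mean | logistic in log2 abundance, slope 0.3 per log2 unit (0 = uniform) |
| contaminant rate | 0.02 per bond | balanced background cleavages |
| fragments per cleavage | one observable side | detectability; `sides = "both"` available |
| peptide length | 6–40 aa | observable window |

The large balanced background is what gives the z statistic its contrast
(see above): with these defaults a simulated experiment carries roughly
150–200 balanced semi-tryptic peptides against 20 planted products, so
products sit several population standard deviations above the mean.
Dropout is the main error source in both directions: a product dropped from
both WT replicates is a miss; a balanced background peptide dropped from
both EQ replicates mimics a WT-only product and becomes a false call at the
scaled fold-change.

What the generator deliberately does **not** model: search-engine
identification errors (FDR), retention-time alignment artefacts,
charge-state and modification-level splitting of peptide signals,
ratio compression, or correlated (batch) dropout. Passing recovery tests
therefore demonstrates that the statistical chain is implemented correctly
under the stated generative model, not that the method is robust to every
failure mode of real LC-MS/MS data.

The test suite measures parameter recovery over 50 seeds of the default
configuration (about 2,400 peptides per seed) and in the noise-free limit
(5 sites, no noise, no dropout, no contaminants), where recovery must be
exact. Scoring (`score_calls()`) computes recall over planted non-blind
sites and precision over all calls; with no calls precision is undefined
and reported as `NA` rather than 0.

## Numerical and policy details

* Coordinates are 1-based with inclusive interval ends everywhere; bonds
  are written (P1, P1′) with P1′ = P1 + 1.
* Significance is strictly `z > threshold`: a peptide at exactly the
  threshold is not significant.
* Peptides matching no protein, or more than one position across the
  supplied FASTA (overlapping occurrences count), are excluded and logged,
  never guessed. I/L-equivalent matching is available (`il_equivalent`)
  and off by default, since MS cannot distinguish the two residues but
  most search engines report a single localisation.
* Duplicate (sequence, modifications) table rows are aggregated by
  summation with a warning — the common cause is charge-state splitting,
  for which summation is the standard practice.
* Reports round z and log2 ratios to one decimal; full precision is kept
  internally and in the returned tibbles.
* All pipeline stages are deterministic; the only randomness in the
  package lives in the simulator and derives entirely from its mandatory
  seed.
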