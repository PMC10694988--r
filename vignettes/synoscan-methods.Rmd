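---
title: "Scoring synonymous codon substitution screens with synoscan"
author: "synoscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring synonymous codon substitution screens with synoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synoscan)
```

## The experimental design being modelled

A toxin–antitoxin (TA) operon such as *ccdAB* couples toxin expression to
cell fate twice over: free toxin kills a sensitive host, and the
toxin–antitoxin complex autorepresses the operon promoter. A library of
*single synonymous codon substitutions* in the toxin gene — every
degenerate codon at every position — is transformed into three strains:

* a **resistant** strain (neutral; measures library composition),
* a **sensitive** strain (survival falls with free toxin),
* a **reporter** strain carrying a RelE toxin gene under the operon
  promoter (survival rises with the amount of repressing complex).

Deep sequencing of the recovered plasmid pools, in two biological
replicates per strain, yields the per-variant read-count tables this
package starts from. `synoscan` deliberately begins at count tables:
demultiplexing and variant calling from raw reads are upstream concerns.

## From counts to enrichment scores

The container is `SynMutExperiment`, a `SummarizedExperiment` whose rows
are variants (plus exactly one reference row) and whose columns are the
six strain × replicate conditions. `scoreVariants()` runs, in order:

1. **Depth filter.** A variant must have ≥ 20 resistant-strain reads in
   *both* replicates. The threshold is inclusive ("fewer than 20 are
   discarded" makes 20 the smallest retained count) and the reference row
   is exempt — every downstream score is a ratio to it, so dropping it is
   never useful, and a zero reference count is instead a hard error at
   scoring time.
2. **Fractions.** Within each condition, counts are divided by the column
   total over the *retained* set, so fractions are a proper composition
   (sum 1 within 1e-12) of the analysed variants. Whether the original
   analysis normalised before or after filtering is not determinable from
   its description; recomputing after filtering is the reading under which
   the fractions describe the analysed set, and enrichment scores are
   nearly invariant to the choice because the discarded mass is shared by
   numerator and denominator conditions.
3. **Ratios and scores.** Per replicate, the deep-seq ratio
   F(selective)/F(resistant) is normalised by the reference variant's
   ratio; the reference therefore scores exactly 1 by construction, not by
   convergence. Replicates are combined by arithmetic mean on the linear
   scale (the geometric mean is available via `average = "geometric"`).
   One practical consequence, asserted in the test suite: re-referencing a
   library to a different anchor variant (as done when a parent
   hyperactive mutation is the new "wild type") commutes with scoring per
   replicate, but not after arithmetic averaging.
4. **Degree of variation.** Scores are multiplicative, so spread within a
   codon position is measured on fold distances `x = max(ES, 1/ES)`:
   `DoV = log2(x / x_min)` with the per-position minimiser at exactly 0.
   Selective dropouts (ES = 0) are flagged `depleted` and excluded from
   DoV with a warning; a pseudocount mode (`pseudocount = 0.5`) keeps
   log statistics defined when needed.
5. **Classification.** Hyperactive below 0.7, inactive above 1.8 on
   ES^CcdB; repressing above, derepressing below 1 on ES^RelE. All
   inequalities are strict: a score equal to a threshold is not called.
   The combined H+D/H+R/I+D/I+R phenotype is assigned only when both axes
   are called; everything else is neutral. `kmeansThresholds()` (k = 3 on
   log2 scores, 100 restarts, fixed seed) can suggest data-driven
   boundaries but is advisory only — the fixed constants are normative.

## Codon-usage covariates

All metrics are ratios of mutant to WT codon properties, so the identity
substitution is always 1 (or 0 for ΔGC):

* **RCU** — genome-wide usage frequency ratio, from the packaged
  *E. coli* K-12 per-1000 table; "rare" and "optimal" follow this table's
  ranking.
* **CAI** — geometric mean of relative-adaptiveness weights
  `w = f / max f` per synonymous box, derived from the same usage table.
  An external reference-gene-set weight table can be supplied instead;
  deriving weights from the usage table removes the web-tool dependency
  while keeping the standard definition.
* **tAI** — per-codon weights `Σ (1 − s) · tGCN` over recognising
  anticodons under standard prokaryotic wobble rules (including the
  lysidine isoacceptor for AUA), normalised to a maximum of 1, zero
  weights replaced by the geometric mean of the non-zero ones. The wobble
  `s` defaults are the standard published values (G:U 0.41, I:C 0.28,
  I:A 0.9999, U:G 0.68, lysidine 0.89) and are overridable.
* **RtrnaA** — ratio of tRNA pool percentages, summing all tRNAs that
  decode a codon.
* **Hydropathy** — raw Kyte–Doolittle per residue, with an optional
  centred smoothing window; published "hydropathy index" traces often use
  undocumented windows, so no particular smoothed value is asserted.

The packaged tRNA gene-copy and pool-fraction tables are **synthetic**:
an *E. coli*-like anticodon repertoire with realistic copy numbers, and
pool fractions proportional to copy number. They are internally
consistent and adequate for method development and testing, but users
wanting quantitative tAI/RtrnaA values should load measured tables; the
relevant functions accept any table with the documented columns.

## RNA energetics

All thermodynamics are delegated to the ViennaRNA command-line tools
through the `ViennaEngine` interface (37 °C, current Turner parameters,
engine-default dangling ends), which keeps the package free of any
re-implementation of the folding recursions:

* `sdDuplexEnergy()` / `duplexEnergies()` use `RNAduplex`, a strictly
  bimolecular model (no intramolecular structure) appropriate for 8–10-nt
  SD:anti-SD duplexes. Predicted ΔG ≥ 0 is reported as 0, "no stable
  duplex".
* `asdWindowProfile()` scans 10-nt windows (step 1) of the transcript
  against the anti-SD consensus `CACCUCCU`; internal SD-like motifs are
  putative ribosome pause sites. `deltaASD()` averages mutant-minus-WT
  differences over the **affected windows** only (those whose sequence
  changed — at most window + 2 for a codon substitution). Averaging over
  all ~300 windows of a 324-nt transcript would scale a local effect by
  an arbitrary gene-length factor; the two conventions differ by exactly
  (total/affected), an identity the tests assert. Positive ΔaSD = less
  predicted pausing than WT.
* `mfeWindowAverage()` folds 30-nt windows (step 1) with `RNAfold` and
  averages; `deltaMFE()` differences against WT (positive = destabilised
  mutant transcript). The transcript model is the CDS plus an 18-nt
  upstream stretch containing the putative SD (324 nt for a 306-nt CDS);
  whole-operon folding is deliberately out of scope — at ~500 nt the
  prediction is no longer reliable and the neighbouring gene's structure
  is treated as independent.
* `rbsAccessibility()` folds a short RBS-containing region and reports
  the unpaired fraction of the SD span in the MFE structure.

Determinism: the engine contract requires identical energies for
identical inputs, which the CLI tools satisfy; no stochastic sampling
mode is used.

## Conservation

Homolog hits (alignments are user-supplied; database searches are out of
scope) are filtered to ≤ 95 % identity and 90–100 % query coverage,
boundaries inclusive. `codonConservation()` tallies, per codon position
of the in-frame WT row, the synonymous codons observed among homologs;
gapped or ambiguous codons and codons encoding a different amino acid are
excluded from the synonymous ranking (conservation "at the amino acid
level" ranks codons of the WT residue) but reported in separate columns.
The WT codon is "most" conserved only as a strict maximum and "least"
only as a strict minimum; ties are intermediate — with no stated
tie-break in the source analyses, strict extrema are the conservative
choice. `residueConservation()` is the per-column percent identity of a
protein alignment, among non-gap residues.

## The synthetic-data generator

`simulateSynScreen()` emulates the study conditions: a ~100-codon gene,
every synonymous variant (~2.5 per codon), uniform library composition
(a Dirichlet option models cloning bottlenecks), and one multinomial draw
of the configured depth per strain × replicate. Default depth is 10^6
reads per condition, matching the scale at which a screen resolves
two-fold effects; the estimator-recovery checks run at this depth with
200 variants. Seeding uses fixed per-condition offsets of the master
seed, so adding a condition or replicate never perturbs existing draws,
and a fixed seed reproduces tables byte-identically.

Ground truth comes in two modes. **Direct** mode specifies each variant's
true selection ratios (ρ_sen, ρ_relE) — the cleanest setting for
estimator tests, since the enrichment score is a consistent estimator of
ρ. **Mechanistic** mode derives ratios from a translational efficiency ε
and folded fraction φ per variant: functional toxin t = εφ, complex
min(t, α) for antitoxin capacity α, free toxin t − complex, and
exponential survival models in the free-toxin and derepression
differences from WT. As stated, this model's free-toxin and derepression
axes can never increase together, so two of the four phenotype classes
(H+D, I+R) are unreachable under any constants — inconsistent with the
operon biology in which WT sits above the repression optimum. The
generator therefore adds an optional conditional-cooperativity
coefficient γ (excess toxin disrupting the repressing complex, the
textbook TA-operon mechanism); γ = 0, the default, recovers the plain
model exactly. The classification-recovery tests engineer each class
with scenario-specific constants chosen so the true scores sit well
outside the threshold guard bands.

What the generator does *not* model: PCR and sequencing error, barcode
misassignment, replicate-specific bottlenecks, and any coupling between
variants. Passing recovery tests therefore demonstrates correctness of
the estimator and classifier under multinomial sampling noise, not
robustness to real-library artefacts.

## Numerical and reporting choices

* Geometric means (CAI, tAI) are computed in the log domain; tests pin
  them to a product-domain oracle at 1e-12.
* Pearson matrices are computed from the closed-form r and the t
  distribution on n − 2 df, pairwise-complete, and pinned to `cor.test`
  at 1e-10; cells with fewer than 3 pairs or zero variance are missing.
  The significance mask uses p ≤ 0.05 with no multiple-testing
  correction by default (matching the figure-level convention of crossing
  out non-significant cells); Benjamini–Hochberg is available.
* Moving averages are centred with truncated edges and preserve length;
  mutant ordering for windowed plots is ascending position, then codon
  lexicographic.
* `runPipeline()` writes TSVs and a log with no timestamps, so a rerun
  under the same seed is byte-identical — the determinism contract the
  acceptance checks exercise.
* Test and acceptance problem sizes (200-variant screens at depth 10^6;
  40-codon genes for the classification scenarios) were chosen as the
  smallest sizes at which sampling noise is clearly below the effect
  sizes being asserted.

## Known limitations

* The packaged tRNA tables are synthetic stand-ins (above); absolute tAI
  and RtrnaA values should not be interpreted against measured data.
* Reporter-strain scores obtained under a re-assigned reference compress
  near the new anchor when the anchor was itself extreme; the package
  computes them but they warrant caution, as flagged in
  `scoreVariants()`'s documentation.
* Conservation classes depend on the homolog set supplied; the package
  makes no attempt to reproduce any particular database snapshot.
* Energy values depend on the installed ViennaRNA parameter set; the
  packaged checks pass with current Turner parameters at 37 °C.
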