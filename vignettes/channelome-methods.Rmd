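---
title: "Methods: channel annotation, orthology profiling, and pattern positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel annotation, orthology profiling, and pattern positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The annotation model

A curated ion-channel table records, per protein, its membrane topology as
a comma-separated segment list (`T:8-36,I:71-76,...`), where `T` marks a
transmembrane segment that fully crosses the bilayer and `I` an
intramembrane segment that only partially embeds. Coordinates are 1-based
inclusive residue indices, the UniProt convention. Both the en-dash and
the hyphen are accepted on input because curated spreadsheets routinely
contain either; output always uses the hyphen.

The *pore-containing functional domain* is defined as the span from the
first residue of the first TM segment to the last residue of the last TM
segment: it covers the conduction pathway and every membrane-crossing
helix while excluding flanking accessory domains. Curated tables print
the domain length as `end − start`; whether that convention is deliberate
or an off-by-one is not decidable from the table itself, so this package
reports both: `reported_length = end − start` (matching the printed
convention, e.g. 220 for the 8–228 aquaporin-1 domain) and
`span = end − start + 1` (the inclusive residue count, 221).

Unit classification is a total function of three inputs: a derivable pore
domain makes the entry pore-containing (or a two-pore channel when the
curated two-pore flag is set — tandem-pore architecture is a curation
fact, not something this package infers from coordinates); no pore domain
plus experimental evidence of membership in a channel complex makes it an
auxiliary subunit; no pore domain and no complex evidence excludes the
entry from the curated channel list. TM segments themselves are taken as
given — reconciling TM predictors, UniProt annotations, and literature
calls is curation work upstream of this package, which ingests one
reconciled list per protein.

## 2. The synthetic-data generator

Everything downstream is testable because the generator produces every
input with recorded ground truth. Its defaults are the package's study
conditions and were fixed once:

* **Proteins**: 240 residues from a uniform amino-acid profile
  (a configuration hook accepts any background profile). 240 aa is a
  typical single-domain membrane-protein length and long enough for
  unambiguous local alignment at the divergences used.
* **Pore subregion**: residues 61–180, substituting at `rho = 0.3` times
  the background rate. The slow subregion is what makes the domain-based
  orthology pipeline informative, mirroring the observation that channel
  sequence similarity concentrates in the pore-containing domain.
* **Substitution**: along a branch of length *t* (expected
  substitutions/site), each site substitutes independently with
  probability `1 − exp(−t)` (times `rho` inside the pore region), with
  replacement uniform over the 19 other residues. Site-independence with
  uniform replacement is deliberately the simplest model that makes
  reciprocal-best-hit recovery tunable by branch length; an
  exchangeability-matrix hook would slot into `.evolve_branch`.
* **Duplication / loss**: Poisson counts per branch at 0.05 expected
  events per unit branch length each — retained gene duplications are
  rare on these timescales, and this rate plants enough co-ortholog and
  loss events to exercise relation typing without overwhelming the
  one-to-one backbone. Duplicated copies evolve independently from the
  duplication point, which is what makes them detectable co-orthologs.
* **Seeds**: one RNG stream per generator stage, derived from the master
  seed (`stage_seed()`), so stages can be regenerated independently;
  identical configs give byte-identical FASTA/TSV output.

The generator also plants metadata defects (unreviewed status, weak
protein-existence evidence, fragment/fusion lengths, non-standard
residues, low-complexity expansions, inflated sequence versions, absent
cross-references), alignment columns conserved in a labelled foreground,
and term annotations enriched in chosen clusters — each independently,
each recorded in a truth ledger.

What the generator does **not** emulate: indel evolution and alignment
inference (synthetic alignments are emitted pre-aligned), domain
architecture beyond one slow subregion, compositional bias of real
proteomes, and correlated evolution between sites. Passing tests
therefore demonstrate correctness of the algorithms under a clean,
exchangeable null and planted-signal alternatives — not performance on
real proteomes, where alignment error and domain shuffling add failure
modes this package does not model.

## 3. Orthology inference

The pipeline composes: forward search (e ≤ 1e-5) → reciprocal search
(e ≤ 1e-200 by default) → reciprocal-best-hit pairing → Markov clustering
→ within-cluster filtering, run twice (full-length sequences and
pore-domain subsequences extracted by coordinates), followed by
intersection of the two pair sets, relation typing, and metadata
validation.

Decisions worth recording:

* **Top-hit ties.** "Top hit" is undefined when bit scores tie; pairs are
  ordered by bit score, then e-value, then target identifier, making the
  top hit — and hence the whole pipeline — deterministic.
* **Forward mode.** By default only the top forward hit per organism
  enters the reciprocal stage (matching the description of the original
  procedure). `forward_mode = "all"` carries every forward hit below the
  cutoff; this is the only mode in which two duplicate targets in one
  organism can both be retained, so it is the mode to use when the goal
  is explicit co-ortholog enumeration rather than a conservative
  one-to-one backbone.
* **Relation typing.** The one-to-one / co-ortholog rule is: a pair is
  one-to-one exactly when its query has a single retained target in that
  organism and that target a single retained query; otherwise the whole
  (query, organism) cell is co-ortholog. The upstream procedure displays
  these states without giving a formula; this rule is the natural
  RBH-uniqueness reading and is applied after clustering and filtering.
* **Reciprocal threshold.** 1e-200 is the shipped default, meaningful for
  full-length proteins of realistic length searched against large
  databases. Synthetic proteins of a few hundred residues cannot reach
  such e-values (a perfect 240-residue self-match scores around 1e-139),
  so every synthetic run relaxes the reciprocal cutoff to 1e-5. Both are
  plain configuration values.
* **MCL.** Markov clustering is implemented directly (expansion = matrix
  squaring; inflation = entrywise power with column renormalisation;
  convergence at max entrywise change < 1e-6 or 200 iterations;
  self-loops at each node's maximum incident weight; attractor-based
  cluster extraction with clusters renumbered by their lexicographically
  smallest member for determinism). Edge weights default to forward bit
  scores; `-log10` e-values are available. Inflation defaults to 1.5, the
  conventional coarse-granularity setting for ortholog graphs.
* **Dual evidence.** The intersection requires the *same* (query, target)
  pair in both analyses. When a query-side duplication leaves two human
  co-ortholog copies, the full-length and domain pipelines can
  legitimately pair a target with different copies, and the intersection
  then drops that cell. This is an inherent conservatism of dual-evidence
  RBH, visible in the planted-truth recall (slightly below 1 at
  moderate duplication rates), not an implementation error.
* **Recall scoring.** Planted-ortholog recall is scored per
  (family × organism) cell: a truth presence counts as recovered when at
  least one retained pair links any query copy of the family to a
  same-family gene of that organism. Families lost on the query lineage
  have no query sequence and are excluded from the denominator — a
  query-centric search cannot recover them by construction.

## 4. Validation cascade

Reviewed entries pass outright; unreviewed entries with protein-existence
evidence 1–3 pass at step 2; everything else must clear five integrity
checks. The cascade names its checks but no cutoffs, so the package fixes
configurable defaults: sequence version ≤ 100; low-complexity coverage
≤ 0.5 with a 12-residue window and a 2.2-bit Shannon-entropy cutoff
(SEG-like scale: a window holding fewer than ~5 effective residue types
is flagged); non-standard residue fraction ≤ 0.05 (anything outside the
20 canonical letters counts, so B, J, O, U, X, Z all do); length within
30–5000 aa (printed explicitly by the source procedure); and
cross-references failing only when domain annotations *and* other
cross-referenced metadata are both absent. A "very old version update"
staleness check would need modification dates, which the metadata schema
does not carry; only the high-version rule is implemented. Each check can
be toggled independently.

## 5. Profiling, clustering, enrichment

Profile cells distinguish one-to-one from co-ortholog, but for the
percentage formula and for clustering both count as presence (the state
distinction is display-level). The family × lineage percentage is exactly
`100 · found / (n_organisms · family_size)` with co-orthologs counted
once per (query, organism) cell.

Clustering uses Ward linkage on Euclidean distances over the 0/1
presence matrix (`hclust(method = "ward.D2")`, whose heights the test
suite checks against a from-scratch Lance–Williams recurrence), cut to
exactly *k* clusters. Rows are sorted lexicographically before clustering
and clusters renumbered by first member, so results are invariant to row
order. Prokaryotic profiles are typically sparse; selecting eukaryote
columns only is done by passing the organism subset.

Enrichment is the one-sided hypergeometric tail `P(X ≥ k)` per
(cluster, term), computed by `phyper` (log-space internally, so no
overflow), with Benjamini–Hochberg correction across all cluster × term
tests jointly; per-cluster correction is available. The default universe
is the profiled query set: the scientific question is which functions
distinguish one cluster of channels from the others, not from the whole
genome. A genome-wide universe can be passed explicitly. Retention uses
FDR < 0.01. Term maps are flat (no ontology-graph propagation).

Hypergeometric p-values are discrete, hence conservative: the fraction of
null tests with p < α sits at or somewhat below α, approaching α as term
sizes grow. The calibration test uses 300 genes, 9 clusters and 250
background terms at assignment rate 0.1 — sizes chosen to mirror a
few-hundred-channel curation with hundreds of terms — where discreteness
is mild.

## 6. Pattern positions

The detector is a contrast-statistic analogue of Bayesian pattern-set
partitioning ("BPPS-style"), not a re-implementation of the hierarchical
Gibbs sampler: per column, with foreground matches k_F of n_F and
background k_B of n_B (gaps excluded; pseudocount a = 1),

score = max(0, k_F·ln(p̂/q) + (n_F − k_F)·ln((1−p̂)/(1−q))),
p̂ = (k_F + a)/(n_F + 2a), q = (k_B + a)/(n_B + 2a),

maximised over a residue set grown greedily from the most frequent
foreground residue while the score increases (ties broken by residue
alphabet). Significance is by label permutation of the column's maximal
score — the null re-runs the greedy growth, so the adaptivity of the
statistic is part of the null. Permutations are drawn as multivariate
hypergeometric foreground counts, vectorised across draws, which is
what makes thousands of permutations per column affordable.

Two numerical choices matter:

* **Tie handling.** Permutation scores tie heavily (they are functions of
  small counts). The classical `(1 + #{null ≥ obs})/(P + 1)` p-value is
  then super-uniform and would fail any uniformity diagnostic. The
  default p-value breaks rank ties uniformly at random (seeded), which
  makes null p-values exactly uniform on the achievable grid;
  `tie = "conservative"` restores the classical estimate, and
  `exact = TRUE` enumerates all label assignments for small families.
* **Permutation count.** The attainable p-value floor is `1/(n_perm+1)`;
  BH selection at FDR < 0.01 across ~100 columns needs a floor near
  3e-4, hence the default of 2999 permutations. With too few
  permutations the detector cannot select anything at a stringent FDR —
  a resolution limit, not a power limit.

Reference numbering counts non-gap reference positions up to the column;
columns where the reference is gapped are flagged and report the
preceding residue number. The two-level analysis runs the detector twice
— whole family vs outgroup, and focal sub-clade vs the remaining family
members — which is how family-wide and clade-specific conserved positions
(the calcium-homeostasis-modulator use case: CALHM1/3 vs CALHM2/4/5/6)
are separated; columns appearing in both tiers are flagged rather than
silently deduplicated.

## 7. Similarity engine

Local alignment is Smith–Waterman with affine gaps via
`Biostrings::pairwiseAlignment` (BLOSUM62; gap open 11, extend 1, the
standard protein defaults; U, O and J scored like X). E-values use the
Karlin–Altschul form `K·m·n·exp(−λ·raw)` with the standard gapped
BLOSUM62 constants λ = 0.267, K = 0.041, m = database letter count,
n = query length, without composition-based adjustment: within this
package e-values are thresholds and ranks, not publication statistics.
The orthology stage consumes hit tables, so externally computed 12-column
tabular hits (the common tab-separated search output) can drive the
pipeline unchanged; results are identical whether hits come from the
internal engine or from an ingested file containing the same hits.

## 8. Problem sizes and runtime choices

The shipped test and acceptance runs use: 4–8 organisms × 4–20 families
of 240-residue proteins for orthology (the 8 × 20, branch-0.3
configuration is the planted-recall condition); 2000-column alignments
of 10 foreground / 20 background sequences for the permutation-null
diagnostic; 120-column alignments of 50 foreground / 200 background
sequences with five planted columns for recovery; and 300-gene,
9-cluster, 250-term simulations for enrichment calibration. These sizes
were chosen so each property is measured with comfortable statistical
resolution while a full suite run stays in the minutes range on one CPU.

## 9. Known limitations

* The search engine is exact Smith–Waterman without heuristic seeding;
  it is meant for curated query sets against modest synthetic or
  benchmark databases, not for proteome-scale scans — real deployments
  would ingest external search output instead (supported).
* The validation cascade models a snapshot of entry metadata; version
  *history* (staleness) is out of reach of the schema.
* Term enrichment ignores ontology structure (no true-path propagation).
* The pattern detector assumes the alignment is given and trustworthy;
  alignment error masquerades as pattern signal.
* Co-ortholog enumeration under the default top-hit forward mode is
  conservative by construction; use `forward_mode = "all"` when
  duplicate targets matter.
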