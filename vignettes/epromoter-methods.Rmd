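---
title: "Methods: Epromoter identification and pleiotropy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Epromoter identification and pleiotropy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in
`epromoter`, the assumptions behind them, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the methodology was genuinely open.

## The regulatory model

An *Epromoter* is a coding-gene promoter that also behaves as an
enhancer for distal genes. Operationally, the package defines it in two
steps: regulatory activity is first measured per genomic region with an
episomal reporter readout ((Cap)STARR-seq), and promoters are then
flagged when they coincide with an active region. Variants inside
Epromoters are candidates for pleiotropic GWAS association because a
single element may regulate several genes; the package quantifies that
association and cross-validates it with orthogonal evidence (eQTL
targets, 3D chromatin contacts, reporter-assay allelic skew, TF-binding
skew, and CRISPRi perturbation).

## Activity calling

Coverage is quantified as FPKM: fragments overlapping the region by at
least 1 bp, divided by region length in kb times million mapped reads.
Sequenced read intervals are extended to the captured fragment length
(default 314 nt) from their 5' end before counting. Regions with input
FPKM below 1 are removed — below that depth a fold-change is dominated
by shot noise. Activity is the output/input FPKM ratio.

The activity threshold is the *knee* of the descending ranked
fold-change curve: both axes are min–max normalised and the knee is the
rank maximising perpendicular distance to the chord joining the first
and last points. Ties break toward the smaller rank, which yields a
higher threshold and therefore fewer, more conservative calls. A flat
curve degenerates to its common value, above which nothing lies
strictly; membership is *strictly greater than* the knee value. The
estimator is deliberately simple and is validated in the tests against
exhaustive enumeration of the maximum-distance rank.

**Replicate merging.** Each replicate is ranked and thresholded
independently; the merged set is the regions active in *every*
replicate, with activity averaged (`merge_replicate_calls(...,
rethreshold = FALSE)`). For peak-style inputs, where each replicate
contributes only its called peaks, the merged common-peak curve is
re-ranked and re-thresholded at its own knee (`rethreshold = TRUE`).
Applying a second knee to a captured-region set that was already
thresholded per replicate is not meaningful: a knee estimator always
cuts *somewhere*, so re-thresholding an already-selected active set
merely truncates it. Treating per-replicate calls as the "peaks" of a
captured-region experiment and intersecting them is both the convention
that keeps merging idempotent on identical replicates and, in
simulation, the one that preserves sensitivity and precision
simultaneously.

## Epromoter calling

Promoters are the `promoter_window` (default 500) bp upstream of each
coding transcript's TSS — `[TSS − 500, TSS)` on the plus strand,
`[TSS, TSS + 500)` on the minus strand — clipped at chromosome bounds,
with duplicate (region, gene) records collapsed. A promoter is flagged
when an enhancer overlap covers at least `overlap_frac` (default 0.5)
of the promoter *or* of the enhancer: the either-fraction rule protects
against both small enhancers inside large promoters and the reverse.
Flagged promoter regions are merged single-linkage at ≥ 1 nt overlap
(abutting regions stay separate); a gene is Epromoter-associated when
any of its transcript promoters is flagged, so merged Epromoters can be
fewer than member genes. All coordinates are 0-based half-open
internally (BED on disk); overlap fractions are computed on interval
lengths in bp.

## Tau and control matching

Tissue specificity is `tau = sum(1 - x_i) / (N - 1)` with `x_i` the
expression profile normalised by its maximal component: 0 for uniform
expression, 1 for single-tissue expression, undefined (returned as
`NA`) for all-zero profiles. Tau is scale-invariant, so no expression
normalisation is required before computing it.

Control promoters are chosen to match Epromoter genes on expression:
each Epromoter gene, processed in lexicographic order, takes the
unassigned non-Epromoter gene nearest in Euclidean distance over the
tissue expression vectors, ties broken lexicographically. The
assignment is injective, giving a control set of equal size. Direct
nearest-neighbour distance is used rather than adjacency in a
hierarchical-clustering dendrogram: leaf adjacency is an accident of
the linkage algorithm, while the underlying metric is the same, so the
nearest neighbour is the well-defined target of "the most similarly
expressed gene". Raw expression is matched by default (`log1p = TRUE`
is available); the deterministic greedy order makes the control set
reproducible.

## Variant pleiotropy

LD between two panel sites is
`r2 = (p_AB − p_A p_B)^2 / (p_A(1 − p_A) p_B(1 − p_B))` from phased
haplotype frequencies; it is undefined (an error) for monomorphic
sites. GWAS lead SNPs are expanded to every panel variant within
±`ld_window_kb` (default 1000, i.e. 1 Mb) whose r² with the lead is
*strictly* greater than `r2_min` (default 0.8); the lead itself is
always included, and a variant proxying several leads unions their
trait sets. Traits are identified by EFO ID and grouped into a fixed
17-label parent-category vocabulary (`efo_parent_categories`),
configurable because no canonical enumeration ships with the ontology.

Variant–promoter membership is half-open: the variant base must lie in
`[start, end)`. Per-promoter trait counts are the size of the union of
member SNPs' trait sets (non-redundant counting); a promoter with ≥ 2
distinct traits is pleiotropic. Enrichment per trait uses the
upper-tail hypergeometric with the population being all GWAS-SNPs
genome-wide, and the Epromoter-vs-control comparison a Pearson
chi-squared on the 2×2 table without continuity correction (the counts
of interest are large; Yates correction is exposed as a flag).
Benjamini–Hochberg FDR columns are reported alongside raw p-values, but
raw values drive the headline filters.

## Target linking

eQTL records are first merged non-redundantly across tissues by
(SNP, target), then classified by |distance| to the target TSS:
all targets within `proximal_bp` (default 2000) → proximal, all beyond
→ distal, otherwise both. The boundary itself is assigned proximal —
the class boundary must land somewhere, and counting an exactly-2-kb
target as proximal is the conservative choice for distal claims.

A distal eQTL target is *P–P consistent* when some interaction has one
anchor overlapping the SNP's Epromoter and the other anchor overlapping
any promoter of the target gene (gene-level union over alternative
TSSs). Consistency is tissue-agnostic: requiring the same tissue for
the eQTL and the interaction assay would conflate assay coverage with
biology, and the interaction catalogues aggregate many tissues.

The CRISPRi screen takes a z-matrix of targeted promoters × genes
(lower = more repressed). A promoter is *efficiently inactivated* when
its own gene ranks in the `crispri_top_inactivated` (default 2) most
repressed genes of its profile; its `crispri_top_regulated` (default
30) most repressed genes form its regulated set; it is a *distal
regulator* when a regulated gene other than its own has a TSS within
`cis_window_bp` (default 1 Mb). The hypergeometric universe for the
Epromoter/control overlap test is the efficiently inactivated
promoters: enrichment should be judged among perturbations that
worked, not diluted by failed knockdowns. The universe is configurable.

The final list is the strict intersection of four per-SNP evidence
flags — distal eQTL (class distal or both), a P–P-consistent distal
target, MPRA allelic skew, and TF-binding skew (both consumed as
pre-thresholded tables from their source assays) — with members
labelled pleiotropic at ≥ 2 traits and summarised in bins 1 / 2 / ≥ 3.

## Feature statistics

Per-region statistics follow the conventions of the comparative
analyses they feed: CGI is any-overlap; G4 is percent of region bp
covered after merging annotations (so splitting an annotation into
abutting pieces cannot change it); conservation is the sum of per-base
scores (wider tiles weight by overlapped width); ChIP counts
deduplicate (TF, interval) pairs and count distinct biotypes. TFBS
density counts sites with score strictly above 400 (the P ≤ 1e-4
operating point of the source scoring; strictness at the boundary is a
documented choice), diversity the distinct TF families among them.
CAGE directionality widens each promoter to TSS ± 500 bp and classifies
divergent (sense + antisense peaks), unidirectional (sense only), else
unclassified, with orientation defined relative to the gene strand;
window signal is summed (score × bp), summation being the natural
aggregate for count-like signal. Chromatin-state fold enrichment is
`[overlap_bp/state_bp] / [region_bp/genome_size]`, compared between
sets as a log2 ratio.

## The synthetic world

`generate_world()` builds a deterministic miniature study from a seed:

* **Genome/annotation** — `n_chromosomes` × `chrom_length_bp` with
  `n_genes` in disjoint slots, 1–6 transcripts per gene with TSSs
  spaced 600 bp so that promoters never overlap. This keeps planted
  truth exact: an active planted promoter can flag only itself.
* **Planted Epromoters** — a fraction `frac_epromoters` (default 0.1)
  of genes, planted at their first-transcript promoter with expected
  output/input fold `epromoter_fold_effect` (default 5) over a
  background of `background_fold_mean` (default 1).
* **Fragments** — per-region counts are negative binomial with mean
  depth × fold and size `nb_size` (default 20, a moderate assay-level
  overdispersion); 50-nt reads are emitted at either fragment end and
  extended back by the pipeline. Fragments are placed fully inside
  their region, so no cross-contamination between neighbouring
  promoters; declared library totals exceed on-target counts (capture
  is never complete), and both libraries share one declared total so
  the expected fold-change of a planted region is exactly the
  configured effect.
* **Expression** — profiles come from 60 shared expression programs
  (co-expression modules) whose concentration parameters span the tau
  range, with gene-level log-normal peak expression (median 10,
  log-sd 1) and 0.25-sd multiplicative noise. The program structure is
  what gives every gene shape-mates, making expression matching
  meaningful; fully independent per-gene profiles would leave
  mid-specificity genes without matchable neighbours.
* **Haplotype panel** — block-copy LD: each lead SNP and its proxies
  copy a founder haplotype (frequency 0.15–0.5) with per-site mutation
  probability 0.01 (two high-LD proxies) or 0.35 (one low-LD decoy);
  100 singleton rare variants sit inside promoters. With the default
  200 haplotypes a singleton has MAF 0.005, below the 1% common/rare
  cut.
* **GWAS catalog** — a quarter of `n_gwas_leads` (default 600) are
  pleiotropic leads placed inside planted Epromoters with
  2 + Poisson(`pleiotropy_boost`) traits; the rest carry one trait and
  sit in non-Epromoter promoters (85%) or intergenic space.
* **eQTLs / P–P / CRISPRi / skew tables** — planted pleiotropic SNPs
  receive proximal and/or distal target eQTLs (class drawn
  0.2/0.3/0.5); distal targets get a supporting P–P interaction with
  probability 0.9 on top of 200 background promoter pairs; the CRISPRi
  z-matrix represses the own gene (z = −8) for 90% of promoters and
  planted distal targets at z ≈ −5 against N(0, 1) noise; MPRA and
  TF-skew tables contain 90% of planted SNPs plus a 5% background.
* **Feature tracks** — CGI/G4/TFBS/ChIP/CAGE/conservation/state tracks
  with planted-vs-background enrichment in the direction expected of
  regulatory elements.

What the generator does *not* emulate: genomic sequence content,
overlapping genes and bidirectional promoters, capture edge effects
(fragments leaking into adjacent regions), LD decay within blocks,
population structure, realistic trait ontologies, and tissue-specific
eQTL effect structure. Passing recovery tests on these worlds therefore
demonstrates the correctness and joint calibration of the pipeline's
rules, not performance on real data, where peak structure and LD are
substantially messier.

## Problem sizes and numerical choices

The recovery tests run the full chain at the study conditions — 2000
genes on 2 × 8 Mb, 10% planted Epromoters, fold effect 5, 40× depth,
two replicates, ten seeds — which completes in a couple of minutes;
unit tests use 200-gene worlds. Matched-control neutrality is checked
at 500 planted genes. Determinism is bitwise: the same seed reproduces
the world, its serialized text files, and the pipeline report exactly.
Degenerate inputs are handled explicitly: knee estimation requires ≥ 3
points and a sorted-descending curve; flat curves yield no active
regions; all-zero expression profiles give `NA` tau with a warning;
monomorphic panel sites are an error for r²; empty replicate
intersections warn and return empty tables rather than failing.

## Known limitations

* The knee estimator is a geometric rule; on noise-only data it still
  calls a small number of regions active (a ranked curve always has a
  point of maximum chord distance). Downstream conclusions should rely
  on the planted/matched comparisons, not on the absolute call count.
* Greedy without-replacement matching is order-dependent by design
  (deterministic lexicographic order); a global optimal assignment
  (e.g. Hungarian) would be marginally tighter but non-streaming.
* r² is computed from phased haplotypes; unphased genotype input would
  require an EM step that is out of scope.
* The CRISPRi test treats rows independently; off-target effects and
  guide-level variability are not modelled.
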