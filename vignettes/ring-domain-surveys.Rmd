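---
title: "Rule-based RING zinc-finger surveys: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based RING zinc-finger surveys: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringzf)
```

## The problem

RING-type zinc fingers are ~40–60 residue domains that coordinate two zinc
ions through eight ordered metal-ligand residues (mostly Cys and His) in a
cross-brace arrangement; they define one of the major classes of E3
ubiquitin ligases. Genome-wide family surveys — such as those carried out
for hexaploid wheat and other plants — classify every family member into
subtypes by which residues occupy the eight ligand positions and how many
residues separate them, then characterize the family: physicochemical
properties, selective pressure (Ka/Ks), phylogeny, promoter cis-elements,
and expression behaviour.

`ringzf` re-implements that survey as a reusable pipeline whose every stage
can be validated on synthetic inputs carrying planted ground truth.

## The domain model: ligand rules

A subtype is encoded as a `ligand_rule`: an ordered list of eight (nine for
the accessory IBR domain) ligand *slots*, each with a set of allowed
residues, and seven inclusive spacer ranges between consecutive slots. The
default table encodes:

| rule | ligands | spacers |
|------|---------|---------|
| RING-M | M, R, C, H, C, C, C, C | fixed 2, 14, 1, 2, 2, 10, 2 |
| RING-D | C, C, C, H, **D**, C, C, C | generic |
| RING-H2 | C, C, C, H, **H**, C, C, C | generic |
| RING-HC | C, C, C, H, **C**, C, C, C | generic |
| IBR (accessory) | C×7, H, C | 4, 14–30, 1–4, 4, 2, 4, 4, 4 |

"Generic" means the canonical RING consensus spacing
C-X2-C-X(9–39)-C-X(1–3)-H-X(2–3)-C/H-X2-C-X(4–48)-C-X2-C. RING-M is the
modified subtype with Met and Arg in the first zinc-coordinating centre and
conventional RING-HC-type ligands at positions 3 and 4; its spacers are
fully fixed. No additional overall length cap is imposed beyond the slot
ranges: the 40–60-residue figure quoted for RING domains is descriptive,
and adding a cap would silently reject consensus-conformant matches.

**Matching semantics.** Candidate assignments of residues to slots are
enumerated left to right. Per first-ligand position, one hit is kept: the
assignment with the lexicographically smallest spacer vector, which the
depth-first search finds directly by trying smaller spacers first. Hits
anchored at different positions are all reported even when they overlap;
`X` never satisfies a slot (an ambiguity code cannot certify a metal
ligand). Rules are applied in priority order, so a RING-M domain — whose
later ligands also satisfy RING-HC — keeps the RING-M label; accessory IBR
hits never compete with core hits.

**One domain per protein.** The family census assigns each protein its
highest-priority, leftmost core hit, mirroring surveys that report one
domain per member while listing multi-domain proteins separately.

**Open design points.** Two aspects of the classification are not fixed by
any published consensus and are therefore configuration, prominently
recorded in outputs rather than asserted as biology. (1) The HCa/HCb
split: this package discriminates on a spacer threshold, by default spacer
6 (the variable X(4–48) region), HCa iff ≥ 8. (2) The RING-D rule: which
ligand carries the Asp substitution is unstated in the literature we
mirror; the default places D at slot 5. Both are arguments
(`split_hc()` criterion, editable JSON rule tables).

Percentages throughout use **half-up rounding at one decimal**
(`census_percentage()`), the convention that reproduces every family
percentage the mirrored survey prints (e.g. 59/75 → 78.7); note R's
`round()` would give half-to-even instead.

## Synthetic data: what is emulated, what is not

`make_protein_set()` builds proteins whose spacers and flanks are drawn
from a filler alphabet (A, G, L, S, T, V, P, E, Q, N) that excludes every
residue any default slot allows, so the planted domain is *provably* the
only match and truth tables are exact. Decoys are filler-only. Consequences
worth stating: synthetic proteins have unrealistic composition (no C/H/M/R
outside domains), and passing the planted-truth tests demonstrates the
scanner's correctness, not its specificity on real proteomes, where
C/H-rich non-RING regions can satisfy the generic consensus by chance.
Planted domains concatenated closer than the maximum generic spacer (48)
can legitimately admit junction-spanning assignments; generators therefore
separate domains by more than that.

`make_codon_pair()` plants at most one substitution per codon, which makes
NG86 pathway averaging unambiguous and `(Sd, Nd)` exactly equal to the
planted counts; multi-hit codons are exercised separately against an
exhaustive path-enumeration oracle. `make_promoter()` draws background
from an alphabet (default A/T) in which no motif of the active table can
be spelled on either strand, plants concrete instances of the (possibly
degenerate) patterns, and verifies the assembled sequence scans to exactly
the planted truth. `make_expression_matrix()` uses multiplicative
lognormal noise parameterized by a coefficient of variation — simple,
positive-valued, and mean-preserving — around four planted group
archetypes plus an intermediate "ungrouped" level. `make_qpcr_table()`
encodes fold changes as exact CT shifts with a constant reference gene.
None of these simulate hexaploid genome structure, homoeolog expression
bias, read-level RNA-seq, or technical qPCR noise.

The default planted sizes mirror the wheat family survey this pipeline is
modeled on: 138 proteins split 57/59/16/3/3 across
H2/HCa/HCb/D/M, chromosome groups 19, 21, 35, 20, 16, 12, 13, 2, and
expression groups 22/47 (constitutive high/low) and 20/27
(stress-induced/repressed).

## Molecular evolution

`kaks()` implements Nei–Gojobori (1986) counting with Jukes–Cantor
correction. Synonymous *sites* per codon position are the fraction of the
three single-nucleotide changes that are synonymous (changes creating
stops are never synonymous); site counts are averaged over the two
sequences, so S + N equals the nucleotide length exactly. *Differences*
for a codon pair differing at k positions are averaged over all k!
single-step orderings, excluding orderings that pass through a stop codon
and renormalizing over the valid ones; codons whose every path hits a stop
are dropped with a logged count. `Ks = -(3/4) ln(1 - (4/3) ps)`; a
proportion ≥ 3/4 makes the distance undefined — flagged, never an
exception. ω = Ka/Ks is undefined when Ks is 0 or undefined.

The estimator is deliberately the fully specified, oracle-checkable NG86
(the survey literature typically cites an omnibus "Ka/Ks calculator"
without pinning a model); the result records its method, and alternative
estimators can sit behind the same result shape. Divergence time uses
T = Ks/(2λ) with the grass synonymous rate λ = 6.5 × 10⁻⁹ per site per
year, reported in Mya: Ks = 0.013 ↦ 1.0 Mya.

## Phylogeny

`cluster_redundant()` is a deterministic greedy surrogate for CD-HIT:
sequences sorted by decreasing length join the first representative whose
global-alignment identity (matches over the shorter length, the CD-HIT
convention) strictly exceeds the cutoff (default 0.95). `neighbor_joining()`
wraps the Saitou–Nei algorithm (via ape) with input validation and clamps
negative branch-length estimates to zero, recording how many were clamped.
Distances are p-distances over gap-free column pairs — the substitution
model is a documented assumption, configurable by supplying a different
matrix. `bootstrap_support()` resamples alignment columns with
replacement and reports, per internal bipartition of the full-data tree,
the percentage of replicate trees containing it.

Correctness is validated on additive matrices: the NJ tree must reproduce
the generating distances exactly, and for 4–6 taxa the recovered topology
is checked to be the *unique* zero-residual least-squares fit among all
exhaustively enumerated unrooted topologies (for 7–8 taxa exact distance
reproduction suffices, since the additive tree is unique). Ties in the
Q-criterion on degenerate matrices resolve by the wrapped implementation's
internal order; for additive inputs with positive internal edges no ties
arise.

## Promoters and expression

Promoter windows are the 1.5 kb upstream of the annotated gene start
(reverse-complemented for minus-strand genes), clipped at contig edges
with a `truncated` flag. Motif scanning tests every position on both
strands against IUPAC patterns; subject `N` matches nothing, and a
palindromic motif (e.g. G-box CACGTG) yields one hit per strand at the
same locus — the census is unaffected because presence is per gene. The
shipped motif table is curated PLACE/PlantCARE-style input, editable JSON
with per-entry provenance, an editable input rather than asserted truth.

Expression grouping quantifies "constitutively high/low in nearly all
stages" as TPM ≥ 10 (or < 1) in ≥ 80% of stage columns, and
stress-response as a treatment/control ratio ≥ 2 (or ≤ 1/2) in ≥ 50% of
treatment columns with a 0.5 pseudocount on both sides; the
ratio-to-control reading of "high/low abundance under stress" is the
implemented interpretation of an ambiguous phrasing, and every output
records the parameters used. Heatmap ordering uses average-linkage
clustering on 1 − Pearson correlation of row-scaled log2(TPM + 1)
profiles (log transform as variance stabilization; constant rows are
flagged and placed at distance 1). The qPCR fold change is the standard
double-delta: ΔΔCt = (CT_target,cond − CT_ref,cond) −
(CT_target,control − CT_ref,control), fold = 2^−ΔΔCt, exactly 1 for the
control and invariant to machine CT offsets.

## Numerical choices and problem sizes

- Bisection for pI over pH 0–14 to 0.001 (the net charge is strictly
  monotone); validated against a 10⁻⁴-step grid scan to 0.01.
- Molecular weight uses average residue masses plus one water
  (18.01524 Da); instability uses the Guruprasad DIWV table; GRAVY the
  Kyte–Doolittle scale; aliphatic index Ikai's coefficients (2.9, 3.9);
  pI the EMBOSS pKa set. All ship as versioned TSVs under
  `inst/extdata/`, so adopting another convention is a data edit.
- The validation suite runs at deliberately modest sizes chosen to give
  exhaustive or near-exhaustive coverage: all 4096 codon pairs for the
  NG86 oracle sweep; 200 random sequences for the scanner oracle; 100
  random additive trees of 4–8 taxa; 60 random sequences plus planted
  promoters for the motif oracle; 20 noise replicates for expression
  recovery. These sizes already exercise every code path; scaling them up
  changes nothing qualitatively.

## Known limitations

The rule scanner is a transparent surrogate for profile-HMM search: it has
no scores or E-values and treats the consensus as hard constraints. The
HCa/HCb and RING-D conventions are explicit configuration, not settled
biology. Clustering identity uses global alignment without CD-HIT's k-mer
screening heuristics (results can differ near the cutoff). p-distance NJ
is a simple, assumption-light choice rather than a model-based one. The
synthetic generators certify algorithmic correctness, not performance on
real genomes, which requires external sequence resources deliberately out
of scope here.
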