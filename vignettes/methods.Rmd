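---
title: "Statistical methods behind mutclust3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind mutclust3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutclust3d)
```

## The model

mutclust3d asks, for each residue neighborhood of a protein structure,
whether somatic missense mutations accumulate there beyond what random
scatter over the protein would produce. The unit of recurrence is the
*mutated sample*: at residue $i$, $m(i)$ is the number of distinct tumor
samples with at least one missense mutation at that position. Multiple
alleles in one sample at one residue count once — recurrence across
patients, not allelic diversity within a patient, is the evidence of
selection. Counting events instead of samples would let a single
hypermutated tumor manufacture a cluster.

Candidate clusters are defined purely by structure: every aligned
residue $c$ contributes one cluster $C(c)=\{c\}\cup\{j:
\text{contact}(c,j)\}$, where contact means any inter-atomic distance
$\le 5$ Å. Clusters deliberately overlap and are never merged, so the
test is applied to every residue neighborhood and a residue may be
reported in several clusters.

The null hypothesis is exchangeability of the per-residue counts across
the aligned region: a decoy pattern is a uniformly random bijection of
the observed count multiset (zeros included) onto the aligned
positions. For an assessed cluster with observed score
$S=\sum_{i\in C} m(i)$, the p-value is the fraction of decoys in which
*any* candidate cluster reaches a score $\ge S$. Taking the maximum over
clusters inside the null makes the p-value family-wise with respect to
the (many, overlapping) clusters of one chain: it already accounts for
having scanned every residue neighborhood, which is why no further
per-chain multiple-testing correction is applied.

Two consequences of this design are worth knowing. First, a
single-residue hotspot alone can never be significant: whatever its
count, every decoy places that count at some residue, which is the
center of its own cluster, so the decoy maximum always reaches the
observed score and $p = 1$. The test detects *spatial coincidence
across residues*, complementing frequency-based hotspot methods rather
than replacing them. Second, overlapping clusters containing the same
mutated residues produce correlated, near-duplicate results; the
catalog stage collapses identical residue sets across structures and
keeps the minimum p as representative.

## The cap rule

Oncogenes often carry one dominant hotspot (tens to hundreds of mutated
samples) plus modest clusters elsewhere. Shuffled unmodified, the
dominant count lands somewhere in every decoy and the decoy maximum
always exceeds a modest cluster's score, driving its p-value to 1.
Before decoy generation the counts are therefore truncated at
$\max_{i\in C} m(i)$, the largest count *inside the assessed cluster*.
The observed score is computed on uncapped counts; this is
self-consistent because the cap, by construction, never alters the
assessed cluster's own members. `permutation_pvalue(..., cap = Inf)`
exposes the uncapped test for diagnostics; on a fixture with a count-30
hotspot distant from a (2,2,2) cluster the capped test reaches
$p < 0.01$ while the uncapped test is pinned at $p = 1$ (the acceptance
script recomputes both).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `cutoff` | 5.0 Å | any-atom inter-residue contact distance (inclusive boundary) |
| `min_identity` | 0.90 | minimum sequence-to-structure alignment identity |
| `n_decoys` | $10^5$ | decoys per cap value; p-value resolution $10^{-5}$ |
| `alpha` | 0.05 | catalog significance threshold (a configurable choice, recorded in outputs) |
| TPM threshold | 0.1 | expression filter; gene dropped for a type when $\ge 90\%$ of that type's tumors are below it, or $> 95\%$ of all tumors for types without expression data |

The 5 Å / 90 % / $10^5$ / TPM constants are the method's standard
operating point; `alpha` genuinely is an analysis choice — borderline
clusters (e.g. $p \approx 0.08$) can be biologically interesting, so the
threshold is surfaced in the configuration and stamped on every catalog.

## Numerical and implementation choices

* **Inclusive boundaries.** A contact at exactly 5.0 Å is an edge, and
  a decoy score exactly equal to the observed score counts as an
  exceedance ("equal to or larger"). Both choices are conservative and
  fixed for testability.
* **Distance comparisons** use squared distances with a $10^{-9}$
  absolute slack so that coordinates stored at PDB precision (0.001 Å)
  compare stably at the boundary.
* **PDB parsing policy.** First MODEL only; waters and non-amino-acid
  heteroatoms dropped; for alternate locations the *first-listed*
  altloc is kept (occupancy-based selection would make parsing depend
  on tie-breaking in ambiguous files). Hydrogens participate when
  deposited — the contact rule is any-atom — but typical X-ray
  structures carry none.
* **Indices.** Residues are addressed by 1-based ordinal position along
  the parsed chain (the natural choice in R); author numbering and
  insertion codes are carried for I/O, and mutations are mapped only
  through the alignment's explicit one-to-one pairs — no independent
  renumbering.
* **Neighbors outside the aligned region are excluded from clusters.**
  The null shuffles only aligned positions; a member that can never
  receive shuffled counts would inflate observed scores relative to the
  null and bias p-values downward.
* **Decoy streams** are generated per distinct cap value — the capped
  multiset depends on the assessed cluster only through its cap — and
  clusters sharing a cap share a stream. This is statistically
  identical to independent streams and reduces work by roughly the
  number of tested clusters. Streams are seeded by (gene, cap, seed),
  so results are independent of processing order and safe under
  per-gene parallelism.
* **Zero exceedances** are reported as $p = 0$ with a `zero_exceed`
  flag, to be read as $p < 1/n_\text{decoys}$. No add-one smoothing is
  applied: the raw fraction is the method's published definition, and
  smoothing would shift every reported value.
* **Exact oracle.** `exact_pvalue()` enumerates all distinct placements
  of the capped multiset (the multinomial coefficient is computed first
  and enumeration refuses above $10^6$ placements). It exists to verify
  the Monte Carlo path and for tiny inputs, not for production use.
* **Degenerate inputs.** Chains with no amino-acid residues are skipped
  with a warning; a gene with no missense mutations yields an empty
  result, not an error; `apply_cap` rejects caps below 1 because a
  testable cluster always contains a mutation.

## The synthetic generator

`make_structure()` emits CA-only traces: straight chains at a chosen
spacing (3.8 Å, the canonical CA–CA virtual bond, gives exactly the
$(i,i{+}1)$ contact set at the 5 Å cutoff — a fully controlled graph)
and ideal α-helices with rise 1.5 Å/residue, 100°/residue, radius
2.3 Å. With these constants the helix CA–CA distances are 3.83 Å
($i,i{+}1$), 5.05 Å ($i,i{+}3$) and 6.20 Å ($i,i{+}4$): just outside
the 5 Å cutoff for $i\pm3$, so the CA-trace helix is a locally connected
$(i,i{\pm}1)$ graph. Real helices gain $i\pm3/i\pm4$ contacts through
side-chain atoms, which CA traces do not model; fixture tests assert
against a brute-force distance oracle on the generated coordinates, not
against secondary-structure intuition.

`make_mutations()` injects ground-truth clusters (each injected residue
mutated in a chosen number of distinct samples) and uniform background
(each event in its own sample, so per-residue counts are exactly
conserved), alongside a trivial identity alignment. `null_batch()`
produces replicate background-only tables for calibration runs.

What passing tests on these fixtures does *not* show: robustness to
alignment error (fixtures use identity alignments), to inter-chain or
quaternary contacts (per-chain maps only, as designed), to mutation
annotation errors upstream, or to the heterogeneous residue sizes and
packing of real folds. The fixtures validate the statistics, not
structural biology.

## Problem sizes used in the checks

The automated checks run desk-scale versions of the method's
properties, chosen to keep each property statistically decisive: exact
vs Monte Carlo agreement at $10^5$ decoys on fixtures of up to 8
positions (enumeration sizes up to a few thousand placements);
family-wise calibration over 500 null replicates of a 50-residue helix
with 20 background mutations at $10^4$ decoys (binomial 3σ band around
the nominal 0.05 gives the [0, 0.08] acceptance window); injected-
cluster recovery over 100 replicates of a 100-residue helix. With the
acceptance-script seeds the measured family-wise rate is ≈ 0.02 and the
recovery rate 1.00; both are recomputed, not stored.

## Known limitations

* Protein-level blacklist matching (gene, position, ref, alt) is a
  simplification relative to genomic-coordinate matching; variants that
  differ at the DNA level but coincide at the protein level are
  conflated.
* The per-sample counting rule for multi-allele hits is a documented
  choice; event-level counting would change scores for hypermutated
  cohorts.
* Only intra-chain clusters are considered; interface clusters between
  chains are out of scope.
* The catalog's significance threshold is a choice, not a derived
  quantity; downstream users should treat borderline entries
  accordingly.
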