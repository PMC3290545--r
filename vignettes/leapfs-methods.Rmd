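---
title: "Methods: dynamics-perturbation and literature-based functional-site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics-perturbation and literature-based functional-site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapfs)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices taken where the design was
genuinely open, and what the synthetic-data tests do and do not establish
about real data.

## The structure-based arm: Dynamics Perturbation Analysis

A protein domain is modelled as an anisotropic elastic network: one node
per C-alpha, Hookean springs of strength $\gamma$ between all node pairs
within a cutoff $r_c$. The Hessian is assembled from pairwise $3\times 3$
blocks $-\gamma\,\hat u \hat u^\top$ ($\hat u$ the unit bond vector), with
diagonal blocks making every row of blocks sum to zero. The equilibrium
conformational distribution is the Gaussian
$P^{(0)}(\mathbf x) \propto \exp(-\mathbf x^\top H^{(0)} \mathbf x / 2)$;
the factor $k_BT$ is absorbed into $\gamma$, which therefore defaults to 1
— only ratios of spring constants enter the final signal.

The domain is then decorated with $M$ surface test points. Point $m$,
held fixed, couples to every node within $r_s$ with springs of strength
$\gamma_s$, adding $\gamma_s\,\hat u_i \hat u_i^\top$ to each contacted
node's diagonal block. The signal at point $m$ is the relative entropy

$$D_x^{(m)} = \mathrm{KL}\!\left(P^{(m)} \,\|\, P^{(0)}\right)$$

between the perturbed and unperturbed Gaussians. Points whose interaction
most perturbs the vibrational distribution — typically points nestled in
concave pockets, where they contact many nodes from many directions — mark
candidate functional sites.

Defaults follow the published protocol for this method: $r_c = 10.5$ Å,
$r_s = 15.5$ Å, $\gamma_s = 12\gamma$, probe radius 1.5 Å, one surface
point per Å², selection of points in the upper tail of an extreme-value
fit (fitted CDF $\ge 0.96$), spatial clustering at 5 Å with at least
3 points per cluster, and site residues taken as all residues with a heavy
atom within 5 Å of a cluster point. Sites are ranked by mean $D_x$ and
labelled O, P, Q, … in descending order; points below threshold are
labelled NN and above-threshold points that fail to cluster XX.

### Numerical choices

* **Direction of the divergence.** The defining papers of the method
  compute the divergence of the perturbed distribution against the
  unperturbed one, and that is the default here
  (`direction = "m_vs_0"`); the opposite direction is available on every
  entry point, since the verbal description "relative entropy between
  $P^{(0)}$ and $P^{(m)}$" does not fix an order.
* **Rigid-body modes.** $H^{(0)}$ has six zero modes (translation,
  rotation). Both quadratic forms are projected onto the complement of
  the null space of $H^{(0)}$ before the closed-form Gaussian divergence
  is evaluated. A pseudo-determinant treatment was rejected because the
  perturbed Hessian is generally nonsingular and the two conventions then
  disagree. Degenerate geometries (e.g. collinear networks) have more
  than six near-zero modes; all of them are projected out, and a
  perturbed form that is still numerically rank-deficient on the retained
  subspace is an error rather than a silent answer.
* **Low-rank evaluation.** A point contacting $c$ nodes perturbs the
  Hessian by a rank-$c$ update, so $D_x$ is evaluated through the
  Woodbury/determinant-lemma identity on a $c\times c$ matrix rather than
  a $3N\times 3N$ eigenproblem per point. The test suite verifies this
  path agrees with the direct full-matrix evaluation to $10^{-9}$.
* **Threshold fit.** The extreme-value family is the Gumbel, fitted by
  maximum likelihood with moment-based start values. "Upper 96%" is read
  as fitted CDF $\ge 0.96$, selecting roughly 4% of points; the literal
  reading (96% of all points) would contradict the sparse site labels the
  output format allows for. On fields whose empirical upper tail is
  shorter than the fitted Gumbel tail the selection can be empty; the
  pipeline then simply reports no sites.
* **Clustering.** The published protocol clusters with OPTICS at a single
  fixed distance threshold, which at one threshold reduces to
  density-connected components: points within 5 Å are connected, and
  components with at least three members become clusters.
* **Surface points.** An internal deterministic generator stands in for
  an external molecular-surface triangulation: every heavy atom carries a
  Fibonacci lattice on a sphere of radius $r_{vdw} + r_{probe}$, sized to
  the target areal density, and points buried inside any other atom's
  expanded sphere are removed. The construction is deterministic, so the
  whole pipeline is reproducible without a seed. It is
  translation-equivariant but, like any fixed triangulation, not
  rotation-equivariant; the rigid-motion invariance guaranteed (and
  tested) is that of the structure-plus-points system. Vertex files from
  an external triangulation tool can be imported instead for
  bit-compatibility studies.

## The text-based arm

Residue mentions are extracted with compositional regular expressions:
alternations for amino-acid names (full names with common variants,
3-letter and 1-letter abbreviations), a position, connector characters
(hyphen, space, em dash U+2014, arrow U+2192) and boundaries. Covered
surface forms include `Asp104`, `His-554`, `aspartic acid 104`,
enumerations (`cysteines at positions 6, 24, and 393`), and mutations in
short (`G146A`, `Gly23Ala`, `Asp104→Ala`) and linguistic (`His-554
mutated to glutamine`) forms. A bare amino-acid name without a position is
never a mention. Each match is normalized to wild-type 3-letter code,
position, optional mutant code, and character span.

The default mode intentionally reproduces two documented error behaviours
of this class of extractor — a name followed by a parenthesised citation
number (`tyrosine (6)`) is read as a residue, and a trailing capital
letter after a 3-letter mention (`Cys105L`, where L is a chain label) is
read as a mutation — because evaluation against corpora annotated with
such systems depends on them; `strict = TRUE` suppresses both classes.
One-letter matches inside gene-name-like tokens (`E2F`, `R377`) are not
specially filtered in the default mode. Positions are capped at 99999.

Evaluation follows the standard protocol: a true positive requires
agreement of the normalized code and position (both codes for mutations),
optionally plus the exact character span for span-annotated corpora;
precision, recall and F1 come from the pooled TP/FP/FN counts.

## Grounding, transfer, conservation

**Grounding** maps each abstract's mentions to physical residues in the
linked structures in four steps: group mentions by position into text
residues; discard groups with conflicting primary names; match position
against author residue numbering and name against the primary or mutant
code over all protein chains; and accept multiple matches only when they
derive from a single molecular entity (homodimer copies ground together,
cross-entity matches are ambiguous and dropped). Matching is exact on
position — no renumbering offsets — and text positions match only
residues with a blank insertion code, choices that favour precision over
recall. For PDB-format input, which has no entity records, protein chains
with identical residue sequences are assigned a shared entity.

**Annotation transfer** composes protein-level alignments (domains of one
protein) with a family-level alignment of per-protein representatives
(longest domain, ties by identifier) into a virtual alignment, and
propagates NSM/curated/text annotations to aligned residues. A transfer
requires the source and target amino acids to share a fuzzy group; the
shipped grouping — \{D,E\}, \{K,R,H\}, \{S,T\}, \{N,Q\}, \{I,L,V,M\},
\{F,Y,W\}, \{A,G\}, \{C\}, \{P\} — is an explicit, versioned
reconstruction of the catalytic-site template convention and can be
overridden with any grouping table.

**Conservation.** Column conservation is the normalized Shannon entropy
over the 22-symbol alphabet (20 amino acids, gap, wildcard):
$H = -\sum_i p_i \ln p_i$, $H_{norm} = 1 - H/\ln 22$. The reference
implementation in bio3d normalizes by the largest observed column entropy
instead of the fixed $\ln 22$; the two differ by a monotone transform
only, and every downstream use here is rank-based, so ranks — and hence
all site scores — are identical under either convention. The test suite
pins our raw entropies to bio3d's exactly and asserts identical column
ranking. Residues are ranked within a domain (most conserved first, ties
averaged), and a site of $L$ scored residues gets the lumped score $z$,
the product of its residues' percentile ranks. Under the null of randomly
drawn residues the percentiles are independent uniforms, giving the
closed-form p-value

$$P \;=\; z \sum_{k=0}^{L-1} \frac{(-\ln z)^k}{k!},$$

equivalently the upper tail of a Gamma($L$, 1) at $-\ln z$ — the form
used for $L > 50$ for numerical stability. The closed form was validated
against a Monte-Carlo oracle before use. Residues without conservation
data are excluded from $L$ rather than imputed; percentiles use the
rank$/N$ convention. Fractional conservation scores (0 = least, 1 = most
conserved) require an alignment of at least 10 distinct sequences.

## Integration

Residue-wise overlap uses set arithmetic on residue keys: the recall of
an NSM site is the fraction of its residues covered by the union of all
predicted sites; the precision of a predicted site is the fraction of its
residues inside the union of all NSM (or NSM-valid) residues. "A site
matches" means a nonempty residue-set intersection, with no minimum size.
Threshold curves report the fraction of sites at or above each cutoff
($\ge$ comparisons). Fold enrichments offer two rounding modes: `"paper"`
first rounds each rate to the printed precision (whole percent, or one
decimal below 1%) and divides the rounded figures — the arithmetic that
reproduces printed worked ratios exactly — while `"exact"` divides raw
fractions. The combined report has one row per (site, residue) pair with
the fixed 13-column layout (cluster id, entity, chain, number, insertion
code, name, and binary flags for text match, catalytic annotation,
NSM-valid, NSM, family-curated and family-NSM, plus the hetero codes of
nearby molecules with their curation status).

Small-molecule handling: a "small molecule" is any non-domain chain —
organic compounds, ions, short peptides, nucleic acids — with no
molecular-weight filter. Waters are excluded by default
(`exclude_water = TRUE`): including them would mark nearly every surface
residue as near a small molecule. Hetero-code list matching against
curation records is ordered and exact, with an optional user-supplied
synonym map (e.g. GGL↔GLU) absorbing naming drift between structure files
and curation databases; covalently linked hetero residues numbered
consecutively in one author chain are kept together as one molecule.

## What the synthetic data does and does not show

The generators produce: a compact sheet-like C-alpha scaffold (serpentine
grid, 3.8 Å along the chain) with one sidechain-proxy atom per residue, a
2×2 notch as a concave pocket, and a three-atom ligand seated in it, with
the gold near-small-molecule residue set computed by brute force at
generation time; abstracts with planted mentions in mixed surface styles,
exact spans, and controlled distractor tokens that extract as false
positives; and protein/family alignment pairs with chosen fully conserved
columns. All outputs are byte-identical under a fixed seed.

Default study conditions: 56-residue domains (large enough that the
point–protein cutoff $r_s$ does not span the whole structure, so the
$D_x$ field has genuine spatial contrast; a 30-residue variant is
exercised in the invariance tests), surface density 1 point/Å², and the
analysis parameters above — i.e. the published protocol's values, applied
to miniature structures. Monte-Carlo checks use $10^5$ draws per grid
cell; these sizes keep the full suite under a minute of numerical work
per component.

What passing these tests shows: the geometry, statistics and bookkeeping
are implemented correctly — distances, the divergence field and its
invariances, selection, clustering, grounding and transfer logic, and the
closed-form p-value. What they do not show: performance on real
structures. Synthetic scaffolds have no secondary-structure elasticity,
no realistic packing or B-factors, pocket geometry far simpler than real
clefts, and abstracts far cleaner than real prose. Corpus-scale
percentages reported for the full public-database survey (coverage rates,
table-level statistics) depend on specific historical database snapshots
and are out of scope at desk scale.

## Known limitations

* The elastic network couples test points to C-alpha nodes only; a flag
  for all-heavy-atom coupling is a possible extension but the default
  follows the coarse-grained network convention.
* Mention extraction is pattern-based; its coverage is defined by the
  documented surface forms plus the evaluation protocol, not by identity
  with any particular historical pattern inventory.
* Grounding requires exact position matches and therefore misses
  renumbered constructs by design.
* The internal surface generator approximates a triangulated molecular
  surface; site boundaries can differ by a residue or two from runs using
  an external triangulation, which is why the accession-based benchmark
  script makes no exact-match claim.
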