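---
title: "Methods: FeADH subfamily classification and diagnostic-residue annotation"
author: "FeADHtools"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and rules
it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## 1. The family and its reference frame

Iron-containing (type-III) alcohol dehydrogenases (FeADHs, CDD family
cd08551) form 19 CDD-defined subfamilies. Thirteen of them contain
eukaryotic members and eight span all three domains of life; no subfamily
has members in animals, plants and fungi simultaneously. The packaged
registry (`inst/extdata/feadh_registry.tsv`, loaded and validated by
`loadRegistry()`) transcribes this structure once, and every other module
reads it from there.

All coordinates in this package are **1-based inclusive positions in human
ADHFE1** (467 residues), the family's customary reference frame.
`anchorMap()` centralizes the diagnostic coordinates: the
coenzyme-specificity determinant at 81, the GGGS pyrophosphate-binding loop
at 138–141, the metal tetrad Asp242/His246/His330/His357, the
catalysis-candidate position 334, the two HOT-subfamily insertions at
256–274 (19 residues) and 342–354 (13 residues), and the domain split at
229/230. A query is placed in this frame by `mapToReference()`: a global
pairwise alignment to an anchored reference sequence whose residue–residue
columns define a partial bijection between query and reference positions.

Assumption made explicit: residue-level numbering through *pairwise*
alignment is reliable only because the family retains an alignable
conserved scaffold. For real sequences that scaffold is structural (the
21 conserved secondary-structure elements); the synthetic generator must
reproduce an analogue of it (section 5).

## 2. Annotation rules

- **Coenzyme (position 81).** Asp/Thr ⇒ NAD⁺; Gly ⇒ NADP⁺-capable
  (including dual-coenzyme use). We extend Asp with Glu (conservative
  charge equivalent) and Gly with Ala (short side chain); both extensions
  are documented as such. Serine is *not* called: serine binds the
  2'-phosphate in other NADP⁺-dependent enzyme families, but in this family
  threonine occurs in NAD⁺-binding enzymes, so any call for Ser would be
  invented. Gaps and all other residues return `ambiguous`.
- **Metal site (242, 246, 330, 357).** Intact (D,H,H,H) ⇒
  `metal_dependent`. Asn/Arg (maleylacetate reductases) or Gln (FeADH2,
  some HEPD members) at 242 with all three histidines intact ⇒
  `metal_independent_likely`. Everything else — including histidine
  substitutions, whose functional effect is not established — is
  `indeterminate` rather than guessed.
- **GGGS motif.** Matched at 138–141 with a configurable mismatch
  tolerance (default 1); unmapped positions count as mismatches and a
  fully unmapped span is `FALSE`.
- **HOT insertions.** The insert length is the number of query residues
  mapped inside each reference span. The `hot_like` call requires **both**
  inserts to reach their minima (defaults 15 and 9, i.e. ≈80%/70% of the
  full 19/13) — all HOT proteins carry both insertions, and requiring both
  makes the call robust to the one failure mode a global aligner still
  has at family-level divergence: pulling flank residues of an insert-free
  query into a single span (never both).
- **Family boundary.** Glycerol dehydrogenases retain only the
  His357-equivalent of the tetrad (they bind zinc through a different
  residue set); `flagGdhLike()` fires when His357 is present and neither
  His246 nor His330 is a histidine, and the classifier refuses such
  sequences (`excluded_gdh_like`) instead of assigning them.
- Position 334 is extracted and reported but feeds no call: it is linked
  to catalysis, not metal binding, and no decision rule exists for it.

## 3. Alignment and its metrics

`globalAlign()` wraps Needleman–Wunsch global alignment
(`Biostrings::pairwiseAlignment`) under BLOSUM62 with affine gap costs
gapOpening = 11, gapExtension = 1 (community defaults; a gap of length L
costs 11 + L). Tie-breaking among co-optimal alignments is the library's
deterministic traceback: identical inputs always give identical output.

Percent identity is computed from the aligned strings, not taken from the
library, because published identity figures rarely state their
denominator. The default denominator is every column in which at least one
sequence has a residue (gaps count against identity); `"shared"`
(residue–residue columns only) is available because both readings of
published numbers are plausible. Identity counts only exact matches of
non-X residues — X never counts as identity. Similarity is the fraction of
residue–residue columns with a positive substitution score; identity can
never exceed similarity because every identical non-X pair scores
positively under BLOSUM62.

## 4. Classification

Each subfamily is represented by a seed set (≥ 3 sequences). A query's
subfamily score is the mean of its `k` best global-alignment scores
against that set (default k = 3); the best and second-best subfamily
scores give a margin. Assignment requires:

1. margin ≥ `minMarginFrac` × |best score| (default 0.05), ties resolved
   toward `divergent_unassigned` — the conservative direction; and
2. a reciprocal-best-hit (RBH) confirmation.

**RBH operationalization.** Database-style RBH has no unique translation
to seed-set scoring, so this package defines it as: let s\* be the query's
best seed; the check passes when s\* reciprocally prefers the query over
every seed *outside its own subfamily* (its own siblings are treated as
equivalent to the query — they represent the same orthologous group). A
naive "s\*'s best partner is the query or a sibling" reading is vacuously
true whenever seed sets are tight, and would not reject unrelated
sequences; under the implemented semantics genuine members pass easily
(within-subfamily scores dwarf cross-subfamily ones) while sequences
unrelated to the family fail, because even cross-subfamily seeds share the
conserved scaffold and outscore them.

Raising `minMarginFrac` can only demote assignments, never promote them,
and classification results are independent of query order.

Phyletic summaries count assigned queries per subfamily × taxon group and
report shares both at one decimal and **truncated to an integer** — the
convention used in prose ("656 of 868, thus 75%"); raw counts always
accompany the percentages so they recompute exactly.

## 5. The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, so
that every pipeline stage is testable without downloads:

- **One anchored reference** (`makeReference()`): 467 random residues with
  every diagnostic planted (D81, GGGS, D242/H246/H330/Y334/H357, both
  insert spans).
- **19 subfamily ancestors** (`makeSubfamilyAncestors()`): built from the
  reference; non-HOT ancestors have both insert spans deleted (indels
  occur *only* as whole-insert presence/absence, so reference numbering is
  exact by construction); each ancestor carries its registry-specified
  anchor residues (e.g. MAR: Thr81 + Asn242; FeADH2: Gln242; BDH: Gly81).
- **Conservation architecture.** Three site classes emulate the family's
  conserved scaffold: (i) an invariant core — the diagnostic anchors plus
  6-residue blocks flanking each insert (the helix ends the insert loops
  hang between); (ii) partially conserved *element blocks* — ten scattered
  3-residue cores plus windows around each diagnostic cluster (75–87,
  134–145, 238–250, 326–338), mutating at 0.3× the variable-site rate,
  standing in for the 21 conserved secondary-structure elements; (iii)
  variable sites, substituted independently (uniform over the 19
  alternative residues). Without class (ii), 20%-identity sequences are
  pairwise-unalignable at residue level — the same reason the original
  family analysis needed a structure-guided alignment.
- **Calibration.** The variable-site rate is solved from the closed-form
  match model ((1−q)² + q²/19 per site class) for the 20% inter-subfamily
  identity target, then refined by deterministic bisection against the
  identity actually measured with the package's own metric (accept band
  ±4, hard bound ±5 — the family's figure is "ca. 20%"); an unreachable
  target is an error that reports the identity achieved. Achieved values
  land at ≈22–24%. The shared uniform draws make the bisection a pure
  function of (seed, q), so generation is byte-reproducible.
- **Sampling.** Within a subfamily, sequences mutate only variable and
  scaffold-block sites (anchor environments stay fixed — functional-site
  conservation), at the rate implied by the 70% within-subfamily identity
  target. Taxon groups are drawn from per-subfamily weights that honour
  the registry's phyletic flags; a weight on a flagged-absent group is an
  error.
- **Alignability guarantee (rejection sampling).** Every ancestor and
  every emitted sequence is checked to be *reference-numberable*: the
  planted anchors must be recoverable through the package's own mapping.
  Draws that break numbering (rare, but systematic for unlucky scaffold
  draws) are redrawn, deterministically and with a bounded retry count.
  This emulates the structural alignability of real family members and is
  disclosed openly: annotation-recovery tests therefore verify the rule
  machinery on top of a guaranteed mapping, while classification accuracy,
  logo composition and tree/bootstrap behaviour remain genuine end-to-end
  properties.
- **GDH decoys** (`makeGdhDecoys()`): the same scaffold without inserts
  and with the tetrad reduced to (D,A,S,H) — His only at 357 — to exercise
  the family-boundary exclusion.

What the generator does **not** emulate: realistic substitution processes
(no rate heterogeneity beyond the three site classes, no
amino-acid-exchangeability structure, no profile-HMM emission), real taxon
abundances (656/868 etc.), length variation beyond the two inserts, or
nested subfamily relatedness (ancestors form a star by default). Passing
tests on this data therefore demonstrate that the pipeline's rules,
scoring and bookkeeping are correct under the family's stated divergence
structure — not that the pipeline would resolve every real borderline
sequence.

## 6. Phylogenetics

Distances are p-distances (1 − identity fraction over shared columns;
pairwise deletion), with the Poisson correction −ln(1 − p) available
(capped, with a warning, when p ≥ 1). Trees are inferred with
neighbor-joining (`ape::nj`), which is exact on additive matrices — the
package's oracle tests exploit this. The family's published trees come
from maximum-likelihood inference, but the same study reports that
minimum-evolution and neighbor-joining gave similar topologies, which is
what licenses NJ as the desk-scale method here; ML, model selection and
gamma-rate estimation are out of scope.

Numerical conventions: negative NJ branch estimates are clamped to zero
with the raw values kept in an attribute; a 2-taxon input returns the
trivial single-edge tree by convention; fewer than 2 labels is an error.
Bootstrap supports resample the columns of the reference-projected
pseudo-alignment (columns with > 50% gaps dropped — the insert columns
drop out automatically in mixed sets), rebuild the NJ tree per replicate
(500 replicates is the family-analysis convention; the pipeline default is
100 for interactive use), and count bipartition recovery; runs are seeded
and byte-reproducible. Monophyly is evaluated on **bipartitions** of the
unrooted tree — no outgroup is assumed — with the trivial groups (all
leaves, single leaf) reported as 100 by convention and an absent
bipartition reported as `NA` ("not recovered").

Newick output is written by a small in-package serializer because the
standard writer replaces spaces in labels with underscores instead of
quoting them; labels containing Newick metacharacters are single-quoted,
and reading (via `ape::read.tree`) strips the quotes, so write→read
round-trips topology, lengths and supports.

## 7. Sequence logos

Column information content is Schneider–Stephens:
R = log₂20 − (H + eₙ), with H the Shannon entropy of the observed residue
frequencies and the optional small-sample correction
eₙ = 19/(2·n·ln 2). Letter heights are frequency × R, so heights stack to
the column information. Gaps and X are excluded from the counts (the
common logo convention; whether the family's published logos applied the
correction is unstated, so both modes are supported and the default is
off). R is clamped at zero — for very small n the correction exceeds
log₂20 − H. Note the correction only falls below 0.01 bits from n ≈ 1371
onward (eₙ(1000) ≈ 0.0137).

## 8. Problem sizes and determinism

The shipped tests run the full parameter-recovery study at 19 subfamilies
× 50 queries with 3 seeds per subfamily (the package's chosen study size —
large enough that every subfamily's rules and the classifier are exercised
at scale), plus a 20-taxon, 500-replicate bootstrap study for tree
support; smaller six-subfamily fixtures back the per-module tests. Every
random draw flows from a single integer seed per dataset, and reruns —
including whole pipeline bundles via `runPipeline()` — are byte-identical
(the configuration copy written next to a run's outputs omits only the
output directory path).

## 9. Known limitations

- Residue-level numbering is pairwise-alignment-based; for real sequences
  more divergent than the family's scaffold supports, the numbering
  low-confidence flag (coverage below 0.5) should be treated as a warning
  that anchor extraction may shift, and a structure-guided alignment is
  the proper tool.
- The classifier's scores are global-alignment scores, not E-values; they
  are comparable within a run but not across substitution matrices.
- The RBH criterion and the margin threshold are this package's
  operationalization of a procedure whose original parameters were not
  published; both are configurable.
- The truncated-percentage formatter exists to match prose conventions;
  machine-readable outputs always carry the raw counts.
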