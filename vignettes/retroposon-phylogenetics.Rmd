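---
title: "Retroposon presence/absence phylogenetics with retromark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retroposon presence/absence phylogenetics with retromark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

retromark analyzes phylogenies from retroposon (SINE) insertion markers.
A retroposed element pastes a copy of itself at an effectively random
genomic position; once fixed, the insertion is inherited by every
descendant lineage, parallel insertions at the same orthologous site are
vanishingly rare, and precise excision essentially never happens. Shared
presence of an element at an orthologous locus is therefore a
near-homoplasy-free signal of common ancestry, and the natural model of
character change is *gains only*. This vignette describes the models and
algorithms in the package, the choices made where the methods literature
leaves the design open, and what the synthetic-data generator does and
does not emulate.

## Marker matrices and their states

A `marker_matrix` records taxa by markers with states `+` (present), `-`
(absent), `?` (missing data) and `d` (deleted). Two coding decisions
matter downstream:

* **Deletions are missing, not absent.** A non-specific deletion destroys
  the locus, so presence there is unknowable; coding `d` as absence would
  manufacture false conflict. The packaged marsupial matrix contains one
  such site (marker 168a in the marsupial mole), and its clade is counted
  as supported despite it -- exactly what treating `d` as missing yields.
* **Missing states are compatible with either side.** In support counting
  and in parsimony, `?`/`d` leaves may take either state at no cost.

The packaged 21-taxon x 53-marker marsupial matrix (`marsupial_markers()`)
uses full species names as taxon labels because the original tabulation
abbreviated two different taxa identically ("Pt"); identity is positional.

## Support patterns and the insertion significance test

`support_pattern()` counts the `[k l m]` pattern around an internal edge:
`k` markers present in every scored taxon of the focal clade and absent in
every scored taxon outside it; `l` and `m` count markers supporting the
two alternative pairings of the clade's daughter lineages with the
in-frame outside taxa. The outgroup can never belong to an alternative
ingroup clade, so it is excluded from the present side of the alternative
counts; when no in-frame outside lineage exists (the monophyly edge of the
whole ingroup) there is no alternative to support and `l = m = 0`.

Under the null of a hard polytomy, each marker independently supports one
of the three resolutions of the edge with probability 1/3. For a
conflict-free pattern the p-value is the closed form `(1/3)^k`
(`conflict_free_p()`); `multinomial_p()` generalizes to conflicted
patterns as the exact tail probability, over the trinomial
`(n = k + l + m, 1/3, 1/3, 1/3)`, of a support margin
`a - max(b, c) >= k - max(l, m)`, computed by full enumeration. The two
routes agree to numerical precision on conflict-free patterns, which is
asserted in the tests. Three or more conflict-free markers give p < 0.05.
No multiple-edge correction is applied, matching standard practice for
this test.

## Irreversible (gains-only) parsimony

`irreversible_parsimony_score()` scores a rooted tree under Camin--Sokal
transformation: every character starts at 0 at the root, a 0 to 1 gain on
an edge costs one step, and losses are forbidden. With binary states this
reduces to counting, per character, the maximal subtrees that contain a
scored presence and no scored absence -- computed with two bitmasks per
node, 64 characters per machine word, in C++. The scorer accepts
polytomies. Rooting follows the outgroup: if the matrix outgroup is among
the tree's tips, the tree is (re)rooted on the outgroup's edge before
scoring, so a Newick basal trichotomy is interpreted the way parsimony
programs display unrooted trees. The dynamic program is validated in the
test suite against exhaustive enumeration of all ancestral-state
assignments on small trees and against an independent asymmetric-cost
Sankoff implementation.

The consistency index is the minimum conceivable number of steps (one per
character with at least one scored presence, since the root is fixed at
absent) divided by the realized tree length; CI = 1 means no homoplasy.

`heuristic_search()` is the classic two-phase heuristic: each replicate
builds a starting tree by stepwise addition in a seeded random taxon
order, scoring every insertion point and breaking ties uniformly at
random, then hill-climbs with branch swapping (TBR by default, SPR and
NNI available) under first-improvement acceptance until no rearrangement
shortens the tree. Swapping operates on the unrooted tree; every
candidate is scored rooted at the outgroup. Distinct optimal *binary*
topologies are collected across all replicates and deduplicated by a
canonical rooted form. On the packaged matrix, 1,000 replicates take a
few seconds and find length 53 with CI 1.

A caution on "numbers of equally parsimonious trees": where no character
varies within a group of taxa, every binary resolution of that group ties
under gains-only scoring, so the count of distinct optimal binary
topologies is the product of the resolution counts of the consensus
polytomies and can be large even when the consensus is stable. Counts
reported by other programs depend on their tree-collapsing and
tree-saving conventions and are not comparable across conventions.
`strict_consensus()` (validated against the ape consensus) reduces the
optimal set to the clades common to all optima.

## The TinT activity chronology

Young elements insert into older elements, never the reverse. The nesting
direction between repeat families therefore orders their activity in
time. `detect_nested_insertions()` finds
transposition-in-transposition events in a repeat annotation: a guest hit
lying strictly between two same-family, same-strand host fragments with
no intervening hit, host fragments at least `min_fragment` (default 30)
bp long, and consensus coordinates continuous across the guest to within
`continuity_window` (default 30) bp. The defaults are conservative and
configurable; two candidate guests between the same host fragments are
ambiguous and yield no event (precision over recall). Self-nesting is
counted like any other family pair.

`estimate_activity()` fits the chronology model to the guest-into-host
count matrix `N`. Family `f` is active at times Normal(`mu_f`,
`sigma_f`) on a latent relative axis (larger = more recent). A guest
inserting at time `t` can only land in host copies already present, so

    P(host = j | guest = i) = E_t[ w_j F_j(t) ] / sum_k E_t[ w_k F_k(t) ]

with `F_j` the host activity CDF, `w_j` its relative copy abundance, and
the expectation over `t ~ Normal(mu_i, sigma_i)` evaluated by fixed-node
Gauss--Hermite quadrature (32 nodes by default). Each guest row of `N` is
multinomial. Choices that matter:

* **Identifiability.** The time axis is relative, so `mean(mu) = 0` and
  `mean(sigma) = 1` are imposed; spreads are optimized on the log scale
  (softmax-normalized) and floored at `sigma_floor = 1e-3`.
* **Copy weights.** `w` is fixed, not estimated. When genome-wide copy
  counts are available they should be passed as `copy_weights`; the
  default uses each family's share of total nesting participation as a
  proxy, since the count matrix itself carries no copy totals.
* **Optimization.** Multi-start BFGS (10 restarts by default, seeded);
  the first start orders families by their guest-minus-host excess.
* **Boundary behavior.** The spread of the youngest family is weakly
  identified -- almost nothing nests into a pool of copies that barely
  existed yet -- and its maximum-likelihood `sigma` can collapse to the
  floor (symmetrically for the oldest). Recovery simulations in the test
  suite recover the activity *ordering* (Kendall tau at least 0.9 at
  5,000 events and 6 families), and the 50%/90% activity
  intervals (`activity_intervals()`, `mu ± 0.6745 sigma` and
  `mu ± 1.6449 sigma`) cover the true location reliably for time-interior
  families, but interval coverage at the extremes should not be trusted.

`classify_lineages()` partitions families into lineage-specific and
shared groups by their presence in each genome's annotation, the grouping
used to target marker screening at particular tree depths.

## The synthetic-data generator

`simulate_retroposons()` emulates the generative structure the analysis
assumes, with complete ground-truth ledgers. Families insert along a
rooted species tree whose branch durations share the activity time axis,
so lineage-specific versus shared families emerge from where `mu` falls
relative to the splits. Insertions land uniformly in the growing genome
(background plus existing element material); a hit inside an existing
element splits it into fragments with continuous consensus coordinates (a
true TinT event), and every insertion event is a presence/absence marker
gained on its edge. Per-tip RepeatMasker-style annotations, the insertion
ledger, a per-tip TinT truth table, the marker matrix, gain-edge table
and the true tree are all returned and can be written to files that the
package's own readers parse back (`write_dataset()`).

Details that make the truth ledger exact rather than approximate: split
offsets within one host are kept at least 2 bp apart so every annotated
fragment respects the closed-interval coordinate invariants and no two
guests share an insertion point; an event is flagged `clean` in the
ledger when both final flanking fragments are at least `min_fragment` bp
and the guest itself was never split. On such events the detector
achieves exact precision and recall, which the tests assert tip by tip.

Perturbations are applied to the matrix last and logged: masking to `?`
(`missing_rate`, applied to scored cells), non-specific deletions to `d`
(`deletion_rate`), and an incomplete-lineage-sorting emulation
(`ils_rate`). The ILS move deserves a note: re-drawing a marker's *gain
edge* can never create marker conflict, because any collection of clades
of one tree is pairwise compatible. To emulate the hemiplasy signal that
real ILS produces, a perturbed marker's presence set is instead re-drawn
discordantly around its gain edge -- one daughter lineage of the gain
node paired with a sibling lineage (tip-edge markers deepen onto the
parent edge). This is a pattern-level perturbation, not a coalescent
model; conflict rates rise monotonically with `ils_rate`, which is what
the analysis-side diagnostics need to see.

What the simulator does *not* emulate: nucleotide sequences (coordinates
and labels only), insertion-site motif preference, element truncation and
decay, genome size change feedback, and coalescent ILS. Tests passing on
synthetic data therefore validate the bookkeeping and the statistical
machinery, not sequence-level marker curation -- that step is covered
separately by `validate_marker()` on alignment inputs.

## Marker validation on locus alignments

`validate_marker()` applies the orthology criteria to a gapped alignment
of one candidate locus: identical insertion points (within a 2-column
slop by default -- alignment jitter around indel-rich flanks makes exact
column identity too strict), identical orientation and subtype, matching
target-site duplications when recorded, shared diagnostic indels
(identical gap pattern within the element span), and consistency across
replicate sequences of a taxon. Present requires every checkable
criterion to pass; absent requires a clean empty site (aligned flanks, no
residue in the span); everything else is missing. The schematic locus
generator used in the tests (`make_synthetic_locus()`) builds alignments
with known truth, including destroyed sites, which must come out as
missing -- the same treatment the deletion state receives in the matrix.

## Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and is reproducible from
it. The test suite runs the full 1,000-replicate TBR search on the
packaged matrix (a few seconds), parameter recovery at 5,000 nesting
events and 6 families, simulator-versus-detector checks on genomes of a
few hundred kilobases with ~1,000 insertions, and 48 small simulations
for the ILS monotonicity check; the whole suite completes in a few
minutes on one core. `scripts/acceptance.R` re-runs the headline
computation (search plus significance values) from scratch against the
installed package.

## Known limitations

* The activity model fixes copy weights rather than estimating them, and
  spreads of time-extreme families are weakly identified (see above).
* The nesting detector requires both host fragments to be annotated and
  adjacent to the guest; hosts fragmented below `min_fragment`, or guests
  that were themselves split, are deliberately not called (precision over
  recall), so genome-scale event totals depend on these thresholds.
* `validate_marker()` checks alignment-level orthology criteria; it does
  not compute alignments or discover loci.
* The ILS perturbation is a pattern-level emulation; inference about
  coalescent parameters is out of scope.
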