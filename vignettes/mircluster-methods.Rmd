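---
title: "mircluster: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mircluster: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircluster)
```

## The question

Animal microRNA genes are often clustered: two or more hairpin precursors lie
within a few kilobases of each other on the same strand and are usually
processed from one polycistronic primary transcript. Three mechanisms can
create such an arrangement: tandem duplication of an existing microRNA,
de novo birth of a new hairpin inside an existing microRNA transcript, and
relocation of previously unlinked microRNAs into proximity (fusion, whether
"put together" by selection or "left together" by genome rearrangement).
`mircluster` implements the comparative procedure that distinguishes these
mechanisms for each cluster of a reference species, and a simulator that
generates repertoires with known history to measure how well the procedure
recovers the truth.

## Cluster definition

A cluster is a maximal set of ≥ 2 precursors on one chromosome and strand in
which consecutive members are separated by **less than** `max_gap`
nucleotides (default 10 000). Numerical conventions, chosen once:

* **Gap convention.** The inter-precursor distance is the nearest-edge gap,
  `start(downstream) − end(upstream) − 1` — the number of intervening
  nucleotides. An alternative (midpoint or start-to-start) convention is not
  used: "distance between two microRNAs" most naturally measures intervening
  sequence, and on real annotations adjacent hairpins then sit ~10² nt apart,
  the scale reported for clustered microRNAs. The choice only matters within
  ~100 nt of the threshold.
* **Strict inequality** at the threshold (`gap < max_gap`, not `≤`).
* **Overlapping precursors** on the same strand count as gap 0 (sense-nested
  hairpins are one transcriptional unit for our purposes).
* Loci on different chromosomes, strands, or species are **incomparable**
  (`NA`), never "infinitely distant", so distance statistics cannot mix them.
* Chaining uses the running maximum of member ends, which equals the
  transitive closure over all pairwise gaps (verified against a brute-force
  closure oracle in the tests) and is robust to nested intervals.

Coordinates are GFF3 1-based inclusive throughout; only the BED6 export
converts to 0-based half-open.

## Co-expression versus distance

Co-expression of neighbouring precursors is the Pearson correlation of raw
("absolute") read counts across tissues/stages. No normalisation or
transformation is applied by default (`log1p` is available behind a flag);
the quantity of interest is the co-production of mature products from a
shared transcript, which raw counts capture directly. Pairs are consecutive
same-strand loci (an all-pairs mode exists behind a flag), each pair falls
in exactly one distance bin, and a pair whose count vector has zero variance
is *excluded* as undefined, not imputed as 0. Bin edges are configurable
(default 0, 1 kb, 10 kb, 100 kb, open-ended).

## Ages: Dollo parsimony

A microRNA family is assumed to be gained once and lost freely (Dollo). The
origin of a microRNA is then the MRCA of the species in which it is present,
which is also the single-gain placement minimising losses (the tests verify
this against an exhaustive search over all gain placements). Ages are
compared by node depth: a node nearer the root is older. Leaves double as
terminal lineages; the fixture aliases the *D. melanogaster* leaf to the
lineage name "Melanogaster" so a microRNA found in no other species has age
Melanogaster.

**Families versus ortholog groups.** Two labels attach to each locus:
`annotation_family` (database-style grouping, used for composition
statistics) and `phylo_family` (phylogeny-informed grouping, used by the
classifier; it may merge annotation families, e.g. mir-996 into mir-279).
Ages, however, are per microRNA, not per family: a young tandem copy of an
ancient microRNA is young. The homology map therefore carries an optional
`ortholog_group` label (defaulting to `phylo_family`) that identifies
orthologous copies across species at sub-family resolution; age inference
uses the group, duplication/fusion logic uses the family. The simulator
emits exact groups (orthologs share a locus id by descent). Without this
distinction, a later duplication of the older founder would masquerade as a
cluster's founding event.

## Classifying a cluster's founding event

Members are ranked by age, with deterministic tie-breaking by (age, start
coordinate, identifier) so the call is invariant to member order. The two
oldest members are the candidate founders. In order:

1. Founders of the same `phylo_family` → **DUPLICATION**. The cluster's
   origin lineage is the younger founder's origin (the time of the
   cluster-forming copy). If the family also has single-copy homologs in
   species that diverged *before* that origin, the call is annotated with a
   warning — a de novo origin masked by later loss of the partner (the
   mir-2/mir-71 pattern) cannot then be excluded — but the call itself is
   unchanged.
2. Otherwise, the **fusion** test: the founders must be found "apart" in a
   species that diverged at or before the putative origin, and no equally
   old species may show them together. "Together" means cluster
   co-membership — chained through intermediate members of any family — not
   direct pairwise distance, because the two founders of a long cluster can
   legitimately sit > 10 kb apart at its ends. Requiring the unlinked
   configuration in an *old* species prevents a lineage-specific
   translocation away from an ancestral cluster from masquerading as fusion
   evidence. If the test passes → **FUSION** (no distinction is attempted
   between "put together" and "left together").
3. Founders of different families but equal age → **UNKNOWN**: the founding
   event cannot be ordered from presence/absence data.
4. Otherwise → **NEW_HAIRPIN**: the younger founder was born de novo inside
   the older founder's transcript; `original_mirna` records the older
   founder, and the cluster's origin lineage is the younger founder's
   origin.

When more than two members tie as oldest, DUPLICATION takes precedence if
any two of them share a family; otherwise the call is UNKNOWN. This matches
the treatment of clusters consisting of several equally old mir-2-family
copies (duplication) versus equally old members of distinct families
(unknown).

For microRNA pairs clustered in another species but not in the reference,
`classify_cross_species_pair()` distinguishes: independent local duplication
(same family, extra copies restricted to the clade where clustering is
seen), independent new hairpin (a strictly younger partner family that
originated inside that clade), linked-beyond-threshold (both present on one
chromosome arm in the reference, just beyond the distance cut-off), and
cluster split (ancestrally clustered, genuinely unlinked in the reference).
The strict-youth requirement is what routes ancient equal-age pairs (the
mir-1/mir-133 pattern) to linked-beyond-threshold rather than new-hairpin.

## The simulator's stated world

`simulate_mirna_evolution()` evolves a repertoire of loci along each branch
of a species tree by Gillespie sampling over six event types. Rates are per
unit branch length (branch lengths are arbitrary time units):

| parameter | default | units |
|---|---|---|
| `rate_new_hairpin_in_transcript` | 0.15 | per transcript |
| `rate_intergenic_birth` | 0.05 | per genome |
| `rate_tandem_duplication` | 0.08 | per locus |
| `rate_loss_mirna` | 0.05 | per **singleton** locus |
| `rate_loss_cluster` | 0.01 | per cluster |
| `rate_translocation` | 0 | per locus |
| `tandem_offset` | 50–500 nt | copy-to-template gap |
| `birth_offset` | 50–2000 nt | child-to-parent gap |
| `n_root_loci` | 25 | seed repertoire |
| `rho` | 0.9 | within-cluster expression correlation |

No empirical event rates exist for these processes; the defaults are chosen
for signal separation in recovery experiments (enough events of each kind on
a 7-species tree of depth 1) and are configuration, not biological claims.
Choices a user should know about:

* The **root repertoire** is placed ≥ 5 × `max_gap` apart, so the ancestral
  state contains no clusters and every extant cluster has a founding event
  in the log.
* A **new hairpin** is born on its parent's strand within `birth_offset`
  (< `max_gap`, so it is born clustered) and founds a globally new family; a
  **tandem copy** keeps its template's family. Overlap with existing loci is
  resolved by shifting downstream.
* **Losses**: individual loss applies to singletons; clustered loci die only
  with their whole cluster. This encodes the observation that clusters
  either stay together or are lost as units, and it is what generates the
  rising fraction of clustered microRNAs with age; applying individual loss
  inside clusters would invert that pattern.
* **Coordinate drift** between speciations jitters inter-locus gaps
  multiplicatively (×0.85–1.18) but clamps each gap on its own side of
  `max_gap`, so linkage classes are preserved exactly while coordinates
  diverge between species.
* **Random streams** are keyed by `(seed, branch, purpose)`, so a fixed seed
  gives byte-identical outputs and subtree results do not depend on event
  draws elsewhere. Replaying the event log (recorded coordinates, re-derived
  drift streams) reproduces the extant genomes exactly, which is asserted on
  every simulation in the tests.
* **Homology is exact by default** (orthologs share ids); a per-species
  false-negative rate can emulate homology-detection misses.

`generate_expression()` draws, per cluster, a latent log-normal per-sample
profile; a member's expected count is `rho × cluster profile + (1 − rho) ×
own profile`, observed counts are negative-binomial (`size = 1/dispersion`;
Poisson at dispersion 0). With `rho = 1` and small dispersion within-cluster
correlations approach 1; with `rho = 0` members are independent.

**What the generator does not emulate:** sequence evolution (no nucleotides
are generated — homology is an input, not inferred), expression-level
normalisation artefacts, annotation incompleteness of young microRNAs,
population-genetic dynamics (the linkage-interference model of cluster
maintenance is outside scope), and gene conversion between paralogs. A green
recovery test therefore establishes that the *decision procedure* is sound
when homology and ages are knowable — not that real homology searches are
error-free.

## Ground truth in recovery experiments

The true founding event of an *extant* cluster is defined as the creation
event of its second-oldest surviving member — the event that made the
observable group a cluster. If the original founder was lost and a tandem
copy now forms the oldest pair, the truth is DUPLICATION; this mirrors the
masking phenomenon the classifier is also subject to, so classifier and
truth are compared on the same observable configuration. Intergenic births
that happen to land within `max_gap` of an existing locus count as new
hairpins (from the genome's point of view they are). Two births on the same
branch produce equal-age founders that no presence/absence method can order;
such clusters are classified UNKNOWN by construction, an identifiability
limit rather than a defect.

## The packaged fixture

The 21-record *D. melanogaster* cluster fixture ships members in genomic
order, their recorded founding source and origin lineage, and dual family
labels. Its genomic coordinates and its cross-species presence/absence are
**synthetic**: homologs are placed co-located in every species of each
member's age clade on a 7-species tree (dme, dsi, dps, aga, tca, lgi, hsa
with lineages Melanogaster ⊂ Drosophila ⊂ Diptera ⊂ Insects ⊂ Protostomes ⊂
Metazoans), constructed so that Dollo inference reproduces each member's
recorded age and the classifier reproduces each cluster's recorded source.
The fixture validates the pipeline's logic; it is not a genome annotation,
and reproducing the recorded tallies (13 new hairpin, 6 duplication, 2
unknown, 0 fusion; 4 single-family clusters) from it establishes internal
consistency, not an independent re-measurement.

One record ("310/311/312/313/2498/991/992") is noted as probably two
clusters but kept as one record, matching the 21-row source of truth; the
"6-3…309" record encodes the conservative insect age although the cluster
may be older; "100/let-7/125" encodes distinct phylogenetic families of
equal age (the recorded paralogy of mir-100 and mir-125 is carried as a note
only), which yields UNKNOWN.

## Known limitations

* Ages are bounded by the species sampled: a microRNA present only in one
  leaf is "leaf-aged" even if it is older and merely unobserved elsewhere.
* New-hairpin counts are a lower bound: later loss can convert a de novo
  founding into an apparent duplication (flagged, not corrected).
* The 10 kb rule is a proxy for co-transcription; no promoter or
  transcription-unit inference is attempted.
* The CLI's `classify` subcommand requires the homology TSV to cover every
  clustered reference locus; partial homology is an error, not a guess.
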