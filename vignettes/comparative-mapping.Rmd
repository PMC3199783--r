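---
title: "Comparative genetic mapping and synteny inference with synmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genetic mapping and synteny inference with synmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
```

## The problem

Cucumber (2n = 14) and melon (2n = 24) are congeneric cucurbits whose
genomes are believed to differ mainly by chromosome fusion: the seven
cucumber chromosomes would derive from a twelve-chromosome ancestor
resembling melon. Because the two species cannot be crossed, the
syntenic relationships between their chromosomes have to be inferred
indirectly: cross-species SSR markers are mapped genetically in melon
populations, the same primer pairs are located on cucumber draft-genome
scaffolds by in silico PCR, and the scaffolds are tied to cucumber
chromosomes through previously mapped markers. A melon map position plus
a scaffold plus a scaffold-to-chromosome assignment yields, transitively,
a melon-to-cucumber chromosome correspondence, and runs of neighbouring
melon loci pointing at the same cucumber chromosome form syntenic
blocks.

`synmapr` implements that entire chain as tested, tibble-first R code:
segregation screening, two-point linkage estimation for F2 and selfed
RIL populations, LOD grouping and marker ordering, consensus-map
merging with a heterogeneity filter, virtual PCR, transitive chromosome
assignment, block detection with a colinearity statistic, and a
ground-truthed simulator of fused, rearranged genomes that stands in for
real data whose marker tables are not publicly deposited.

## Linkage model

Two-point recombination fractions are estimated per marker pair.

* **F2 (codominant).** The 3x3 joint genotype table is a multinomial
  whose class probabilities follow from random union of two independent
  meioses with recombination fraction $r$; the double heterozygote is a
  phase mixture with probability $((1-r)^2 + r^2)/2$. The MLE is found
  by EM: the E-step resolves the double-heterozygote ambiguity
  (expected recombinant gametes $2r^2/((1-r)^2+r^2)$), the M-step
  divides expected recombinant gametes by total gametes. The estimate is
  clamped to $[0, 0.5]$ and the test suite verifies it against a
  grid-search maximiser of the likelihood and checks the EM monotonicity
  property.
* **Selfed RIL (F8).** Heterozygous calls are treated as missing, the
  observed recombinant fraction $R$ among A/B-typed line pairs is
  corrected to the meiotic scale with the Haldane-Waddington relation
  $r = R/(2 - 2R)$, treating F8 lines as fully inbred. The residual F8
  heterozygosity is $(1/2)^7 \approx 0.0078$ per locus; dropping those
  calls biases $r$ far less than the sampling error at $n = 80$.

`LOD = \log_{10} L(\hat r) - \log_{10} L(0.5)`, floored at zero. Linkage
groups are single-linkage connected components of the graph with edges
where LOD $\ge$ 4.0 and $\hat r < 0.5$; pairs typed in fewer than 10
common individuals are excluded. Marker order within a group minimises
the sum of adjacent recombination fractions (greedy insertion plus
window-2/3 reversal passes, orientation normalised to the
lexicographically smaller terminal), and cumulative positions use the
Kosambi function $d = 25\,\ln((1+2r)/(1-2r))$ cM.

### Guarding single linkage against spurious edges

With ~300 markers a population yields ~45,000 marker pairs; at a LOD 4.0
cutoff the expected number of spurious significant pairs between
unlinked chromosomes is a substantial fraction of one *per run*, and a
single such edge chains two chromosomes irrecoverably. Mapping packages
handle this with multiple rounds of grouping and manual curation; we use
two deterministic safeguards:

1. **Bridge removal.** An edge that is the only connection between two
   parts of a group, with at least 2 markers on each side and
   $\hat r \ge 0.10$, is removed (graph bridges are found with igraph).
   Genuine neighbours in a dense map are supported by many parallel
   edges; a spurious join by exactly one. The thresholds are
   deliberately aggressive because the failure modes are asymmetric:
   cutting a real group merely fragments a chromosome into co-labelled
   pieces, while a false join corrupts the map. The RIL case dictates
   $\hat r \ge 0.10$: the Haldane-Waddington correction compresses a
   spurious edge's estimate to roughly 0.18 at $n = 80$.
2. **Gap splitting.** After ordering, a group is cut wherever adjacent
   loci show $\hat r \ge 0.30$ (~35 cM Kosambi), an adjacency dense maps
   do not produce genuinely.

Linkage groups are then labelled with chromosome names by majority vote
over a small set of label anchors (the role played in practice by
previously published maps of the species); groups that receive no label
are excluded from synteny inference, and co-labelled fragments are
reported under one chromosome (suffixed `a`, `b`, ... on the map, pooled
in the correspondence table).

## Consensus map

The F2 and RIL maps are merged keeping the F2 order fixed. Shared
markers are anchor candidates; each adjacent shared pair is first tested
for between-population heterogeneity of the recombination fraction with
the likelihood-ratio statistic
$G = 2[\ln L_1(\hat r_1) + \ln L_2(\hat r_2) - \ln L_1(\hat r_p) -
\ln L_2(\hat r_p)]$ against $\chi^2_1$ (the RIL likelihood is expressed
in meiotic $r$ through $R = 2r/(1+2r)$ so the two populations pool
coherently); pairs with $P < 0.05$ are excluded from anchoring. The test
suite confirms the type-I error is 0.05 &plusmn; 0.02 under the null at
1,000 replicates. RIL-only loci are placed by piecewise-linear
interpolation between flanking anchors rescaled into the F2 frame
(terminal segments extrapolate at their own scale); anchors whose
second-map order conflicts with the reference (outside the longest
order-concordant subsequence) are demoted. Because the anchor frame maps
each anchor exactly onto its reference position, the merge is
order-preserving by construction, which the tests quantify as Kendall
tau = 1 between reference and consensus over shared loci.

## Virtual PCR and anchoring

Primer pairs are located on scaffolds by IUPAC-aware scanning
(Biostrings) with at most 1 mismatch per primer, none within the 3
terminal 3' bases, and a product window of 40-5,000 bp; all four
settings are exposed because published in silico PCR implementations do
not agree on them, so exact replication of any particular tool's hit
counts is not claimed. Hits are reported 1-based inclusive on the
forward strand; interval overlap against a repeat annotation is computed
half-open internally. A marker is `unique`, `multi_copy`, `no_hit`, or
`repeat_region` (a unique hit inside an annotated repeat). Gene and EST
markers without primers anchor by gapless seed-and-extend (31-mer exact
seeds, best location by identity x coverage, thresholds 0.9 and 0.5);
this is sufficient at the ~90% cross-genome identity of conserved
cucurbit regions and deliberately avoids reimplementing a full local
aligner.

Chromosome assignment is direct for markers already on the target
reference map; otherwise the marker inherits the chromosome carried by
at least 2/3 of its scaffold's reference markers, at their median cM
(median rather than mean because recombination suppression clusters
markers and a single stray locus should not drag the position).
Scaffolds failing the majority rule are reported `ambiguous`, scaffolds
without mapped markers leave the query `unanchored`.

## Blocks, colinearity, correspondence

Along each source chromosome in map order, maximal runs of loci sharing
a target chromosome become blocks; one interleaved discordant locus per
block is absorbed (noted, not counted as a member), runs below 2 members
are reported as singletons and never support a correspondence. The
greedy segmentation is verified exhaustively against an
interval-enumeration oracle on all target strings up to length 8.
Colinearity is Kendall's tau (tie-corrected) between source and target
positions: `colinear` at tau &ge; 0.8, `inverted` at tau &le; -0.8,
`rearranged` between, `undetermined` below 3 placed members. The 0.8
cutoff is this package's operationalisation of "colinearity broken",
not a published constant. The correspondence table lists, per chromosome
of either genome, the partner chromosomes supported by at least one
block; both views derive from one block list, so the relation is
symmetric by construction. Block *views* additionally re-segment along
the target genome (walking the fused chromosome itself), which is what
makes a nested fusion visible as an A-B-A segment stack.

## The synthetic study

`simulate_study()` generates every input under one seed. Its defaults
are the study conditions the package is calibrated to, not tuning knobs:

| quantity | default | rationale |
|---|---|---|
| source genome | 12 chromosomes, 401 loci, 1,028.9 cM | consensus-map scale (per-chromosome lengths and locus counts of the published summary table) |
| fusion pattern | C1=II+XII alternating, C2=V+XI(1st half)+III(1st half), C3=IV+VI side-by-side, C4=VII with VIII(1st half) nested, C5=IX+X alternating, C6=III+XI+VIII (2nd halves), C7=I intact + one inversion | the published 12-to-7 correspondence, including the chromosomes that split across two fusion products |
| populations | F2 n=91, RIL n=80 (F8, 7 selfing meioses) | the two mapping populations' sizes |
| polymorphism rates | 0.80 (F2), 0.65 (RIL) | produce marker panels and a shared-anchor count in the published proportions (~324 and ~259 mapped loci, ~200 shared) |
| crossover model | Haldane (no interference) | matches the estimation-side choice of estimating with Kosambi while simulating without interference; the resulting map-length bias is documented and only rf, order and block recovery are asserted |
| missing data | 2% uniform | typical silver-stained SSR gel scoring |
| marker cassette | 20-24 nt unique primers, 160 bp insert, 300 bp spacer | products ~200 bp, inside the virtual-PCR window |
| scaffolds | lognormal, median ~1.5 kb (2-4 marker cassettes) | matches the multiplicity of mapped markers per draft scaffold (a few), which sets the positional resolution of transitive anchoring |
| reference map | 20% of panel markers mapped directly + 3 target-only markers per scaffold | the two anchoring routes (direct and scaffold-transitive) both exercised |

Because marker cassettes are densely packed (~500 bp per locus instead
of hundreds of kb), the simulated genome is physically miniature; that
is intentional, since anchoring logic, not assembly scale, is under
test. Scaffold N-gaps and sequence evolution along branches are not
simulated: a passing end-to-end run shows the *inference chain* is
correct under Mendelian segregation and exact planted primers, not that
real cross-species amplification rates or draft-assembly artefacts are
reproduced. The corruption module (`corrupt()`) adds the realistic
failure classes - deleted primer sites, duplicated amplicons, relocated
markers - with truth labels retained, and the test suite checks
graceful degradation (11 of 12 chromosome partner sets still recovered
at 5% mis-anchoring).

```{r quick-look, eval = FALSE}
study <- simulate_study(seed = 1)
run <- run_pipeline(study)
dplyr::select(run$correspondence, view, chromosome, partners_label)
autoplot(run$views, view = "target")
```

## Numerical choices

* EM starts at $r_0 = 0.25$, stops at $|\Delta r| < 10^{-9}$ or 200
  iterations; estimates below $10^{-8}$ are reported as exactly 0.
* Likelihood evaluations clamp $r$ (and the RIL observed scale) to
  $[10^{-12}, \cdot]$ so boundary estimates never produce `-Inf` - `-Inf`.
* The pooled heterogeneity MLE uses golden-section search plus explicit
  evaluation of both per-population MLEs, since the boundary $r = 0$ is
  never visited by the search itself.
* Group numbering, fragment numbering and orientation are all
  deterministic (size-descending, ties by smallest member id;
  lexicographically smaller terminal first), so maps are invariant
  under input shuffling.
* Percentages are rounded half-up to one decimal. One published
  percentage (45.9% for 1,123/2,442) is not reproducible under any
  rounding convention (the quotient is 45.98) and is excluded from
  checks; all other printed percentages reproduce exactly.
* Adjacent recombination fractions are capped at 0.49 when converting to
  Kosambi distances so a weakly joined adjacency widens the map instead
  of aborting the group.

## Problem sizes in the test suite

The unit tests run reduced scales chosen for statistical adequacy:
oracle comparisons use 20-individual tables (100 random instances),
brute-force virtual-PCR checks use 100 random 50 kb scaffolds, the
segmentation oracle is exhaustive to length 8, and the end-to-end
recovery test runs the full default study (401 loci, n = 91/80) once.
Reduced-scale studies (10 loci per chromosome, n = 60) cover the
orchestration paths.

## Known limitations

* Ordering is two-point SARF, not multipoint likelihood; at n &approx; 90
  local flips of markers under ~1 cM apart are expected and tolerated by
  the block detector's gap absorption, but fine-scale order inside
  blocks should not be over-interpreted.
* The consensus merge places second-map loci by interpolation; it cannot
  reveal order conflicts *between* anchors (those loci inherit the
  reference frame by construction).
* Transitive anchoring quantises target positions to scaffold medians;
  colinearity statistics within short blocks therefore understate |tau|
  when scaffolds are large relative to block span.
* Dominant markers (RAPD/AFLP) are out of scope throughout, as is
  interference-aware likelihood modelling and any sequence-level
  microsynteny.
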