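---
title: "Methods: checklist synthesis and assemblage analysis for regional polypore data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: checklist synthesis and assemblage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyporeR implements the analytical core of a regional polypore
(wood-fungus) checklist synthesis: occurrence-record validation and
recoding, nonparametric richness estimation, checklist reconciliation and
turnover accounting, rule-based substrate-association classification, and
assemblage analysis with ordination, permutation tests and host
clustering. This vignette explains the models and rules, the parameters
that matter, the numerical choices, and what the synthetic test bed does —
and does not — demonstrate about real data.

## The data model

One record is one observation of basidiomes of one species on one
substrate unit. Beyond species, source dataset and year, a record may
carry a plot, the stand descriptors (site-type group as a proxy of soil
nutrient and moisture regime; tree-species composition in three classes
*Picea*/*Pinus*/deciduous; stand age as old (>100 yr)/other/
early-successional), the host taxon, the woody fraction, and a five-class
decay stage. Ingestion (`read_records()`) is strict: every row is either
validated or rejected with a row number and reason; unknown vocabulary
tokens are never coerced. Aggregate host taxa (*Betula* spp., *Salix*
spp., *Ulmus* spp., *Alnus* split into species) follow the granularity
regional host tables typically use; the host vocabulary is
config-supplied because datasets mix genus- and species-level
determinations.

Three recoding rules map field annotations onto analysis categories:

* **Decay**: stages I–II → `early`, III → `medium`, IV–V → `late`
  (`recode_decay()`); free-text "extremely decayed" annotations map to
  `late`. Missing stages propagate as missing, never guessed.
* **Woody fraction** (`classify_substrate_fraction()`): live trees are
  their own class; any dead item under 10 cm diameter at the basidiome
  location is fine woody debris whether fallen or standing; at or above
  10 cm, standing stems and stumps are snags/stumps and the rest coarse
  fallen wood. Because the FWD definition is strictly "under 10 cm", the
  boundary value 10 cm goes to the coarse classes.
* **Habitat keys** (`habitat_key()`): a habitat type is the triple
  site-type group × tree class × age class, or a single pooled label for
  special habitats (parks, wooded meadows, bog forests, heath forests)
  that are represented by one species list rather than plots. A record
  carrying both forms, or an incomplete triple, is an error rather than a
  silent guess. Early-successional keys are flagged so assemblage
  analyses can exclude post-clear-cut stands.

Counts exported in report tables are censored above a configurable
threshold (default 100) as `">100"`; censoring is strictly above the
threshold, so a count of exactly 100 prints as `100`. All percentage
rules operate on raw counts before banding.

## Richness and checklist accounting

`chao1()` implements the classic estimator
$\hat S = S_{obs} + f_1^2/(2 f_2)$ with the usual bias-corrected fallback
$S_{obs} + f_1(f_1-1)/2$ when no doubletons exist, and the bias-corrected
variant $S_{obs} + f_1(f_1-1)/(2(f_2+1))$. The classic form is the
default because it is the form under which the published worked example
(221 species, 17 singletons, 6 doubletons → 245) reproduces exactly; the
bias-corrected variant gives 240.4 on the same tallies. Raw values are
returned; rounding happens only in reports.

`apply_ledger()` reconciles a historical checklist: merges and exclusions
remove names, additions and splits add them, and the accepted count obeys
the conservation identity. One design tension deserves note: the
contracts "an entry referencing an unknown name is an error" and
"re-applying an applied ledger changes nothing" cannot both hold, because
re-application necessarily references already-removed names. The default
(`strict = TRUE`) errors, which catches typos at first application;
`strict = FALSE` turns inapplicable removals and re-additions into logged
no-ops, under which application is idempotent (property-tested).

The Regionally-Extinct rule flags species whose last record is *more
than* `horizon` (default 50) calendar years before the reference year —
a strict inequality, so a gap of exactly 50 years is not flagged.
`turnover()` uses the symmetric denominator
$100\,(|L|+|G|)/(2 S_{ref})$, i.e. the average of the loss and gain
rates against the old-list size. Published turnover figures rarely state
their denominator, so the report retains the raw loss/gain lists and any
alternative formula can be recomputed from them.

## Substrate associations

`build_association_table()` cross-tabulates species × category for one
axis (host, fraction, decay class). Records lacking the axis annotation
are excluded from the cells but kept in the per-species totals: the
classification thresholds refer to a species' total regional record
count, not to the annotated subset. The regular/specialist rules are a
plain disjunction/conjunction of count and share thresholds (see
`classify_regular()`, `classify_specialist()`); the reporting order
a → b → c is a convention for naming *which* rule fired, not a
precedence — the boolean is an OR. Two consequences are intentional and
left as the rules imply:

* a species with 8 of 9 records on one category (88.9 %) fails both
  specialist clauses, although 9 of 10 (90 %) would pass;
* rule (b) makes the classification scale-dependent only in the
  small-total regime (totals under 40 records); the ratio rules (a, c)
  are scale-invariant, which the suite verifies by multiplying tables by
  10.

Host-range classes (1–2, 3–7, ≥8 host species) are computed only for
species recorded strictly more than 10 times. Host clustering uses
presence/absence restricted to *regular* host–species pairs (≥5 % of the
species' or the host's records), because raw presence/absence
over-weights incidental substrates; the matrix feeds Bray-Curtis + UPGMA.

## Assemblage engine

**0/1/2 recode.** Per-habitat record counts are recoded 0 (absent),
1 (one record), 2 (more than one) — a compromise between raw counts,
which inherit survey-effort bias, and presence/absence, which
over-emphasises rare species. Censored banded counts recode to 2.
Species known from a single habitat type are removed before ordination
and testing; they carry no information about assemblage differences.

**Bray-Curtis** is delegated to `vegan::vegdist()` behind
`bray_curtis()`, which adds the validation the pipeline needs (negative
entries, all-zero samples named in the error) and is property-tested
against a naive double loop.

**NMDS** (`nmds()`) is implemented in the package. For a candidate
configuration the disparities $\hat d$ are the weighted
pool-adjacent-violators fit (`pava_monotone()`, also exported) of the
configuration distances ordered by the input dissimilarities, and the
loss is Kruskal's stress-1 $\sqrt{\sum(d-\hat d)^2 / \sum d^2}$. Each
start is minimised by steepest descent on the analytic gradient with a
backtracking line search that only ever accepts improvements, so the
stress sequence within a start is non-increasing by construction — a
property the suite asserts against the metric start. Ties in the
dissimilarities follow Kruskal's primary approach (tied dissimilarities
may receive unequal disparities): the pair order is re-resolved by the
current distances at every iteration. Defaults: `k = 2`, 20 random
starts plus one metric (classical-scaling) start, `max_iter = 300`,
relative tolerance `1e-7`. The final configuration is centred, rotated
to principal axes (axis 1 carries maximal site-score variance), and
sign-fixed deterministically. With a fixed seed the whole procedure is
reproducible; non-convergence is a warning, not an error.

**MRPP** (`mrpp()`) computes the weighted mean within-group
dissimilarity $\delta = \sum_g w_g \bar d_g$ with weights proportional
to group size $n_g$ by default ($n_g-1$ and pair-count variants are
available; published analyses rarely state the scheme, and the
$n_g$-proportional weighting matches the common default of the ecology
packages). The null distribution is exhaustive — all distinct
relabelings, enumerated — whenever their number is at most 10,000, in
which case the p-value is the exact fraction of relabelings (the
observed one included) with $\delta \le \delta_{obs}$. Otherwise B
random relabelings are drawn and the add-one estimator
$(1+\#\{\delta^* \le \delta_{obs}\})/(B+1)$ avoids $p = 0$. The
chance-corrected agreement is $A = 1 - \delta_{obs}/E[\delta]$.
Bonferroni adjustment is `min(1, m p)`.

**UPGMA** (`upgma()`) wraps `stats::hclust(method = "average")` — the
size-weighted average-linkage agglomeration — behind a dendrogram class
with cophenetic access, `cutree` passthrough and Newick export via ape.
Exported branch lengths are halved by default so leaf-to-leaf path
lengths equal merge heights; `halve = FALSE` instead makes root depth
equal the root merge height. The suite checks hand-traced 3-, 4- and
5-leaf merges, the ultrametric inequality on random inputs, and the
fixed-point property (an ultrametric input is returned exactly).

**Overlap counts** (`overlap_counts()`) compute, for a combination of
habitat types, the species present in every member and the subset found
nowhere else — the two numbers an area-proportional overlap diagram
displays. Diagram *layout* is out of scope; only the counts are
computed.

## The synthetic generator

`sample_species_pool()` + `simulate_survey()` emulate the structure the
analyses assume, with every construction recorded as ground truth:

* **Abundances** follow a log-series distribution (probability
  $\propto \theta^n/n$, truncated at $n = 2\times10^4$). The default
  $\theta = 0.99999$ was calibrated once so that roughly 5–10 % of the
  200-species pool appears as singletons at default survey effort,
  matching the strongly right-skewed frequency structure regional
  fungal datasets show (tens of thousands of records yet many species
  recorded once or twice).
* **Habitat structure.** Each species draws a log-normal preference per
  *site-type group* (sd `habitat_sd`, default 0.75) and a
  tree-composition multiplier (`tree_affinity`, default 3) applied when
  a stand's tree class matches the species' host block. Assemblages are
  therefore organised along soil and tree-composition gradients — the
  two gradients such surveys recover — while stand age carries no
  constructed signal. Setting `habitat_sd = 0, tree_affinity = 1`
  yields exchangeable, structureless assemblages; the type-I
  calibration of MRPP runs under exactly those conditions.
* **Hosts.** Hosts belong to three phylogenetic blocks (conifers,
  soft-wooded deciduous, hardwoods); a species prefers its block's
  hosts, with weak cross-block use (`cross_block_weight = 0.08`) and
  mild log-normal within-block variation.
* **Specialists.** `round(S × specialist_fraction)` species
  (default fraction 0.15) are constructed as specialists, alternating
  host- and habitat-type. A constructed host specialist places 0.995 of
  its preference mass on one focal host: a "specialist" is by
  definition near-exclusive, and anything much looser would leave
  3–9-record species failing the all-records clause through a single
  stray record — a property of the classifier, not of the generator.
* **Survey protocol.** Per plot, species are drawn in a seeded random
  order proportional to abundance × habitat affinity; the first 10
  records per species and 150 per plot are kept, mirroring a
  fixed-effort protocol that describes only the first ten substrates of
  each species. The casual stream (expected 500 records) additionally
  weights species by a detectability multiplier in (0.2, 1]; no
  quantitative detectability estimates exist for such streams, so this
  is a free parameter, not an estimate.

Simplifications to keep in mind when reading test results: substrate and
decay assignment are independent of habitat given the species; plots are
spatially independent; there are no temporal dynamics; casual records
draw their stand descriptors from the species' affinities rather than
from a collector model. Passing recovery tests therefore show the
*machinery* is correct under the stated data-generating process — they do
not show that real fungarium data satisfy that process.

## What the test suite establishes

The suite (testthat, all fixtures generated in code) covers each module's
contracts plus statistical properties at deliberately modest problem
sizes, chosen so the whole suite runs in well under a minute of engine
time per property:

* exhaustive-vs-Monte-Carlo agreement of MRPP on a 6-sample design (all
  20 relabelings);
* type-I error of MRPP at α = 0.05 within [0.03, 0.07] over 500
  structureless simulations of 12 assemblages in two groups of six —
  a design whose 924-relabeling null makes the nominal level attainable
  (attainable size 46/924 ≈ 0.0498) despite permutation discreteness;
* NMDS recovery of a one-dimensional gradient (20 habitats × 60 species,
  Gaussian response curves): axis-1 Spearman |ρ| ≥ 0.95 in at least 9 of
  10 seeds;
* UPGMA hand-traces, the ultrametric inequality on 100 random matrices,
  and the fixed-point property;
* the specialist ⇒ regular implication over the exhaustive grid
  `n_cat ≤ n_total ≤ 60`;
* recovery of the constructed host blocks (Rand index vs. truth,
  averaged over 20 seeds) and of constructed host specialists
  (sensitivity over 20 seeds, among truth specialists with ≥3 simulated
  records — species with fewer records are structurally unclassifiable
  because the rule itself requires more than two);
* bit-identical reproducibility of the full pipeline on the packaged
  demo config.

PAVA is verified against an exact brute-force oracle (enumeration of all
ordered level-set partitions for short inputs) and `stats::isoreg`;
Bray-Curtis against a naive double loop; Chao1 against an independent
implementation; NMDS and MRPP against vegan's optimiser and
permutation test as independent cross-checks — never as the
implementation.

## Known limitations

* NMDS uses steepest descent with line search; it is robust but not the
  fastest optimiser, and with few starts on difficult inputs it can
  return a local minimum (increase `n_starts`).
* The exhaustive MRPP enumerator materialises the relabeling matrix; the
  10,000-relabeling default cap keeps memory trivial, but do not raise
  it by orders of magnitude.
* The ledger model is linear: it does not resolve chains (A merged into
  B, B later excluded) beyond the order the entries are written in.
* Classification thresholds (5 %, 40, 90 %, 3–9, >10 records) are the
  field's published conventions, exposed as defaults rather than
  hard-coded, but no inferential uncertainty is attached to the
  resulting classes — they are descriptive.
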