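---
title: "Tree-based constraint-aware redescription mining on two-view data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based constraint-aware redescription mining on two-view data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusrm)
```

## The problem

Biomedical cohorts are often described by two disjoint attribute sets over
the same subjects — for instance a *clinical* view (cognitive test scores,
symptom indicators) and a *biological* view (blood measurements, imaging
markers). A **redescription** is a pair of queries, one per view, that
describe (nearly) the same subject subset. Finding such pairs surfaces
cross-view associations: "the patients with these clinical scores are the
patients with these biomarker levels." `clusrm` implements a tree-based
miner for conjunctive redescriptions on such data, including data with
missing values, with user-defined attribute constraints, and with post-hoc
analytics on the mined set.

## Queries, support semantics and accuracy

A query is a conjunction of single-attribute conditions: a closed numeric
interval `a <= x <= b` or a categorical value set (`x = c` when singleton).
With missing values a query is evaluated under three-valued (Kleene)
semantics per instance:

* **in** — every condition holds on observed values, none referenced missing;
* **out** — some condition is definitely violated by an observed value (one
  false conjunct falsifies the conjunction regardless of missing cells);
* **unknown** — no violation, but at least one referenced value is missing.

Crossing the two queries' states splits the instances into nine cells
`E11, E10, E01, E00, E1q, Eq1, E0q, Eq0, Eqq` (`q` = undeterminable). The
accuracy measure is the **query non-missing Jaccard index**

$$ J_{qnm} = \frac{|E_{11}|}{|E_{11}| + |E_{?,1}| + |E_{1,?}| + |E_{0,1}| + |E_{1,0}|} $$

which penalises instances described by one query but unevaluable under the
other, ignores doubly-unevaluable ones, and reduces to the plain Jaccard
index on fully observed data. Significance assumes the two supports are
independently sampled with marginal probabilities $p_i = |supp(q_i)|/n$; the
overlap then follows $\mathrm{Binomial}(n, p_1 p_2)$ and the p-value is the
upper tail $P(X \ge |E_{11}|)$, computed through the stable survival
function (`pbinom(..., lower.tail = FALSE)`, optionally on the log scale) so
that values far below `1e-300` remain representable.

Three conventions worth stating: a 0/0 Jaccard (both supports empty) is
defined as 0 with a warning — such pairs carry no evidence and are filtered
anyway; the p-value is computed on the full instance count $n$, exactly as
the formula reads, not on a non-missing subset; and the support sizes
$|supp(q_i)|$ entering $p_i$ count *definite* members only — membership that
cannot be established from the data is not membership.

## The mining loop

Mining alternates between the views (the CLUS-RM scheme):

1. **Initialisation.** Each view is stacked on an attribute-shuffled copy of
   itself (per attribute, every synthetic cell is copied from a uniformly
   random original row, with replacement). Shuffling preserves every
   marginal but destroys attribute interactions, so a tree separating
   originals (target 1) from copies (target 0) must exploit exactly the
   co-occurrence structure redescriptions are made of.
2. **Trees.** A multi-target predictive clustering tree is grown per view:
   splits maximise the summed variance reduction over all 0/1 target
   columns. Candidate thresholds are midpoints between consecutive distinct
   values; categorical splits are one-vs-rest. Every node of the tree is a
   cluster, and the conjunction of split outcomes on its root path is a
   conjunctive query (single-sided outcomes are canonicalised to closed
   intervals using the attribute's observed range; repeated conditions on
   one attribute intersect).
3. **Alternation.** The membership vectors (unknown counts as 0) of one
   view's rules become the targets for the next tree on the *other* view:
   each view is asked to re-describe the groups the other view found. New
   rules of each view are paired with the previous iteration's rules of the
   opposite view — never with same-iteration rules.
4. **Screening and set optimisation.** Each candidate pair is evaluated into
   a redescription and screened against the quality constraints (minimum
   $J_{qnm}$, maximum p-value, support interval, maximum query length).
   Survivors enter a bounded redescription set (below).
5. **Minimisation.** Finally every retained redescription is greedily
   minimised: a condition is dropped (insertion order, repeated to a fixed
   point) whenever accuracy does not decrease and all quality constraints
   still hold.

### Redescription-set optimisation

The set has fixed capacity (default 100). Each member is scored

$$ sc(R) = \alpha_1\,(1 - J_{qnm}(R)) + \alpha_2\,\mathrm{redScoreInst}(R)
         + \alpha_3\,\mathrm{redScoreAttr}(R) $$

where the redundancy scores are the coverage of $R$'s support (respectively
attribute set) by the *other* members, normalised by the set's total
coverage mass; for a candidate outside the set the numerator uses all
current members and the denominator additionally counts the candidate
itself. Weights default to $1/3$ each. When the set is full, the member with
the highest score difference against the candidate is replaced **iff** that
difference is strictly positive — a replacement must improve the set; ties
resolve to the earliest-inserted member, and a tie at difference zero
discards the candidate, for determinism. Coverage counters are updated on
every change and are exactly recomputable from the members at any time.
Candidates whose query pair already sits in the set are discarded: a
duplicate can only raise redundancy.

### Attribute constraints

A constraint family $C = \{C_1, \dots, C_n\}$ of attribute sets focuses the
search. Three modes:

* **strict** — admissible only if all attributes of some $C_i$ occur in the
  queries (the classical definition);
* **soft** — admissible only if some $C_i$ is partially hit; compliance is
  rewarded by the score;
* **suggested** — everything admissible; compliance only improves the score.

The compliance score is
$\tfrac12 \max_i |attrs(R) \cap C_i|/|C_i| + \tfrac12\,|attrs(R) \cap \bigcup_i C_i|/|attrs(R)|$,
and in constraint modes the total score gains a fourth term
$\alpha_4 (1 - \mathrm{score})$ (default weights $1/4$ each). Inadmissible
candidates (score $-\infty$) never enter the set. Rule pairs are pre-filtered
before evaluation: in strict mode on the pair's *joint* attribute set (the
weaker reading — each pair that could satisfy a $C_i$ is evaluated, and the
strict predicate is enforced on the assembled, minimised redescription); in
soft mode on non-empty intersection. In strict and soft modes minimisation
additionally runs *before* insertion, and a redescription whose minimisation
drops a constrained attribute is discarded: if the key attribute is
support-redundant, the association does not genuinely involve it. Suggested
mode with $\alpha_4 = 0$ is exactly unconstrained mining (a tested
invariant). Instance-level constraints are out of scope of this version; the
specification object keeps a granularity slot for them.

## Numerical and procedural choices

* **Split ties** resolve to the lowest attribute index, then the smallest
  threshold; a split must improve by more than `1e-12` to be accepted. Tree
  growth is fully deterministic given data, targets and parameters.
* **Missing values during induction**: instances missing the split
  attribute are excluded from gain computation and routed to the child with
  more non-missing members (tie: left). This is documented behaviour, not a
  reconstruction of any particular reference implementation.
* **Leaf bound**: the default is *half* the lower bound of the support
  interval (clamped to $[2, n/4]$). Setting it to the support bound itself
  would freeze refinement — a cluster at exactly the minimal admissible
  support could never be split again, and the deterministic alternation
  reaches a fixed point within a few iterations without ever isolating
  finer structure.
* **Initialisation leaves** are smaller still (`min_leaf / 5` by default):
  the alternation is deterministic, so all exploration diversity has to
  come from the initial original-vs-copy trees; small initial leaves yield
  many diverse seed rules. Both bounds are exposed
  (`min_leaf`, `init_min_leaf`).
* **Query minimisation** accepts a removal only when $J_{qnm}$ does not
  decrease *and* the quality constraints still hold, so it can never push a
  member out of the admissible region.
* **Condition language**: the "rest" branch of a one-vs-rest categorical
  split on more than two categories is represented as a value-set condition
  (`x in {a,b}`); equality is its singleton case. Numeric conditions are
  closed intervals; the right branch of `x <= t` is canonicalised to
  `[v, max]` with `v` the smallest observed value above `t`.
* All randomness (the initialisation shuffles, the generator) flows from
  explicit seeds; `mine_redescriptions()` is bit-for-bit reproducible given
  its configuration.

## The synthetic benchmark

`plant_spec()` / `generate_two_view()` emulate the structure of a two-view
clinical–biological cohort: uniform background on $[0, 100]$, a 5-level
ordinal diagnosis-style label (CN / SMC / EMCI / LMCI / AD), per-attribute
missingness, and *planted* cross-view associations: an instance subset whose
values fall in narrow, randomly placed intervals on chosen attributes of
both views. Background values on planted attributes are kept outside the
planted interval, so with no noise and no masking each ground-truth query
describes exactly its subset and an accuracy-1 redescription exists by
construction. Plants are label-homogeneous, so entropy analyses have known
ground truth. Default conditions: $n = 500$, 10 numeric attributes per view,
one plant of 100 instances using 2 attributes per view, interval width 15%
of the range (random overlap of an uninvolved instance with a 2-attribute
box is then ~2%, keeping the binomial p-value discriminative), noise and
missingness 0 unless requested.

What the generator deliberately does **not** emulate: realistic biomarker
distributions or covariance, ordinal clinical scales with few levels, or
structured (non-random) missingness. Passing the recovery tests therefore
shows the machinery works under controlled conditions; it does not certify
performance on real cohort data.

The recovery checks in the test suite run the miner at $n = 500$ with
support interval $[50, 200]$, $J_{qnm} \ge 0.5$, $p \le 0.01$, capacity 100
and 10 alternation iterations — sizes chosen so the whole suite stays
interactive. Masked-data recovery uses a 20% missing rate on one planted
attribute per view, matching how the emulated cohort tables carry
missingness in *some* columns rather than uniformly; masking every column at
20% would push the definite support of the 2+2-attribute ground truth
($100 \cdot 0.8^4 \approx 41$) below any support interval starting at 50,
i.e. outside the regime the constraints describe.

## Post-hoc analytics

* `support_entropy()` — Shannon entropy (base 2, plug-in estimator) of the
  class labels inside a support set, over the classes *present* in the
  support; 0 means the described group is diagnosis-homogeneous.
  `entropy_by_interval()` summarises it per support-size band
  ($[5,10], [11,39], [40,99], \ge 100$ by default).
* `cooccurrence_tables()` — how often each unordered attribute pair occurs
  together in one redescription's queries, tallied separately per view-pair
  class (bio–bio, clin–clin, bio–clin) given an attribute tag map; counts
  add element-wise when sets are merged.
* `pair_correlation()` — correlation of an attribute pair over complete
  observations: each attribute is screened for normality with a one-sample
  Kolmogorov–Smirnov test against a fitted normal ($\alpha = 0.05$);
  Pearson's $r$ is reported when both pass and neither is ordinal, else
  Spearman's $\rho$. The screen estimates its parameters from the same
  sample, which is approximate (anticonservative); the result flags this
  (`screen = "ks-estimated"`). Group-vs-group distribution tests are *not*
  reimplemented: `group_values()` extracts the support and control samples
  and standard routines (`stats::ks.test`, `stats::wilcox.test`, ...) do the
  testing. No multiple-testing correction is applied anywhere; filtering is
  on raw p-values and correction is left to downstream analysis.

## A worked run

```{r example, fig.width = 5, fig.height = 4}
sim <- generate_two_view(plant_spec(
  n = 300, attrs1 = 6, attrs2 = 6,
  plants = list(list(size = 80, k1 = 2, k2 = 2, label = "AD")),
  seed = 42))

cfg <- engine_config(
  max_iter = 5, seed = 42, capacity = 50,
  quality = quality_constraints(min_jaccard = 0.5, max_pvalue = 0.01,
                                support = c(40, 160)))
set <- suppressWarnings(mine_redescriptions(sim$data, cfg))
set

best <- which.max(vapply(set$members, recovery_jaccard, 0,
                         truth_instances = sim$truth[[1]]$instances))
set$members[[best]]
support_entropy(set$members[[best]], sim$data$labels)
plot(set)
```

## Known limitations

* Conjunctive queries only — no disjunction or negation literals.
* Single trees per iteration; no random-forest diversification, no pruning.
* The alternation is deterministic; datasets whose planted structure is
  marginal relative to the quality gates (e.g. accuracy barely above the
  threshold even for the ground truth) may yield empty sets for some seeds.
* Attribute-level constraints only; instance-level constraints are a
  declared extension point.
* The optimiser maintains one set per run; stratifying by support interval
  means running the miner once per interval.
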