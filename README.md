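# clusrm — constraint-based redescription mining on two-view data

`clusrm` finds **redescriptions** in two-view tabular data: pairs of
conjunctive queries, one over each of two disjoint attribute sets (views)
describing the same instances, whose support sets (nearly) coincide. The
motivating use case is biomedical cohort data — a *clinical* view (test
scores, symptoms) and a *biological* view (blood markers, imaging) over the
same subjects — where a redescription such as

```
q_clin: 0 <= GDTOTAL <= 2 & GDALIVE = 0        (204 subjects)
q_bio:  0.5 <= HMT18 <= 16 & -3.86 <= SPARE_AD <= -0.93   (172 subjects)
```

says that two very different measurement modalities isolate essentially the
same group. It is aimed at researchers doing exploratory cross-view
association analysis on mixed-type tables with missing values.

## Method

A redescription `R = (q1, q2)` is scored by

* the **query non-missing Jaccard index**
  `Jqnm = |E11| / (|E11| + |E?1| + |E1?| + |E01| + |E10|)`, where the nine
  cells `E{x,y}` partition the instances by definite/undeterminable
  membership in each query under three-valued logic (a missing referenced
  value makes membership undeterminable; one violated conjunct still makes
  it a definite non-member). On fully observed data `Jqnm` equals the plain
  Jaccard index `|supp(q1) ∩ supp(q2)| / |supp(q1) ∪ supp(q2)|`.
* a **binomial-tail p-value**: supports are modelled as independently
  sampled with marginals `p_i = |supp(q_i)|/n`, so the overlap is
  `Binomial(n, p1·p2)` and the p-value is `P(X ≥ |E11|)`.

Mining is tree-based and alternating (the CLUS-RM scheme): each view is
first separated from an attribute-shuffled copy of itself by a predictive
clustering tree, every tree node becomes a conjunctive query, and then the
views take turns re-describing each other — rule memberships of one view are
the multi-target 0/1 outputs the next tree on the other view is grown for.
Quality-screened query pairs (minimum `Jqnm`, maximum p-value, support
interval, maximum query length) feed a capacity-bounded **redescription
set** that greedily minimises
`sc(R) = α1·(1 − Jqnm) + α2·redScoreInst + α3·redScoreAttr`, a weighted sum
of inaccuracy and instance/attribute redundancy; retained queries are then
minimised condition-by-condition.

**Attribute constraints** focus the search on user-chosen attribute sets
`C = {C1, …, Cn}` in three modes — *strict* (some `Ci` fully contained in the
query attributes), *soft* (some `Ci` partially hit, compliance rewarded),
*suggested* (compliance only raises the score, via a fourth weight `α4`).

Post-hoc analytics: Shannon entropy of class labels inside each support set
(group homogeneity), attribute co-occurrence tables per view-pair class, and
normality-screened Pearson/Spearman correlation reporting. A synthetic
benchmark generator plants ground-truth redescriptions (with noise, missing
cells and label structure) so the whole pipeline is testable end to end.

See `vignettes/redescription-mining.Rmd` for the full model description and
design choices.

## Worked example

```r
library(clusrm)

sim <- generate_two_view(plant_spec(
  n = 300, attrs1 = 6, attrs2 = 6,
  plants = list(list(size = 80, k1 = 2, k2 = 2, label = "AD")),
  seed = 42))

cfg <- engine_config(
  max_iter = 5, seed = 42, capacity = 50,
  quality = quality_constraints(min_jaccard = 0.5, max_pvalue = 0.01,
                                support = c(40, 160)))
set <- mine_redescriptions(sim$data, cfg)
set
#> Redescription set: 15 / 50 members
#>   Jqnm: min 0.503, median 0.661, max 1.000
#>   support size: min 77, median 80, max 130

top <- which.max(vapply(set$members, function(R) R$jqnm, 0))
set$members[[top]]
#> q1: 42.2940517601 <= bio1 <= 56.872735233
#> q2: 20.6881235773 <= clin2 <= 36.0468725429 & 70.6719146622 <= clin1 <= 96.5392887243
#> |supp| = 80, Jqnm = 1.000, p = 3.02e-25

recovery_jaccard(set$members[[top]], sim$truth[[1]]$instances)
#> [1] 1
support_entropy(set$members[[top]], sim$data$labels)
#> [1] 0
```

The miner recovered the planted 80-subject group exactly: one biological
interval and two clinical intervals describe the identical subjects
(`Jqnm = 1`), the overlap is far beyond chance (`p ≈ 3e-25`), and the group
is diagnosis-homogeneous (entropy 0 bits).

Quality measures can also be used directly: two queries supporting 204 and
172 of 820 subjects with overlap 156 give
`jaccard_index(204, 172, 156)` = 0.709 and
`redescription_pvalue(820, 204, 172, 156)` ≈ 2.7e-44.

A command-line front end (`inst/cli/clusrm.R`) wraps the same functions:

```sh
Rscript inst/cli/clusrm.R simulate --out sim --seed 5 --n 300
Rscript inst/cli/clusrm.R mine --view1 sim/view1.tsv --view2 sim/view2.tsv \
    --labels sim/labels.tsv --out mined --seed 5 --support 40:160 --jmin 0.5
Rscript inst/cli/clusrm.R analyze --redescriptions mined/redescriptions.tsv \
    --view1 sim/view1.tsv --view2 sim/view2.tsv --labels sim/labels.tsv --out analysis
```

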