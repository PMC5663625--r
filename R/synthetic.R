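# Synthetic two-view benchmark generator with planted redescriptions,
# missing values, and label structure, so every pipeline stage is testable
# without external data.

#' Specification of a planted two-view benchmark
#'
#' Describes a synthetic dataset emulating the structure of a two-view
#' clinical/biological study: two views of numeric attributes over shared
#' instances, per-attribute missingness, a 5-level ordinal diagnosis-style
#' label, and planted cross-view associations — instance subsets whose values
#' fall inside narrow intervals on selected attributes of *both* views, so a
#' ground-truth redescription exists for each plant.
#'
#' @param n number of instances (default 500).
#' @param attrs1,attrs2 numeric attribute counts per view (default 10 each).
#' @param plants list of plants; each a list with elements `size` (subset
#'   size), `k1`, `k2` (attributes used per view, default 2), `width`
#'   (planted interval width as a fraction of the value range, default 0.15),
#'   `noise` (fraction of planted cells perturbed outside the interval,
#'   default 0) and `label` (class assigned to the subset).
#' @param missing per-attribute missing-cell rate: scalar or vector of length
#'   `attrs1 + attrs2` (default 0).
#' @param labels the ordinal label alphabet (default the 5-level
#'   CN/SMC/EMCI/LMCI/AD dementia staging).
#' @param seed integer seed.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(n = 500L, attrs1 = 10L, attrs2 = 10L,
                       plants = list(list(size = 100L)),
                       missing = 0,
                       labels = c("CN", "SMC", "EMCI", "LMCI", "AD"),
                       seed = 1L) {
  plants <- lapply(seq_along(plants), function(i) {
    p <- plants[[i]]
    p$size <- as.integer(p$size)
    if (p$size > n) stop("plant larger than the dataset")
    p$k1 <- as.integer(if (is.null(p$k1)) 2L else p$k1)
    p$k2 <- as.integer(if (is.null(p$k2)) 2L else p$k2)
    if (is.null(p$width)) p$width <- 0.15
    if (is.null(p$noise)) p$noise <- 0
    if (p$noise < 0 || p$noise >= 1) stop("noise rate must be in [0, 1)")
    if (is.null(p$label)) p$label <- labels[min(i + 3L, length(labels))]
    p
  })
  k <- attrs1 + attrs2
  missing <- rep_len(missing, k)
  if (any(missing < 0 | missing >= 1)) stop("missing rate must be in [0, 1)")
  if (sum(vapply(plants, function(p) p$k1, 0L)) > attrs1 ||
      sum(vapply(plants, function(p) p$k2, 0L)) > attrs2)
    stop("plants demand more attributes than a view contains")
  structure(list(n = as.integer(n), attrs1 = as.integer(attrs1),
                 attrs2 = as.integer(attrs2), plants = plants,
                 missing = missing, labels = labels, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a planted two-view dataset
#'
#' Background cells are uniform on `[0, 100]`. For each plant, a disjoint
#' instance subset and disjoint attribute blocks in each view are selected;
#' the subset's values on those attributes are drawn uniformly inside a
#' narrow interval (width `width * 100`, randomly placed), except a `noise`
#' fraction of cells re-drawn outside the interval. On planted attributes the
#' background is kept outside the planted interval, so with `noise = 0` and
#' no masking each ground-truth query describes exactly its planted subset
#' (an accuracy-1 redescription exists by construction). Missing cells are then
#' masked independently at the per-attribute rate. Planted subsets receive
#' their plant's label; the remaining instances draw labels uniformly from
#' the remaining classes, so each ground-truth redescription is
#' label-homogeneous.
#'
#' @param spec a [plant_spec()].
#' @return List with `data` (a [two_view_dataset()]) and `truth`: one entry
#'   per plant with `instances` (indices), `q1`, `q2` (the ground-truth
#'   interval queries) and `label`.
#' @export
generate_two_view <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  n <- spec$n
  mk <- function(k, prefix) {
    tab <- as.data.frame(lapply(seq_len(k), function(j) stats::runif(n, 0, 100)))
    names(tab) <- paste0(prefix, seq_len(k))
    tab
  }
  v1 <- mk(spec$attrs1, "bio"); v2 <- mk(spec$attrs2, "clin")
  free_inst <- seq_len(n)
  free1 <- seq_len(spec$attrs1); free2 <- seq_len(spec$attrs2)
  labels <- rep(NA_character_, n)
  truth <- list()
  for (pi in seq_along(spec$plants)) {
    p <- spec$plants[[pi]]
    if (length(free_inst) < p$size) stop("plants demand overlapping instances")
    inst <- sort(sample(free_inst, p$size))
    free_inst <- setdiff(free_inst, inst)
    a1 <- free1[seq_len(p$k1)]; free1 <- setdiff(free1, a1)
    a2 <- free2[seq_len(p$k2)]; free2 <- setdiff(free2, a2)
    w <- p$width * 100
    draw_outside <- function(k, lo, hi) {
      # uniform over [0, lo) u (hi, 100], proportional to segment lengths
      below <- stats::runif(k) < lo / (100 - (hi - lo))
      ifelse(below, stats::runif(k, 0, lo), stats::runif(k, hi, 100))
    }
    plant_cols <- function(tab, cols) {
      conds <- list()
      for (j in cols) {
        lo <- stats::runif(1, 0, 100 - w); hi <- lo + w
        vals <- stats::runif(length(inst), lo, hi)
        if (p$noise > 0) {
          flip <- stats::runif(length(inst)) < p$noise
          vals[flip] <- draw_outside(sum(flip), lo, hi)   # perturb off-interval
        }
        tab[inst, j] <- vals
        # construction guarantee: background stays outside the planted
        # interval, so the ground-truth query describes exactly the subset
        bg <- setdiff(seq_len(nrow(tab)), inst)
        inside <- bg[!is.na(tab[bg, j]) & tab[bg, j] >= lo & tab[bg, j] <= hi]
        if (length(inside))
          tab[inside, j] <- draw_outside(length(inside), lo, hi)
        conds[[length(conds) + 1L]] <- cond_interval(names(tab)[j], lo, hi)
      }
      list(tab = tab, conds = conds)
    }
    r1 <- plant_cols(v1, a1); v1 <- r1$tab
    r2 <- plant_cols(v2, a2); v2 <- r2$tab
    labels[inst] <- p$label
    truth[[pi]] <- list(instances = inst,
                        q1 = conjunctive_query(1L, r1$conds),
                        q2 = conjunctive_query(2L, r2$conds),
                        label = p$label)
  }
  planted_labels <- unique(vapply(spec$plants, function(p) p$label, ""))
  rest <- setdiff(spec$labels, planted_labels)
  if (length(rest) == 0L) rest <- spec$labels
  labels[is.na(labels)] <- sample(rest, sum(is.na(labels)), replace = TRUE)
  # mask missing cells per attribute
  mask <- function(tab, rates) {
    for (j in seq_along(tab)) {
      if (rates[j] > 0) {
        hit <- stats::runif(n) < rates[j]
        tab[hit, j] <- NA
      }
    }
    tab
  }
  v1 <- mask(v1, spec$missing[seq_len(spec$attrs1)])
  v2 <- mask(v2, spec$missing[spec$attrs1 + seq_len(spec$attrs2)])
  data <- two_view_dataset(v1, v2, labels = factor(labels, levels = spec$labels))
  list(data = data, truth = truth)
}

#' Null dataset: two independent views
#'
#' Generates two views independently (uniform background, no planted
#' structure, labels drawn independently), so no true cross-view association
#' exists. Used for false-discovery property checks.
#'
#' @param n instances.
#' @param attrs1,attrs2 attribute counts per view.
#' @param seed integer seed.
#' @return A [two_view_dataset()].
#' @export
null_two_view <- function(n = 500L, attrs1 = 10L, attrs2 = 10L, seed = 1L) {
  set.seed(seed)
  mk <- function(k, prefix) {
    tab <- as.data.frame(lapply(seq_len(k), function(j) stats::runif(n, 0, 100)))
    names(tab) <- paste0(prefix, seq_len(k))
    tab
  }
  two_view_dataset(mk(attrs1, "bio"), mk(attrs2, "clin"),
                   labels = factor(sample(c("CN", "SMC", "EMCI", "LMCI", "AD"),
                                          n, replace = TRUE)))
}

#' Support Jaccard between a mined redescription and a ground-truth plant
#'
#' @param R a [redescription()].
#' @param truth_instances integer indices of the planted subset.
#' @return `|supp(R) n plant| / |supp(R) u plant|`.
#' @export
recovery_jaccard <- function(R, truth_instances) {
  s <- if (inherits(R, "redescription")) R$support else as.integer(R)
  length(intersect(s, truth_instances)) / length(union(s, truth_instances))
}
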