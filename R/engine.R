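# The CLUS-RM main loop: initialisation on shuffled copies, alternating
# re-description of rule supports across the two views, quality-filtered
# Cartesian combination of rule sets, bounded set optimisation, and query
# minimisation.

#' Engine configuration
#'
#' @param max_iter number of alternation iterations (default 50).
#' @param quality a [quality_constraints()] object.
#' @param capacity redescription-set capacity (default 100).
#' @param alphas score weights; `NULL` selects `c(1,1,1)/3` for unconstrained
#'   mining and `c(1,1,1,1)/4` when attribute constraints are supplied.
#' @param seed integer seed driving every random draw of a run (the
#'   initialisation shuffles); `NULL` uses the current RNG state.
#' @param max_depth maximal tree depth (default 8, matching the maximal
#'   query length).
#' @param min_leaf minimal leaf size; `NULL` uses half the lower bound of the
#'   quality support interval (clamped to at least 2), so that a cluster at
#'   the minimal admissible support can still be split and refined.
#' @param init_min_leaf minimal leaf size of the two *initialisation* trees;
#'   `NULL` uses `min_leaf / 5` (at least 2). The alternation is
#'   deterministic, so all exploration diversity must come from the
#'   initialisation: small initial leaves yield many seed rules for the first
#'   round of cross-view targets.
#' @return Object of class `engine_config`.
#' @export
engine_config <- function(max_iter = 50L, quality = quality_constraints(),
                          capacity = 100L, alphas = NULL, seed = NULL,
                          max_depth = 8L, min_leaf = NULL,
                          init_min_leaf = NULL) {
  stopifnot(max_iter >= 1L, inherits(quality, "quality_constraints"))
  structure(list(max_iter = as.integer(max_iter), quality = quality,
                 capacity = as.integer(capacity), alphas = alphas,
                 seed = seed, max_depth = as.integer(max_depth),
                 min_leaf = min_leaf, init_min_leaf = init_min_leaf),
            class = "engine_config")
}

# Build a tree on one view and return its node queries with cached
# evaluations on the original dataset.
.grow_rules <- function(data, view, targets, tab = NULL, config, iter) {
  if (is.null(tab)) tab <- view_table(data, view)
  tree <- build_pct(tab, targets, max_depth = config$max_depth,
                    min_leaf = config$.min_leaf)
  rules <- extract_rules(tree, tab, view)
  rules <- Filter(function(q) query_length(q) <= config$quality$max_length,
                  rules)
  evals <- lapply(rules, evaluate_query, data = data)
  for (i in seq_along(rules)) attr(rules[[i]], "iter") <- iter
  list(rules = rules, evals = evals)
}

# Evaluate the Cartesian product of two rule lists (row-major over
# rules1 x rules2), screening with constraints and quality; feed survivors to
# the set optimiser. Returns the updated set (plus pairing provenance when
# tracing).
.combine_into <- function(set, rs1, rs2, data, config, constraints,
                          trace_env = NULL) {
  Q <- config$quality
  for (i in seq_along(rs1$rules)) {
    for (j in seq_along(rs2$rules)) {
      q1 <- rs1$rules[[i]]; q2 <- rs2$rules[[j]]
      if (!is.null(trace_env))
        trace_env$pairs[[length(trace_env$pairs) + 1L]] <-
          c(attr(q1, "iter"), attr(q2, "iter"))
      if (!pair_admissible(q1, q2, constraints)) next
      R <- redescription(q1, q2, data, e1 = rs1$evals[[i]], e2 = rs2$evals[[j]])
      if (!isTRUE(c(check_quality(R, Q)))) next
      if (!is.null(constraints) && constraints$mode %in% c("strict", "soft")) {
        R <- minimize_query(R, data, Q, constraints)
        if (is.null(R)) next
      }
      cs <- if (length(set$alphas) == 4L) {
        if (is.null(constraints)) 1 else constraint_mode_score(R$attrs, constraints)
      } else NULL
      set <- add_replace_discard(set, R, constraint_score = cs)
    }
  }
  set
}

#' Mine redescriptions from a two-view dataset
#'
#' Runs the alternating tree-based mining loop. Both views are first augmented
#' with attribute-shuffled copies and a tree separating originals from copies
#' seeds the rule sets. Each iteration then re-describes the supports of one
#' view's rules with the other view's attributes: rule memberships become the
#' 0/1 targets of a multi-target predictive clustering tree, every tree node
#' yields a conjunctive query, and new rules of each view are paired with the
#' previous iteration's rules of the opposite view. Quality-passing (and,
#' under constraints, admissible) pairs enter a bounded redescription set
#' maintained by [add_replace_discard()]; all retained redescriptions are
#' finally query-minimised.
#'
#' @param data a [two_view_dataset()].
#' @param config an [engine_config()].
#' @param constraints optional [constraint_spec()]; in strict/soft mode query
#'   minimisation additionally runs before insertion, and a redescription
#'   whose minimisation drops a constrained attribute is discarded.
#' @param verbose print per-iteration progress.
#' @param trace record rule-pairing provenance (iteration indices) as
#'   attribute `"pairings"` of the result, for structural checks.
#' @return A [redescription_set()]; attribute `"config"` stores the
#'   configuration used.
#' @examples
#' sim <- generate_two_view(plant_spec(n = 120, attrs1 = 3, attrs2 = 3,
#'   plants = list(list(size = 40, k1 = 1, k2 = 1)), seed = 7))
#' cfg <- engine_config(max_iter = 2, seed = 7,
#'   quality = quality_constraints(min_jaccard = 0.5, support = c(20, 80)))
#' mine_redescriptions(sim$data, cfg)
#' @export
mine_redescriptions <- function(data, config = engine_config(),
                                constraints = NULL, verbose = FALSE,
                                trace = FALSE) {
  stopifnot(inherits(data, "two_view"))
  if (ncol(data$view1) == 0L || ncol(data$view2) == 0L)
    stop("both views must contain attributes")
  if (!is.null(constraints)) validate_constraints(constraints, data)
  if (!is.null(config$seed)) set.seed(config$seed)
  Q <- config$quality
  lo <- Q$support[1]
  # Half the minimal support: a cluster at the minimal admissible support
  # must still be splittable, otherwise alternation cannot refine it.
  config$.min_leaf <- if (!is.null(config$min_leaf)) as.integer(config$min_leaf)
    else max(2L, min(as.integer(ceiling(if (is.finite(lo)) lo / 2 else 2)),
                     data$n %/% 4L))
  alphas <- config$alphas
  if (is.null(alphas)) alphas <- if (is.null(constraints)) rep(1 / 3, 3) else rep(1 / 4, 4)
  set <- redescription_set(data$n, capacity = config$capacity, alphas = alphas)
  trace_env <- if (trace) new.env() else NULL
  if (trace) trace_env$pairs <- list()

  # initialisation: originals vs shuffled copies, one tree per view
  init_ml <- if (!is.null(config$init_min_leaf)) as.integer(config$init_min_leaf)
    else max(2L, config$.min_leaf %/% 5L)
  init_rules <- lapply(1:2, function(v) {
    init <- build_initial_data(view_table(data, v))
    tree <- build_pct(init$table, matrix(init$target, ncol = 1),
                      max_depth = config$max_depth,
                      min_leaf = init_ml)
    rules <- extract_rules(tree, init$table, v)
    rules <- Filter(function(q) query_length(q) <= Q$max_length, rules)
    for (i in seq_along(rules)) attr(rules[[i]], "iter") <- 0L
    list(rules = rules, evals = lapply(rules, evaluate_query, data = data))
  })
  prev1 <- init_rules[[1]]; prev2 <- init_rules[[2]]

  for (ind in seq_len(config$max_iter)) {
    t1 <- construct_targets(prev2$rules, data, prev2$evals)
    t2 <- construct_targets(prev1$rules, data, prev1$evals)
    if (ncol(t1) == 0L && ncol(t2) == 0L) {
      warning(sprintf("iteration %d: no rules to re-describe; stopping", ind))
      break
    }
    new1 <- if (ncol(t1)) .grow_rules(data, 1L, t1, config = config, iter = ind)
      else list(rules = list(), evals = list())
    new2 <- if (ncol(t2)) .grow_rules(data, 2L, t2, config = config, iter = ind)
      else list(rules = list(), evals = list())
    if (length(new1$rules) == 0L && length(new2$rules) == 0L) {
      warning(sprintf("iteration %d: trees produced no rules; iteration skipped", ind))
      next
    }
    # line 9: rW1(ind) x rW2(ind-1)  union  rW1(ind-1) x rW2(ind)
    set <- .combine_into(set, new1, prev2, data, config, constraints, trace_env)
    set <- .combine_into(set, prev1, new2, data, config, constraints, trace_env)
    if (verbose)
      message(sprintf("iteration %d: %d + %d new rules, set size %d",
                      ind, length(new1$rules), length(new2$rules),
                      length(set$members)))
    if (length(new1$rules)) prev1 <- new1
    if (length(new2$rules)) prev2 <- new2
  }

  # line 11: minimise every retained redescription
  set <- .finalize_set(set, data, Q, constraints)
  attr(set, "config") <- config
  if (trace) attr(set, "pairings") <- do.call(rbind, trace_env$pairs)
  set
}

# Minimise all members, apply the constraint discard rule, deduplicate, and
# rebuild the coverage counters from scratch.
.finalize_set <- function(set, data, Q, constraints) {
  out <- redescription_set(set$n, capacity = set$capacity, alphas = set$alphas)
  for (R in set$members) {
    Rm <- minimize_query(R, data, Q, constraints)
    if (is.null(Rm)) next
    cs <- if (length(set$alphas) == 4L) {
      if (is.null(constraints)) 1 else constraint_mode_score(Rm$attrs, constraints)
    } else NULL
    out <- add_replace_discard(out, Rm, constraint_score = cs)
  }
  out
}

#' Greedy query minimisation
#'
#' Attempts to drop each condition of both queries in insertion order,
#' repeating until a fixed point: a removal is kept iff the accuracy (query
#' non-missing Jaccard) does not decrease and all quality constraints still
#' hold. Under strict or soft constraint modes, a redescription whose
#' minimisation removed any constrained attribute from its attribute set is
#' discarded (`NULL`).
#'
#' @param R a quality-screened [redescription()].
#' @param data the dataset it was mined from.
#' @param quality a [quality_constraints()] object.
#' @param constraints optional [constraint_spec()].
#' @return The minimised [redescription()], or `NULL` when discarded.
#' @export
minimize_query <- function(R, data, quality, constraints = NULL) {
  attrs_before <- R$attrs
  repeat {
    improved <- FALSE
    for (side in 1:2) {
      qs <- list(R$q1, R$q2)
      k <- 1L
      while (k <= length(qs[[side]]$conditions)) {
        cand_q <- qs[[side]]
        cand_q$conditions[[k]] <- NULL
        cand <- if (side == 1L) redescription(cand_q, R$q2, data)
          else redescription(R$q1, cand_q, data)
        if (cand$jqnm >= R$jqnm && isTRUE(c(check_quality(cand, quality)))) {
          R <- cand
          qs <- list(R$q1, R$q2)
          improved <- TRUE
        } else {
          k <- k + 1L
        }
      }
    }
    if (!improved) break
  }
  if (!is.null(constraints) && constraints$mode %in% c("strict", "soft")) {
    key_attrs <- unique(unlist(constraints$sets))
    removed <- setdiff(attrs_before, R$attrs)
    if (length(intersect(removed, key_attrs)) > 0L) return(NULL)
  }
  R
}
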