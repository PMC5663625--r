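# Multi-target predictive clustering trees over one view, and conversion of
# every tree node into a conjunctive query.

#' Initialisation table: originals vs attribute-shuffled copies
#'
#' Builds the 2n-row training table used to seed the miner: the n original
#' rows (target 1) stacked on n synthetic rows (target 0) in which, per
#' attribute independently, each cell is copied from a uniformly random
#' original instance with replacement. This breaks inter-attribute
#' correlations in the copies while preserving every marginal value set, so a
#' tree separating originals from copies must exploit attribute interactions.
#'
#' @param view data frame (one view's table).
#' @param seed optional integer seed; the draw is reproducible given the seed.
#' @return List with `table` (2n rows) and `target` (numeric 1/0 vector).
#' @export
build_initial_data <- function(view, seed = NULL) {
  n <- nrow(view)
  if (n < 1L) stop("empty view")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  synth <- view
  for (j in seq_along(view)) {
    synth[[j]] <- view[[j]][sample.int(n, n, replace = TRUE)]
  }
  tab <- rbind(view, synth)
  rownames(tab) <- NULL
  list(table = tab, target = c(rep(1, n), rep(0, n)))
}

# Find the best split at a node. Gain is the summed variance reduction over
# all targets: for 0/1 targets the within-group sum of squares with s ones in
# m rows is s - s^2/m, so the reduction simplifies to
# sL^2/nL + sR^2/nR - S^2/m (the linear terms cancel). y: targets matrix restricted to node members.
# Returns NULL or list(attr, type, threshold | category, gain).
.best_split <- function(tab, members, targets, min_leaf) {
  y_node <- targets[members, , drop = FALSE]
  best <- NULL
  for (j in seq_along(tab)) {
    x <- tab[[j]][members]
    obs <- !is.na(x)
    if (sum(obs) < 2L * min_leaf) next
    xo <- x[obs]
    yo <- y_node[obs, , drop = FALSE]
    m <- length(xo)
    S <- colSums(yo)
    if (is.numeric(x)) {
      ord <- order(xo)
      xs <- xo[ord]
      cs <- apply(yo[ord, , drop = FALSE], 2, cumsum)
      if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(yo))
      # valid cut after position i: distinct neighbours, leaf sizes ok
      i <- seq_len(m - 1L)
      valid <- which(xs[i] != xs[i + 1L] & i >= min_leaf & (m - i) >= min_leaf)
      if (length(valid) == 0L) next
      sL <- cs[valid, , drop = FALSE]
      nL <- valid
      nR <- m - valid
      sR <- sweep(-sL, 2, S, `+`)
      gain <- rowSums(sL^2 / nL + sR^2 / nR) - sum(S^2) / m
      k <- which.max(gain)   # first maximum -> smallest threshold
      g <- gain[k]
      if (g > 1e-12 && (is.null(best) || g > best$gain + 1e-12)) {
        thr <- (xs[valid[k]] + xs[valid[k] + 1L]) / 2
        best <- list(attr = names(tab)[j], type = "num", threshold = thr,
                     gain = g)
      }
    } else {
      cats <- sort(unique(xo))
      if (length(cats) < 2L) next
      for (cc in cats) {
        left <- xo == cc
        nL <- sum(left); nR <- m - nL
        if (nL < min_leaf || nR < min_leaf) next
        sL <- colSums(yo[left, , drop = FALSE])
        g <- sum(sL^2) / nL + sum((S - sL)^2) / nR - sum(S^2) / m
        if (g > 1e-12 && (is.null(best) || g > best$gain + 1e-12)) {
          best <- list(attr = names(tab)[j], type = "cat", category = cc,
                       gain = g)
        }
      }
    }
  }
  best
}

#' Grow a multi-target predictive clustering tree
#'
#' Binary tree grown top-down on one view's table; each split maximises the
#' total variance reduction summed over all (0/1) target columns, which for
#' indicator targets coincides with the Gini-style impurity reduction.
#' Candidate thresholds for numeric attributes are midpoints between
#' consecutive distinct values; categorical splits are one-vs-rest equality
#' tests. Instances missing the split attribute are excluded from gain
#' computation and routed to the child with more non-missing members (tie:
#' left). Growth stops at `max_depth`, when a child would fall below
#' `min_leaf`, or when no split achieves positive reduction. Ties between
#' equal-gain splits resolve to the lowest attribute index, then the smallest
#' threshold — tree growth is fully deterministic.
#'
#' @param tab data frame of descriptive attributes.
#' @param targets numeric matrix of 0/1 indicators, one row per row of `tab`.
#' @param max_depth maximal tree depth (root = depth 0).
#' @param min_leaf minimal number of non-missing training instances per child.
#' @return Root node: nested list with `members`, `depth` and, for internal
#'   nodes, `split`, `left`, `right`.
#' @export
build_pct <- function(tab, targets, max_depth = 8L, min_leaf = 2L) {
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(tab)) stop("targets not row-aligned with the table")
  grow <- function(members, depth) {
    node <- list(members = members, depth = depth)
    if (depth >= max_depth || length(members) < 2L * min_leaf) return(node)
    sp <- .best_split(tab, members, targets, min_leaf)
    if (is.null(sp)) return(node)
    x <- tab[[sp$attr]][members]
    if (sp$type == "num") {
      go_left <- x <= sp$threshold
    } else {
      go_left <- x == sp$category
    }
    miss <- is.na(x)
    nL <- sum(go_left & !miss); nR <- sum(!go_left & !miss)
    if (any(miss)) go_left[miss] <- nL >= nR   # route missing to larger child
    node$split <- sp
    node$left <- grow(members[go_left], depth + 1L)
    node$right <- grow(members[!go_left], depth + 1L)
    node
  }
  grow(seq_len(nrow(tab)), 0L)
}

# Intersect a new condition into a condition list keyed by attribute.
.merge_condition <- function(conds, cn) {
  i <- match(cn$attr, vapply(conds, function(c0) c0$attr, ""))
  if (is.na(i)) return(c(conds, list(cn)))
  old <- conds[[i]]
  if (old$type == "interval" && cn$type == "interval") {
    lo <- max(old$lo, cn$lo); hi <- min(old$hi, cn$hi)
    if (lo > hi) return(NULL)        # empty path: unreachable node
    conds[[i]] <- cond_interval(cn$attr, lo, hi)
  } else if (old$type == "set" && cn$type == "set") {
    v <- intersect(old$values, cn$values)
    if (length(v) == 0L) return(NULL)
    conds[[i]] <- cond_equals(cn$attr, v)
  } else stop("mixed condition types on one attribute")
  conds
}

#' Extract conjunctive queries from every tree node
#'
#' Every non-root node is a cluster; its query is the conjunction of the split
#' outcomes along the root-to-node path. Single-sided numeric outcomes are
#' canonicalised to closed intervals using the attribute's observed range in
#' the training table (`x <= t` becomes `[min_obs, t]`; `x > t` becomes
#' `[v, max_obs]` with `v` the smallest observed value above `t`); repeated
#' conditions on one attribute are intersected into a single interval or value
#' set. Duplicate queries are removed. The node's training member set is kept
#' as attribute `"members"` of each query.
#'
#' @param tree a [build_pct()] result.
#' @param tab the training table the tree was grown on.
#' @param view which view (1 or 2) the queries address.
#' @return List of [conjunctive_query()] objects (empty for a root-only tree).
#' @export
extract_rules <- function(tree, tab, view) {
  ranges <- lapply(tab, function(col) {
    if (is.numeric(col)) {
      v <- col[!is.na(col)]
      if (length(v)) sort(unique(v)) else numeric()
    } else sort(unique(col[!is.na(col)]))
  })
  out <- list()
  walk <- function(node, conds) {
    if (is.null(node$split)) return(invisible())
    sp <- node$split
    if (sp$type == "num") {
      vals <- ranges[[sp$attr]]
      cl <- cond_interval(sp$attr, min(vals), sp$threshold)
      above <- vals[vals > sp$threshold]
      cr <- cond_interval(sp$attr, min(above), max(vals))
    } else {
      vals <- ranges[[sp$attr]]
      cl <- cond_equals(sp$attr, sp$category)
      cr <- cond_equals(sp$attr, setdiff(vals, sp$category))
    }
    for (side in c("left", "right")) {
      cn <- if (side == "left") cl else cr
      child <- node[[side]]
      cc <- .merge_condition(conds, cn)
      if (!is.null(cc)) {
        q <- conjunctive_query(view, cc)
        attr(q, "members") <- child$members
        out[[length(out) + 1L]] <<- q
        walk(child, cc)
      }
    }
  }
  walk(tree, list())
  if (length(out) == 0L) return(out)
  keys <- vapply(out, format, "")
  out[!duplicated(keys)]
}

#' Rule-membership target matrix
#'
#' Turns a rule set from one view into the binary target matrix driving tree
#' induction on the opposite view: entry (i, j) is 1 iff instance i is
#' definitely described by rule j; instances whose membership is
#' undeterminable due to missing values are labelled 0.
#'
#' @param rules list of conjunctive queries.
#' @param data a [two_view_dataset()].
#' @param evals optional list of precomputed evaluation vectors for `rules`.
#' @return Numeric n x length(rules) matrix of 0/1 (zero columns if no rules).
#' @export
construct_targets <- function(rules, data, evals = NULL) {
  if (length(rules) == 0L) return(matrix(0, nrow = data$n, ncol = 0L))
  cols <- lapply(seq_along(rules), function(j) {
    e <- if (is.null(evals)) evaluate_query(rules[[j]], data) else evals[[j]]
    as.numeric(!is.na(e) & e)
  })
  do.call(cbind, cols)
}
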