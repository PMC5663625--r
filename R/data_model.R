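#' Two-view dataset
#'
#' Bundles two attribute-value tables (views) describing the same ordered set
#' of instances, plus an optional per-instance class label (e.g. a diagnosis)
#' used only for post-hoc analysis, never during mining. Attribute names must
#' be disjoint between the views; cells may be `NA` (missing).
#'
#' @param view1,view2 data frames with one row per instance. Columns are
#'   attributes: numeric columns are treated as numeric, everything else
#'   (character, factor, logical) as categorical.
#' @param ids optional character vector of instance identifiers (defaults to
#'   row names, falling back to `"1"`, `"2"`, ...).
#' @param labels optional vector (length = number of instances) of class
#'   labels; coerced to factor.
#' @return An object of class `two_view`: a list with elements `view1`,
#'   `view2`, `ids`, `labels`, `n` and an attribute summary table `attrs`
#'   (name, view, kind, observed range / levels).
#' @examples
#' d <- two_view_dataset(data.frame(x = c(1, 5, NA)),
#'                       data.frame(y = c(0, 1, 1)))
#' d$n
#' @export
two_view_dataset <- function(view1, view2, ids = NULL, labels = NULL) {
  view1 <- as.data.frame(view1, stringsAsFactors = FALSE)
  view2 <- as.data.frame(view2, stringsAsFactors = FALSE)
  if (nrow(view1) != nrow(view2))
    stop("views must describe the same instances (row counts differ)")
  n <- nrow(view1)
  if (n == 0L) stop("dataset has no instances")
  if (length(intersect(names(view1), names(view2))) > 0L)
    stop("attribute names must be disjoint between the two views")
  if (anyDuplicated(names(view1)) || anyDuplicated(names(view2)))
    stop("attribute names must be unique within a view")
  if (is.null(ids)) {
    ids <- rownames(view1)
    if (is.null(ids)) ids <- as.character(seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) != number of instances")
  if (anyDuplicated(ids)) stop("duplicate instance identifiers")
  if (!is.null(labels)) {
    if (length(labels) != n) stop("length(labels) != number of instances")
    labels <- as.factor(labels)
  }
  # normalise categorical columns to character
  norm <- function(v) {
    for (j in seq_along(v)) {
      if (!is.numeric(v[[j]])) v[[j]] <- as.character(v[[j]])
    }
    v
  }
  view1 <- norm(view1); view2 <- norm(view2)
  rownames(view1) <- rownames(view2) <- NULL
  obj <- structure(list(view1 = view1, view2 = view2, ids = ids,
                        labels = labels, n = n),
                   class = "two_view")
  obj$attrs <- attribute_table(obj)
  obj
}

attribute_table <- function(data) {
  one <- function(tab, vi) {
    if (ncol(tab) == 0L)
      return(data.frame(name = character(), view = integer(),
                        kind = character(), stringsAsFactors = FALSE))
    kind <- vapply(tab, function(col) if (is.numeric(col)) "numeric" else "categorical", "")
    data.frame(name = names(tab), view = vi, kind = unname(kind),
               stringsAsFactors = FALSE)
  }
  rbind(one(data$view1, 1L), one(data$view2, 2L))
}

#' @export
print.two_view <- function(x, ...) {
  cat(sprintf("Two-view dataset: %d instances; view 1: %d attributes, view 2: %d attributes\n",
              x$n, ncol(x$view1), ncol(x$view2)))
  miss <- function(v) if (ncol(v)) mean(is.na(as.matrix(v))) else 0
  cat(sprintf("  missing cells: %.1f%% (view 1), %.1f%% (view 2)\n",
              100 * miss(x$view1), 100 * miss(x$view2)))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

view_table <- function(data, view) {
  stopifnot(view %in% c(1L, 2L))
  if (view == 1L) data$view1 else data$view2
}

#' Query conditions
#'
#' A conjunctive query is built from conditions on single attributes: a closed
#' numeric interval `lo <= attr <= hi`, or a categorical value set
#' (`cond_equals()` with one value is the plain equality printed as
#' `attr = v`).
#'
#' @param attr attribute name.
#' @param lo,hi closed interval bounds, `lo <= hi`.
#' @param values one or more admissible category values.
#' @return A condition object (class `rm_condition`).
#' @examples
#' cond_interval("GDTOTAL", 0, 2)
#' cond_equals("GDALIVE", "0")
#' @export
cond_interval <- function(attr, lo, hi) {
  if (is.na(lo) || is.na(hi) || lo > hi) stop("need lo <= hi for interval condition")
  structure(list(attr = attr, type = "interval", lo = as.numeric(lo),
                 hi = as.numeric(hi)),
            class = "rm_condition")
}

#' @rdname cond_interval
#' @export
cond_equals <- function(attr, values) {
  if (length(values) < 1L) stop("need at least one category value")
  structure(list(attr = attr, type = "set",
                 values = sort(unique(as.character(values)))),
            class = "rm_condition")
}

#' @export
format.rm_condition <- function(x, ...) {
  if (x$type == "interval") {
    sprintf("%s <= %s <= %s", format(x$lo, digits = 12),
            x$attr, format(x$hi, digits = 12))
  } else if (length(x$values) == 1L) {
    sprintf("%s = %s", x$attr, x$values)
  } else {
    sprintf("%s in {%s}", x$attr, paste(x$values, collapse = ","))
  }
}

#' @export
print.rm_condition <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Conjunctive query
#'
#' A conjunction of conditions over attributes of a single view, at most one
#' condition per attribute. The empty conjunction is valid and describes every
#' instance.
#'
#' @param view which view the query addresses (1 or 2).
#' @param conditions list of conditions (see [cond_interval()]).
#' @return Object of class `conjunctive_query`.
#' @examples
#' q <- conjunctive_query(1, list(cond_interval("x", 0, 2)))
#' format(q)
#' @export
conjunctive_query <- function(view, conditions = list()) {
  if (inherits(conditions, "rm_condition")) conditions <- list(conditions)
  attrs <- vapply(conditions, function(cn) cn$attr, "")
  if (anyDuplicated(attrs)) stop("at most one condition per attribute")
  structure(list(view = as.integer(view), conditions = conditions),
            class = "conjunctive_query")
}

#' @export
format.conjunctive_query <- function(x, ...) {
  if (length(x$conditions) == 0L) return("TRUE")
  paste(vapply(x$conditions, format, ""), collapse = " & ")
}

#' @export
print.conjunctive_query <- function(x, ...) {
  cat(sprintf("[view %d] %s\n", x$view, format(x))); invisible(x)
}

query_attrs <- function(q) vapply(q$conditions, function(cn) cn$attr, "")

query_length <- function(q) length(q$conditions)

#' Evaluate a conjunctive query under three-valued semantics
#'
#' Each instance maps to `TRUE` (described), `FALSE` (definitely not
#' described) or `NA` (membership undeterminable because a referenced value is
#' missing). The semantics are Kleene's: one definitely violated conjunct
#' makes the instance `FALSE` even if other conjuncts are unevaluable; an
#' instance is `TRUE` only if every conjunct holds on observed values.
#'
#' @param q a [conjunctive_query()].
#' @param data a [two_view_dataset()].
#' @return Logical vector of length `data$n` with `NA` for undeterminable
#'   instances.
#' @examples
#' d <- two_view_dataset(data.frame(x = c(1, 5, NA)), data.frame(y = 1:3))
#' evaluate_query(conjunctive_query(1, list(cond_interval("x", 0, 2))), d)
#' @export
evaluate_query <- function(q, data) {
  tab <- view_table(data, q$view)
  out <- rep(TRUE, data$n)
  for (cn in q$conditions) {
    if (!cn$attr %in% names(tab))
      stop(sprintf("query references unknown attribute '%s' in view %d",
                   cn$attr, q$view))
    v <- tab[[cn$attr]]
    if (cn$type == "interval") {
      if (!is.numeric(v))
        stop(sprintf("interval condition on non-numeric attribute '%s'", cn$attr))
      r <- v >= cn$lo & v <= cn$hi
    } else {
      r <- as.character(v) %in% cn$values
      r[is.na(v)] <- NA
    }
    out <- out & r   # Kleene conjunction: FALSE dominates NA
  }
  out
}

#' Nine-cell support partition of two three-valued query evaluations
#'
#' Splits the instance set by the pair of membership states (in / out /
#' undeterminable) under the two queries of a redescription. Cell `E11` is the
#' redescription support; `Eq1`, `E1q` etc. hold instances whose membership in
#' one query cannot be determined because of missing values.
#'
#' @param e1,e2 equal-length logical vectors with `NA` = undeterminable, as
#'   returned by [evaluate_query()].
#' @return Object of class `support_partition`: list with `counts` (named
#'   integer vector over the nine cells) and `cells` (instance index sets).
#' @export
partition_support <- function(e1, e2) {
  if (length(e1) != length(e2))
    stop("internal error: evaluation vectors differ in length")
  code <- function(e) ifelse(is.na(e), "q", ifelse(e, "1", "0"))
  key <- paste0("E", code(e1), code(e2))
  cells_all <- c("E11", "E10", "E01", "E00", "E1q", "Eq1", "E0q", "Eq0", "Eqq")
  cells <- lapply(cells_all, function(k) which(key == k))
  names(cells) <- cells_all
  counts <- vapply(cells, length, 0L)
  structure(list(counts = counts, cells = cells, n = length(e1)),
            class = "support_partition")
}

#' @export
print.support_partition <- function(x, ...) {
  print(x$counts); invisible(x)
}

#' Jaccard index of two support sets
#'
#' `|supp(q1) n supp(q2)| / |supp(q1) u supp(q2)|`, the redescription accuracy
#' on fully observed data. When both supports are empty the index is defined
#' as 0 (with a warning): an empty pair of descriptions carries no evidence of
#' association.
#'
#' @param supp1,supp2 support sizes of the two queries.
#' @param intersection size of their intersection.
#' @return Numeric in `[0, 1]`.
#' @examples
#' jaccard_index(204, 172, 156)  # 156/220
#' @export
jaccard_index <- function(supp1, supp2, intersection) {
  if (intersection > min(supp1, supp2))
    stop("intersection larger than a support set")
  union <- supp1 + supp2 - intersection
  if (union == 0) {
    warning("both supports empty; Jaccard defined as 0")
    return(0)
  }
  intersection / union
}

#' Query non-missing Jaccard index
#'
#' Accuracy measure for data with missing values:
#' `|E11| / (|E11| + |Eq1| + |E1q| + |E01| + |E10|)`. Instances described by
#' one query but unevaluable under the other (`E1q`, `Eq1`) penalise the
#' score; doubly-unevaluable or out-plus-unevaluable instances (`Eqq`, `E0q`,
#' `Eq0`) do not. Equals the plain Jaccard index when no referenced value is
#' missing.
#'
#' @param p a [partition_support()] result.
#' @return Numeric in `[0, 1]`; 0 when the denominator is empty.
#' @export
qnm_jaccard <- function(p) {
  ct <- p$counts
  den <- ct[["E11"]] + ct[["Eq1"]] + ct[["E1q"]] + ct[["E01"]] + ct[["E10"]]
  if (den == 0) return(0)
  ct[["E11"]] / den
}

#' Binomial-tail significance of a redescription
#'
#' Models the two query supports as independently sampled instance subsets
#' with marginal probabilities `p1 = supp1/n`, `p2 = supp2/n`; the overlap
#' size then follows `Binomial(n, p1 * p2)` and the p-value is the upper tail
#' `P(X >= overlap)`. Computed through the stable binomial survival function;
#' `log = TRUE` returns the natural-log p-value, finite far below the smallest
#' positive double.
#'
#' @param n number of instances in the dataset.
#' @param supp1,supp2 query support sizes (definite members only).
#' @param overlap observed size of the support intersection.
#' @param log return the log p-value.
#' @return Upper-tail probability (or its log).
#' @examples
#' redescription_pvalue(820, 204, 172, 156) < 2e-17
#' @export
redescription_pvalue <- function(n, supp1, supp2, overlap, log = FALSE) {
  if (n <= 0) stop("n must be positive")
  if (overlap < 0 || overlap > n) stop("overlap outside [0, n]")
  pr <- (supp1 / n) * (supp2 / n)
  stats::pbinom(overlap - 1, size = n, prob = pr,
                lower.tail = FALSE, log.p = log)
}

#' Redescription quality constraints
#'
#' The user-defined screening thresholds a redescription must satisfy to be a
#' candidate for the redescription set: minimum accuracy (query non-missing
#' Jaccard), maximum p-value, a support-size interval, and the maximum number
#' of conditions per query.
#'
#' @param min_jaccard minimal accuracy (default 0.2).
#' @param max_pvalue maximal significance level (default 0.01).
#' @param support two-element numeric `c(lo, hi)` support-size interval;
#'   `hi = Inf` allowed.
#' @param max_length maximal number of conditions per query (default 8).
#' @return Object of class `quality_constraints`.
#' @export
quality_constraints <- function(min_jaccard = 0.2, max_pvalue = 0.01,
                                support = c(5, Inf), max_length = 8L) {
  stopifnot(min_jaccard >= 0, min_jaccard <= 1,
            max_pvalue > 0, max_pvalue <= 1,
            length(support) == 2L, support[1] <= support[2],
            max_length >= 1L)
  structure(list(min_jaccard = min_jaccard, max_pvalue = max_pvalue,
                 support = as.numeric(support),
                 max_length = as.integer(max_length)),
            class = "quality_constraints")
}

#' Construct and evaluate a redescription
#'
#' Pairs one query per view, evaluates both under the three-valued semantics,
#' and caches the support partition, support set, accuracy (query non-missing
#' Jaccard) and binomial-tail p-value. Query support sizes entering the
#' p-value count definite members only.
#'
#' @param q1,q2 conjunctive queries on view 1 and view 2 respectively.
#' @param data a [two_view_dataset()].
#' @param e1,e2 optional precomputed evaluation vectors (to reuse cached
#'   evaluations).
#' @return Object of class `redescription` with elements `q1`, `q2`,
#'   `partition`, `support` (instance indices), `jqnm`, `pvalue`,
#'   `log_pvalue`, `attrs`.
#' @examples
#' d <- two_view_dataset(data.frame(x = c(1, 2, 9)), data.frame(y = c(0, 0, 1)))
#' r <- redescription(conjunctive_query(1, list(cond_interval("x", 0, 5))),
#'                    conjunctive_query(2, list(cond_interval("y", 0, 0))), d)
#' r$jqnm
#' @export
redescription <- function(q1, q2, data, e1 = NULL, e2 = NULL) {
  if (q1$view != 1L || q2$view != 2L)
    stop("q1 must address view 1 and q2 view 2")
  if (is.null(e1)) e1 <- evaluate_query(q1, data)
  if (is.null(e2)) e2 <- evaluate_query(q2, data)
  part <- partition_support(e1, e2)
  s1 <- sum(e1, na.rm = TRUE)
  s2 <- sum(e2, na.rm = TRUE)
  ov <- part$counts[["E11"]]
  structure(list(q1 = q1, q2 = q2, partition = part,
                 support = part$cells$E11,
                 jqnm = qnm_jaccard(part),
                 pvalue = redescription_pvalue(data$n, s1, s2, ov),
                 log_pvalue = redescription_pvalue(data$n, s1, s2, ov, log = TRUE),
                 supp1 = s1, supp2 = s2,
                 attrs = sort(unique(c(query_attrs(q1), query_attrs(q2))))),
            class = "redescription")
}

#' @export
format.redescription <- function(x, ...) {
  sprintf("q1: %s\nq2: %s\n|supp| = %d, Jqnm = %.3f, p = %.3g",
          format(x$q1), format(x$q2), length(x$support), x$jqnm, x$pvalue)
}

#' @export
print.redescription <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Screen a redescription against quality constraints
#'
#' @param R a [redescription()].
#' @param Q a [quality_constraints()] object.
#' @return Logical; attribute `"reasons"` lists the violated constraints
#'   (`"jaccard"`, `"pvalue"`, `"support"`, `"length"`) when `FALSE`.
#' @export
check_quality <- function(R, Q) {
  reasons <- character()
  if (R$jqnm < Q$min_jaccard) reasons <- c(reasons, "jaccard")
  if (R$pvalue > Q$max_pvalue) reasons <- c(reasons, "pvalue")
  s <- length(R$support)
  if (s < Q$support[1] || s > Q$support[2]) reasons <- c(reasons, "support")
  if (query_length(R$q1) > Q$max_length || query_length(R$q2) > Q$max_length)
    reasons <- c(reasons, "length")
  structure(length(reasons) == 0L, reasons = reasons)
}
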