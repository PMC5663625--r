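# Bounded redescription-set maintenance: redundancy scores over instance and
# attribute coverage, and the replace-on-improvement insertion policy.

#' Create an empty redescription set
#'
#' A bounded collection of redescriptions together with the coverage counters
#' that drive the set-optimisation scores: `inst_cover[i]` counts the members
#' whose support contains instance i; `attr_cover[a]` counts the members
#' whose queries use attribute a.
#'
#' @param n number of instances in the dataset the members describe.
#' @param capacity maximal number of members (default 100).
#' @param alphas score weights: length 3 (accuracy, instance redundancy,
#'   attribute redundancy) or length 4 (plus constraint compliance); must sum
#'   to 1.
#' @return Object of class `redescription_set`.
#' @export
redescription_set <- function(n, capacity = 100L, alphas = rep(1 / 3, 3)) {
  stopifnot(capacity >= 1L, length(alphas) %in% c(3L, 4L),
            all(alphas >= 0), all(alphas <= 1),
            abs(sum(alphas) - 1) < 1e-8)
  structure(list(members = list(), n = n, capacity = as.integer(capacity),
                 alphas = alphas,
                 inst_cover = integer(n),
                 attr_cover = integer(),   # named
                 total_supp = 0L, total_attr = 0L,
                 keys = character(),
                 seq = integer(), next_seq = 1L),
            class = "redescription_set")
}

#' Instance-redundancy score of a redescription w.r.t. a set
#'
#' For a member R: the coverage of R's support by the *other* members, summed
#' over supp(R), divided by the total coverage mass of the set
#' (sum of all member support sizes). For a candidate outside the set the
#' numerator uses the frequencies of all current members and the denominator
#' additionally counts the candidate's own support. Lower means less
#' redundant.
#'
#' @param R a [redescription()].
#' @param set a [redescription_set()].
#' @param member index of R within the set, or `NULL` for an outside
#'   candidate.
#' @return Numeric in `[0, 1)`.
#' @export
red_score_inst <- function(R, set, member = NULL) {
  s <- length(R$support)
  if (is.null(member)) {
    den <- set$total_supp + s
    if (den == 0) return(0)
    sum(set$inst_cover[R$support]) / den
  } else {
    if (set$total_supp == 0) return(0)
    (sum(set$inst_cover[R$support]) - s) / set$total_supp
  }
}

#' Attribute-redundancy score of a redescription w.r.t. a set
#'
#' Analogue of [red_score_inst()] over the (distinct) attributes used in the
#' redescription's queries and the set's attribute-usage counters.
#'
#' @inheritParams red_score_inst
#' @return Numeric in `[0, 1)`.
#' @export
red_score_attr <- function(R, set, member = NULL) {
  a <- R$attrs
  k <- length(a)
  cov <- set$attr_cover[a]
  cov[is.na(cov)] <- 0L
  if (is.null(member)) {
    den <- set$total_attr + k
    if (den == 0) return(0)
    sum(cov) / den
  } else {
    if (set$total_attr == 0) return(0)
    (sum(cov) - k) / set$total_attr
  }
}

#' Total redescription score
#'
#' `sc(R) = a1 * (1 - accuracy) + a2 * redScoreInst + a3 * redScoreAttr`
#' and, when a fourth weight is present,
#' `+ a4 * (1 - constraint score)`. Lower is better. A constraint score of
#' `-Inf` (the strict/soft gate) makes the redescription inadmissible:
#' `total_score` returns `Inf`.
#'
#' @inheritParams red_score_inst
#' @param constraint_score optional constraint-compliance score in `[0, 1]`
#'   or `-Inf` (inadmissible); required iff the set carries four weights.
#' @return Numeric score (lower is better); `Inf` for inadmissible.
#' @export
total_score <- function(R, set, member = NULL, constraint_score = NULL) {
  al <- set$alphas
  sc <- al[1] * (1 - R$jqnm) +
    al[2] * red_score_inst(R, set, member) +
    al[3] * red_score_attr(R, set, member)
  if (length(al) == 4L) {
    if (is.null(constraint_score)) stop("constraint score required (4 weights)")
    if (is.infinite(constraint_score) && constraint_score < 0) return(Inf)
    sc <- sc + al[4] * (1 - constraint_score)
  }
  sc
}

.cover_add <- function(set, R, sign = +1L) {
  set$inst_cover[R$support] <- set$inst_cover[R$support] + sign
  for (a in R$attrs) {
    cur <- set$attr_cover[a]
    set$attr_cover[a] <- if (is.na(cur)) sign else cur + sign
  }
  set$total_supp <- set$total_supp + sign * length(R$support)
  set$total_attr <- set$total_attr + sign * length(R$attrs)
  set
}

.red_key <- function(R) paste(format(R$q1), format(R$q2), sep = " || ")

#' Insert a redescription under the add / replace / discard policy
#'
#' If the set is below capacity the candidate is appended. Otherwise the
#' member with the highest score difference `sc(member) - sc(candidate)` is
#' found (earliest-inserted member on ties) and replaced iff the difference is
#' strictly positive — replacement must improve the set; otherwise the
#' candidate is discarded. Coverage counters are updated on every change. A
#' candidate whose query pair is already in the set is discarded. Candidates
#' with an inadmissible (`-Inf`) constraint score never enter.
#'
#' @param set a [redescription_set()].
#' @param R a quality-screened [redescription()].
#' @param constraint_score see [total_score()].
#' @return The updated set (invisible copy semantics: reassign the result).
#' @export
add_replace_discard <- function(set, R, constraint_score = NULL) {
  cs <- constraint_score
  if (!is.null(cs) && is.infinite(cs) && cs < 0) return(set)
  if (!is.null(cs)) attr(R, "constraint_score") <- cs
  key <- .red_key(R)
  if (key %in% set$keys) return(set)
  if (length(set$members) < set$capacity) {
    set$members[[length(set$members) + 1L]] <- R
    set$keys <- c(set$keys, key)
    set$seq <- c(set$seq, set$next_seq)
    set$next_seq <- set$next_seq + 1L
    return(.cover_add(set, R, +1L))
  }
  cand_sc <- total_score(R, set, member = NULL, constraint_score = cs)
  if (is.infinite(cand_sc)) return(set)
  mem_sc <- vapply(seq_along(set$members), function(i) {
    m <- set$members[[i]]
    total_score(m, set, member = i,
                constraint_score = if (length(set$alphas) == 4L)
                  attr(m, "constraint_score") else NULL)
  }, 0)
  diffs <- mem_sc - cand_sc
  best <- max(diffs)
  if (best <= 0) return(set)
  ties <- which(diffs == best)
  i <- ties[which.min(set$seq[ties])]   # earliest-inserted wins ties
  set <- .cover_add(set, set$members[[i]], -1L)
  set$members[[i]] <- R
  set$keys[i] <- key
  set$seq[i] <- set$next_seq
  set$next_seq <- set$next_seq + 1L
  .cover_add(set, R, +1L)
}

# From-scratch counter recomputation (consistency checks / tests).
recompute_covers <- function(set) {
  inst <- integer(set$n)
  attrc <- integer()
  for (R in set$members) {
    inst[R$support] <- inst[R$support] + 1L
    for (a in R$attrs) {
      cur <- attrc[a]
      attrc[a] <- if (is.na(cur)) 1L else cur + 1L
    }
  }
  list(inst_cover = inst, attr_cover = attrc,
       total_supp = sum(vapply(set$members, function(R) length(R$support), 0L)),
       total_attr = sum(vapply(set$members, function(R) length(R$attrs), 0L)))
}

#' @export
print.redescription_set <- function(x, ...) {
  cat(sprintf("Redescription set: %d / %d members\n",
              length(x$members), x$capacity))
  if (length(x$members)) {
    j <- vapply(x$members, function(R) R$jqnm, 0)
    s <- vapply(x$members, function(R) length(R$support), 0L)
    cat(sprintf("  Jqnm: min %.3f, median %.3f, max %.3f\n",
                min(j), stats::median(j), max(j)))
    cat(sprintf("  support size: min %d, median %d, max %d\n",
                min(s), as.integer(stats::median(s)), max(s)))
  }
  invisible(x)
}

#' @export
summary.redescription_set <- function(object, ...) {
  df <- as.data.frame(object)
  structure(list(table = df, capacity = object$capacity),
            class = "summary.redescription_set")
}

#' @export
print.summary.redescription_set <- function(x, ...) {
  cat(sprintf("Redescription set (%d members, capacity %d)\n",
              nrow(x$table), x$capacity))
  print(utils::head(x$table[order(-x$table$jqnm), ], 10), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.redescription_set <- function(x, ...) {
  if (length(x$members) == 0L)
    return(data.frame(q1 = character(), q2 = character(),
                      support = integer(), jqnm = numeric(),
                      pvalue = numeric(), n_attrs = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    q1 = vapply(x$members, function(R) format(R$q1), ""),
    q2 = vapply(x$members, function(R) format(R$q2), ""),
    support = vapply(x$members, function(R) length(R$support), 0L),
    jqnm = vapply(x$members, function(R) R$jqnm, 0),
    pvalue = vapply(x$members, function(R) R$pvalue, 0),
    n_attrs = vapply(x$members, function(R) length(R$attrs), 0L),
    stringsAsFactors = FALSE)
}

#' @export
plot.redescription_set <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df) == 0L) {
    graphics::plot.new(); graphics::title("empty redescription set")
    return(invisible(x))
  }
  graphics::plot(df$support, df$jqnm, xlab = "support size |E11|",
                 ylab = "query non-missing Jaccard", ylim = c(0, 1),
                 pch = 19, col = grDevices::adjustcolor("steelblue", 0.6), ...)
  invisible(x)
}
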