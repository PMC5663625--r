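# Attribute-constraint handling: strict / soft / suggested mining modes and
# the constraint-compliance scores.

#' Attribute constraint specification
#'
#' A family of attribute sets `C = {C1, ..., Cn}` the user wants redescription
#' queries to involve, plus a mode:
#' \describe{
#'   \item{strict}{a redescription is admissible only if all attributes of
#'     some `Ci` occur in its queries;}
#'   \item{soft}{admissible only if it shares at least one attribute with
#'     some `Ci`; compliance is additionally rewarded by the score;}
#'   \item{suggested}{every redescription is admissible; compliance only
#'     raises the score.}
#' }
#' Constraints are attribute-level; a `granularity` slot is kept for future
#' instance-level constraints.
#'
#' @param sets list of non-empty character vectors of attribute names.
#' @param mode one of `"strict"`, `"soft"`, `"suggested"`.
#' @param granularity currently only `"attribute"`.
#' @return Object of class `constraint_spec`.
#' @examples
#' constraint_spec(list(c("SPARE_AD")), mode = "strict")
#' @export
constraint_spec <- function(sets, mode = c("strict", "soft", "suggested"),
                            granularity = "attribute") {
  mode <- match.arg(mode)
  granularity <- match.arg(granularity)
  if (length(sets) == 0L) stop("need at least one constraint set")
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    if (length(s) == 0L) stop("constraint sets must be non-empty")
    s
  })
  structure(list(sets = sets, mode = mode, granularity = granularity),
            class = "constraint_spec")
}

validate_constraints <- function(C, data) {
  known <- data$attrs$name
  bad <- setdiff(unlist(C$sets), known)
  if (length(bad))
    stop("constraint attributes not in the dataset: ",
         paste(bad, collapse = ", "))
  invisible(C)
}

#' Constraint-compliance score
#'
#' `1/2 * max_i |attrs(R) n Ci| / |Ci| + 1/2 * |attrs(R) n (U Ci)| / |attrs(R)|`:
#' the first term rewards covering a large fraction of a single constraint
#' set, the second rewards queries whose attributes mostly come from the
#' constrained attributes. Equals 1 iff some `Ci` is fully contained in
#' `attrs(R)` and every query attribute is constrained.
#'
#' @param attrs character vector of the redescription's (distinct) query
#'   attributes, or a [redescription()].
#' @param C a [constraint_spec()].
#' @return Numeric in `[0, 1]`; 0 for an empty attribute set.
#' @examples
#' constraint_score(c("a", "b", "c"), constraint_spec(list(c("a", "d"))))  # 5/12
#' @export
constraint_score <- function(attrs, C) {
  if (inherits(attrs, "redescription")) attrs <- attrs$attrs
  if (length(attrs) == 0L) return(0)
  frac_best <- max(vapply(C$sets,
                          function(Ci) length(intersect(attrs, Ci)) / length(Ci),
                          0))
  allC <- unique(unlist(C$sets))
  0.5 * frac_best + 0.5 * length(intersect(attrs, allC)) / length(attrs)
}

#' Soft-mode constraint score
#'
#' The compliance score when the redescription shares at least one attribute
#' with some constraint set; `-Inf` (inadmissible) otherwise.
#'
#' @inheritParams constraint_score
#' @return Numeric in `[0, 1]` or `-Inf`.
#' @export
soft_constraint_score <- function(attrs, C) {
  if (inherits(attrs, "redescription")) attrs <- attrs$attrs
  hit <- any(vapply(C$sets, function(Ci) length(intersect(attrs, Ci)) > 0, NA))
  if (!hit) return(-Inf)
  constraint_score(attrs, C)
}

#' Strict-mode constraint score
#'
#' 1 when all attributes of some constraint set occur among the
#' redescription's query attributes; `-Inf` (inadmissible) otherwise.
#'
#' @inheritParams constraint_score
#' @return 1 or `-Inf`.
#' @export
strict_constraint_score <- function(attrs, C) {
  if (inherits(attrs, "redescription")) attrs <- attrs$attrs
  ok <- any(vapply(C$sets, function(Ci) all(Ci %in% attrs), NA))
  if (ok) 1 else -Inf
}

# Mode dispatch used by the engine.
constraint_mode_score <- function(attrs, C) {
  switch(C$mode,
         strict = strict_constraint_score(attrs, C),
         soft = soft_constraint_score(attrs, C),
         suggested = constraint_score(attrs, C))
}

#' Admissibility of a rule pair under attribute constraints
#'
#' Pre-filter applied before a rule pair is evaluated into a redescription:
#' in strict mode the pair's combined attribute set must contain some
#' constraint set in full; in soft mode it must intersect some constraint
#' set; in suggested mode every pair is admissible (constraints act through
#' the score only).
#'
#' @param q1,q2 conjunctive queries (opposite views).
#' @param C a [constraint_spec()] or `NULL` (no constraints: admissible).
#' @return Logical.
#' @export
pair_admissible <- function(q1, q2, C) {
  if (is.null(C)) return(TRUE)
  attrs <- unique(c(query_attrs(q1), query_attrs(q2)))
  switch(C$mode,
         strict = any(vapply(C$sets, function(Ci) all(Ci %in% attrs), NA)),
         soft = any(vapply(C$sets,
                           function(Ci) length(intersect(attrs, Ci)) > 0, NA)),
         suggested = TRUE)
}
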