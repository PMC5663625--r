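# Post-hoc redescription-set analytics: support-set label entropy, per
# view-pair attribute co-occurrence tables, and normality-screened
# correlation reporting.

#' Shannon entropy of class labels within a support set
#'
#' `H = -sum(p_i * log2(p_i))` over the label classes occurring in the
#' support, with `p_i` the within-support class frequency (plug-in
#' estimator). 0 means the described group is label-homogeneous; the maximum
#' is `log2` of the number of classes present.
#'
#' @param R a [redescription()], or an integer vector of instance indices.
#' @param labels per-instance class labels (factor or vector) covering every
#'   instance.
#' @return Entropy in bits.
#' @examples
#' support_entropy(1:4, c("AD", "AD", "CN", "CN"))  # 1 bit
#' @export
support_entropy <- function(R, labels) {
  idx <- if (inherits(R, "redescription")) R$support else as.integer(R)
  if (length(idx) == 0L) stop("empty support set has no entropy")
  if (max(idx) > length(labels)) stop("labels do not cover all instances")
  cls <- labels[idx]
  if (anyNA(cls)) stop("missing labels inside the support set")
  p <- as.numeric(table(as.character(cls)))
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p)) + 0   # `+ 0` normalises IEEE negative zero
}

#' Entropy summary per support-size interval
#'
#' Groups a redescription set's members by support-size interval and reports
#' entropy distribution summaries per group.
#'
#' @param set a [redescription_set()].
#' @param labels per-instance class labels.
#' @param intervals list of `c(lo, hi)` support intervals.
#' @return Data frame with one row per interval (n, min/median/mean/max
#'   entropy).
#' @export
entropy_by_interval <- function(set, labels,
                                intervals = list(c(5, 10), c(11, 39),
                                                 c(40, 99), c(100, Inf))) {
  ent <- vapply(set$members, support_entropy, 0, labels = labels)
  supp <- vapply(set$members, function(R) length(R$support), 0L)
  rows <- lapply(intervals, function(iv) {
    sel <- supp >= iv[1] & supp <= iv[2]
    e <- ent[sel]
    data.frame(interval = sprintf("[%g,%g]", iv[1], iv[2]), n = sum(sel),
               min = if (any(sel)) min(e) else NA_real_,
               median = if (any(sel)) stats::median(e) else NA_real_,
               mean = if (any(sel)) mean(e) else NA_real_,
               max = if (any(sel)) max(e) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attribute co-occurrence tables by view pair
#'
#' Counts, over all redescriptions of a set, how often each unordered
#' attribute pair occurs together in one redescription's queries. Counts are
#' kept separately per view-pair class (e.g. bio-bio, clin-clin, bio-clin)
#' given a tag per attribute; each unordered pair is counted once per
#' redescription.
#'
#' @param set a [redescription_set()].
#' @param view_map named character vector mapping attribute name to a view
#'   tag (e.g. `c(x1 = "bio", y1 = "clin")`).
#' @return Named list of data frames `(attribute_a, attribute_b, count)`
#'   sorted by decreasing count; names are the view-pair classes
#'   (`"bio-bio"` etc.).
#' @export
cooccurrence_tables <- function(set, view_map) {
  members <- if (inherits(set, "redescription_set")) set$members else set
  tally <- new.env(parent = emptyenv())
  for (R in members) {
    a <- sort(unique(R$attrs))
    if (length(a) < 2L) next
    miss <- setdiff(a, names(view_map))
    if (length(miss))
      stop("attributes without a view tag: ", paste(miss, collapse = ", "))
    cmb <- utils::combn(a, 2L)
    for (k in seq_len(ncol(cmb))) {
      pr <- cmb[, k]
      cls <- paste(sort(view_map[pr]), collapse = "-")
      key <- paste(cls, pr[1], pr[2], sep = "\r")
      cur <- get0(key, envir = tally, ifnotfound = 0L)
      assign(key, cur + 1L, envir = tally)
    }
  }
  keys <- ls(tally)
  tags <- sort(unique(view_map))
  # all unordered tag pairs
  classes <- unique(unlist(lapply(seq_along(tags), function(i)
    vapply(seq(i, length(tags)), function(j)
      paste(sort(c(tags[i], tags[j])), collapse = "-"), ""))))
  out <- lapply(classes, function(cls) {
    sel <- keys[startsWith(keys, paste0(cls, "\r"))]
    if (length(sel) == 0L)
      return(data.frame(attribute_a = character(), attribute_b = character(),
                        count = integer(), stringsAsFactors = FALSE))
    parts <- do.call(rbind, strsplit(sel, "\r", fixed = TRUE))
    df <- data.frame(attribute_a = parts[, 2], attribute_b = parts[, 3],
                     count = vapply(sel, function(k) get(k, envir = tally), 0L),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df[order(-df$count, df$attribute_a, df$attribute_b), , drop = FALSE]
  })
  names(out) <- classes
  out
}

#' Correlation of an attribute pair with a normality screen
#'
#' Drops incomplete pairs, screens each attribute for normality with a
#' one-sample Kolmogorov-Smirnov test against a normal distribution with
#' estimated mean and standard deviation, and reports the Pearson
#' correlation when both attributes pass the screen (p >= `alpha`) and
#' neither is declared ordinal; otherwise the Spearman rank correlation.
#' The estimated-parameter KS screen is approximate (parameters are fitted
#' from the same sample) and is flagged in the result.
#'
#' @param a,b paired numeric observation vectors.
#' @param kinds length-2 character; `"ordinal"` entries force Spearman.
#' @param alpha screen level (default 0.05).
#' @return List with `method` (`"pearson"`/`"spearman"`, `NA` if fewer than 3
#'   complete pairs), `estimate`, `p.value`, `n`, `normal` (screen outcomes)
#'   and `screen` = `"ks-estimated"`.
#' @export
pair_correlation <- function(a, b, kinds = c("numeric", "numeric"),
                             alpha = 0.05) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L)
    return(list(method = NA_character_, estimate = NA_real_,
                p.value = NA_real_, n = n, normal = c(NA, NA),
                screen = "ks-estimated",
                note = "fewer than 3 complete pairs"))
  ks_normal <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(FALSE)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value) >= alpha
  }
  normal <- c(ks_normal(a), ks_normal(b))
  method <- if (all(normal) && !any(kinds == "ordinal")) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(a, b, method = method))
  list(method = method, estimate = unname(ct$estimate),
       p.value = ct$p.value, n = n, normal = normal,
       screen = "ks-estimated")
}

#' Support-vs-control group extraction
#'
#' Returns the values of one attribute split into the redescription's support
#' group and a reference label group (e.g. cognitively normal controls), with
#' missing values dropped, ready for standard two-sample distribution tests
#' (`ks.test`, `wilcox.test`, ...), which this package deliberately does not
#' reimplement.
#'
#' @param R a [redescription()] (or index vector).
#' @param data a [two_view_dataset()].
#' @param attr attribute name.
#' @param control_label label value defining the reference group.
#' @return List with numeric vectors `support` and `control`.
#' @export
group_values <- function(R, data, attr, control_label = "CN") {
  idx <- if (inherits(R, "redescription")) R$support else as.integer(R)
  tab <- if (attr %in% names(data$view1)) data$view1 else data$view2
  if (!attr %in% names(tab)) stop("unknown attribute: ", attr)
  v <- tab[[attr]]
  if (is.null(data$labels)) stop("dataset has no labels")
  ctrl <- which(data$labels == control_label)
  list(support = v[idx][!is.na(v[idx])],
       control = v[ctrl][!is.na(v[ctrl])])
}
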