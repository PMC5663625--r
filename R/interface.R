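# File I/O: delimited two-view input, redescription reports, and query
# string round-tripping. Tab-separated output, "." decimal, p-values in
# scientific notation with 3 significant digits.

.read_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "?", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "", quote = "\"")
}

# numeric if every non-missing cell parses as a number
.infer_types <- function(tab) {
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    num <- suppressWarnings(as.numeric(v))
    if (!any(is.na(num) & !is.na(v))) tab[[j]] <- num
  }
  tab
}

#' Read a two-view dataset from delimited files
#'
#' Each file is CSV (by `.csv` extension) or TSV with a header row; the first
#' column is the instance identifier; empty cells and `"?"` are missing.
#' Instances are aligned by identifier (inner join; a warning reports drops).
#' A column is numeric when all its non-missing cells parse as numbers,
#' otherwise categorical.
#'
#' @param view1_path,view2_path paths to the two view files.
#' @param labels_path optional path to a two-column file (id, label).
#' @return A [two_view_dataset()].
#' @export
read_two_view <- function(view1_path, view2_path, labels_path = NULL) {
  t1 <- .read_table(view1_path); t2 <- .read_table(view2_path)
  id1 <- as.character(t1[[1]]); id2 <- as.character(t2[[1]])
  if (anyDuplicated(id1) || anyDuplicated(id2))
    stop("duplicate instance identifiers in a view file")
  shared <- intersect(id1, id2)
  if (length(shared) == 0L) stop("the views share no instance identifiers")
  dropped <- (length(id1) - length(shared)) + (length(id2) - length(shared))
  if (dropped > 0L)
    warning(sprintf("%d instances present in only one view were dropped", dropped))
  t1 <- .infer_types(t1[match(shared, id1), -1, drop = FALSE])
  t2 <- .infer_types(t2[match(shared, id2), -1, drop = FALSE])
  labels <- NULL
  if (!is.null(labels_path)) {
    lt <- .read_table(labels_path)
    labels <- as.character(lt[[2]])[match(shared, as.character(lt[[1]]))]
  }
  two_view_dataset(t1, t2, ids = shared, labels = labels)
}

#' Parse a query string
#'
#' Inverse of `format()` on a [conjunctive_query()]: understands
#' `lo <= attr <= hi`, `attr = v`, `attr in {a,b}` and the empty query
#' `TRUE`, with conjuncts joined by `&`.
#'
#' @param s query string.
#' @param view which view the query addresses.
#' @return A [conjunctive_query()].
#' @export
parse_query <- function(s, view) {
  s <- trimws(s)
  if (s == "TRUE" || s == "") return(conjunctive_query(view, list()))
  parts <- trimws(strsplit(s, " & ", fixed = TRUE)[[1]])
  conds <- lapply(parts, function(p) {
    if (grepl("<=", p, fixed = TRUE)) {
      m <- regmatches(p, regexec("^(\\S+) <= (\\S+) <= (\\S+)$", p))[[1]]
      if (length(m) != 4L) stop("cannot parse interval condition: ", p)
      cond_interval(m[3], as.numeric(m[2]), as.numeric(m[4]))
    } else if (grepl(" in \\{", p)) {
      m <- regmatches(p, regexec("^(\\S+) in \\{(.*)\\}$", p))[[1]]
      if (length(m) != 3L) stop("cannot parse set condition: ", p)
      cond_equals(m[2], strsplit(m[3], ",", fixed = TRUE)[[1]])
    } else {
      m <- regmatches(p, regexec("^(\\S+) = (.*)$", p))[[1]]
      if (length(m) != 3L) stop("cannot parse condition: ", p)
      cond_equals(m[2], m[3])
    }
  })
  conjunctive_query(view, conds)
}

#' Write redescription reports
#'
#' Writes (a) a human-readable listing (`redescriptions.txt`): both queries in
#' interval/conjunction syntax, support size, accuracy, p-value and — when
#' labels are available — the support's label distribution and entropy;
#' (b) a machine-readable TSV (`redescriptions.tsv`) with the query strings
#' and statistics; (c) optionally a support-membership matrix
#' (`support_matrix.tsv`, instances x redescriptions).
#'
#' @param set a [redescription_set()].
#' @param out_dir output directory (created if needed).
#' @param labels optional per-instance labels.
#' @param support_matrix also write the membership matrix.
#' @return Invisibly, the paths written.
#' @export
write_redescriptions <- function(set, out_dir, labels = NULL,
                                 support_matrix = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(set)
  tsv <- file.path(out_dir, "redescriptions.tsv")
  out <- df
  if (nrow(out)) {
    out$jqnm <- sprintf("%.6f", out$jqnm)
    out$pvalue <- sprintf("%.3g", out$pvalue)
  }
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- file.path(out_dir, "redescriptions.txt")
  con <- file(txt, "w"); on.exit(close(con))
  writeLines(sprintf("# %d redescriptions", length(set$members)), con)
  for (i in seq_along(set$members)) {
    R <- set$members[[i]]
    writeLines(sprintf("R%d:\n  q1: %s\n  q2: %s\n  |E11| = %d, Jqnm = %.6f, p = %.3g",
                       i, format(R$q1), format(R$q2), length(R$support),
                       R$jqnm, R$pvalue), con)
    if (!is.null(labels)) {
      tb <- table(as.character(labels[R$support]))
      writeLines(sprintf("  labels: %s; entropy = %.4f bits",
                         paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
                         support_entropy(R, labels)), con)
    }
  }
  paths <- c(tsv, txt)
  if (support_matrix && length(set$members)) {
    mat <- vapply(set$members, function(R) {
      v <- integer(set$n); v[R$support] <- 1L; v
    }, integer(set$n))
    colnames(mat) <- paste0("R", seq_along(set$members))
    smp <- file.path(out_dir, "support_matrix.tsv")
    utils::write.table(mat, smp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, smp)
  }
  invisible(paths)
}

#' Read a redescription statistics table back
#'
#' Parses the TSV written by [write_redescriptions()] and re-evaluates each
#' query pair on the dataset, so the round trip preserves every query and
#' recomputes every statistic.
#'
#' @param path path to `redescriptions.tsv`.
#' @param data the [two_view_dataset()] the set was mined from.
#' @return List of [redescription()] objects.
#' @export
read_redescriptions <- function(path, data) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  lapply(seq_len(nrow(df)), function(i)
    redescription(parse_query(df$q1[i], 1L), parse_query(df$q2[i], 2L), data))
}

#' Write a two-view dataset (plus ground truth) to delimited files
#'
#' Emits `view1.tsv`, `view2.tsv` (first column `id`), optionally
#' `labels.tsv`, and for generated benchmarks a `truth.tsv` sidecar listing
#' each plant's instances and defining conditions.
#'
#' @param data a [two_view_dataset()].
#' @param out_dir output directory.
#' @param truth optional ground-truth list from [generate_two_view()].
#' @return Invisibly, the paths written.
#' @export
write_two_view <- function(data, out_dir, truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wv <- function(tab, path) {
    out <- cbind(id = data$ids, tab)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "?")
  }
  p1 <- file.path(out_dir, "view1.tsv"); wv(data$view1, p1)
  p2 <- file.path(out_dir, "view2.tsv"); wv(data$view2, p2)
  paths <- c(p1, p2)
  if (!is.null(data$labels)) {
    pl <- file.path(out_dir, "labels.tsv")
    utils::write.table(data.frame(id = data$ids, label = as.character(data$labels)),
                       pl, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pl)
  }
  if (!is.null(truth)) {
    pt <- file.path(out_dir, "truth.tsv")
    df <- do.call(rbind, lapply(seq_along(truth), function(i) {
      tr <- truth[[i]]
      data.frame(plant = i, label = tr$label,
                 q1 = format(tr$q1), q2 = format(tr$q2),
                 instances = paste(data$ids[tr$instances], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(df, pt, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pt)
  }
  invisible(paths)
}
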