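# Shared builders for small in-memory fixtures.

# A dataset with known per-instance query states.
toy_dataset <- function(x = c(1, 5, NA), y = c(0, 1, 1)) {
  two_view_dataset(data.frame(x = x), data.frame(y = y))
}

# Random mixed-type two-view dataset with controllable missingness.
random_dataset <- function(n = 30, k1 = 3, k2 = 3, miss = 0.1, seed = 1,
                           with_cat = TRUE) {
  set.seed(seed)
  mk <- function(k, prefix) {
    cols <- lapply(seq_len(k), function(j) {
      if (with_cat && j == k && k > 1) {
        v <- sample(c("a", "b", "c"), n, replace = TRUE)
      } else {
        v <- round(stats::runif(n, 0, 10), 2)
      }
      if (miss > 0) v[stats::runif(n) < miss] <- NA
      v
    })
    stats::setNames(as.data.frame(cols, stringsAsFactors = FALSE),
                    paste0(prefix, seq_len(k)))
  }
  two_view_dataset(mk(k1, "x"), mk(k2, "y"))
}

# Random conjunctive query over a dataset's view.
random_query <- function(data, view, max_conds = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- if (view == 1) data$view1 else data$view2
  k <- sample(0:max_conds, 1)
  attrs <- sample(names(tab), k)
  conds <- lapply(attrs, function(a) {
    v <- tab[[a]]
    if (is.numeric(v)) {
      b <- sort(stats::runif(2, 0, 10))
      cond_interval(a, b[1], b[2])
    } else {
      cond_equals(a, sample(c("a", "b", "c"), sample(1:2, 1)))
    }
  })
  conjunctive_query(view, conds)
}

# Reference interpreter for three-valued query evaluation: per instance, per
# condition, no vectorisation. The independent oracle for evaluate_query().
eval_query_oracle <- function(q, data) {
  tab <- if (q$view == 1) data$view1 else data$view2
  vapply(seq_len(data$n), function(i) {
    any_missing <- FALSE
    for (cn in q$conditions) {
      v <- tab[[cn$attr]][i]
      if (is.na(v)) { any_missing <- TRUE; next }
      ok <- if (cn$type == "interval") v >= cn$lo && v <= cn$hi
        else as.character(v) %in% cn$values
      if (!ok) return(FALSE)
    }
    if (any_missing) NA else TRUE
  }, NA)
}

# Brute-force binomial upper tail: term-by-term summation.
pvalue_oracle <- function(n, s1, s2, overlap) {
  pr <- (s1 / n) * (s2 / n)
  if (overlap <= 0) return(1)
  sum(vapply(overlap:n, function(k)
    choose(n, k) * pr^k * (1 - pr)^(n - k), 0))
}

# Redescription stub with prescribed support / attributes / accuracy, for
# exercising the set optimiser in isolation. `id` makes the query pair unique.
fake_red <- function(id, support, attrs, jqnm, pvalue = 1e-6) {
  q1 <- conjunctive_query(1, list(cond_equals(attrs[1], paste0("v", id))))
  q2 <- conjunctive_query(2, list(cond_equals(attrs[length(attrs)],
                                              paste0("w", id))))
  structure(list(q1 = q1, q2 = q2, support = as.integer(support),
                 jqnm = jqnm, pvalue = pvalue,
                 attrs = sort(unique(attrs))),
            class = "redescription")
}

# Tri-state vector -> partition via explicit states.
states_partition <- function(s1, s2) {
  dec <- function(s) ifelse(s == "q", NA, s == "1")
  partition_support(dec(s1), dec(s2))
}
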