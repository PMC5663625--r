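test_that("three-valued query evaluation follows conjunction semantics", {
  d <- toy_dataset(x = c(1, 5, NA))
  # empty conjunction is vacuously true everywhere
  expect_identical(evaluate_query(conjunctive_query(1, list()), d),
                   rep(TRUE, 3))
  q <- conjunctive_query(1, list(cond_interval("x", 0, 2)))
  expect_identical(evaluate_query(q, d), c(TRUE, FALSE, NA))
  # a definite violation dominates an unevaluable conjunct
  d2 <- two_view_dataset(data.frame(x = NA_real_, y = 9), data.frame(z = 1))
  q2 <- conjunctive_query(1, list(cond_interval("x", 0, 2),
                                  cond_interval("y", 0, 5)))
  expect_identical(evaluate_query(q2, d2), FALSE)
  expect_error(evaluate_query(conjunctive_query(1, list(cond_interval("nope", 0, 1))), d),
               "unknown attribute")
})

test_that("vectorised evaluation agrees with the per-instance interpreter", {
  for (seed in 1:8) {
    d <- random_dataset(n = 50, miss = 0.15, seed = seed)
    for (view in 1:2) {
      q <- random_query(d, view, max_conds = 3, seed = seed * 100 + view)
      expect_identical(evaluate_query(q, d), eval_query_oracle(q, d),
                       info = sprintf("seed %d view %d", seed, view))
    }
  }
})

test_that("dropping a conjunct never shrinks the in-set nor grows the out-set", {
  for (seed in 1:6) {
    d <- random_dataset(n = 40, miss = 0.2, seed = seed)
    q <- random_query(d, 1, max_conds = 3, seed = seed + 500)
    if (length(q$conditions) == 0) next
    full <- evaluate_query(q, d)
    for (k in seq_along(q$conditions)) {
      sub <- q
      sub$conditions[[k]] <- NULL
      e <- evaluate_query(sub, d)
      expect_true(all(which(!is.na(full) & full) %in% which(!is.na(e) & e)))
      expect_true(all(which(!is.na(e) & !e) %in% which(!is.na(full) & !full)))
    }
  }
})

test_that("support partition assigns each instance to exactly one of nine cells", {
  p <- partition_support(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(unname(p$counts[["E11"]]), 7)
  expect_equal(sum(p$counts), 7)

  p2 <- states_partition(c("1", "1", "q", "0"), c("1", "0", "1", "0"))
  expect_equal(unname(p2$counts[c("E11", "E10", "Eq1", "E00")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(p2$counts), 4)

  p3 <- partition_support(rep(NA, 5), rep(NA, 5))
  expect_equal(unname(p3$counts[["Eqq"]]), 5)

  # property: cells always partition the instance set
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    e1 <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    e2 <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    p <- partition_support(e1, e2)
    expect_equal(sum(p$counts), n)
    expect_equal(sort(unname(unlist(p$cells))), seq_len(n))
  }
  expect_error(partition_support(c(TRUE, TRUE), TRUE), "length")
})

test_that("Jaccard index matches hand arithmetic and edge conventions", {
  expect_equal(jaccard_index(204, 172, 156), 156 / 220)
  expect_equal(round(jaccard_index(204, 172, 156), 3), 0.709)
  expect_equal(jaccard_index(50, 50, 50), 1)
  expect_equal(jaccard_index(10, 10, 0), 0)
  expect_warning(j0 <- jaccard_index(0, 0, 0), "empty")
  expect_equal(j0, 0)
  expect_error(jaccard_index(3, 3, 5), "larger")
})

test_that("query non-missing Jaccard penalises only half-determined instances", {
  # fully observed: equals the plain Jaccard of the same counts
  p <- states_partition(c(rep("1", 204), rep("0", 616)),
                        c(rep("1", 156), rep("0", 48), rep("1", 16), rep("0", 600)))
  expect_equal(qnm_jaccard(p), 156 / 220)

  p1 <- states_partition(rep("1", 10), rep("1", 10))
  expect_equal(qnm_jaccard(p1), 1)

  # E11=5, Eq1=1, E1q=2, E01=1, E10=1 plus ignorable cells -> 5/10
  s1 <- c(rep("1", 5), "q", "1", "1", "0", "1", "0", "q", "0")
  s2 <- c(rep("1", 5), "1", "q", "q", "1", "0", "0", "q", "q")
  p2 <- states_partition(s1, s2)
  expect_equal(unname(p2$counts[c("E11", "Eq1", "E1q", "E01", "E10")]),
               c(5L, 1L, 2L, 1L, 1L))
  expect_equal(qnm_jaccard(p2), 0.5)

  # empty denominator
  expect_equal(qnm_jaccard(states_partition("0", "0")), 0)
})

test_that("Jqnm equals J on fully observed data and stays in [0,1]", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:80, 1)
    e1 <- sample(c(TRUE, FALSE), n, replace = TRUE)
    e2 <- sample(c(TRUE, FALSE), n, replace = TRUE)
    p <- partition_support(e1, e2)
    s1 <- sum(e1); s2 <- sum(e2); ov <- sum(e1 & e2)
    j <- if (s1 + s2 - ov > 0) ov / (s1 + s2 - ov) else 0
    expect_equal(qnm_jaccard(p), j)
  }
  for (i in 1:200) {
    n <- sample(2:80, 1)
    e1 <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    e2 <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    jq <- qnm_jaccard(partition_support(e1, e2))
    expect_gte(jq, 0); expect_lte(jq, 1)
  }
})

test_that("binomial-tail p-value matches term-by-term summation", {
  expect_equal(redescription_pvalue(3, 2, 3, 2), 20 / 27, tolerance = 1e-12)
  expect_equal(redescription_pvalue(17, 5, 9, 0), 1)
  # grid against the brute-force oracle
  for (n in c(4, 9, 16, 25)) {
    for (s1 in unique(c(0, 1, n %/% 3, n))) {
      for (s2 in unique(c(1, n %/% 2, n))) {
        for (ov in unique(c(0, 1, min(s1, s2) %/% 2, min(s1, s2)))) {
          got <- redescription_pvalue(n, s1, s2, ov)
          want <- pvalue_oracle(n, s1, s2, ov)
          if (want > 0) {
            expect_equal(got, want, tolerance = 1e-10,
                         info = sprintf("n=%d s1=%d s2=%d ov=%d", n, s1, s2, ov))
          } else {
            expect_equal(got, 0)
          }
        }
      }
    }
  }
  # non-increasing in overlap
  pv <- vapply(0:20, function(ov) redescription_pvalue(20, 12, 9, ov), 0)
  expect_true(all(diff(pv) <= 1e-15))
  expect_error(redescription_pvalue(0, 0, 0, 0), "positive")
})

test_that("quality screening reports the violated constraints", {
  Q <- quality_constraints(min_jaccard = 0.2, max_pvalue = 0.01,
                           support = c(100, 410), max_length = 8)
  ex <- fake_red(1, seq_len(156), c("a", "b"), jqnm = 0.709, pvalue = 2e-17)
  expect_true(c(check_quality(ex, Q)))

  low_j <- fake_red(2, seq_len(156), "a", jqnm = 0.1, pvalue = 1e-9)
  r <- check_quality(low_j, Q)
  expect_false(c(r)); expect_true("jaccard" %in% attr(r, "reasons"))

  small <- fake_red(3, seq_len(99), "a", jqnm = 0.9, pvalue = 1e-9)
  r2 <- check_quality(small, Q)
  expect_false(c(r2)); expect_true("support" %in% attr(r2, "reasons"))
})

test_that("redescription construction caches a coherent summary", {
  d <- two_view_dataset(data.frame(x = c(1, 2, 9, NA)),
                        data.frame(y = c(0, 0, 1, 0)))
  R <- redescription(conjunctive_query(1, list(cond_interval("x", 0, 5))),
                     conjunctive_query(2, list(cond_equals("y", "0"))), d)
  expect_equal(R$support, c(1L, 2L))
  expect_equal(R$jqnm, qnm_jaccard(R$partition))
  expect_equal(R$attrs, c("x", "y"))
  expect_equal(R$pvalue,
               redescription_pvalue(4, R$supp1, R$supp2, length(R$support)))
  expect_true(is.finite(R$log_pvalue))
})
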