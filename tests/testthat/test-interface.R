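test_that("two-view files align by identifier with missing-token handling", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tx\ty", "s1\t1\ta", "s2\t2.5\tb", "s3\t?\ta"),
             file.path(dir, "v1.tsv"))
  writeLines(c("id\tz", "s2\t0.1", "s3\t0.2", "s4\t0.3"),
             file.path(dir, "v2.tsv"))
  expect_warning(
    d <- read_two_view(file.path(dir, "v1.tsv"), file.path(dir, "v2.tsv")),
    "dropped")
  expect_equal(d$n, 2)
  expect_equal(d$ids, c("s2", "s3"))
  expect_true(is.numeric(d$view1$x))
  expect_true(is.na(d$view1$x[2]))        # "?" parsed as missing
  expect_false(is.numeric(d$view1$y))     # letters stay categorical

  writeLines(c("id,x", "s1,1", "s1,2"), file.path(dir, "dup.csv"))
  expect_error(read_two_view(file.path(dir, "dup.csv"),
                             file.path(dir, "v2.tsv")), "duplicate")
})

test_that("query strings round-trip through format and parse", {
  qs <- list(
    conjunctive_query(1, list(cond_interval("GDTOTAL", 0, 2),
                              cond_equals("GDALIVE", "0"))),
    conjunctive_query(1, list(cond_equals("grp", c("a", "b")))),
    conjunctive_query(1, list(cond_interval("SPARE_AD", -3.86, -0.93))),
    conjunctive_query(1, list()))
  for (q in qs) {
    back <- parse_query(format(q), 1)
    expect_equal(format(back), format(q))
  }
})

test_that("redescription reports round-trip through write and read", {
  sim <- generate_two_view(plant_spec(n = 100, attrs1 = 3, attrs2 = 3,
    plants = list(list(size = 30, k1 = 1, k2 = 1)), seed = 12))
  d <- sim$data
  s <- redescription_set(d$n, capacity = 10)
  s <- add_replace_discard(s, redescription(sim$truth[[1]]$q1,
                                            sim$truth[[1]]$q2, d))
  q1 <- conjunctive_query(1, list(cond_interval("bio2", 10, 60)))
  q2 <- conjunctive_query(2, list(cond_interval("clin2", 5, 80)))
  s <- add_replace_discard(s, redescription(q1, q2, d))
  dir <- withr::local_tempdir()
  paths <- write_redescriptions(s, dir, labels = d$labels,
                                support_matrix = TRUE)
  expect_true(all(file.exists(paths)))
  back <- read_redescriptions(file.path(dir, "redescriptions.tsv"), d)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(format(back[[i]]$q1), format(s$members[[i]]$q1))
    expect_equal(format(back[[i]]$q2), format(s$members[[i]]$q2))
    expect_equal(back[[i]]$jqnm, s$members[[i]]$jqnm)
    expect_equal(back[[i]]$support, s$members[[i]]$support)
  }
  # empty set: header-only files, still readable
  s0 <- redescription_set(d$n, capacity = 5)
  write_redescriptions(s0, dir)
  expect_length(read_redescriptions(file.path(dir, "redescriptions.tsv"), d), 0)
})

test_that("dataset files round-trip including the ground-truth sidecar", {
  sim <- generate_two_view(plant_spec(n = 60, attrs1 = 2, attrs2 = 2,
    plants = list(list(size = 20, k1 = 1, k2 = 1)), missing = 0.1, seed = 7))
  dir <- withr::local_tempdir()
  write_two_view(sim$data, dir, truth = sim$truth)
  d2 <- read_two_view(file.path(dir, "view1.tsv"), file.path(dir, "view2.tsv"),
                      file.path(dir, "labels.tsv"))
  expect_equal(d2$n, 60)
  expect_equal(names(d2$view1), names(sim$data$view1))
  expect_equal(which(is.na(d2$view1$bio1)), which(is.na(sim$data$view1$bio1)))
  expect_equal(as.character(d2$labels), as.character(sim$data$labels))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
})

test_that("the command line drives simulate, mine and analyze end to end", {
  cli <- system.file("cli", "clusrm.R", package = "clusrm")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  run <- function(...) {
    suppressWarnings(system2(rscript, c(cli, ...),
                             stdout = TRUE, stderr = TRUE))
  }
  out1 <- run("simulate", "--out", file.path(dir, "sim"), "--seed", "5",
              "--n", "150", "--attrs1", "4", "--attrs2", "4",
              "--plant-size", "50")
  expect_null(attr(out1, "status"))
  out2 <- run("mine", "--view1", file.path(dir, "sim", "view1.tsv"),
              "--view2", file.path(dir, "sim", "view2.tsv"),
              "--labels", file.path(dir, "sim", "labels.tsv"),
              "--out", file.path(dir, "mined"), "--seed", "5",
              "--support", "25:100", "--jmin", "0.5", "--max-iter", "3",
              "--capacity", "20")
  expect_null(attr(out2, "status"))
  expect_true(file.exists(file.path(dir, "mined", "redescriptions.tsv")))
  out3 <- run("analyze",
              "--redescriptions", file.path(dir, "mined", "redescriptions.tsv"),
              "--view1", file.path(dir, "sim", "view1.tsv"),
              "--view2", file.path(dir, "sim", "view2.tsv"),
              "--labels", file.path(dir, "sim", "labels.tsv"),
              "--out", file.path(dir, "analysis"))
  expect_null(attr(out3, "status"))
  expect_true(file.exists(file.path(dir, "analysis", "entropy.tsv")))
  # a bad path exits non-zero with a one-line diagnostic
  bad <- run("mine", "--view1", "missing.tsv", "--view2", "missing2.tsv",
             "--out", file.path(dir, "x"))
  expect_false(is.null(attr(bad, "status")))
})

test_that("strict constrained mining from the command line honours the constraint", {
  cli <- system.file("cli", "clusrm.R", package = "clusrm")
  rscript <- file.path(R.home("bin"), "Rscript")
  dir <- withr::local_tempdir()
  run <- function(...) suppressWarnings(
    system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE))
  run("simulate", "--out", file.path(dir, "sim"), "--seed", "5",
      "--n", "150", "--attrs1", "4", "--attrs2", "4", "--plant-size", "50")
  writeLines("bio1", file.path(dir, "constraints.txt"))
  out <- run("mine-constrained",
             "--view1", file.path(dir, "sim", "view1.tsv"),
             "--view2", file.path(dir, "sim", "view2.tsv"),
             "--out", file.path(dir, "cmined"), "--seed", "5",
             "--support", "25:100", "--jmin", "0.5", "--max-iter", "3",
             "--capacity", "20",
             "--constraints", file.path(dir, "constraints.txt"),
             "--mode", "strict")
  expect_null(attr(out, "status"))
  tab <- utils::read.table(file.path(dir, "cmined", "redescriptions.tsv"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_gt(nrow(tab), 0)
  expect_true(all(grepl("bio1", paste(tab$q1, tab$q2))))
})
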