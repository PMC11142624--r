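test_that("gmt parsing collapses duplicates and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2\tG2", "SETC\tdesc\tG3\tG4"), path)
  sets <- load_gmt(path)
  expect_setequal(as.character(sets$SETA), c("G1", "G2"))
  expect_length(sets$SETA, 2L)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1", "SETB\tdesc"), bad)
  expect_error(load_gmt(bad), "line 2")

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1", "SETA\tdesc\tG2"), dup)
  expect_error(load_gmt(dup), "duplicate set name")
})

test_that("gmt reading agrees with the fgsea reader on valid files", {
  skip_if_not_installed("fgsea")
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\td1\tA\tB\tC", "SET2\td2\tB\tD\tE\tF"), path)
  ours <- load_gmt(path)
  theirs <- fgsea::gmtPathways(path)
  expect_identical(names(ours), names(theirs))
  for (nm in names(ours))
    expect_setequal(as.character(ours[[nm]]), theirs[[nm]])
})

test_that("hypergeometric p-values match the explicit tail-sum oracle", {
  # the forced extreme: all 10 query genes inside a set of 20 in 100
  universe <- sprintf("U%03d", 1:100)
  sets <- list(HIT = universe[1:20])
  res <- ora_test(universe[1:10], sets, universe, min_size = 20)
  expect_equal(res$p, hyper_tail_oracle(10, 20, 10, 100), tolerance = 1e-12)

  # k = 0 -> upper tail is exactly 1
  res0 <- ora_test(universe[21:30], sets, universe, min_size = 20)
  expect_equal(res0$k, 0L)
  expect_equal(res0$p, 1)

  # randomized instances, N <= 500
  set.seed(61)
  for (rep in 1:60) {
    N <- sample(50:500, 1L)
    uni <- sprintf("R%04d", seq_len(N))
    K <- sample(20:min(100, N), 1L)
    n <- sample(5:min(80, N), 1L)
    sets_r <- list(S = sample(uni, K))
    query <- sample(uni, n)
    res_r <- ora_test(query, sets_r, uni, min_size = 20)
    k <- length(intersect(query, sets_r$S))
    expect_equal(res_r$p, hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("the minimum effective set size gates sets at exactly 20", {
  universe <- sprintf("U%03d", 1:100)
  sets <- list(SIZE19 = universe[1:19], SIZE20 = universe[1:20],
               PADDED = c(universe[1:19], "NOT_IN_UNIVERSE"))
  res <- ora_test(universe[1:10], sets, universe)
  expect_identical(sort(res$set), "SIZE20")  # 19 and 19-effective excluded
  res2 <- ora_test(universe[1:10], sets, universe, min_size = 19)
  expect_setequal(res2$set, c("SIZE19", "SIZE20", "PADDED"))
})

test_that("results are deterministic and invariant to set-file ordering", {
  universe <- sprintf("U%03d", 1:200)
  set.seed(71)
  sets <- lapply(1:8, function(i) sample(universe, 30))
  names(sets) <- sprintf("S%02d", 1:8)
  query <- sample(universe, 40)
  res_fwd <- ora_test(query, sets, universe)
  res_rev <- ora_test(query, rev(sets), universe)
  expect_identical(res_fwd, res_rev)
  expect_false(is.unsorted(res_fwd$p_adj))
  expect_true(all(res_fwd$p_adj >= res_fwd$p))
})

test_that("validation errors cover empty inputs and out-of-universe queries", {
  universe <- sprintf("U%03d", 1:50)
  sets <- list(S = universe[1:25])
  expect_error(ora_test(character(), sets, universe), "empty query")
  expect_error(ora_test("U001", sets, character()), "empty universe")
  expect_warning(res <- ora_test(c("U001", "ALIEN"), sets, universe,
                                 min_size = 10), "outside the universe")
  expect_equal(res$n[1], 1L)
})

test_that("Benjamini-Hochberg adjustment follows the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand-computed step-up on an uneven vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.6)
  manual <- pmin(1, rev(cummin(rev(p * 5 / seq_len(5)))))
  expect_equal(bh_adjust(p), manual)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher dependency testing matches full margin-fixed enumeration", {
  mk_table <- function(a, b, c_, d) {
    # build an annotation table whose DOMAIN/PTM presence realises (a,b,c,d)
    rows <- c(rep("11", a), rep("10", b), rep("01", c_), rep("00", d))
    tbl <- assemble_table(list())
    for (i in seq_along(rows)) {
      r <- as.list(stats::setNames(rep("", 23), ANNOTATION_COLUMNS))
      r$event_id <- sprintf("E%03d", i)
      r$p_value <- r$fdr <- r$dpsi <- NA_real_
      if (substr(rows[i], 1, 1) == "1") r$domain <- "D"
      if (substr(rows[i], 2, 2) == "1") r$ptm <- "P"
      tbl <- rbind(tbl, as.data.frame(r, check.names = FALSE))
    }
    tbl
  }
  res <- feature_dependency_test(mk_table(10, 10, 10, 10), "DOMAIN", "PTM")
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)

  res2 <- feature_dependency_test(mk_table(5, 1, 1, 5), "DOMAIN", "PTM")
  expect_equal(res2$p, fisher_enum_oracle(5, 1, 1, 5), tolerance = 1e-10)
  expect_equal(res2$odds_ratio, 25)

  set.seed(83)
  for (rep in 1:20) {
    cells <- sample(1:12, 4L, replace = TRUE)
    r <- feature_dependency_test(mk_table(cells[1], cells[2], cells[3],
                                          cells[4]), "DOMAIN", "PTM")
    expect_equal(r$p, fisher_enum_oracle(cells[1], cells[2], cells[3],
                                         cells[4]), tolerance = 1e-10)
  }

  # zero cell -> Haldane-corrected sample odds ratio
  res3 <- feature_dependency_test(mk_table(4, 0, 3, 5), "DOMAIN", "PTM")
  expect_equal(res3$odds_ratio, (4.5 * 5.5) / (0.5 * 3.5))

  # all-zero margin -> degenerate
  expect_error(feature_dependency_test(mk_table(0, 0, 4, 4), "DOMAIN", "PTM"),
               "degenerate")
  expect_error(feature_dependency_test(mk_table(1, 1, 1, 1), "DOMAIN",
                                       "NOPE"), "unknown class")
})
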