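test_that("published per-site index scores reproduce from the survey matrix", {
  fx <- antisana_fixture()
  s <- score_all_sites(fx$community, fx$bmwp_col)
  got <- stats::setNames(s$score, s$site)
  expect_identical(got[["AL3"]], 9L)
  expect_identical(got[["H2"]], 82L)
  expect_identical(got[["H1"]], 75L)
  expect_identical(got[["J1B"]], 74L)
  expect_identical(got[["H3"]], 69L)
  expect_identical(got[["H4"]], 61L)
  expect_identical(got[["A1"]], 58L)
  expect_identical(got[["H5"]], 57L)
  expect_identical(got[["J1A"]], 47L)
  expect_identical(range(got), c(9L, 82L))
  ## classes follow the published grouping of the survey table
  cls <- stats::setNames(s$class, s$site)
  expect_identical(unname(cls[names(fx$classes)]), unname(fx$classes))
})

test_that("ABI tolerance table reproduces the published site values", {
  fx <- antisana_fixture()
  s <- score_all_sites(fx$community, abi_table())
  got <- stats::setNames(s$score, s$site)
  expect_identical(got[["H1"]], 60L)
  expect_identical(got[["H2"]], 66L)
  expect_identical(got[["AL3"]], 6L)
  expect_identical(range(got), c(6L, 66L))
  expect_identical(stats::setNames(s$class, s$site)[c("H1", "H2")],
                   c(H1 = "good", H2 = "good"))
})

test_that("worked two-family example scores 9, very bad", {
  r <- compute_index_score(c("Chironomidae", "Baetidae"), bmwp_col_table())
  expect_identical(r$score, 9L)
  expect_identical(r$class, "very bad")
  expect_identical(r$n_present, 2L)
  expect_identical(r$n_scored, 2L)
})

test_that("empty presence set scores zero with empty counts", {
  r <- compute_index_score(character(), bmwp_col_table())
  expect_identical(r$score, 0L)
  expect_identical(r$n_present, 0L)
  expect_identical(r$n_scored, 0L)
})

test_that("ASPT divides score by scored richness and is NA when undefined", {
  r <- compute_index_score(c("Chironomidae", "Baetidae"), bmwp_col_table())
  expect_equal(compute_aspt(r), 4.5)
  one <- compute_index_score("Gripopterygidae", bmwp_col_table())
  expect_equal(compute_aspt(one), 10)
  none <- compute_index_score("Acari", bmwp_col_table())
  expect_identical(none$n_scored, 0L)
  expect_true(is.na(compute_aspt(none)))
})

test_that("class boundaries follow the published thresholds", {
  sch <- bmwp_col_classes()
  expect_identical(classify_score(c(9, 15, 16, 35, 36, 47, 60, 61, 82, 99, 100, 150), sch),
                   c("very bad", "very bad", "bad", "bad", "poor", "poor",
                     "poor", "moderate", "moderate", "moderate", "good", "good"))
  expect_identical(classify_score(c(34, 35, 58, 59, 96, 97), abi_classes()),
                   c("bad", "regular", "regular", "good", "good", "very good"))
  expect_identical(classify_score(c(34, 35, 49, 50, 89, 90, 120, 121), aambi_classes()),
                   c("bad", "regular", "regular", "good", "good", "very good",
                     "very good", "excellent"))
})

test_that("every score 0..500 maps to exactly one label per scheme", {
  for (sch in list(bmwp_col_classes(), abi_classes(), aambi_classes())) {
    labs <- classify_score(0:500, sch)
    expect_identical(length(labs), 501L)
    expect_false(anyNA(labs))
    ## labels appear in blocks ordered worst -> best
    expect_identical(unique(labs), sch$label)
  }
  expect_error(class_scheme(c(0, 20), c(15, Inf), c("a", "b")), "adjacent")
})

test_that("index score is monotone and additive over presence sets", {
  tb <- bmwp_col_table()
  fams <- names(tb$scores)
  with_seed(99, {
    for (i in 1:50) {
      a <- sample(fams, sample.int(length(fams) - 1, 1))
      extra <- sample(setdiff(fams, a), 1)
      s_a <- compute_index_score(a, tb)$score
      expect_gt(compute_index_score(c(a, extra), tb)$score, s_a)
      expect_lt(compute_index_score(setdiff(a, a[1]), tb)$score, s_a)
      b <- sample(fams, sample.int(length(fams), 1))
      expect_identical(
        compute_index_score(union(a, b), tb)$score +
          compute_index_score(intersect(a, b), tb)$score,
        compute_index_score(a, tb)$score + compute_index_score(b, tb)$score)
    }
  })
})

test_that("scores agree with a brute-force loop-sum on random subsets", {
  fx <- antisana_fixture()
  tb <- fx$bmwp_col
  all_fams <- colnames(fx$community)   # includes the three unscored families
  with_seed(123, {
    for (i in 1:1000) {
      sub <- sample(all_fams, sample.int(length(all_fams), 1))
      expect_identical(compute_index_score(sub, tb)$score,
                       as.integer(loop_sum_score(sub, tb$scores)))
    }
  })
})

test_that("score_all_sites is a pure function with stable ordering", {
  fx <- antisana_fixture()
  tables <- list(fx$bmwp_col, abi_table())
  a <- score_all_sites(fx$community, tables)
  b <- score_all_sites(fx$community, tables)
  expect_identical(a, b)
  expect_identical(unique(a$site), rownames(fx$community))
})

test_that("tolerance tables reject out-of-range scores", {
  expect_error(tolerance_table("x", c(A = 0L), bmwp_col_classes()), "1, 10")
  expect_error(tolerance_table("x", c(A = 11L), bmwp_col_classes()), "1, 10")
  expect_silent(tolerance_table("x", c(A = 10L, B = NA), bmwp_col_classes()))
})
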