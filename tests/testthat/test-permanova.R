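test_that("sums of squares decompose exactly on random instances", {
  for (i in 1:50) {
    cm <- random_community(sample(6:12, 1), 10, seed = 500 + i, p_zero = 0.4)
    cm <- community_matrix(unclass(cm)[rowSums(cm) > 0, , drop = FALSE])
    if (nrow(cm) < 4) next
    d <- bray_curtis(cm)
    g <- with_seed(600 + i, sample(rep(c("x", "y"), length.out = nrow(cm))))
    r <- permanova(d, g, n_perm = 9, seed = 1)
    tab <- r$table
    expect_equal(tab$SS[3], tab$SS[1] + tab$SS[2], tolerance = 1e-9)
    expect_identical(tab$Df[3], nrow(cm) - 1L)
    expect_equal(tab$MS[1], tab$SS[1] / tab$Df[1], tolerance = 1e-12)
    expect_gte(r$p, 1 / (r$n_permutations + 1))
    expect_lte(r$p, 1)
  }
})

test_that("pseudo-F equals the classical one-way ANOVA F on 1-D Euclidean data", {
  with_seed(70, {
    for (i in 1:10) {
      x <- rnorm(12)
      g <- sample(rep(c("a", "b", "c"), each = 4))
      d <- as.matrix(stats::dist(x))
      r <- permanova(d, g, n_perm = 9, seed = 1)
      f_ref <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
      expect_equal(r$f, f_ref, tolerance = 1e-8)
    }
  })
})

test_that("exhaustive p equals brute-force enumeration for N = 6", {
  with_seed(71, {
    x <- c(rnorm(3), rnorm(3) + 2)
  })
  g <- rep(c("a", "b"), each = 3)
  d <- as.matrix(stats::dist(x))
  r <- permanova(d, g, n_perm = 99, seed = 1)   # 20 arrangements -> exhaustive
  expect_true(r$exact)
  expect_identical(r$n_permutations, 20L)
  ## independent brute force over all 6!/(3!3!) assignments via combn
  d2 <- d^2
  f_of <- function(gg) {
    sst <- sum(d2[lower.tri(d2)]) / 6
    ssw <- 0
    for (lev in unique(gg)) {
      idx <- which(gg == lev)
      ssw <- ssw + sum(d2[idx, idx][lower.tri(diag(length(idx)))]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  picks <- utils::combn(6, 3)
  fs <- apply(picks, 2, function(p) {
    gg <- rep("b", 6); gg[p] <- "a"; f_of(gg)
  })
  expect_equal(r$p, mean(fs >= r$f - 1e-12), tolerance = 1e-12)
})

test_that("pseudo-F matches the reference implementation", {
  fx <- antisana_fixture()
  d <- bray_curtis(fx$community)
  r <- permanova(d, fx$classes, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = unname(fx$classes)),
                        permutations = 99)
  expect_equal(r$f, ref$F[1], tolerance = 1e-10)
  expect_equal(r$table$SS[1], ref$SumOfSqs[1], tolerance = 1e-10)
})

test_that("permutation p is invariant to renaming the group labels", {
  cm <- random_community(10, 8, seed = 520, p_zero = 0.3)
  d <- bray_curtis(cm)
  g1 <- rep(c("ctrl", "impact"), each = 5)
  g2 <- rep(c("Z9", "A0"), each = 5)
  r1 <- permanova(d, g1, n_perm = 199, seed = 11)
  r2 <- permanova(d, g2, n_perm = 199, seed = 11)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$f, r2$f)
})

test_that("degenerate groupings are rejected", {
  d <- as.matrix(stats::dist(1:6))
  expect_error(permanova(d, rep("a", 6), seed = 1), "two groups")
  expect_error(permanova(d, c("a", "b", "a"), seed = 1), "one group label per site")
  expect_error(permanova(d, rep("a", 6), n_perm = 9), "seed")
})

test_that("pairwise post hoc applies Benjamini-Hochberg across pairs", {
  ## three well-separated 1-D groups
  with_seed(72, {
    x <- c(rnorm(4, 0, .2), rnorm(4, 5, .2), rnorm(4, 10, .2))
  })
  g <- rep(c("a", "b", "c"), each = 4)
  d <- as.matrix(stats::dist(x))
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 2)
  expect_identical(nrow(pw), 3L)
  expect_equal(pw$p_adjusted, stats::p.adjust(pw$p, method = "BH"))
  ## BH hand computation on a fixed p vector
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.9), method = "BH"),
               c(0.03, 0.03, 0.9))
  ## two groups: single pair, adjustment is a no-op
  pw2 <- pairwise_permanova(d[1:8, 1:8], g[1:8], n_perm = 99, seed = 2)
  expect_identical(nrow(pw2), 1L)
  expect_identical(pw2$p, pw2$p_adjusted)
  ## groups that are exchangeable copies of each other: F = 0, p = 1
  xs <- rep(c(0, 5), 4)
  gs <- rep(c("a", "a", "b", "b"), 2)   # each group holds {0, 5, 0, 5}
  rs <- permanova(as.matrix(stats::dist(xs)), gs, n_perm = 99, seed = 3)
  expect_lt(abs(rs$f), 1e-12)
  expect_gte(rs$p, 0.9)
})

test_that("type-I error under the null is nominal", {
  ## planted-null check at reduced size; the acceptance suite runs the
  ## full 500-replicate version
  n_sim <- 60
  rej <- 0
  for (i in seq_len(n_sim)) {
    cm <- random_community(10, 12, seed = 700 + i, p_zero = 0.3)
    d <- bray_curtis(cm)
    g <- with_seed(800 + i, sample(rep(c("a", "b"), each = 5)))
    r <- permanova(d, g, n_perm = 99, seed = 900 + i)
    if (r$p <= 0.05) rej <- rej + 1
  }
  expect_lt(rej / n_sim, 0.15)
})
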