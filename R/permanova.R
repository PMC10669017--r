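## Permutational multivariate analysis of variance on a dissimilarity
## matrix. Sums of squares are computed from squared inter-point
## dissimilarities: SS_total = sum_{i<j} d_ij^2 / N and the residual
## (within-group) term is the analogous per-group sum divided by the group
## size; the pseudo-F statistic is their ratio of mean squares. Inference is
## by permutation of the group labels: exhaustive enumeration of distinct
## label arrangements when their number is small, seeded random sampling
## with the add-one estimator otherwise.

#' PERMANOVA: permutational multivariate ANOVA
#'
#' @param d symmetric dissimilarity matrix (or `dist`) between sites.
#' @param groups group label per site: a (optionally named) vector matching
#'   the rows of `d`; at least two groups, each non-empty, covering all sites.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutations (mandatory).
#' @param exhaustive_limit when the number of distinct label arrangements is
#'   at most this, enumerate them all instead of sampling; the p-value is
#'   then exact.
#' @return An object of class `permanova`: list with `table` (an ANOVA-style
#'   data frame with Source, Df, SS, MS, F, N.Perm, p), `f`, `p`,
#'   `n_permutations`, `exact`, `seed`.
#' @examples
#' x <- c(0, 0.1, 0.2, 5, 5.1, 5.2)
#' d <- as.matrix(dist(x))
#' permanova(d, rep(c("a", "b"), each = 3), seed = 1)$p
#' @export
permanova <- function(d, groups, n_perm = 9999, seed,
                      exhaustive_limit = 20000) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- .align_groups(groups, rownames(d), n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab == 0)) stop("empty group")
  d2 <- d^2
  f_obs <- .pseudo_f(d2, groups, n, length(tab))
  n_arr <- .n_arrangements(tab)
  if (!is.na(n_arr) && n_arr <= exhaustive_limit) {
    arr <- .enumerate_arrangements(as.integer(tab))
    fs <- vapply(seq_len(nrow(arr)), function(i)
      .pseudo_f(d2, names(tab)[arr[i, ]], n, length(tab))$f, numeric(1))
    p <- sum(fs >= f_obs$f - 1e-12) / length(fs)
    n_used <- length(fs); exact <- TRUE
  } else {
    fs <- numeric(n_perm)
    with_seed(seed, {
      for (i in seq_len(n_perm))
        fs[i] <- .pseudo_f(d2, groups[sample.int(n)], n, length(tab))$f
    })
    p <- (1 + sum(fs >= f_obs$f - 1e-12)) / (1 + n_perm)
    n_used <- n_perm; exact <- FALSE
  }
  a <- length(tab)
  tab_df <- data.frame(
    Source = c("between-classes", "residual", "total"),
    Df = c(a - 1L, n - a, n - 1L),
    SS = c(f_obs$ss_b, f_obs$ss_w, f_obs$ss_t),
    MS = c(f_obs$ss_b / (a - 1), f_obs$ss_w / (n - a), NA),
    F = c(f_obs$f, NA, NA),
    N.Perm = c(n_used, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab_df, f = f_obs$f, p = p,
                 n_permutations = n_used, exact = exact, seed = seed),
            class = "permanova")
}

.align_groups <- function(groups, site_ids, n) {
  g <- as.character(unlist(groups, use.names = FALSE))
  names(g) <- names(groups)
  if (!is.null(names(g)) && !is.null(site_ids)) {
    if (!setequal(names(g), site_ids))
      stop("group labels do not cover the sites of the dissimilarity matrix")
    g <- g[site_ids]
  }
  if (length(g) != n) stop("one group label per site required")
  unname(g)
}

.pseudo_f <- function(d2, groups, n, a) {
  low <- lower.tri(d2)
  ss_t <- sum(d2[low]) / n
  ss_w <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1)
      ss_w <- ss_w + sum(d2[idx, idx][lower.tri(diag(length(idx)))]) / length(idx)
  }
  ss_b <- ss_t - ss_w
  f <- (ss_b / (a - 1)) / (ss_w / (n - a))
  list(f = f, ss_t = ss_t, ss_w = ss_w, ss_b = ss_b)
}

## number of distinct arrangements of the group-label multiset: N!/prod(n_g!)
.n_arrangements <- function(tab) {
  v <- lfactorial(sum(tab)) - sum(lfactorial(tab))
  if (v > log(.Machine$integer.max) + 30) return(NA_real_)
  round(exp(v))
}

## enumerate all distinct multiset permutations of group indices 1..k with
## multiplicities `sizes`; returns a matrix with one arrangement per row
.enumerate_arrangements <- function(sizes) {
  k <- length(sizes)
  recur <- function(sizes) {
    if (sum(sizes) == 0L) return(matrix(integer(0), 1L, 0L))
    out <- list()
    for (g in seq_len(k)) {
      if (sizes[g] > 0L) {
        s2 <- sizes; s2[g] <- s2[g] - 1L
        sub <- recur(s2)
        out[[length(out) + 1L]] <- cbind(g, sub, deparse.level = 0)
      }
    }
    do.call(rbind, out)
  }
  recur(as.integer(sizes))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$f, x$p, if (x$exact) "exact" else "sampled", x$n_permutations))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Pairwise post hoc PERMANOVA with FDR adjustment
#'
#' Runs [permanova()] on every unordered pair of groups and adjusts the
#' permutation p-values across pairs with the Benjamini-Hochberg step-up
#' procedure.
#'
#' @inheritParams permanova
#' @return Data frame with one row per pair: `group1`, `group2`, `f`,
#'   `p`, `p_adjusted`, `n_permutations`, `exact`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 9999, seed,
                               exhaustive_limit = 20000) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  d <- as.matrix(d)
  groups <- .align_groups(groups, rownames(d), nrow(d))
  levs <- unique(groups)
  if (length(levs) < 2) stop("need at least two groups")
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    keep <- groups %in% pairs[, j]
    r <- permanova(d[keep, keep, drop = FALSE], groups[keep], n_perm = n_perm,
                   seed = seed + j, exhaustive_limit = exhaustive_limit)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j], f = r$f, p = r$p,
               n_permutations = r$n_permutations, exact = r$exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("group1", "group2", "f", "p", "p_adjusted",
                 "n_permutations", "exact")]
  rownames(out) <- NULL
  out
}
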