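#' Bray-Curtis dissimilarity between sites
#'
#' BC(i, j) = 1 - 2 * sum_f min(x_if, x_jf) / (sum_f x_if + sum_f x_jf),
#' computed on raw counts by default. On presence/absence input the value
#' equals the Sorensen dissimilarity. A pair of all-zero sites has an
#' undefined ratio; it is reported as 0 with a warning.
#'
#' @param cm a [community_matrix], or any numeric matrix with sites in rows.
#' @param transform `"none"` (default), `"presence"` (reduce counts to 0/1)
#'   or `"sqrt"` (square-root transform before computing).
#' @return Symmetric sites-by-sites matrix in `[0, 1]` with zero diagonal,
#'   with attribute `"method" = "bray-curtis"`.
#' @examples
#' bray_curtis(community_matrix(rbind(a = c(6, 2), b = c(2, 2))))[1, 2]  # 1/3
#' @export
bray_curtis <- function(cm, transform = c("none", "presence", "sqrt")) {
  transform <- match.arg(transform)
  x <- unclass(as.matrix(cm))
  storage.mode(x) <- "double"
  if (transform == "presence") x <- (x > 0) * 1
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  tot <- rowSums(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      denom <- tot[i] + tot[j]
      if (denom == 0) {
        warning(sprintf("sites '%s' and '%s' are both empty; Bray-Curtis set to 0",
                        rownames(x)[i], rownames(x)[j]))
        bc <- 0
      } else {
        bc <- 1 - 2 * sum(pmin(x[i, ], x[j, ])) / denom
      }
      d[i, j] <- d[j, i] <- bc
    }
  }
  attr(d, "method") <- "bray-curtis"
  d
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged). The
#' two-sided p-value is computed by exact enumeration of all n! rank
#' permutations for n <= 9 and by the t approximation
#' t = rho * sqrt((n-2) / (1-rho^2)) otherwise. When either variable has
#' zero rank variance, rho is undefined and returned as `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list with `rho`, `p`, `n` and `method`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  vx <- sum((rx - mean(rx))^2); vy <- sum((ry - mean(ry))^2)
  if (vx == 0 || vy == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rho_of <- function(ryy) sum((rx - mean(rx)) * (ryy - mean(ryy))) / sqrt(vx * vy)
  rho <- rho_of(ry)
  if (n <= 9) {
    perms <- .all_permutations(n)
    stats_ <- (matrix(ry[perms], nrow(perms), n) %*% (rx - mean(rx))) / sqrt(vx * vy)
    ## center of the permuted statistic is 0; two-sided exact tail
    p <- mean(abs(stats_ - mean(stats_)) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    t <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

## all permutations of 1..n as a (n!) x n integer matrix (n <= 9)
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Correlate environmental variables with ordination axes
#'
#' Computes the Spearman rank correlation of each environmental variable
#' against each ordination axis, emulating the usual vector-overlay reading
#' of an NMDS plot.
#'
#' @param ord an [nmds()] result (or any list with a `points` matrix whose
#'   row names are site labels).
#' @param env a data frame of numeric variables with site labels as row names
#'   (or a `site` column).
#' @return Data frame with columns `variable`, `axis`, `rho`, `p`;
#'   zero-variance variables yield `NA` and are flagged in `note`.
#' @export
env_axis_correlations <- function(ord, env) {
  pts <- ord$points
  if (!is.null(env$site)) {
    rownames(env) <- env$site
    env$site <- NULL
  }
  if (!setequal(rownames(pts), rownames(env)))
    stop("site sets of ordination and environmental table differ")
  env <- env[rownames(pts), , drop = FALSE]
  rows <- list()
  for (v in names(env)) {
    for (a in seq_len(ncol(pts))) {
      vec <- env[[v]]
      if (stats::var(vec, na.rm = TRUE) == 0 || all(is.na(vec))) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, axis = a, rho = NA_real_, p = NA_real_,
          note = "zero variance", stringsAsFactors = FALSE)
      } else {
        r <- spearman_cor(vec, pts[, a])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, axis = a, rho = r$rho, p = r$p, note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
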