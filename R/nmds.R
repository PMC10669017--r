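## Non-metric multidimensional scaling, Kruskal stress-1 formulation.
##
## Each restart alternates (a) monotone (isotonic) regression of the current
## configuration distances on the rank order of the input dissimilarities --
## primary treatment of ties: tied dissimilarities impose no order constraint
## among themselves -- and (b) a Guttman transform pulling the configuration
## towards the fitted distances. Stress-1 = sqrt(sum (d - dhat)^2 / sum d^2).

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 over `k`-dimensional configurations. Restart 0
#' starts from the classical metric-scaling solution; subsequent restarts
#' start from seeded random configurations. The best restart is returned;
#' results are deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix (or `dist`) between sites.
#' @param k number of dimensions (default 2); requires `n >= k + 1` sites.
#' @param n_restarts number of starts (first is metric-scaling based).
#' @param max_iter,tol iteration cap and relative stress-improvement
#'   convergence threshold per restart.
#' @param seed integer seed for the random restarts (mandatory, echoed in the
#'   result).
#' @return An object of class `nmds_fit`: list with `points` (n x k, centred),
#'   `stress`, `k`, `n_restarts`, `converged`, `seed`.
#' @examples
#' xy <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' fit <- nmds(as.matrix(dist(xy)), k = 2, n_restarts = 4, seed = 1)
#' fit$stress
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 500, tol = 1e-6, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 sites")
  if (!isSymmetric(unname(d))) stop("dissimilarity matrix must be symmetric")
  low <- which(lower.tri(d))
  diss <- d[low]
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1L) {
        cmd <- suppressWarnings(stats::cmdscale(d, k = k))
        if (ncol(cmd) < k) cbind(cmd, matrix(0, n, k - ncol(cmd))) else cmd
      } else {
        matrix(stats::rnorm(n * k), n, k)
      }
      fit <- .nmds_one(x0, diss, low, n, k, max_iter, tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  rownames(best$points) <- rownames(d)
  structure(list(points = best$points, stress = best$stress, k = k,
                 n_restarts = n_restarts, converged = best$converged,
                 seed = seed),
            class = "nmds_fit")
}

.config_dist <- function(x, low) {
  as.matrix(stats::dist(x))[low]
}

.nmds_one <- function(x, diss, low, n, k, max_iter, tol) {
  x <- sweep(x, 2L, colMeans(x))
  dvec <- .config_dist(x, low)
  stress <- .stress1(dvec, .monotone_fit(dvec, diss))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dhat <- .monotone_fit(dvec, diss)
    xn <- .guttman(x, dhat, low, n)
    dn <- .config_dist(xn, low)
    sn <- .stress1(dn, .monotone_fit(dn, diss))
    if (sn <= stress) {            # accept only non-increasing stress
      improved <- stress - sn
      x <- xn; dvec <- dn; stress <- sn
      if (improved < tol * max(stress, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    } else {
      converged <- TRUE            # Guttman step no longer helps
      break
    }
  }
  list(points = sweep(x, 2L, colMeans(x)), stress = stress, converged = converged)
}

.stress1 <- function(dvec, dhat) {
  ss <- sum(dvec^2)
  if (ss == 0) return(0)
  sqrt(sum((dvec - dhat)^2) / ss)
}

## Isotonic regression of configuration distances on dissimilarity order.
## Primary tie treatment: within blocks of tied dissimilarities the distances
## are sub-ordered by their own value, so ties never generate constraints.
.monotone_fit <- function(dvec, diss) {
  o <- order(diss, dvec)                            # primary ties
  fit <- stats::isoreg(dvec[o])$yf
  out <- numeric(length(dvec))
  out[o] <- fit
  out
}

## Guttman transform: the majorisation update of the configuration towards
## target distances dhat (zero current distances are guarded).
.guttman <- function(x, dhat, low, n) {
  dfull <- as.matrix(stats::dist(x))
  b <- matrix(0, n, n)
  ratio <- numeric(length(low))
  cur <- dfull[low]
  ratio[cur > 0] <- dhat[cur > 0] / cur[cur > 0]
  b[low] <- -ratio
  b <- b + t(b)
  diag(b) <- -rowSums(b)
  (b %*% x) / n
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS (%d sites, k = %d): stress-1 = %.5f (%d restarts, seed %d)%s\n",
              nrow(x$points), x$k, x$stress, x$n_restarts, x$seed,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
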