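## Functional feeding groups: crisp one-group-per-family allocation, site
## composition summaries, and Rao's quadratic entropy on the trait distances.

#' The six functional feeding group labels
#'
#' Collector-filterers (CF), shredders (SH), scrapers (SC), parasites (PA),
#' predators (PR) and collector-gatherers (CG).
#' @export
FFG_LABELS <- c("CF", "SH", "SC", "PA", "PR", "CG")

#' Trait table: family -> functional feeding group
#'
#' Each family carries exactly one FFG label (crisp allocation; fuzzy-coded
#' multi-group affinities are collapsed before analysis).
#'
#' @param x named character vector, family -> label in [FFG_LABELS].
#' @return A validated named character vector of class `trait_table`.
#' @export
trait_table <- function(x) {
  .check_labels(names(x), "family")
  bad <- setdiff(unique(x), FFG_LABELS)
  if (length(bad))
    stop(sprintf("unknown FFG label(s): %s (expected %s)",
                 paste(bad, collapse = ", "), paste(FFG_LABELS, collapse = ", ")))
  structure(x, class = "trait_table")
}

#' Packaged trait table of the Andean survey families
#' @return A [trait_table] for the 20 packaged families.
#' @export
antisana_traits <- function() {
  path <- system.file("extdata", "antisana_taxa.tsv", package = "bioticindices")
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  trait_table(stats::setNames(df$ffg, df$family))
}

#' Aggregate family counts into functional feeding groups
#'
#' Each family's abundance is credited to its FFG; site totals are conserved.
#' All six groups are always reported (zeros for absent groups).
#'
#' @param cm a [community_matrix].
#' @param traits a [trait_table] covering every family of `cm`.
#' @return Integer matrix, sites x 6 FFGs.
#' @examples
#' fx <- antisana_fixture()
#' allocate_ffg(fx$community, fx$traits)
#' @export
allocate_ffg <- function(cm, traits) {
  stopifnot(inherits(cm, "community_matrix"))
  missing <- setdiff(colnames(cm), names(traits))
  if (length(missing))
    stop(sprintf("families without a trait entry: %s", paste(missing, collapse = ", ")))
  g <- factor(unname(traits[colnames(cm)]), levels = FFG_LABELS)
  agg <- t(rowsum(t(unclass(cm)), g))  # sites x groups present
  out <- matrix(0L, nrow(cm), length(FFG_LABELS),
                dimnames = list(rownames(cm), FFG_LABELS))
  out[, colnames(agg)] <- agg
  out
}

#' Per-site functional feeding group composition summary
#'
#' For each site: total abundance, FFG richness (number of the six groups
#' present) and its percentage of 6, then per group the absolute abundance,
#' the relative abundance (% of the site total; `NA` for empty sites) and the
#' number of families carrying that group.
#'
#' @param cm a [community_matrix].
#' @param traits a [trait_table].
#' @return Data frame, one row per site.
#' @export
ffg_summary <- function(cm, traits) {
  agg <- allocate_ffg(cm, traits)
  pres <- presence(cm)
  g <- factor(unname(traits[colnames(cm)]), levels = FFG_LABELS)
  famr <- t(rowsum(t(pres * 1L), g))
  nfam <- matrix(0L, nrow(cm), length(FFG_LABELS),
                 dimnames = list(rownames(cm), FFG_LABELS))
  nfam[, colnames(famr)] <- famr
  total <- rowSums(agg)
  rel <- sweep(agg, 1L, total, "/") * 100
  rel[total == 0, ] <- NA_real_
  out <- data.frame(site = rownames(cm),
                    total_abundance = as.integer(total),
                    ffg_richness = as.integer(rowSums(agg > 0)),
                    ffg_richness_rel = rowSums(agg > 0) / length(FFG_LABELS) * 100,
                    stringsAsFactors = FALSE)
  for (lab in FFG_LABELS) {
    out[[paste0(lab, "_abundance")]] <- agg[, lab]
    out[[paste0(lab, "_rel")]] <- rel[, lab]
    out[[paste0(lab, "_n_families")]] <- nfam[, lab]
  }
  rownames(out) <- NULL
  out
}

#' Pairwise trait dissimilarity between taxa
#'
#' `discrete` mode gives d = 0 for identical FFG and 1 otherwise (the
#' convention used with a single categorical trait). `gower` mode accepts a
#' multi-trait data frame (rows = taxa) and computes the Gower coefficient
#' via [cluster::daisy()]; with a single categorical trait it coincides with
#' `discrete`.
#'
#' @param traits a [trait_table] (single FFG trait) or, for `mode = "gower"`,
#'   a data frame of traits with taxa as row names.
#' @param mode `"discrete"` or `"gower"`.
#' @return Symmetric taxon-by-taxon matrix in `[0, 1]` with zero diagonal.
#' @export
trait_distance_matrix <- function(traits, mode = c("discrete", "gower")) {
  mode <- match.arg(mode)
  if (is.data.frame(traits)) {
    if (mode == "discrete")
      stop("discrete mode expects a single-trait trait_table")
    df <- data.frame(lapply(traits, function(col)
      if (is.character(col)) factor(col) else col), row.names = rownames(traits))
    d <- as.matrix(cluster::daisy(df, metric = "gower"))
    dimnames(d) <- list(rownames(traits), rownames(traits))
    return(d)
  }
  fam <- names(traits)
  if (mode == "gower") {
    df <- data.frame(ffg = factor(unname(traits), levels = FFG_LABELS),
                     row.names = fam)
    d <- as.matrix(cluster::daisy(df, metric = "gower"))
    dimnames(d) <- list(fam, fam)
    return(d)
  }
  d <- 1 - outer(unname(traits), unname(traits), "==") * 1
  diag(d) <- 0
  dimnames(d) <- list(fam, fam)
  d
}

#' Rao's quadratic entropy for one community
#'
#' Q = sum_ij d_ij p_i p_j, the expected trait dissimilarity between two
#' individuals drawn at random (with replacement) from the community, where
#' p are relative abundances. With discrete 0/1 distances on a single trait
#' this equals the Gini-Simpson index 1 - sum_g p_g^2 on the trait-pooled
#' proportions.
#'
#' @param abundances named non-negative numeric vector of per-taxon counts.
#' @param d taxon dissimilarity matrix covering the taxa of `abundances`.
#' @return A list with `q` (NA when total abundance is zero) and `n_taxa`.
#' @examples
#' d <- trait_distance_matrix(trait_table(c(a = "CG", b = "SC")))
#' rao_q(c(a = 10, b = 4), d)  # 2 * (10/14) * (4/14)
#' @export
rao_q <- function(abundances, d) {
  stopifnot(all(abundances >= 0))
  taxa <- names(abundances)
  if (is.null(taxa)) stop("abundances must be named by taxon")
  missing <- setdiff(taxa, rownames(d))
  if (length(missing))
    stop(sprintf("taxa absent from distance matrix: %s", paste(missing, collapse = ", ")))
  total <- sum(abundances)
  if (total == 0) return(list(q = NA_real_, n_taxa = 0L))
  p <- abundances / total
  dm <- d[taxa, taxa, drop = FALSE]
  list(q = as.numeric(p %*% dm %*% p), n_taxa = sum(abundances > 0))
}

#' Rao's quadratic entropy for every site of a community matrix
#'
#' @param cm a [community_matrix].
#' @param traits a [trait_table].
#' @param mode trait distance mode, see [trait_distance_matrix()].
#' @return Data frame with columns `site`, `q`, `n_taxa`, `distance_mode`.
#' @export
rao_all_sites <- function(cm, traits, mode = c("discrete", "gower")) {
  mode <- match.arg(mode)
  d <- trait_distance_matrix(traits[colnames(cm)] |> trait_table(), mode)
  res <- lapply(rownames(cm), function(s) {
    r <- rao_q(stats::setNames(as.numeric(cm[s, ]), colnames(cm)), d)
    data.frame(site = s, q = r$q, n_taxa = r$n_taxa, distance_mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
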