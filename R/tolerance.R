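#' Ordered ecological-condition class scheme
#'
#' A class scheme maps every non-negative integer score to exactly one
#' ordinal condition label. Intervals are closed, integer-valued, disjoint
#' and exhaustive over `[0, Inf)`; labels are ordered worst to best.
#'
#' @param lower,upper integer interval bounds (last `upper` may be `Inf`).
#' @param label condition labels, worst first.
#' @return A `class_scheme` data frame.
#' @examples
#' bmwp_col_classes()
#' @export
class_scheme <- function(lower, upper, label) {
  stopifnot(length(lower) == length(upper), length(lower) == length(label))
  o <- order(lower)
  lower <- lower[o]; upper <- upper[o]; label <- label[o]
  if (lower[1] != 0) stop("class scheme must start at 0")
  if (!is.infinite(upper[length(upper)])) stop("last class must be unbounded above")
  if (length(lower) > 1 && any(lower[-1] != utils::head(upper, -1) + 1))
    stop("class intervals must be adjacent (disjoint and exhaustive)")
  structure(data.frame(lower = lower, upper = upper, label = label,
                       stringsAsFactors = FALSE),
            class = c("class_scheme", "data.frame"))
}

#' Map scores to ecological-condition classes
#'
#' @param score non-negative integer score(s).
#' @param scheme a [class_scheme].
#' @return Character vector of class labels.
#' @examples
#' classify_score(c(9, 47, 82), bmwp_col_classes())
#' @export
classify_score <- function(score, scheme) {
  stopifnot(inherits(scheme, "class_scheme"), all(score >= 0))
  idx <- vapply(score, function(s) which(s >= scheme$lower & s <= scheme$upper),
                integer(1))
  scheme$label[idx]
}

#' Tolerance table for a presence-based biotic index
#'
#' Bundles the per-family tolerance scores (integers 1-10; higher = more
#' sensitive to pollution) with the index's class scheme. Families absent
#' from `scores` simply contribute nothing to the index, matching the index
#' definitions, which ignore unlisted taxa.
#'
#' @param index index name, e.g. `"BMWP-Col"`.
#' @param scores named integer vector, family -> score in `[1, 10]`.
#' @param classes a [class_scheme].
#' @return A `tolerance_table` object.
#' @export
tolerance_table <- function(index, scores, classes) {
  scores <- scores[!is.na(scores)]
  stopifnot(is.character(index), length(index) == 1,
            inherits(classes, "class_scheme"))
  if (length(scores)) {
    .check_labels(names(scores), "family")
    if (any(scores < 1 | scores > 10 | scores != round(scores)))
      stop("tolerance scores must be integers in [1, 10]")
  }
  structure(list(index = index, scores = as.integer(round(scores)) |>
                   stats::setNames(names(scores)),
                 classes = classes),
            class = "tolerance_table")
}

#' @export
print.tolerance_table <- function(x, ...) {
  cat(sprintf("tolerance table '%s': %d scored families, classes %s\n",
              x$index, length(x$scores), paste(x$classes$label, collapse = " < ")))
  invisible(x)
}

## ---- built-in class schemes -------------------------------------------------
## BMWP-Col publishes ">=100 good, 61-100 moderate, 36-60 poor, 16-35 bad,
## 0-15 very bad"; 100 sits in two printed bands and is assigned "good" (the
## ">=" bound is explicit), so moderate runs 61-99.

#' @rdname class_scheme
#' @export
bmwp_col_classes <- function() {
  class_scheme(lower = c(0, 16, 36, 61, 100),
               upper = c(15, 35, 60, 99, Inf),
               label = c("very bad", "bad", "poor", "moderate", "good"))
}

#' @rdname class_scheme
#' @export
abi_classes <- function() {
  class_scheme(lower = c(0, 35, 59, 97),
               upper = c(34, 58, 96, Inf),
               label = c("bad", "regular", "good", "very good"))
}

## The published AAMBI bands omit the integers 35 and 121; each is absorbed
## into the nearest class (35 -> regular, 121 -> excellent) so that
## classification is total.

#' @rdname class_scheme
#' @export
aambi_classes <- function() {
  class_scheme(lower = c(0, 35, 50, 90, 121),
               upper = c(34, 49, 89, 120, Inf),
               label = c("bad", "regular", "good", "very good", "excellent"))
}

## ---- built-in tables --------------------------------------------------------

.read_score_column <- function(file, column) {
  path <- system.file("extdata", file, package = "bioticindices")
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  s <- suppressWarnings(as.integer(df[[column]]))  # "-" -> NA -> dropped
  stats::setNames(s, df$family)
}

#' Built-in tolerance tables
#'
#' `bmwp_col_table()` carries the BMWP-Col scores of the 20 families of the
#' packaged Andean survey (the three families without a published BMWP-Col
#' value are unscored). `abi_table()` is transcribed from the published ABI
#' tolerance list (external provenance; see `inst/extdata/abi_scores.tsv`).
#' `aambi_table()` is a synthetic stand-in calibrated to the survey's printed
#' per-site AAMBI values (see `inst/extdata/aambi_scores_synthetic.tsv`).
#'
#' @return A [tolerance_table].
#' @examples
#' bmwp_col_table()
#' @export
bmwp_col_table <- function() {
  tolerance_table("BMWP-Col",
                  .read_score_column("antisana_taxa.tsv", "score_bmwp_col"),
                  bmwp_col_classes())
}

#' @rdname bmwp_col_table
#' @export
abi_table <- function() {
  tolerance_table("ABI", .read_score_column("abi_scores.tsv", "score_abi"),
                  abi_classes())
}

#' @rdname bmwp_col_table
#' @export
aambi_table <- function() {
  tolerance_table("AAMBI",
                  .read_score_column("aambi_scores_synthetic.tsv", "score_aambi"),
                  aambi_classes())
}

#' Read a tolerance table from TSV
#'
#' Expects columns `family` and the requested score column; `"-"` marks an
#' unscored family.
#'
#' @param path TSV path.
#' @param index index name stored in the result.
#' @param column score column name (default `paste0("score_", tolower(index))`
#'   with non-alphanumerics as underscores).
#' @param classes a [class_scheme].
#' @return A [tolerance_table].
#' @export
read_tolerance_table <- function(path, index, classes,
                                 column = paste0("score_", gsub("[^a-z0-9]+", "_", tolower(index)))) {
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  if (!column %in% names(df)) stop(sprintf("no column '%s' in %s", column, path))
  s <- suppressWarnings(as.integer(df[[column]]))
  tolerance_table(index, stats::setNames(s, df$family), classes)
}

## ---- scoring ----------------------------------------------------------------

#' Score one site's presence set under a biotic index
#'
#' The index score is the sum of the tolerance scores of the scored families
#' present; unscored families count towards richness (`n_present`) but not
#' towards the sum or `n_scored`.
#'
#' @param present character vector of (canonicalized) families present.
#' @param table a [tolerance_table].
#' @return A list with `score`, `class`, `n_present`, `n_scored` and `index`.
#' @examples
#' compute_index_score(c("Chironomidae", "Baetidae"), bmwp_col_table())
#' @export
compute_index_score <- function(present, table) {
  stopifnot(inherits(table, "tolerance_table"))
  present <- unique(present)
  scored <- present[present %in% names(table$scores)]
  score <- sum(table$scores[scored])
  list(index = table$index,
       score = as.integer(score),
       class = classify_score(score, table$classes),
       n_present = length(present),
       n_scored = length(scored))
}

#' Average score per taxon (ASPT)
#'
#' The index score divided by the number of scored families present. With no
#' scored family the ratio is undefined and `NA` is returned.
#'
#' @param result a result of [compute_index_score()], or a score when
#'   `n_scored` is given.
#' @param n_scored number of scored families (when `result` is a bare score).
#' @return Numeric ASPT value, `NA` if undefined.
#' @examples
#' compute_aspt(compute_index_score(c("Chironomidae", "Baetidae"), bmwp_col_table()))
#' @export
compute_aspt <- function(result, n_scored = NULL) {
  if (is.list(result)) {
    n_scored <- result$n_scored
    result <- result$score
  }
  if (is.null(n_scored) || n_scored == 0) return(NA_real_)
  result / n_scored
}

#' Score every site of a community matrix under one or more indices
#'
#' @param cm a [community_matrix] (counts or presence).
#' @param tables a [tolerance_table] or list of them.
#' @param aspt also append the average score per taxon column.
#' @return A data frame with one row per (site, index), in input site order:
#'   `site`, `index`, `score`, `class`, `n_present`, `n_scored` (and `aspt`).
#' @examples
#' fx <- antisana_fixture()
#' score_all_sites(fx$community, fx$bmwp_col)
#' @export
score_all_sites <- function(cm, tables, aspt = FALSE) {
  stopifnot(inherits(cm, "community_matrix"))
  if (inherits(tables, "tolerance_table")) tables <- list(tables)
  rows <- list()
  for (tb in tables) {
    for (s in rownames(cm)) {
      r <- compute_index_score(site_presence(cm, s), tb)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, index = r$index, score = r$score, class = r$class,
        n_present = r$n_present, n_scored = r$n_scored,
        aspt = compute_aspt(r), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), index = character(), score = integer(),
               class = character(), n_present = integer(), n_scored = integer(),
               aspt = numeric())
  if (!aspt) out$aspt <- NULL
  rownames(out) <- NULL
  out
}
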