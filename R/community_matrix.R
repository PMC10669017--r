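#' Community matrix of macroinvertebrate counts
#'
#' Builds the central data container of the package: a sites-by-families
#' matrix of non-negative integer abundances. Presence/absence surveys are
#' stored as counts in \{0, 1\}; `presence()` derives the logical presence
#' matrix, so every downstream index works identically for abundance and
#' presence data.
#'
#' @param counts numeric matrix (or object coercible to one) of non-negative
#'   integers. By default rows are sites and columns are families; see
#'   `orientation`.
#' @param site_ids,family_ids optional character vectors overriding the
#'   dimnames of `counts`. Labels must be unique and non-empty.
#' @param orientation `"sites-in-rows"` (default) or `"sites-in-columns"`
#'   (the canonical file layout, families in rows, is transposed on input).
#' @return An object of class `community_matrix`: an integer matrix with
#'   sites in rows and families in columns.
#' @examples
#' cm <- community_matrix(rbind(s1 = c(3, 0), s2 = c(1, 2)),
#'                        family_ids = c("Baetidae", "Chironomidae"))
#' presence(cm)
#' @export
community_matrix <- function(counts, site_ids = NULL, family_ids = NULL,
                             orientation = c("sites-in-rows", "sites-in-columns")) {
  orientation <- match.arg(orientation)
  counts <- as.matrix(counts)
  if (orientation == "sites-in-columns") counts <- t(counts)
  if (!is.null(site_ids)) rownames(counts) <- site_ids
  if (!is.null(family_ids)) colnames(counts) <- family_ids
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0)
    colnames(counts) <- paste0("family", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  if (anyNA(counts)) stop("community matrix contains missing values")
  if (any(counts < 0)) stop("community matrix contains negative counts")
  if (any(counts != round(counts))) stop("community matrix counts must be integers")
  storage.mode(counts) <- "integer"
  .check_labels(rownames(counts), "site")
  .check_labels(colnames(counts), "family")
  structure(counts, class = c("community_matrix", "matrix"))
}

.check_labels <- function(x, what) {
  if (any(!nzchar(x)) || anyNA(x)) stop(sprintf("empty %s label", what))
  dup <- unique(x[duplicated(x)])
  if (length(dup))
    stop(sprintf("duplicate %s labels: %s", what, paste(dup, collapse = ", ")))
  invisible(x)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community matrix: %d sites x %d families (total count %d)\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @rdname community_matrix
#' @param cm a `community_matrix`.
#' @export
presence <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  cm > 0L
}

#' Families present at one site
#'
#' @param cm a `community_matrix`.
#' @param site a site label present in `cm`.
#' @return Character vector of family names with positive counts at `site`.
#' @export
site_presence <- function(cm, site) {
  stopifnot(inherits(cm, "community_matrix"))
  if (!site %in% rownames(cm)) stop(sprintf("unknown site '%s'", site))
  colnames(cm)[cm[site, ] > 0L]
}

#' Read a community matrix from delimited text
#'
#' Accepts the two layouts used in practice for benthic survey tables:
#' * `wide` - one row per family (canonical) or per site, one column per
#'   site/family. Cells may be counts, or presence marks (`"p"`, `"P"`,
#'   `"1"`); blank, `"0"` or missing cells mean absent.
#' * `long` - three columns `site`, `family`, `count` (header required).
#'
#' @param source path to a file, or a character vector of lines.
#' @param layout `"wide"` or `"long"`.
#' @param orientation for wide input, whether sites are the columns
#'   (`"sites-in-columns"`, the canonical survey-table layout) or the rows.
#' @param sep field separator; default tab.
#' @return A [community_matrix].
#' @export
read_community_matrix <- function(source, layout = c("wide", "long"),
                                  orientation = c("sites-in-columns", "sites-in-rows"),
                                  sep = "\t") {
  layout <- match.arg(layout)
  orientation <- match.arg(orientation)
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE)) {
    if (!file.exists(source)) stop(sprintf("file not found: %s", source))
    df <- utils::read.delim(source, sep = sep, check.names = FALSE,
                            colClasses = "character", comment.char = "#",
                            blank.lines.skip = TRUE, fill = TRUE)
  } else {
    df <- utils::read.delim(text = source, sep = sep, check.names = FALSE,
                            colClasses = "character", comment.char = "#",
                            blank.lines.skip = TRUE, fill = TRUE)
  }
  if (layout == "long") {
    need <- c("site", "family", "count")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: site, family, count")
    cnt <- .parse_cells(df$count, df$site, df$family)
    sites <- unique(df$site); fams <- unique(df$family)
    if (anyDuplicated(paste(df$site, df$family, sep = "\r")))
      stop("duplicate (site, family) pairs in long input")
    m <- matrix(0L, length(sites), length(fams), dimnames = list(sites, fams))
    m[cbind(match(df$site, sites), match(df$family, fams))] <- cnt
    return(community_matrix(m))
  }
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  parsed <- .parse_cells(as.vector(m),
                         rep(labels, ncol(m)),
                         rep(colnames(m), each = nrow(m)))
  m2 <- matrix(parsed, nrow(m), ncol(m), dimnames = list(labels, colnames(m)))
  if (orientation == "sites-in-columns") {
    community_matrix(m2, orientation = "sites-in-columns")
  } else {
    community_matrix(m2)
  }
}

## parse a cell vector: counts, presence marks, blanks; error names the cell
.parse_cells <- function(x, row_lab, col_lab) {
  x <- trimws(x)
  out <- integer(length(x))
  blank <- is.na(x) | x == "" | x == "0"
  mark <- !blank & tolower(x) == "p"
  out[mark] <- 1L
  rest <- !blank & !mark
  val <- suppressWarnings(as.numeric(x[rest]))
  bad <- is.na(val) | val < 0 | val != round(val)
  if (any(bad)) {
    i <- which(rest)[which(bad)[1L]]
    stop(sprintf("cannot parse cell '%s' (row '%s', column '%s') as a non-negative count",
                 x[i], row_lab[i], col_lab[i]))
  }
  out[rest] <- as.integer(val)
  out
}

#' Write a community matrix in the canonical layout
#'
#' Canonical layout: families in rows, sites in columns, tab-separated,
#' first column named `family`. `write` then `read` round-trips both the
#' values and the row/column order.
#'
#' @param cm a [community_matrix].
#' @param path output file path.
#' @param presence_marks write `"p"` for presence and blank for absence
#'   instead of counts (only sensible for presence/absence data).
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path, presence_marks = FALSE) {
  stopifnot(inherits(cm, "community_matrix"))
  m <- t(unclass(cm))  # families in rows
  cells <- if (presence_marks) ifelse(m > 0L, "p", "") else format(m, trim = TRUE)
  lines <- c(paste(c("family", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(cells, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Normalise family spellings against a synonym table
#'
#' Lookup is case-insensitive and whitespace-trimmed. Names found in the
#' synonym map are replaced by their canonical spelling; names already
#' canonical are case-corrected; unknown names pass through unchanged and are
#' flagged (attribute `"unknown"`, plus a warning unless `quiet = TRUE`).
#'
#' @param x character vector of family names.
#' @param synonyms named character vector `synonym -> canonical`; defaults to
#'   the packaged synonym table.
#' @param canonical optional character vector of known canonical names used
#'   for case correction (defaults to the canonical values of `synonyms`).
#' @param quiet suppress the unknown-name warning.
#' @return `x` with canonical spellings, with a logical attribute `"unknown"`.
#' @export
canonicalize_family_name <- function(x, synonyms = default_family_synonyms(),
                                     canonical = NULL, quiet = FALSE) {
  key <- tolower(trimws(x))
  canon <- unique(c(canonical, unname(synonyms)))
  out <- trimws(x)
  hit_syn <- match(key, tolower(names(synonyms)))
  out[!is.na(hit_syn)] <- unname(synonyms)[hit_syn[!is.na(hit_syn)]]
  hit_can <- match(key, tolower(canon))
  use <- is.na(hit_syn) & !is.na(hit_can)
  out[use] <- canon[hit_can[use]]
  unknown <- is.na(hit_syn) & is.na(hit_can)
  if (any(unknown) && !quiet)
    warning(sprintf("unknown family name(s): %s",
                    paste(unique(out[unknown]), collapse = ", ")))
  attr(out, "unknown") <- unknown
  out
}

#' @rdname canonicalize_family_name
#' @export
default_family_synonyms <- function() {
  path <- system.file("extdata", "family_synonyms.tsv", package = "bioticindices")
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  stats::setNames(df$canonical, df$synonym)
}

#' Cross-check a community matrix against tolerance and trait tables
#'
#' Reports, without modifying anything, which families of the matrix carry no
#' tolerance score under each supplied index and which have no functional
#' feeding group assignment.
#'
#' @param cm a [community_matrix].
#' @param tables a single [tolerance_table] or a list of them.
#' @param traits optional trait table (named character vector family -> FFG).
#' @return A list with one character vector of unscored families per index,
#'   and `missing_ffg` when `traits` is given.
#' @export
validate_against_tables <- function(cm, tables, traits = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  if (inherits(tables, "tolerance_table")) tables <- list(tables)
  fams <- colnames(cm)
  report <- lapply(tables, function(tb) fams[!fams %in% names(tb$scores)])
  names(report) <- vapply(tables, function(tb) tb$index, character(1))
  if (!is.null(traits)) report$missing_ffg <- fams[!fams %in% names(traits)]
  report
}
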