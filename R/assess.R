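## End-to-end assessment: score -> classify -> FFG -> Rao -> ordination ->
## PERMANOVA, with every output written as CSV plus a JSON manifest carrying
## the seeds and options, so a run is reproducible from (inputs, config).

#' Run configuration for a full assessment
#'
#' Collects all inputs and options of [run_full_assessment()]. A YAML file
#' with the same flat keys can be loaded with [read_run_config()]; arguments
#' given here override the file.
#'
#' @param matrix path to a community matrix (TSV) or a [community_matrix].
#' @param layout,orientation passed to [read_community_matrix()] when
#'   `matrix` is a path.
#' @param indices character subset of `c("bmwp_col", "abi", "aambi")`.
#' @param traits path to a taxa TSV with columns `family`, `ffg`, or a
#'   [trait_table], or `NULL` to skip the trait stages.
#' @param transform Bray-Curtis input transform, see [bray_curtis()].
#' @param distance_mode Rao trait distance mode.
#' @param k,n_restarts NMDS dimensions and restarts.
#' @param n_perm PERMANOVA permutations.
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(matrix, layout = "wide", orientation = "sites-in-columns",
                       indices = c("bmwp_col", "abi", "aambi"),
                       traits = NULL, transform = "none",
                       distance_mode = "discrete", k = 2, n_restarts = 20,
                       n_perm = 9999, seed = 1, out_dir = "assessment") {
  indices <- match.arg(indices, several.ok = TRUE)
  structure(list(matrix = matrix, layout = layout, orientation = orientation,
                 indices = indices, traits = traits, transform = transform,
                 distance_mode = distance_mode, k = k, n_restarts = n_restarts,
                 n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with flat keys mirroring the `run_config` arguments.
#' @param ... overrides applied on top of the file's values.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(run_config, vals)
}

#' Run the full bioassessment pipeline and write a report bundle
#'
#' Stages: read/validate the community matrix; score the selected biotic
#' indices and classify every site; allocate functional feeding groups and
#' summarise their composition; compute Rao's quadratic entropy; compute the
#' Bray-Curtis matrix, an NMDS ordination and a PERMANOVA of the community
#' against the best-supported index's condition classes (plus pairwise post
#' hoc comparisons when more than two classes occur). Any stage failure
#' raises an error naming the stage.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_full_assessment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(f) file.path(config$out_dir, f)
  written <- character()
  emit <- function(df, f) {
    utils::write.csv(df, outfile(f), row.names = FALSE)
    written <<- c(written, f)
  }

  cm <- stage("read", {
    if (inherits(config$matrix, "community_matrix")) config$matrix
    else read_community_matrix(config$matrix, layout = config$layout,
                               orientation = config$orientation)
  })

  tables <- stage("score", {
    builders <- list(bmwp_col = bmwp_col_table, abi = abi_table,
                     aambi = aambi_table)
    lapply(config$indices, function(i) builders[[i]]())
  })
  scores <- stage("score", score_all_sites(cm, tables, aspt = TRUE))
  emit(scores, "scores.csv")

  traits <- NULL
  if (!is.null(config$traits)) {
    traits <- stage("ffg", {
      if (inherits(config$traits, "trait_table")) config$traits
      else {
        df <- utils::read.delim(config$traits, comment.char = "#",
                                colClasses = "character")
        trait_table(stats::setNames(df$ffg, df$family))
      }
    })
    emit(stage("ffg", ffg_summary(cm, traits)), "ffg_summary.csv")
    emit(stage("rao", rao_all_sites(cm, traits, mode = config$distance_mode)),
         "rao.csv")
  }

  d <- stage("dissimilarity", bray_curtis(cm, transform = config$transform))
  emit(data.frame(site = rownames(d), as.data.frame(d), check.names = FALSE),
       "bray_curtis.csv")

  ord <- stage("ordination",
               nmds(d, k = config$k, n_restarts = config$n_restarts,
                    seed = config$seed))
  emit(data.frame(site = rownames(ord$points),
                  as.data.frame(ord$points) |>
                    stats::setNames(paste0("NMDS", seq_len(config$k)))),
       "nmds_coordinates.csv")

  first <- scores[scores$index == tables[[1]]$index, ]
  classes <- stats::setNames(first$class, first$site)
  perm_df <- NULL
  pw <- NULL
  if (length(unique(classes)) >= 2) {
    pr <- stage("permanova",
                permanova(d, classes, n_perm = config$n_perm,
                          seed = config$seed))
    perm_df <- pr$table
    emit(perm_df, "permanova.csv")
    if (length(unique(classes)) > 2) {
      pw <- stage("permanova",
                  pairwise_permanova(d, classes, n_perm = config$n_perm,
                                     seed = config$seed))
      emit(pw, "pairwise_permanova.csv")
    }
  }

  manifest <- list(
    package = "bioticindices",
    version = as.character(utils::packageVersion("bioticindices")),
    seed = config$seed,
    config = config[setdiff(names(config), c("matrix", "traits"))],
    n_sites = nrow(cm), n_families = ncol(cm),
    nmds_stress = ord$stress,
    outputs = written)
  if (inherits(config$matrix, "character")) manifest$matrix <- config$matrix
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
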