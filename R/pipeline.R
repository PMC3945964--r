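# End-to-end orchestration: datasets -> screening -> distances ->
# divergence + boundaries -> identification -> evaluation.

#' Pipeline configuration
#'
#' Describes one full evaluation run over one or more markers.  Each marker
#' entry is either a simulation configuration ([sim_config()]) or a pair of
#' input paths (`fasta`, `meta`).
#'
#' @param markers named list; names are marker codes, values either
#'   `sim_config` objects or lists with elements `fasta` and `meta`
#' @param out_dir output directory for all tables
#' @param seed integer seed controlling any randomness of the run
#' @param grid_step threshold grid step for [error_curves()]
#' @param methods identification methods to evaluate
#' @param thresholds optional named numeric vector of per-marker
#'   tree+threshold cutoffs; markers not listed use the run's own optimal
#'   boundary (self-calibration)
#' @param apply_length_filter logical; run [filter_by_length()] on input
#'   datasets
#' @param its2_full_length full-length constant for the ITS2 filter
#' @param bin_width histogram bin width for [gap_histograms()]
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(markers, out_dir, seed = 1L, grid_step = 1e-4,
                            methods = c("nn", "best-hit", "tree", "tree+threshold"),
                            thresholds = NULL, apply_length_filter = FALSE,
                            its2_full_length = NULL, bin_width = 0.01) {
  stopifnot(is.list(markers), length(markers) >= 1L, !is.null(names(markers)))
  structure(list(markers = markers, out_dir = out_dir, seed = as.integer(seed),
                 grid_step = grid_step, methods = methods,
                 thresholds = thresholds,
                 apply_length_filter = apply_length_filter,
                 its2_full_length = its2_full_length, bin_width = bin_width),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full marker-assessment pipeline
#'
#' For every configured marker: load or simulate the dataset, optionally
#' length-filter, trim to the common region, screen unpublished records on
#' a neighbour-joining tree, assemble evaluation sets 1-3, compute the K2P
#' distance matrix, the six-parameter divergence summary with gap
#' histograms, the threshold scan, and the identification success rates of
#' every requested method with set 2 as queries against set 1.  Finishes
#' with Duncan letter tables comparing markers and methods on the per-genus
#' success rates, and writes a JSON manifest of all parameters.  The run is
#' a pure function of the configuration; repeated runs produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with per-marker results (`datasets`, `summary`,
#'   `scan`, `reports`) and the Duncan tables
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  results <- list()
  rate_by_method <- list()
  rate_by_marker <- list()

  for (marker in names(config$markers)) {
    spec <- config$markers[[marker]]
    mdir <- file.path(config$out_dir, marker)
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)

    ds <- .stage(paste0(marker, ":load"), {
      if (inherits(spec, "sim_config")) {
        sim <- simulate_dataset(spec)
        write_tsv(sim$truth, file.path(mdir, "truth.tsv"))
        sim$dataset
      } else {
        read_marker_dataset(spec$fasta, spec$meta, marker = marker)
      }
    })
    if (isTRUE(config$apply_length_filter)) {
      ds <- .stage(paste0(marker, ":filter"),
                   filter_by_length(ds, full_length = config$its2_full_length))
    }
    ds <- .stage(paste0(marker, ":trim"), trim_to_common_region(ds))

    mat_all <- .stage(paste0(marker, ":distances"), distance_matrix(ds))
    if (any(ds$records$status == "unpublished")) {
      ds <- .stage(paste0(marker, ":screen"), {
        scr <- screen_unpublished(nj_tree(mat_all), ds)
        write_tsv(attr(scr, "screening"), file.path(mdir, "screening.tsv"))
        scr
      })
    }
    sets <- .stage(paste0(marker, ":sets"), build_evaluation_sets(ds))
    for (nm in names(sets)) {
      write_marker_dataset(sets[[nm]], file.path(mdir, paste0(nm, ".fasta")),
                           file.path(mdir, paste0(nm, "_meta.tsv")))
    }

    mat1 <- .stage(paste0(marker, ":distances"),
                   distance_matrix(sets$set1))
    write_distance_tsv(mat1, file.path(mdir, "set1_k2p.tsv"))

    summ <- .stage(paste0(marker, ":divergence"), divergence_summary(mat1, sets$set1))
    write_divergence_tables(summ, mdir)
    hist <- .stage(paste0(marker, ":histograms"),
                   gap_histograms(summ$per_species, summ$per_genus,
                                  bin_width = config$bin_width))
    write_gap_histogram(hist, file.path(mdir, "gap_histogram.tsv"))

    scan <- .stage(paste0(marker, ":boundaries"),
                   error_curves(mat1, sets$set1, grid_step = config$grid_step))
    write_threshold_scan(scan, file.path(mdir, "threshold_scan.tsv"))

    thr <- if (!is.null(config$thresholds) && marker %in% names(config$thresholds)) {
      config$thresholds[[marker]]
    } else {
      optimal_threshold(scan)
    }

    union_set <- .union_datasets(sets$set1, sets$set2)
    mat_u <- distance_matrix(union_set)
    tree_u <- nj_tree(mat_u)
    reports <- list()
    for (method in config$methods) {
      rep <- .stage(paste0(marker, ":evaluate:", method),
                    run_evaluation(sets$set2, sets$set1, method = method,
                                   threshold = if (method == "tree+threshold") thr,
                                   mat = mat_u, tree = tree_u))
      write_evaluation_report(rep, mdir)
      reports[[method]] <- rep
      rate_by_method[[method]] <- c(rate_by_method[[method]],
                                    rep$per_genus$success_rate)
      if (method == "nn") {
        rate_by_marker[[marker]] <- rep$per_genus$success_rate
      }
    }

    results[[marker]] <- list(dataset = ds, sets = sets, matrix = mat1,
                              summary = summ, histogram = hist, scan = scan,
                              threshold_used = thr, reports = reports)
  }

  duncan <- list()
  ok_groups <- function(g) length(g) >= 2L && all(vapply(g, length, 0L) >= 2L) &&
    any(vapply(g, stats::var, 0) > 0)
  if (ok_groups(rate_by_method)) {
    duncan$methods <- .stage("duncan:methods",
                             duncan_multiple_range(rate_by_method))
    write_tsv(duncan$methods$table, file.path(config$out_dir, "duncan_methods.tsv"))
  }
  if (ok_groups(rate_by_marker)) {
    duncan$markers <- .stage("duncan:markers",
                             duncan_multiple_range(rate_by_marker))
    write_tsv(duncan$markers$table, file.path(config$out_dir, "duncan_markers.tsv"))
  }

  manifest <- list(
    package = "barcodeval",
    version = as.character(utils::packageVersion("barcodeval")),
    seed = config$seed,
    grid_step = config$grid_step,
    methods = config$methods,
    thresholds = as.list(config$thresholds),
    markers = lapply(config$markers, function(s) {
      if (inherits(s, "sim_config")) unclass(s) else s
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(results, list(duncan = duncan)))
}
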