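# Identification success-rate evaluation and group comparison.

#' Score sequence-identification success of one method on one marker
#'
#' Every query is identified against the reference set with the chosen
#' decision rule; when the query itself occurs in the reference set it is
#' removed from the reference for its own identification (otherwise every
#' rate would trivially approach 100%).  A query is correct when the call
#' state is `assigned` and the assigned species equals the query's labelled
#' species (whitespace/case-normalized exact match; synonyms are not
#' resolved).  Uncertain and no-hit calls count as incorrect.
#'
#' For the tree-based rules a single neighbour-joining tree is built from
#' the union of the reference and query records, and each query is read off
#' that tree (its own leaf is the query; all other leaves act as
#' references).
#'
#' @param query_set [marker_dataset()] of queries (e.g. set 2)
#' @param reference_set [marker_dataset()] of references (e.g. set 1)
#' @param method one of `"nn"`, `"best-hit"`, `"tree"`, `"tree+threshold"`
#' @param threshold distance threshold for `"tree+threshold"`
#' @param mat optional precomputed `k2p_dist` over the union of reference
#'   and query records (computed on demand otherwise)
#' @param tree optional precomputed `phylo` tree over the union
#' @param ... further arguments passed to [best_hit_identify()]
#' @return object of class `evaluation_report`: list with `marker`,
#'   `method`, counts (`n_queries`, `n_correct`, `n_wrong`, `n_uncertain`,
#'   `n_nohit`), `success_rate`, `per_genus` breakdown and the full `calls`
#'   table
#' @export
run_evaluation <- function(query_set, reference_set,
                           method = c("nn", "best-hit", "tree", "tree+threshold"),
                           threshold = NULL, mat = NULL, tree = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(query_set, "marker_dataset"),
            inherits(reference_set, "marker_dataset"))
  if (nrow(query_set$records) == 0L) stop("query set is empty")
  if (method == "tree+threshold" &&
      (is.null(threshold) || !is.numeric(threshold) || threshold <= 0)) {
    stop("method 'tree+threshold' needs a positive threshold")
  }
  missing_sp <- setdiff(query_set$records$species, reference_set$records$species)
  if (length(missing_sp)) {
    warning("query species absent from reference: ",
            paste(missing_sp, collapse = ", "))
  }

  union_set <- .union_datasets(reference_set, query_set)
  needs_mat <- method %in% c("nn", "tree", "tree+threshold")
  if (needs_mat && is.null(mat)) mat <- distance_matrix(union_set)
  if (method %in% c("tree", "tree+threshold") && is.null(tree)) tree <- nj_tree(mat)
  species_map <- stats::setNames(union_set$records$species, union_set$records$id)

  calls <- lapply(seq_len(nrow(query_set$records)), function(i) {
    qid <- query_set$records$id[i]
    switch(method,
      "nn" = nn_identify(qid, mat, subset_records(union_set,
                                                  setdiff(union_set$records$id, qid))),
      "best-hit" = best_hit_identify(query_set$records[i, ], union_set, ...),
      "tree" = liberal_tree_identify(tree, qid, species_map[names(species_map) != qid]),
      "tree+threshold" = liberal_tree_threshold_identify(
        tree, qid, species_map[names(species_map) != qid], mat, threshold))
  })
  ct <- calls_table(calls)
  truth <- .norm_species(query_set$records$species)
  assigned <- .norm_species(ct$assigned_species)
  correct <- ct$state == "assigned" & !is.na(assigned) & assigned == truth
  wrong <- ct$state == "assigned" & !correct
  ct$correct <- correct

  per_genus <- do.call(rbind, lapply(sort(unique(query_set$records$genus)), function(g) {
    idx <- query_set$records$genus == g
    data.frame(genus = g, n_queries = sum(idx), n_correct = sum(correct[idx]),
               success_rate = mean(correct[idx]), stringsAsFactors = FALSE)
  }))

  structure(list(marker = query_set$marker, method = method,
                 n_queries = nrow(ct),
                 n_correct = sum(correct),
                 n_wrong = sum(wrong),
                 n_uncertain = sum(ct$state == "uncertain"),
                 n_nohit = sum(ct$state == "no-hit"),
                 success_rate = mean(correct),
                 per_genus = per_genus,
                 calls = ct),
            class = "evaluation_report")
}

.norm_species <- function(x) {
  out <- tolower(gsub("\\s+", " ", trimws(x)))
  out[is.na(x)] <- NA_character_
  out
}

.union_datasets <- function(a, b) {
  extra <- b$records[!b$records$id %in% a$records$id, , drop = FALSE]
  marker_dataset(rbind(a$records, extra), marker = a$marker, role = "custom")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%s / %s: %d of %d correct (%.2f%%); %d wrong, %d uncertain, %d no-hit\n",
              x$marker, x$method, x$n_correct, x$n_queries,
              100 * x$success_rate, x$n_wrong, x$n_uncertain, x$n_nohit))
  invisible(x)
}

#' Success rate restricted to the queries of one genus
#'
#' The query set is narrowed to one genus while the reference set stays
#' unrestricted.
#'
#' @inheritParams run_evaluation
#' @param genus genus name present in the query set
#' @return an `evaluation_report` for the restricted query set
#' @export
genus_restricted_rate <- function(query_set, reference_set, genus,
                                  method = c("nn", "best-hit", "tree", "tree+threshold"),
                                  threshold = NULL, ...) {
  stopifnot(inherits(query_set, "marker_dataset"))
  idx <- which(query_set$records$genus == genus)
  if (!length(idx)) stop("genus '", genus, "' not present in the query set")
  run_evaluation(subset_records(query_set, idx, role = query_set$role),
                 reference_set, method = method, threshold = threshold, ...)
}

#' Duncan's multiple range test
#'
#' Compares group means with Duncan's stepwise procedure: groups are sorted
#' by mean and ranges of p consecutive means are tested against the least
#' significant range `q * sqrt(MSE / n_h)`, where `q` is the studentized
#' range quantile at protection level `(1 - alpha)^(p - 1)` and `n_h` the
#' harmonic mean group size.  A range found non-significant is not
#' subdivided further.  Groups sharing a letter are statistically
#' indistinguishable at level `alpha`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with >= 2
#'   replicate values)
#' @param alpha significance level (default 0.05)
#' @return object of class `duncan_test`: data frame-bearing list with
#'   `table` (group, n, mean, letters, sorted by decreasing mean), `mse`,
#'   `df`, `alpha`
#' @export
duncan_multiple_range <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named")
  }
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2L)) stop("every group needs at least 2 replicates")
  k <- length(groups)
  N <- sum(sizes)
  means <- vapply(groups, mean, 0)
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df <- N - k
  mse <- sse / df
  if (mse == 0) stop("zero within-group variance across all groups: test undefined")
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  n_h <- k / sum(1 / sizes)
  se <- sqrt(mse / n_h)
  lsr <- function(p) stats::qtukey((1 - alpha)^(p - 1), p, df) * se

  # Step-down testing: a non-significant range is not subdivided, so
  # non-distinct sets form contiguous intervals in the sorted order.
  intervals <- list()
  test_range <- function(i, j) {
    if (i >= j) return(invisible(NULL))
    if (m[i] - m[j] < lsr(j - i + 1L)) {
      intervals[[length(intervals) + 1L]] <<- c(i, j)
    } else {
      test_range(i, j - 1L)
      test_range(i + 1L, j)
    }
  }
  test_range(1L, k)
  # keep maximal intervals only
  if (length(intervals)) {
    keep <- vapply(seq_along(intervals), function(a) {
      !any(vapply(seq_along(intervals), function(b) {
        b != a && intervals[[b]][1L] <= intervals[[a]][1L] &&
          intervals[[b]][2L] >= intervals[[a]][2L]
      }, TRUE))
    }, TRUE)
    intervals <- intervals[keep]
  }
  # singletons not covered by any interval get their own letter
  covered <- rep(FALSE, k)
  for (iv in intervals) covered[iv[1L]:iv[2L]] <- TRUE
  for (i in which(!covered)) intervals[[length(intervals) + 1L]] <- c(i, i)
  starts <- vapply(intervals, `[`, 0, 1L)
  intervals <- intervals[order(starts)]
  letters_of <- rep("", k)
  for (a in seq_along(intervals)) {
    iv <- intervals[[a]]
    letters_of[iv[1L]:iv[2L]] <- paste0(letters_of[iv[1L]:iv[2L]], letters[a])
  }
  structure(list(table = data.frame(group = names(groups)[ord],
                                    n = sizes[ord], mean = m,
                                    letters = letters_of,
                                    row.names = NULL, stringsAsFactors = FALSE),
                 mse = mse, df = df, alpha = alpha),
            class = "duncan_test")
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha=%g, MSE=%.4g, df=%d)\n",
              x$alpha, x$mse, x$df))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %-20s %.4f  %s\n", t$group[i], t$mean[i], t$letters[i]))
  }
  invisible(x)
}

#' Write an evaluation report as TSV files
#'
#' @param report an `evaluation_report`
#' @param dir output directory
#' @return invisibly, the paths written
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- gsub("[^a-zA-Z0-9]+", "_", paste(report$marker, report$method, sep = "_"))
  p1 <- file.path(dir, paste0(tag, "_calls.tsv"))
  p2 <- file.path(dir, paste0(tag, "_per_genus.tsv"))
  p3 <- file.path(dir, paste0(tag, "_summary.tsv"))
  write_tsv(report$calls, p1)
  write_tsv(report$per_genus, p2)
  write_tsv(data.frame(marker = report$marker, method = report$method,
                       n_queries = report$n_queries, n_correct = report$n_correct,
                       n_wrong = report$n_wrong, n_uncertain = report$n_uncertain,
                       n_nohit = report$n_nohit,
                       success_rate = report$success_rate), p3)
  invisible(c(p1, p2, p3))
}
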