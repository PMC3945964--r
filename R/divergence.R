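# Divergence parameters within and between species.
#
# Six headline parameters characterise a marker's barcoding gap:
#   inter-specific (per genus with >= 2 species):
#     - average inter-specific distance: mean over congeneric species pairs
#       of the mean pairwise distance between the two species
#     - theta prime: mean over all heterospecific congeneric sequence pairs
#     - minimum inter-specific distance: smallest heterospecific congeneric
#       pairwise distance in the genus
#   intra-specific (per species with >= 2 records):
#     - average intra-specific distance: pooled mean over conspecific pairs
#     - theta: mean conspecific pairwise distance per species
#     - coalescent depth: maximum conspecific pairwise distance per species
# Undefined (saturated) distances are skipped with a logged count.

.conspecific_pairs <- function(mat, dataset) {
  sp <- dataset$records$species[match(mat$ids, dataset$records$id)]
  pt <- pair_table(mat)
  pt$sp1 <- sp[match(pt$id1, mat$ids)]
  pt$sp2 <- sp[match(pt$id2, mat$ids)]
  pt
}

#' Per-species intra-specific divergence statistics
#'
#' For every species with at least two records: `theta` (mean conspecific
#' pairwise K2P distance), `coalescent_depth` (maximum conspecific pairwise
#' distance) and, for barcoding-gap views, `min_interspecific` (distance to
#' the nearest heterospecific congener, `NA` when the species has none).
#'
#' @param mat a `k2p_dist` from [distance_matrix()]
#' @param dataset the matching [marker_dataset()]
#' @return data frame with one row per eligible species and attribute
#'   `pooled_mean` (mean over all conspecific pairs)
#' @export
intraspecific_stats <- function(mat, dataset) {
  stopifnot(inherits(mat, "k2p_dist"), inherits(dataset, "marker_dataset"))
  pt <- .conspecific_pairs(mat, dataset)
  rec <- dataset$records[match(mat$ids, dataset$records$id), ]
  tab <- table(rec$species)
  eligible <- names(tab)[tab >= 2L]
  if (!length(eligible)) {
    warning("no species with >= 2 records; intra-specific table is empty")
  }
  con <- pt[pt$sp1 == pt$sp2 & pt$sp1 %in% eligible, , drop = FALSE]
  n_undef <- sum(con$undefined)
  if (n_undef) message(sprintf("intraspecific_stats: skipped %d undefined pair(s)", n_undef))
  con_def <- con[!con$undefined, , drop = FALSE]

  out <- do.call(rbind, lapply(eligible, function(s) {
    ds <- con_def$d[con_def$sp1 == s]
    data.frame(species = s,
               genus = rec$genus[match(s, rec$species)],
               n_records = as.integer(tab[[s]]),
               n_pairs = length(ds),
               theta = if (length(ds)) mean(ds) else NA_real_,
               coalescent_depth = if (length(ds)) max(ds) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(species = character(), genus = character(),
                      n_records = integer(), n_pairs = integer(),
                      theta = numeric(), coalescent_depth = numeric())
  }

  # nearest heterospecific congener per eligible species (Figure-2-style view)
  het <- pt[pt$sp1 != pt$sp2 & !pt$undefined, , drop = FALSE]
  gen <- rec$genus[match(het$id1, rec$id)]
  gen2 <- rec$genus[match(het$id2, rec$id)]
  het <- het[gen == gen2, , drop = FALSE]
  out$min_interspecific <- vapply(out$species, function(s) {
    ds <- het$d[het$sp1 == s | het$sp2 == s]
    if (length(ds)) min(ds) else NA_real_
  }, 0)

  attr(out, "pooled_mean") <- if (nrow(con_def)) mean(con_def$d) else NA_real_
  attr(out, "pooled_sd") <- if (nrow(con_def) > 1L) stats::sd(con_def$d) else NA_real_
  attr(out, "n_undefined") <- n_undef
  out
}

#' Per-genus inter-specific divergence statistics
#'
#' For every genus with at least two species: `avg_interspecific` (mean over
#' congeneric species pairs of the species-pair mean distance),
#' `theta_prime` (mean over all heterospecific congeneric sequence pairs)
#' and `min_interspecific` (smallest such distance).
#'
#' @inheritParams intraspecific_stats
#' @return data frame with one row per eligible genus
#' @export
interspecific_stats <- function(mat, dataset) {
  stopifnot(inherits(mat, "k2p_dist"), inherits(dataset, "marker_dataset"))
  pt <- .conspecific_pairs(mat, dataset)
  rec <- dataset$records[match(mat$ids, dataset$records$id), ]
  pt$g1 <- rec$genus[match(pt$id1, rec$id)]
  pt$g2 <- rec$genus[match(pt$id2, rec$id)]
  sp_per_gen <- tapply(rec$species, rec$genus, function(s) length(unique(s)))
  eligible <- names(sp_per_gen)[sp_per_gen >= 2L]
  if (!length(eligible)) {
    warning("no genus with >= 2 species; inter-specific table is empty")
  }
  het <- pt[pt$g1 == pt$g2 & pt$sp1 != pt$sp2 & pt$g1 %in% eligible, , drop = FALSE]
  n_undef <- sum(het$undefined)
  if (n_undef) message(sprintf("interspecific_stats: skipped %d undefined pair(s)", n_undef))
  het <- het[!het$undefined, , drop = FALSE]

  out <- do.call(rbind, lapply(eligible, function(g) {
    hg <- het[het$g1 == g, , drop = FALSE]
    if (!nrow(hg)) {
      return(data.frame(genus = g, n_species = as.integer(sp_per_gen[[g]]),
                        n_pairs = 0L, avg_interspecific = NA_real_,
                        theta_prime = NA_real_, min_interspecific = NA_real_,
                        stringsAsFactors = FALSE))
    }
    key <- paste(pmin(hg$sp1, hg$sp2), pmax(hg$sp1, hg$sp2), sep = "|")
    sp_pair_means <- tapply(hg$d, key, mean)
    data.frame(genus = g,
               n_species = as.integer(sp_per_gen[[g]]),
               n_pairs = nrow(hg),
               avg_interspecific = mean(sp_pair_means),
               theta_prime = mean(hg$d),
               min_interspecific = min(hg$d),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(genus = character(), n_species = integer(),
                      n_pairs = integer(), avg_interspecific = numeric(),
                      theta_prime = numeric(), min_interspecific = numeric())
  }
  attr(out, "n_undefined") <- n_undef
  out
}

#' Six-parameter divergence summary for one marker
#'
#' Headline values are means and standard deviations over the grouping
#' units: genera for the three inter-specific parameters, species for theta
#' and coalescent depth.  The average intra-specific distance is the pooled
#' mean over all conspecific sequence pairs (its sd is over those pairs).
#'
#' @inheritParams intraspecific_stats
#' @return object of class `divergence_summary`: list with `marker`,
#'   `summary` (data frame of parameter, mean, sd, n_units), `per_species`
#'   and `per_genus` tables
#' @export
divergence_summary <- function(mat, dataset) {
  per_sp <- intraspecific_stats(mat, dataset)
  per_gen <- interspecific_stats(mat, dataset)
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
      n = length(x))
  }
  rows <- rbind(
    avg_interspecific = msd(per_gen$avg_interspecific),
    theta_prime = msd(per_gen$theta_prime),
    min_interspecific = msd(per_gen$min_interspecific),
    avg_intraspecific = c(mean = attr(per_sp, "pooled_mean"),
                          sd = attr(per_sp, "pooled_sd"),
                          n = sum(per_sp$n_pairs)),
    theta = msd(per_sp$theta),
    coalescent_depth = msd(per_sp$coalescent_depth))
  summary <- data.frame(parameter = rownames(rows),
                        mean = rows[, "mean"], sd = rows[, "sd"],
                        n_units = as.integer(rows[, "n"]),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(marker = dataset$marker, summary = summary,
                 per_species = per_sp, per_genus = per_gen),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf("Divergence summary for %s (%d species, %d genera)\n",
              x$marker, nrow(x$per_species), nrow(x$per_genus)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s %s\n", s$parameter[i],
                if (is.na(s$mean[i])) "NA"
                else sprintf("%.3f +/- %.3f (n=%d)", s$mean[i],
                             ifelse(is.na(s$sd[i]), 0, s$sd[i]), s$n_units[i])))
  }
  invisible(x)
}

#' Barcoding-gap frequency distributions
#'
#' Bins the per-species minimum inter-specific distances (distance to the
#' nearest heterospecific congener) and the per-species coalescent depths
#' into a common histogram, the classic visual check for a barcoding gap.
#'
#' @param per_species per-species table from [intraspecific_stats()]
#' @param per_genus per-genus table from [interspecific_stats()]; used for
#'   `level = "genus"`
#' @param bin_width positive histogram bin width on the K2P scale
#' @param level `"species"` (default; nearest-congener distances) or
#'   `"genus"` (per-genus minima)
#' @return object of class `gap_histogram`: list with `bin_edges`,
#'   `min_interspecific_counts`, `coalescent_depth_counts`, `overlap`
#'   (logical: do the two occupied ranges intersect?)
#' @export
gap_histograms <- function(per_species, per_genus, bin_width = 0.01,
                           level = c("species", "genus")) {
  level <- match.arg(level)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number")
  }
  mins <- if (level == "species") per_species$min_interspecific else per_genus$min_interspecific
  depths <- per_species$coalescent_depth
  mins <- mins[!is.na(mins)]
  depths <- depths[!is.na(depths)]
  if (!length(mins) && !length(depths)) stop("both component tables are empty")
  top <- max(c(mins, depths, bin_width))
  edges <- seq(0, bin_width * ceiling(top / bin_width + 1e-9), by = bin_width)
  bin_of <- function(x) pmin(findInterval(x, edges, rightmost.closed = FALSE,
                                          left.open = FALSE), length(edges) - 1L)
  count <- function(x) tabulate(bin_of(x), nbins = length(edges) - 1L)
  mc <- count(mins); dc <- count(depths)
  overlap <- length(mins) > 0L && length(depths) > 0L &&
    min(mins) <= max(depths)
  structure(list(bin_edges = edges, min_interspecific_counts = mc,
                 coalescent_depth_counts = dc, overlap = overlap),
            class = "gap_histogram")
}

#' @export
print.gap_histogram <- function(x, ...) {
  cat(sprintf("gap_histogram: %d bins of width %g; distributions %s\n",
              length(x$bin_edges) - 1L, diff(x$bin_edges[1:2]),
              if (x$overlap) "overlap" else "are separated"))
  invisible(x)
}

#' Ratio of mean minimum inter-specific distance to mean coalescent depth
#'
#' A scalar index of barcoding-gap width: how many times further away the
#' nearest heterospecific congener is, on average, than the deepest
#' conspecific split.
#'
#' @param summary a [divergence_summary()]
#' @return the ratio, or `NA` with a warning when the mean coalescent depth
#'   is zero or unavailable
#' @export
ratio_gap_index <- function(summary) {
  stopifnot(inherits(summary, "divergence_summary"))
  s <- summary$summary
  num <- s$mean[s$parameter == "min_interspecific"]
  den <- s$mean[s$parameter == "coalescent_depth"]
  if (is.na(den) || den == 0) {
    warning("mean coalescent depth is zero or undefined; ratio is NA")
    return(NA_real_)
  }
  num / den
}

#' Write the divergence tables of one marker
#'
#' @param summary a [divergence_summary()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_divergence_tables <- function(summary, dir) {
  stopifnot(inherits(summary, "divergence_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%s.tsv", summary$marker,
                                  c("divergence_summary", "per_species", "per_genus")))
  write_tsv(summary$summary, paths[1L])
  write_tsv(summary$per_species, paths[2L])
  write_tsv(summary$per_genus, paths[3L])
  invisible(paths)
}

#' Write a gap histogram as TSV
#'
#' @param hist a [gap_histograms()] result
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gap_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "gap_histogram"))
  df <- data.frame(bin_start = hist$bin_edges[-length(hist$bin_edges)],
                   bin_end = hist$bin_edges[-1L],
                   min_interspecific = hist$min_interspecific_counts,
                   coalescent_depth = hist$coalescent_depth_counts)
  write_tsv(df, path)
  invisible(path)
}
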