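# Integer encoding of residues: A=1 C=2 G=3 T=4, everything else (gaps,
# IUPAC ambiguity codes) NA and excluded by pairwise deletion.
.encode_residues <- function(x) {
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ch <- strsplit(x, "", fixed = TRUE)
  lapply(ch, function(v) unname(map[v]))
}

.k2p_from_counts <- function(n_sites, n_ts, n_tv) {
  if (n_sites == 0L) {
    return(list(n_sites = 0L, P = NA_real_, Q = NA_real_, d = NA_real_,
                undefined = TRUE, reason = "no comparable sites"))
  }
  P <- n_ts / n_sites
  Q <- n_tv / n_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(n_sites = n_sites, P = P, Q = Q, d = NA_real_,
                undefined = TRUE, reason = "saturated (log argument non-positive)"))
  }
  list(n_sites = n_sites, P = P, Q = Q,
       d = -0.5 * log(w1 * sqrt(w2)),
       undefined = FALSE, reason = NA_character_)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P distance `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))`, where
#' `P` and `Q` are the proportions of transition (A/G, C/T) and transversion
#' differences among comparable sites.  Pairwise deletion: columns where
#' either sequence carries a gap or an ambiguity code are skipped.  When the
#' logarithm argument is non-positive (saturation) or no sites are
#' comparable, the distance is flagged undefined rather than raising an
#' error.
#'
#' @param a,b aligned residue strings of equal length
#' @return a list of class `k2p_pair` with elements `n_sites`, `P`, `Q`, `d`
#'   (`NA` when undefined), `undefined` (logical) and `reason`
#' @export
k2p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop(sprintf("sequences have unequal lengths (%d vs %d)", nchar(a), nchar(b)))
  }
  enc <- .encode_residues(c(a, b))
  x <- enc[[1L]]; y <- enc[[2L]]
  ok <- !is.na(x) & !is.na(y)
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  # transitions: within purines {A,G} = {1,3} or pyrimidines {C,T} = {2,4}
  ts <- diff & ((xs %% 2L) == (ys %% 2L))
  out <- .k2p_from_counts(sum(ok), sum(ts), sum(diff & !ts))
  class(out) <- "k2p_pair"
  out
}

#' @export
print.k2p_pair <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("K2P distance: undefined (%s); n_sites=%d\n", x$reason, x$n_sites))
  } else {
    cat(sprintf("K2P distance: %.6f (P=%.4f, Q=%.4f, n_sites=%d)\n",
                x$d, x$P, x$Q, x$n_sites))
  }
  invisible(x)
}

#' Pairwise K2P distance matrix for a marker dataset
#'
#' All record pairs are compared with [k2p_distance()].  Undefined pairs
#' (saturated or without comparable sites) are flagged in `undefined`, not
#' silently zeroed; their `values` entries are `NA`.
#'
#' @param dataset a [marker_dataset()] with equal-length (trimmed) records
#' @return an object of class `k2p_dist` with elements `ids`, `values`
#'   (symmetric distance matrix), `site_counts` and `undefined` (logical
#'   matrix)
#' @export
distance_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (is.na(dataset$alignment_length)) {
    stop("records are not aligned (unequal residue lengths); trim first")
  }
  ids <- dataset$records$id
  n <- length(ids)
  enc <- .encode_residues(dataset$records$residues)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  undef <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) ns[i, i] <- sum(!is.na(enc[[i]]))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      xi <- enc[[i]]
      for (j in (i + 1L):n) {
        yj <- enc[[j]]
        ok <- !is.na(xi) & !is.na(yj)
        xs <- xi[ok]; ys <- yj[ok]
        diff <- xs != ys
        ts <- diff & ((xs %% 2L) == (ys %% 2L))
        p <- .k2p_from_counts(sum(ok), sum(ts), sum(diff & !ts))
        d[i, j] <- d[j, i] <- if (p$undefined) NA_real_ else p$d
        ns[i, j] <- ns[j, i] <- p$n_sites
        undef[i, j] <- undef[j, i] <- p$undefined
      }
    }
  }
  structure(list(ids = ids, values = d, site_counts = ns, undefined = undef),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n_undef <- sum(x$undefined[upper.tri(x$undefined)])
  cat(sprintf("k2p_dist: %d sequences, %d pair(s), %d undefined pair(s)\n",
              length(x$ids), choose(length(x$ids), 2L), n_undef))
  invisible(x)
}

#' Extract defined pairwise distances with labels
#'
#' @param mat a `k2p_dist` from [distance_matrix()]
#' @return data frame with columns `id1`, `id2`, `d`, `n_sites`, `undefined`
#'   for every unordered pair
#' @export
pair_table <- function(mat) {
  stopifnot(inherits(mat, "k2p_dist"))
  n <- length(mat$ids)
  if (n < 2L) {
    return(data.frame(id1 = character(), id2 = character(), d = numeric(),
                      n_sites = integer(), undefined = logical()))
  }
  idx <- which(upper.tri(mat$values), arr.ind = TRUE)
  data.frame(id1 = mat$ids[idx[, 1L]],
             id2 = mat$ids[idx[, 2L]],
             d = mat$values[idx],
             n_sites = mat$site_counts[idx],
             undefined = mat$undefined[idx],
             stringsAsFactors = FALSE)
}

#' Write / read a square distance matrix as TSV
#'
#' Plain tab-separated square layout: first row and first column hold ids;
#' undefined distances are written as `NA`.
#'
#' @param mat a `k2p_dist`
#' @param path output path
#' @return invisibly, the input
#' @export
write_distance_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "k2p_dist"))
  m <- mat$values
  df <- data.frame(id = mat$ids, m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", mat$ids)
  write_tsv(df, path)
  invisible(mat)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  structure(list(ids = ids, values = m,
                 site_counts = matrix(NA_integer_, length(ids), length(ids),
                                      dimnames = list(ids, ids)),
                 undefined = is.na(m) & row(m) != col(m)),
            class = "k2p_dist")
}

#' Write a distance matrix in PHYLIP format
#'
#' Lower-precision interchange format understood by classic phylogenetics
#' tools.  Undefined entries are written as `-1.0`.
#'
#' @param mat a `k2p_dist`
#' @param path output path
#' @return invisibly, the input
#' @export
write_distance_phylip <- function(mat, path) {
  stopifnot(inherits(mat, "k2p_dist"))
  m <- mat$values
  m[is.na(m)] <- -1
  lines <- c(sprintf("%5d", length(mat$ids)),
             vapply(seq_along(mat$ids), function(i) {
               paste0(formatC(mat$ids[i], width = -10),
                      paste(sprintf("%.6f", m[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(mat)
}

#' Wrap a plain symmetric numeric matrix as a `k2p_dist`
#'
#' Handy for handcrafted distance structures; site counts are unknown and
#' `NA` entries off the diagonal are treated as undefined distances.
#'
#' @param m symmetric numeric matrix with identical row and column names
#' @return a `k2p_dist`
#' @export
as_k2p_dist <- function(m) {
  ids <- rownames(m)
  stopifnot(!is.null(ids), identical(ids, colnames(m)))
  structure(list(ids = ids, values = m,
                 site_counts = matrix(NA_integer_, nrow(m), ncol(m),
                                      dimnames = dimnames(m)),
                 undefined = is.na(m) & row(m) != col(m)),
            class = "k2p_dist")
}
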