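# Identification decision rules and reference screening.

.id_call <- function(query_id, method, assigned_species = NA_character_,
                     state = c("assigned", "uncertain", "no-hit"),
                     support = NA_real_, tied_species = character(),
                     detail = NA_character_) {
  state <- match.arg(state)
  if (state == "assigned" && (is.na(assigned_species) || length(tied_species)))
    stop("internal: assigned call must have a species and no ties")
  if (state != "assigned") assigned_species <- NA_character_
  structure(list(query_id = query_id, method = method,
                 assigned_species = assigned_species, state = state,
                 support = support, tied_species = tied_species,
                 detail = detail),
            class = "id_call")
}

#' @export
print.id_call <- function(x, ...) {
  cat(sprintf("[%s] %s -> %s%s\n", x$method, x$query_id,
              switch(x$state, assigned = x$assigned_species,
                     uncertain = "uncertain", `no-hit` = "no hit"),
              if (length(x$tied_species))
                paste0(" (tied: ", paste(x$tied_species, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Combine identification calls into a data frame
#'
#' @param calls list of identification calls
#' @return data frame with columns `query_id`, `method`, `state`,
#'   `assigned_species`, `support`, `tied_species` (collapsed with `;`),
#'   `detail`
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(query_id = cl$query_id, method = cl$method, state = cl$state,
               assigned_species = cl$assigned_species, support = cl$support,
               tied_species = paste(cl$tied_species, collapse = ";"),
               detail = cl$detail, stringsAsFactors = FALSE)
  }))
}

#' Nearest-neighbour identification
#'
#' Assigns the query the species of its minimum-distance reference.  When
#' nearest neighbours (ties at the minimum, compared after rounding to 10
#' decimal places so floating-point noise cannot hide true ties) come from
#' more than one species the call is uncertain.  Undefined distances count
#' as infinitely far; if every reference distance is undefined the call is
#' no-hit.
#'
#' @param query_id id of the query record (present in `mat`)
#' @param mat a `k2p_dist` covering the query and the references
#' @param reference the reference [marker_dataset()]; the query itself is
#'   excluded from the reference by id
#' @return an identification call (`id_call`)
#' @export
nn_identify <- function(query_id, mat, reference) {
  stopifnot(inherits(mat, "k2p_dist"), inherits(reference, "marker_dataset"))
  if (!query_id %in% mat$ids) stop("query '", query_id, "' not in distance matrix")
  ref_ids <- setdiff(intersect(reference$records$id, mat$ids), query_id)
  if (!length(ref_ids)) stop("no reference sequences left after self-exclusion")
  d <- mat$values[query_id, ref_ids]
  d[mat$undefined[query_id, ref_ids]] <- Inf
  d[is.na(d)] <- Inf
  if (all(is.infinite(d))) {
    return(.id_call(query_id, "NN", state = "no-hit",
                    detail = "all reference distances undefined"))
  }
  dr <- round(d, 10)
  nearest <- ref_ids[dr == min(dr)]
  sp <- unique(reference$records$species[match(nearest, reference$records$id)])
  if (length(sp) == 1L) {
    .id_call(query_id, "NN", assigned_species = sp, state = "assigned",
             support = min(d))
  } else {
    .id_call(query_id, "NN", state = "uncertain", support = min(d),
             tied_species = sort(sp))
  }
}

#' Best-hit identification by local alignment
#'
#' Aligns the ungapped query locally (Smith-Waterman with affine gaps,
#' via [Biostrings::pairwiseAlignment()]) against every reference sequence
#' and keeps hits with identity at or above `identity_floor` and E-value at
#' or below `evalue_cutoff`.  Hits are ranked by Karlin-Altschul bit score
#' `(lambda * S - ln K) / ln 2` with `E = m * n * 2^-bit` (`m`, `n` the
#' ungapped query and reference lengths).  The top hit's species is
#' assigned; ties of the top bit score across several species make the call
#' uncertain, and no qualifying hit makes it no-hit.
#'
#' Defaults mirror the classic megablast-style nucleotide scheme: match +2,
#' mismatch -3, gap open 5, gap extend 2, lambda 0.625, K 0.41.
#'
#' @param query a single-row record: list or data frame row with elements
#'   `id` and `residues` (aligned or not; gaps are removed)
#' @param reference the reference [marker_dataset()]; a reference sharing
#'   the query's id is excluded (self-match removal)
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#' @param karlin_params list with `lambda` and `K`
#' @param evalue_cutoff maximum E-value for a qualifying hit
#' @param identity_floor minimum identity fraction for a qualifying hit
#' @param max_hits maximum number of hits retained
#' @return an identification call (`id_call`); `attr(, "hits")` holds the
#'   retained hit table
#' @export
best_hit_identify <- function(query, reference,
                              scoring = list(match = 2, mismatch = -3,
                                             gap_open = 5, gap_extend = 2),
                              karlin_params = list(lambda = 0.625, K = 0.41),
                              evalue_cutoff = 1e-6, identity_floor = 0.8,
                              max_hits = 100L) {
  stopifnot(inherits(reference, "marker_dataset"))
  if (!is.numeric(scoring$match) || scoring$match <= 0) {
    stop("degenerate scoring scheme: match reward must be positive")
  }
  qid <- as.character(query$id)
  qseq <- gsub("-", "", toupper(as.character(query$residues)), fixed = TRUE)
  if (!nzchar(qseq)) stop("query sequence is empty after removing gaps")

  refs <- reference$records[reference$records$id != qid, , drop = FALSE]
  if (!nrow(refs)) stop("no reference sequences left after self-exclusion")
  rseqs <- gsub("-", "", refs$residues, fixed = TRUE)
  keepable <- nzchar(rseqs)
  refs <- refs[keepable, , drop = FALSE]
  rseqs <- rseqs[keepable]

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE,
    type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(rseqs),
    subject = Biostrings::DNAString(qseq),
    type = "local", substitutionMatrix = sub_mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  S <- Biostrings::score(aln)
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  bit <- (karlin_params$lambda * S - log(karlin_params$K)) / log(2)
  evalue <- nchar(qseq) * nchar(rseqs) * 2^(-bit)

  hits <- data.frame(id = refs$id, species = refs$species, score = S,
                     bit_score = bit, evalue = evalue, identity = identity,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$identity >= identity_floor & hits$evalue <= evalue_cutoff, ,
               drop = FALSE]
  hits <- hits[order(-hits$bit_score, hits$id), , drop = FALSE]
  if (nrow(hits) > max_hits) hits <- hits[seq_len(max_hits), , drop = FALSE]

  if (!nrow(hits)) {
    out <- .id_call(qid, "best-hit", state = "no-hit",
                    detail = "no hit above identity floor and below E-value cutoff")
  } else {
    top <- hits[abs(hits$bit_score - hits$bit_score[1L]) < 1e-9, , drop = FALSE]
    sp <- unique(top$species)
    if (length(sp) == 1L) {
      out <- .id_call(qid, "best-hit", assigned_species = sp, state = "assigned",
                      support = hits$bit_score[1L],
                      detail = sprintf("E=%.3g", hits$evalue[1L]))
    } else {
      out <- .id_call(qid, "best-hit", state = "uncertain",
                      support = hits$bit_score[1L], tied_species = sort(sp),
                      detail = "top bit score shared across species")
    }
  }
  attr(out, "hits") <- hits
  out
}

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard neighbour-joining agglomeration (via [ape::nj()]).  Undefined
#' distances are imputed as the matrix maximum (with a message).  Negative
#' branch lengths are clamped to zero with the deficit moved to the sibling
#' branch (any residual negative is floored at zero).
#'
#' @param mat a `k2p_dist` with at least 3 sequences
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(mat) {
  stopifnot(inherits(mat, "k2p_dist"))
  n <- length(mat$ids)
  if (n < 3L) stop("neighbour joining needs at least 3 sequences")
  m <- mat$values
  if (any(is.na(m))) {
    mx <- max(m, na.rm = TRUE)
    message(sprintf("nj_tree: imputed %d undefined pair(s) with the matrix maximum %.4f",
                    sum(is.na(m[upper.tri(m)])), mx))
    m[is.na(m)] <- mx
  }
  tree <- ape::nj(m)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    sib <- which(tree$edge[, 1L] == tree$edge[e, 1L])
    sib <- setdiff(sib, e)
    if (length(sib)) {
      tree$edge.length[sib[1L]] <- tree$edge.length[sib[1L]] + deficit
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Undirected adjacency walk: tip labels on the far side of edge (from, to),
# i.e. the connected component of `to` after deleting that edge.
.side_tips <- function(tree, from, to) {
  edges <- tree$edge
  n_tip <- length(tree$tip.label)
  seen <- c(from, to)
  frontier <- to
  tips <- integer()
  while (length(frontier)) {
    node <- frontier[1L]
    frontier <- frontier[-1L]
    if (node <= n_tip) tips <- c(tips, node)
    nb <- c(edges[edges[, 1L] == node, 2L], edges[edges[, 2L] == node, 1L])
    nb <- setdiff(nb, seen)
    seen <- c(seen, nb)
    frontier <- c(frontier, nb)
  }
  tree$tip.label[tips]
}

#' Liberal tree-based identification
#'
#' Inspects the query's placement on the tree: from the query's attachment
#' node, each adjacent subtree that contains reference leaves of exactly one
#' species nominates that species (this reproduces the classic patterns
#' `((X,X),Q)` -- query sister to a monospecific clade -- and `((X,Q),X)` --
#' query nested within one).  A unique nominee is assigned; several distinct
#' nominees, or none, make the call uncertain.
#'
#' @param tree a `phylo` tree containing the query leaf
#' @param query_id the query's tip label
#' @param species_map named character vector mapping reference tip labels to
#'   species; tips absent from the map (other than the query) are ignored
#' @return an identification call (`id_call`)
#' @export
liberal_tree_identify <- function(tree, query_id, species_map) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(query_id, tree$tip.label)
  if (is.na(tip)) stop("query '", query_id, "' is not a tip of the tree")
  species_map <- species_map[setdiff(names(species_map), query_id)]
  if (length(species_map) < 2L) stop("need at least 2 reference leaves")
  v <- tree$edge[tree$edge[, 2L] == tip, 1L]
  nb <- c(tree$edge[tree$edge[, 1L] == v, 2L], tree$edge[tree$edge[, 2L] == v, 1L])
  nb <- setdiff(nb, c(tip, v))
  nominees <- character()
  for (node in nb) {
    labs <- .side_tips(tree, v, node)
    sp <- unique(species_map[intersect(labs, names(species_map))])
    if (length(sp) == 1L) nominees <- c(nominees, sp)
  }
  nominees <- unique(nominees)
  if (length(nominees) == 1L) {
    .id_call(query_id, "tree", assigned_species = nominees, state = "assigned",
             detail = "monospecific adjacent subtree")
  } else if (length(nominees) > 1L) {
    .id_call(query_id, "tree", state = "uncertain", tied_species = sort(nominees),
             detail = "adjacent subtrees nominate different species")
  } else {
    .id_call(query_id, "tree", state = "uncertain",
             detail = "no monospecific adjacent subtree")
  }
}

#' Liberal tree-based identification with a distance threshold
#'
#' As [liberal_tree_identify()], but an assignment is vetoed (made
#' uncertain) when the query's smallest defined K2P distance to any
#' reference is at or above `threshold`.
#'
#' @inheritParams liberal_tree_identify
#' @param mat a `k2p_dist` covering query and references
#' @param threshold positive distance threshold
#' @return an identification call (`id_call`)
#' @export
liberal_tree_threshold_identify <- function(tree, query_id, species_map, mat,
                                            threshold) {
  stopifnot(inherits(mat, "k2p_dist"), is.numeric(threshold), threshold > 0)
  cl <- liberal_tree_identify(tree, query_id, species_map)
  cl$method <- "tree+threshold"
  ref_ids <- setdiff(intersect(names(species_map), mat$ids), query_id)
  d <- mat$values[query_id, ref_ids]
  d[mat$undefined[query_id, ref_ids]] <- Inf
  d[is.na(d)] <- Inf
  dmin <- min(d)
  cl$support <- if (is.finite(dmin)) dmin else NA_real_
  if (cl$state == "assigned" && !(is.finite(dmin) && dmin < threshold)) {
    cl <- .id_call(query_id, "tree+threshold", state = "uncertain",
                   support = cl$support,
                   detail = sprintf("nearest reference %.4f >= threshold %.4f",
                                    dmin, threshold))
  }
  cl
}

#' Screen unverified reference sequences by tree clustering
#'
#' An unpublished record is admitted (status `"screened-in"`) only if the
#' smallest clade, on the midpoint-rooted tree, that contains it and at
#' least one reliable record (published or locally amplified) holds
#' exclusively records of its own nominal species -- reliable conspecifics
#' plus possibly other unpublished conspecifics.  Otherwise, or when the
#' species has no reliable record at all, it is rejected
#' (`"screened-out"`).  Published and amplified records never change
#' status.
#'
#' @param tree a `phylo` tree whose tips cover every record of `dataset`
#' @param dataset a [marker_dataset()] with status metadata
#' @return the dataset with unpublished records re-statused; the decision
#'   table is attached as `attr(, "screening")`
#' @export
screen_unpublished <- function(tree, dataset) {
  stopifnot(inherits(tree, "phylo"), inherits(dataset, "marker_dataset"))
  rec <- dataset$records
  miss <- setdiff(rec$id, tree$tip.label)
  if (length(miss)) stop("record(s) missing from tree: ", paste(miss, collapse = ", "))
  rtree <- phangorn::midpoint(tree)
  unpub <- which(rec$status == "unpublished")
  reliable <- rec$status %in% c("published", "amplified")
  report <- data.frame(id = character(), decision = character(),
                       reason = character(), stringsAsFactors = FALSE)
  for (i in unpub) {
    sp <- rec$species[i]
    if (!any(reliable & rec$species == sp)) {
      rec$status[i] <- "screened-out"
      report <- rbind(report, data.frame(id = rec$id[i], decision = "screened-out",
                                         reason = "no reliable conspecific",
                                         stringsAsFactors = FALSE))
      next
    }
    tip <- match(rec$id[i], rtree$tip.label)
    node <- tip
    decision <- "screened-out"
    reason <- "no clade with a reliable record"
    repeat {
      parent <- rtree$edge[rtree$edge[, 2L] == node, 1L]
      if (!length(parent)) break
      node <- parent
      labs <- .clade_tips(rtree, node)
      j <- match(labs, rec$id)
      j <- j[!is.na(j)]
      if (any(reliable[j])) {
        if (all(rec$species[j] == sp)) {
          decision <- "screened-in"
          reason <- "clusters with reliable conspecifics"
        } else {
          decision <- "screened-out"
          reason <- "clusters with records of another species"
        }
        break
      }
    }
    rec$status[i] <- decision
    report <- rbind(report, data.frame(id = rec$id[i], decision = decision,
                                       reason = reason, stringsAsFactors = FALSE))
  }
  out <- marker_dataset(rec, marker = dataset$marker, role = dataset$role)
  attr(out, "screening") <- report
  out
}

.clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  tips <- integer()
  frontier <- node
  while (length(frontier)) {
    nd <- frontier[1L]
    frontier <- frontier[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    tips <- c(tips, kids[kids <= n_tip])
    frontier <- c(frontier, kids[kids > n_tip])
  }
  tree$tip.label[tips]
}
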