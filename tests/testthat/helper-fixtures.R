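# In-code fixtures shared across the suite.

# Quick dataset constructor from parallel vectors.
make_dataset <- function(ids, species, seqs, status = NULL, stage = NULL,
                         marker = "COI", role = "custom") {
  rec <- data.frame(id = ids, species = species, residues = seqs,
                    stringsAsFactors = FALSE)
  if (!is.null(status)) rec$status <- status
  if (!is.null(stage)) rec$stage <- stage
  marker_dataset(rec, marker = marker, role = role)
}

# Sequence of length n over a single base.
mono_seq <- function(n, base = "A") paste(rep(base, n), collapse = "")

# Pair of sequences with exactly `ts` transition and `tv` transversion
# differences among `n` comparable sites (A background; G is the transition
# partner of A, C a transversion partner).
diff_pair <- function(n, ts, tv) {
  stopifnot(ts + tv <= n)
  a <- rep("A", n)
  b <- a
  if (ts > 0) b[seq_len(ts)] <- "G"
  if (tv > 0) b[ts + seq_len(tv)] <- "C"
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# Random gap-free nucleotide sequence.
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Symmetric labelled matrix from the upper triangle given as a named list
# "id1|id2" -> distance.
sym_matrix <- function(ids, pairs) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (key in names(pairs)) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    m[p[1], p[2]] <- m[p[2], p[1]] <- pairs[[key]]
  }
  m
}

# Minimal divergence_summary stub for ratio tests.
summary_stub <- function(min_inter_mean, depth_mean) {
  structure(list(marker = "COI",
                 summary = data.frame(
                   parameter = c("min_interspecific", "coalescent_depth"),
                   mean = c(min_inter_mean, depth_mean),
                   sd = NA_real_, n_units = 1L, stringsAsFactors = FALSE)),
            class = "divergence_summary")
}
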