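MARKERS <- c("COI", "16S", "ITS2", "12S")
STATUSES <- c("published", "amplified", "unpublished", "screened-in", "screened-out")
STAGES <- c("adult", "subadult", "unknown")

## reliable = usable as reference evidence without tree screening
RELIABLE_STATUSES <- c("published", "amplified", "screened-in")

# IUPAC nucleotide alphabet plus the alignment gap
RESIDUE_ALPHABET <- c("A", "C", "G", "T",
                      "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N",
                      "-")

#' Construct a marker dataset
#'
#' A `marker_dataset` bundles the aligned sequences of one barcoding marker
#' with per-record taxonomy and reliability metadata.  Records are kept in a
#' single data frame with one row per sequence; the aligned residues live in
#' the `residues` column.
#'
#' @param records data frame with columns `id`, `species`, `genus`, `status`,
#'   `stage`, `residues`.  `genus`, `status` and `stage` may be omitted:
#'   `genus` defaults to the first token of `species`, `status` to
#'   `"published"` and `stage` to `"adult"`.
#' @param marker marker code, one of `"COI"`, `"16S"`, `"ITS2"`, `"12S"` (other
#'   codes are allowed for custom markers).
#' @param role dataset role: `"set1"` (reference library), `"set2"` (query
#'   set: species with multiple accessions), `"set3"` (adults + published
#'   only), or `"custom"`.
#' @return an object of class `marker_dataset` with elements `marker`,
#'   `records`, `alignment_length` (NA when record lengths differ) and `role`.
#' @export
marker_dataset <- function(records, marker = "COI", role = "custom") {
  stopifnot(is.data.frame(records))
  if (!"id" %in% names(records) || !"species" %in% names(records) ||
      !"residues" %in% names(records)) {
    stop("records must have columns 'id', 'species' and 'residues'")
  }
  records$id <- as.character(records$id)
  records$species <- trimws(as.character(records$species))
  if (is.null(records$genus)) {
    records$genus <- vapply(strsplit(records$species, "\\s+"), `[`, "", 1L)
  }
  if (is.null(records$status)) records$status <- "published"
  if (is.null(records$stage)) records$stage <- "adult"
  records$residues <- toupper(as.character(records$residues))
  rownames(records) <- NULL

  dup <- records$id[duplicated(records$id)]
  if (length(dup)) stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(records$residues))) {
    stop("empty residue string for id(s): ",
         paste(records$id[!nzchar(records$residues)], collapse = ", "))
  }
  bad_status <- setdiff(unique(records$status), STATUSES)
  if (length(bad_status)) stop("unknown status value(s): ", paste(bad_status, collapse = ", "))
  bad_stage <- setdiff(unique(records$stage), STAGES)
  if (length(bad_stage)) stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  .check_alphabet(records$residues, records$id)

  lens <- nchar(records$residues)
  alen <- if (length(unique(lens)) == 1L) lens[1L] else NA_integer_

  structure(
    list(marker = marker,
         records = records[, c("id", "species", "genus", "status", "stage", "residues")],
         alignment_length = as.integer(alen),
         role = role),
    class = "marker_dataset")
}

.check_alphabet <- function(residues, ids) {
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[i], "", fixed = TRUE)[[1L]]
    bad <- which(!(ch %in% RESIDUE_ALPHABET))
    if (length(bad)) {
      stop(sprintf("illegal residue character '%s' at position %d in record '%s'",
                   ch[bad[1L]], bad[1L], ids[i]))
    }
  }
  invisible(TRUE)
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("marker_dataset: %d %s record(s), %d species, role=%s, alignment length=%s\n",
              nrow(x$records), x$marker, length(unique(x$records$species)), x$role,
              ifelse(is.na(x$alignment_length), "ragged", x$alignment_length)))
  invisible(x)
}

#' @export
length.marker_dataset <- function(x) nrow(x$records)

#' Subset a marker dataset by record index or id
#'
#' @param dataset a [marker_dataset()]
#' @param i integer/logical index into the record table, or character ids
#' @param role role tag for the returned dataset (defaults to the input's)
#' @return a `marker_dataset` with the selected records, order preserved
#' @export
subset_records <- function(dataset, i, role = dataset$role) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (is.character(i)) {
    miss <- setdiff(i, dataset$records$id)
    if (length(miss)) stop("unknown record id(s): ", paste(miss, collapse = ", "))
    i <- match(i, dataset$records$id)
  }
  marker_dataset(dataset$records[i, , drop = FALSE], marker = dataset$marker, role = role)
}

#' Ungapped sequence lengths
#'
#' Number of residues excluding alignment gaps (`-`) per record.  Ambiguity
#' codes count as residues.
#'
#' @param dataset a [marker_dataset()]
#' @return named integer vector (names are record ids)
#' @export
ungapped_lengths <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  n <- nchar(dataset$records$residues) -
    vapply(gregexpr("-", dataset$records$residues, fixed = TRUE),
           function(m) if (m[1L] == -1L) 0L else length(m), 0L)
  names(n) <- dataset$records$id
  n
}

#' Read an aligned FASTA plus metadata table into a marker dataset
#'
#' The metadata TSV must have columns `id`, `species` and optionally `genus`,
#' `marker`, `status`, `stage`; unknown extra columns are ignored.  Every
#' FASTA id must have a metadata row.  Record order follows the FASTA file.
#'
#' @param fasta_path path to an aligned FASTA file (gaps as `-`)
#' @param metadata_path path to a tab-separated metadata table
#' @param marker marker code for the dataset
#' @return a [marker_dataset()] with `role = "custom"`
#' @export
read_marker_dataset <- function(fasta_path, metadata_path, marker = "COI") {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!all(c("id", "species") %in% names(meta))) {
    stop("metadata must have at least columns 'id' and 'species'")
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate metadata id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  miss <- setdiff(ids, meta$id)
  if (length(miss)) {
    stop("FASTA id(s) missing from metadata: ", paste(miss, collapse = ", "))
  }
  m <- meta[match(ids, meta$id), , drop = FALSE]
  rec <- data.frame(id = ids,
                    species = m$species,
                    residues = toupper(as.character(seqs)),
                    stringsAsFactors = FALSE)
  if (!is.null(m$genus)) rec$genus <- m$genus
  if (!is.null(m$status)) rec$status <- m$status
  if (!is.null(m$stage)) rec$stage <- m$stage
  marker_dataset(rec, marker = marker, role = "custom")
}

#' Write a marker dataset as aligned FASTA + metadata TSV
#'
#' @param dataset a [marker_dataset()]
#' @param fasta_path output FASTA path
#' @param metadata_path output TSV path
#' @return invisibly, the dataset
#' @export
write_marker_dataset <- function(dataset, fasta_path, metadata_path) {
  stopifnot(inherits(dataset, "marker_dataset"))
  lines <- character(2L * nrow(dataset$records))
  lines[c(TRUE, FALSE)] <- paste0(">", dataset$records$id)
  lines[c(FALSE, TRUE)] <- dataset$records$residues
  writeLines(lines, fasta_path)
  meta <- dataset$records[, c("id", "species", "genus", "status", "stage")]
  meta$marker <- dataset$marker
  write_tsv(meta, metadata_path)
  invisible(dataset)
}

#' Filter records by minimum ungapped sequence length
#'
#' Applies per-marker minimum lengths: COI keeps records of at least 450
#' ungapped bases, 16S at least 350, 12S at least 240, and ITS2 at least 70%
#' of the marker's full length.  Lengths are measured on the residues
#' excluding alignment gaps.
#'
#' @param dataset a [marker_dataset()]
#' @param full_length full-length reference size for fractional filters
#'   (required conceptually for ITS2; defaults to the longest ungapped record
#'   in the dataset)
#' @return the filtered dataset; removed record ids are attached as
#'   `attr(, "removed")`
#' @export
filter_by_length <- function(dataset, full_length = NULL) {
  stopifnot(inherits(dataset, "marker_dataset"))
  n <- ungapped_lengths(dataset)
  if (nrow(dataset$records) == 0L) return(dataset)
  min_len <- switch(dataset$marker,
    "COI" = 450,
    "16S" = 350,
    "12S" = 240,
    "ITS2" = {
      if (is.null(full_length)) full_length <- max(n)
      if (!is.numeric(full_length) || full_length <= 0) {
        stop("ITS2 filtering needs a positive 'full_length'")
      }
      0.70 * full_length
    },
    0 # unknown markers pass everything
  )
  keep <- n >= min_len
  removed <- dataset$records$id[!keep]
  if (length(removed)) {
    message(sprintf("filter_by_length: removed %d of %d %s record(s) shorter than %s ungapped bases",
                    length(removed), length(keep), dataset$marker, format(min_len)))
  }
  out <- subset_records(dataset, which(keep))
  attr(out, "removed") <- removed
  out
}

#' Trim an alignment to the region covered by every record
#'
#' Removes leading and trailing alignment columns that fall outside any
#' record's terminal gap runs, so that all records cover the retained
#' region.  Internal gaps are untouched.
#'
#' @param dataset a [marker_dataset()] with equal-length (aligned) records
#' @param min_columns minimum number of surviving columns; fewer is an error
#'   (guards against disjoint fragments)
#' @return the trimmed dataset
#' @export
trim_to_common_region <- function(dataset, min_columns = 50L) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (nrow(dataset$records) == 0L) return(dataset)
  if (is.na(dataset$alignment_length)) {
    stop("records are not aligned (unequal residue lengths)")
  }
  res <- dataset$records$residues
  first <- regexpr("[^-]", res)
  last <- nchar(res) - regexpr("[^-]", vapply(res, .rev_string, "")) + 1L
  if (any(first == -1L)) stop("record(s) consisting only of gaps")
  start <- max(first)
  end <- min(last)
  if (end - start + 1L < min_columns) {
    stop(sprintf("common region has %d column(s), fewer than %d: fragments barely overlap",
                 max(0L, end - start + 1L), min_columns))
  }
  rec <- dataset$records
  rec$residues <- substr(res, start, end)
  marker_dataset(rec, marker = dataset$marker, role = dataset$role)
}

.rev_string <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")

#' Assemble the three evaluation data sets
#'
#' Set 1 is the full reference library: published, locally amplified, and
#' screened-in records.  Set 2 contains all records of species represented
#' by at least two records in set 1 and serves as the query set.  Set 3
#' drops subadult-derived amplified records and all screened-in unverified
#' records from set 1.
#'
#' Screening (see [screen_unpublished()]) must have been applied before this
#' step; records still carrying status `"unpublished"` or `"screened-out"`
#' are excluded from all three sets.
#'
#' @param dataset a [marker_dataset()]
#' @return list with elements `set1`, `set2`, `set3`, each a `marker_dataset`
#' @export
build_evaluation_sets <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  rec <- dataset$records
  in1 <- rec$status %in% c("published", "amplified", "screened-in")
  set1 <- subset_records(dataset, which(in1), role = "set1")

  tab <- table(set1$records$species)
  multi <- names(tab)[tab >= 2L]
  set2 <- subset_records(set1, which(set1$records$species %in% multi), role = "set2")

  drop3 <- (set1$records$status == "amplified" & set1$records$stage == "subadult") |
    set1$records$status == "screened-in"
  set3 <- subset_records(set1, which(!drop3), role = "set3")

  list(set1 = set1, set2 = set2, set3 = set3)
}
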