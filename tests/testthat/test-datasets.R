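test_that("FASTA + metadata round-trip preserves records and order", {
  ds <- make_dataset(c("s1", "s2", "s3"),
                     c("Ixodes ricinus", "Ixodes ricinus", "Rhipicephalus microplus"),
                     c("ACGT-ACGT", "ACGTTACGT", "ACGTCACGT"),
                     status = c("published", "amplified", "unpublished"),
                     stage = c("adult", "subadult", "adult"))
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_marker_dataset(ds, fa, tsv)
  back <- read_marker_dataset(fa, tsv, marker = "COI")
  expect_equal(back$records, ds$records)
  expect_equal(back$role, "custom")
  expect_equal(back$records$genus, c("Ixodes", "Ixodes", "Rhipicephalus"))
})

test_that("reader rejects ids missing from metadata, duplicates, bad residues", {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">s1", "ACGT", ">s2", "ACGT"), fa)
  write.table(data.frame(id = "s1", species = "Ixodes ricinus"), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_marker_dataset(fa, tsv), "s2")

  writeLines(c(">s1", "ACGT", ">s1", "ACGT"), fa)
  expect_error(read_marker_dataset(fa, tsv), "duplicate")

  expect_error(make_dataset("s1", "Ixodes ricinus", "ACXT"),
               "illegal residue character 'X' at position 3")
})

test_that("length filter applies per-marker ungapped thresholds at the stated boundaries", {
  # COI: a 449-ungapped-base record is removed, 450 retained
  coi <- make_dataset(c("a", "b"), c("Sp one", "Sp two"),
                      c(paste0(mono_seq(449), "-"), mono_seq(450)),
                      marker = "COI")
  suppressMessages(f <- filter_by_length(coi))
  expect_equal(f$records$id, "b")
  expect_equal(attr(f, "removed"), "a")

  # 16S: exactly 350 ungapped bases is retained (the rule drops "shorter than")
  s16 <- make_dataset(c("a", "b"), c("Sp one", "Sp two"),
                      c(paste0(mono_seq(350), "--"), paste0(mono_seq(349), "---")),
                      marker = "16S")
  suppressMessages(f <- filter_by_length(s16))
  expect_equal(f$records$id, "a")

  # ITS2 fractional rule with explicit full length: floor is 0.7 * 100 = 70
  its <- make_dataset(c("a", "b"), c("Sp one", "Sp two"),
                      c(mono_seq(70), paste0(mono_seq(69), "-")), marker = "ITS2")
  suppressMessages(f <- filter_by_length(its, full_length = 100))
  expect_equal(f$records$id, "a")

  # empty dataset passes through
  empty <- subset_records(coi, integer(0))
  expect_equal(nrow(filter_by_length(empty)$records), 0L)
})

test_that("length filter is idempotent and partitions the input", {
  set.seed(7)
  ds <- make_dataset(sprintf("r%02d", 1:12), rep("Sp one", 12),
                     vapply(sample(440:460, 12, TRUE),
                            function(n) paste0(random_seq(n), strrep("-", 460 - n)), ""),
                     marker = "COI")
  suppressMessages(once <- filter_by_length(ds))
  suppressMessages(twice <- filter_by_length(once))
  expect_equal(twice$records, once$records)
  expect_equal(nrow(once$records) + length(attr(once, "removed")), nrow(ds$records))
})

test_that("trimming keeps exactly the mutually covered region", {
  # identical full-length records are untouched
  ds <- make_dataset(c("a", "b"), c("Sp one", "Sp one"),
                     c(mono_seq(120), mono_seq(120)))
  expect_equal(trim_to_common_region(ds)$records$residues, rep(mono_seq(120), 2))

  # a 10-column leading overhang is removed for all records
  ds <- make_dataset(c("a", "b"), c("Sp one", "Sp one"),
                     c(paste0(strrep("-", 10), mono_seq(110)), mono_seq(120)))
  tr <- trim_to_common_region(ds)
  expect_equal(tr$alignment_length, 110L)
  expect_equal(tr$records$residues[1], mono_seq(110))

  # three staggered fragments: brute-force column scan gives the overlap
  L <- 200
  cover <- list(a = 1:140, b = 41:180, c = 81:200)
  seqs <- vapply(cover, function(idx) {
    x <- rep("-", L)
    x[idx] <- "A"
    paste(x, collapse = "")
  }, "")
  covered_cols <- Reduce(intersect, cover)
  ds <- make_dataset(names(cover), rep("Sp one", 3), unname(seqs))
  tr <- trim_to_common_region(ds)
  expect_equal(tr$alignment_length, length(covered_cols))

  # disjoint fragments violate the minimum-overlap guard
  ds <- make_dataset(c("a", "b"), c("Sp one", "Sp one"),
                     c(paste0(mono_seq(60), strrep("-", 60)),
                       paste0(strrep("-", 60), mono_seq(60))))
  expect_error(trim_to_common_region(ds), "overlap")
})

test_that("evaluation sets follow the multiple-accession and reliability rules", {
  # 5 species x 4 records, all published adults -> set2 holds all 20 records
  ds <- make_dataset(sprintf("r%02d", 1:20),
                     rep(sprintf("Genus sp%d", 1:5), each = 4),
                     replicate(20, mono_seq(60)))
  sets <- build_evaluation_sets(ds)
  expect_equal(length(sets$set2), 20L)
  expect_equal(sets$set2$role, "set2")

  # singleton species are excluded from set2; all-singleton data -> empty set2
  ds <- make_dataset(c("r1", "r2", "r3"),
                     c("Genus sp1", "Genus sp2", "Genus sp3"),
                     replicate(3, mono_seq(60)))
  expect_equal(length(build_evaluation_sets(ds)$set2), 0L)

  # set1 keeps published/amplified/screened-in only; set3 additionally drops
  # subadult amplified and screened-in records
  ds <- make_dataset(sprintf("r%d", 1:6), rep("Genus sp1", 6),
                     replicate(6, mono_seq(60)),
                     status = c("published", "amplified", "amplified",
                                "screened-in", "screened-out", "unpublished"),
                     stage = c("adult", "adult", "subadult", "adult", "adult", "adult"))
  sets <- build_evaluation_sets(ds)
  expect_setequal(sets$set1$records$id, c("r1", "r2", "r3", "r4"))
  expect_setequal(sets$set3$records$id, c("r1", "r2"))
  expect_true(all(table(sets$set2$records$species) >= 2))
  expect_lte(length(sets$set2), length(sets$set1))
})
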