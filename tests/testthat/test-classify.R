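test_that("nearest-neighbour assignment, ties and no-hit states", {
  ids <- c("q", "a1", "a2", "b1")
  sp <- c("Genus query", "Genus alpha", "Genus alpha", "Genus beta")
  m <- as_k2p_dist(sym_matrix(ids, list("q|a1" = 0.01, "q|a2" = 0.02, "q|b1" = 0.10,
                                        "a1|a2" = 0.01, "a1|b1" = 0.1, "a2|b1" = 0.1)))
  ref <- make_dataset(ids[-1], sp[-1], rep("ACGT", 3))
  cl <- nn_identify("q", m, ref)
  expect_equal(cl$state, "assigned")
  expect_equal(cl$assigned_species, "Genus alpha")
  expect_equal(cl$support, 0.01)

  # exact equidistance across two species -> uncertain with the tie listed
  m2 <- as_k2p_dist(sym_matrix(ids, list("q|a1" = 0.05, "q|a2" = 0.06, "q|b1" = 0.05,
                                         "a1|a2" = 0.01, "a1|b1" = 0.1, "a2|b1" = 0.1)))
  cl <- nn_identify("q", m2, ref)
  expect_equal(cl$state, "uncertain")
  expect_equal(cl$tied_species, c("Genus alpha", "Genus beta"))

  # all reference distances undefined -> no-hit
  v <- sym_matrix(ids, list())
  v[1, -1] <- v[-1, 1] <- NA
  cl <- nn_identify("q", as_k2p_dist(v), ref)
  expect_equal(cl$state, "no-hit")
})

test_that("nn calls equal the row-argmin oracle on a simulated panel", {
  sim <- simulate_dataset(sim_config(seed = 31, n_genera = 3, species_per_genus = 4,
                                     records_per_species = 3, seq_length = 400))
  m <- distance_matrix(sim$dataset)
  species_of <- setNames(sim$dataset$records$species, sim$dataset$records$id)
  for (qid in sim$dataset$records$id[1:20]) {
    ref <- subset_records(sim$dataset, setdiff(sim$dataset$records$id, qid))
    cl <- nn_identify(qid, m, ref)
    oracle_sp <- nn_oracle(qid, m$values, species_of)
    if (length(oracle_sp) == 1) {
      expect_equal(cl$assigned_species, oracle_sp)
    } else {
      expect_equal(cl$state, "uncertain")
      expect_setequal(cl$tied_species, oracle_sp)
    }
  }
})

test_that("best-hit ranking equals an independent Smith-Waterman oracle", {
  set.seed(17)
  refs <- replicate(8, random_seq(90))
  query <- list(id = "q", residues = refs[3])   # identical to one reference
  ds <- make_dataset(sprintf("r%d", 1:8), sprintf("Genus sp%d", 1:8), refs)
  cl <- best_hit_identify(query, ds, identity_floor = 0, evalue_cutoff = Inf)
  hits <- attr(cl, "hits")
  oracle_scores <- vapply(refs, function(r) sw_oracle(query$residues, r), 0)
  expect_equal(hits$score[match(ds$records$id, hits$id)], unname(oracle_scores))
  expect_equal(cl$assigned_species, "Genus sp3")
  # bit score / E-value algebra
  expect_equal(hits$bit_score, (0.625 * hits$score - log(0.41)) / log(2))
  expect_equal(hits$evalue, 90 * 90 * 2^(-hits$bit_score))
})

test_that("best-hit uncertainty, identity floor and no-hit behaviour", {
  base <- random_seq(100)
  ds <- make_dataset(c("r1", "r2", "r3"),
                     c("Genus alpha", "Genus beta", "Genus gamma"),
                     c(base, base, random_seq(100)))
  cl <- best_hit_identify(list(id = "q", residues = base), ds)
  expect_equal(cl$state, "uncertain")
  expect_setequal(cl$tied_species, c("Genus alpha", "Genus beta"))

  # ~70% identity everywhere with a 0.8 floor -> no hit
  set.seed(23)
  mutate30 <- function(s) {
    x <- strsplit(s, "")[[1]]
    i <- sample(length(x), 30)
    x[i] <- vapply(x[i], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(x, collapse = "")
  }
  far <- make_dataset(c("r1", "r2"), c("Genus alpha", "Genus beta"),
                      c(mutate30(base), mutate30(base)))
  cl <- best_hit_identify(list(id = "q", residues = base), far,
                          identity_floor = 0.8, evalue_cutoff = Inf)
  expect_equal(cl$state, "no-hit")

  expect_error(best_hit_identify(list(id = "q", residues = base), ds,
                                 scoring = list(match = 0, mismatch = -3,
                                                gap_open = 5, gap_extend = 2)),
               "match reward")
})

test_that("neighbour joining recovers additive trees and correlates with input", {
  # additive distances from ((A,B),(C,D)) with internal branch 0.3
  bl <- c(A = 0.1, B = 0.2, C = 0.15, D = 0.25)
  ids <- names(bl)
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  internal <- function(i, j) if (i %in% c("A", "B") == j %in% c("A", "B")) 0 else 0.3
  for (i in ids) for (j in ids) if (i != j) m[i, j] <- bl[i] + bl[j] + internal(i, j)
  tree <- nj_tree(as_k2p_dist(m))
  expect_true(all(tree$edge.length >= 0))
  # the split {A,B} | {C,D} must be present and branch lengths exact:
  # an additive matrix is reproduced perfectly by its tree path lengths
  cm <- ape::cophenetic.phylo(tree)[ids, ids]
  expect_equal(cm, m, tolerance = 1e-10)

  # ultrametric 3-taxon matrix: the single unrooted topology, exact lengths
  m3 <- sym_matrix(c("A", "B", "C"), list("A|B" = 0.2, "A|C" = 0.4, "B|C" = 0.4))
  t3 <- nj_tree(as_k2p_dist(m3))
  expect_equal(ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")], m3,
               tolerance = 1e-10)

  expect_error(nj_tree(as_k2p_dist(m3[1:2, 1:2])), "at least 3")

  # noisy 12-taxon data: cophenetic distances track the input matrix
  sim <- simulate_dataset(sim_config(seed = 41, n_genera = 2, species_per_genus = 3,
                                     records_per_species = 2, seq_length = 500))
  mm <- distance_matrix(sim$dataset)
  tr <- nj_tree(mm)
  cm <- ape::cophenetic.phylo(tr)[mm$ids, mm$ids]
  ut <- upper.tri(cm)
  expect_gt(cor(cm[ut], mm$values[ut]), 0.9)
})

test_that("liberal tree rule honours the sister / nested monospecific patterns", {
  sp <- c(x1 = "Genus alpha", x2 = "Genus alpha")
  # ((x1, x2), q): query sister to a monospecific clade
  t1 <- ape::read.tree(text = "((x1:0.01,x2:0.01):0.03,q:0.02);")
  cl <- liberal_tree_identify(t1, "q", sp)
  expect_equal(cl$assigned_species, "Genus alpha")

  # ((x1, q), x2): query nested within a monospecific clade
  t2 <- ape::read.tree(text = "((x1:0.01,q:0.01):0.03,x2:0.02);")
  cl <- liberal_tree_identify(t2, "q", sp)
  expect_equal(cl$assigned_species, "Genus alpha")

  # sibling subtree with two species -> uncertain
  t3 <- ape::read.tree(text = "((x1:0.01,y1:0.01):0.03,q:0.02);")
  cl <- liberal_tree_identify(t3, "q", c(x1 = "Genus alpha", y1 = "Genus beta"))
  expect_equal(cl$state, "uncertain")

  # nested pattern with a different outer species -> ambiguous, uncertain
  t4 <- ape::read.tree(text = "(((x1:0.01,q:0.01):0.02,y1:0.02):0.03,(y2:0.01,y3:0.01):0.03);")
  cl <- liberal_tree_identify(t4, "q", c(x1 = "Genus alpha", y1 = "Genus beta",
                                         y2 = "Genus beta", y3 = "Genus beta"))
  expect_equal(cl$state, "uncertain")
  expect_setequal(cl$tied_species, c("Genus alpha", "Genus beta"))

  expect_error(liberal_tree_identify(t1, "zz", sp), "not a tip")
})

test_that("threshold veto turns distant tree assignments uncertain", {
  tree <- ape::read.tree(text = "((x1:0.01,x2:0.01):0.03,q:0.02);")
  sp <- c(x1 = "Genus alpha", x2 = "Genus alpha")
  mk <- function(dq) as_k2p_dist(sym_matrix(c("q", "x1", "x2"),
                                            list("q|x1" = dq, "q|x2" = dq + 0.01,
                                                 "x1|x2" = 0.01)))
  vetoed <- liberal_tree_threshold_identify(tree, "q", sp, mk(0.20), 0.0613)
  expect_equal(vetoed$state, "uncertain")
  kept <- liberal_tree_threshold_identify(tree, "q", sp, mk(0.01), 0.0613)
  expect_equal(kept$assigned_species, "Genus alpha")

  # composition property: tree call masked by the distance test
  sim <- simulate_dataset(sim_config(seed = 51, n_genera = 2, species_per_genus = 3,
                                     records_per_species = 3, seq_length = 300))
  m <- distance_matrix(sim$dataset)
  tr <- nj_tree(m)
  species_map <- setNames(sim$dataset$records$species, sim$dataset$records$id)
  for (qid in sim$dataset$records$id[1:8]) {
    smap <- species_map[names(species_map) != qid]
    plain <- liberal_tree_identify(tr, qid, smap)
    both <- liberal_tree_threshold_identify(tr, qid, smap, m, 0.05)
    dmin <- min(m$values[qid, names(smap)], na.rm = TRUE)
    if (plain$state == "assigned" && dmin < 0.05) {
      expect_equal(both$assigned_species, plain$assigned_species)
    } else {
      expect_true(both$state != "assigned")
    }
  }
})

test_that("screening admits clustered conspecifics and rejects misplaced sequences", {
  # unpublished record sister to a published conspecific -> in
  tree <- ape::read.tree(
    text = "((unp1:0.01,pub1:0.01):0.05,(pub2:0.01,pub3:0.01):0.05);")
  ds <- make_dataset(c("unp1", "pub1", "pub2", "pub3"),
                     c("Genus alpha", "Genus alpha", "Genus beta", "Genus beta"),
                     rep("ACGT", 4),
                     status = c("unpublished", "published", "published", "published"))
  out <- screen_unpublished(tree, ds)
  expect_equal(out$records$status[1], "screened-in")

  # unpublished record nested among reliable records of another species -> out
  ds2 <- make_dataset(c("unp1", "pub1", "pub2", "pub3"),
                      c("Genus beta", "Genus alpha", "Genus beta", "Genus beta"),
                      rep("ACGT", 4),
                      status = c("unpublished", "published", "published", "published"))
  out2 <- screen_unpublished(tree, ds2)
  expect_equal(out2$records$status[1], "screened-out")
  expect_match(attr(out2, "screening")$reason, "another species")

  # no reliable conspecific anywhere -> out with the dedicated reason
  ds3 <- make_dataset(c("unp1", "pub1", "pub2", "pub3"),
                      c("Genus gamma", "Genus alpha", "Genus beta", "Genus beta"),
                      rep("ACGT", 4),
                      status = c("unpublished", "published", "published", "published"))
  out3 <- screen_unpublished(tree, ds3)
  expect_equal(out3$records$status[1], "screened-out")
  expect_match(attr(out3, "screening")$reason, "no reliable conspecific")

  # published/amplified records never change status
  expect_equal(out$records$status[-1], ds$records$status[-1])
  expect_error(screen_unpublished(tree, make_dataset("zz", "Genus x", "ACGT")),
               "missing from tree")
})
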