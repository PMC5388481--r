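two_locus_fixture <- function() {
  # locus A separates species S1/S2 but interleaves S3/S4; locus B does the
  # opposite; only the concatenation carries both signals.
  set.seed(61)
  ids <- c(paste0("s1_", 1:2), paste0("s2_", 1:2), paste0("s3_", 1:2),
           paste0("s4_", 1:2))
  sp <- rep(c("S1", "S2", "S3", "S4"), each = 2)
  blockA <- c(s1_1 = "AAAAAAAAAA", s1_2 = "AAAAAAAAAA",
              s2_1 = "GGGGGGGGGG", s2_2 = "GGGGGGGGGG",
              s3_1 = "AAAAAGGGGG", s3_2 = "AAAAAGGGGA",
              s4_1 = "AAAAAGGGGG", s4_2 = "AAAAAGGGGA")
  blockB <- c(s1_1 = "CCCCCTTTTT", s1_2 = "CCCCCTTTTC",
              s2_1 = "CCCCCTTTTT", s2_2 = "CCCCCTTTTC",
              s3_1 = "CCCCCCCCCC", s3_2 = "CCCCCCCCCC",
              s4_1 = "TTTTTTTTTT", s4_2 = "TTTTTTTTTT")
  pad <- function(block, L = 60) {
    core <- paste(sample(c("A", "C", "G", "T"), L - 10, TRUE), collapse = "")
    stats::setNames(paste0(block[ids], core), ids)
  }
  list(A = make_dataset(pad(blockA), sp, locus = "A"),
       B = make_dataset(pad(blockB), sp, locus = "B"))
}

test_that("shared specimens are the per-locus id intersection", {
  dsX <- make_dataset(c(a = "ACGT", b = "ACGA", c = "AGGA"),
                      c("P", "P", "Q"), locus = "X")
  dsY <- make_dataset(c(b = "TTGA", c = "TTGG", d = "ATGA"),
                      c("P", "Q", "Q"), locus = "Y")
  expect_setequal(shared_specimens(list(X = dsX, Y = dsY), c("X", "Y")),
                  c("b", "c"))
  expect_error(shared_specimens(list(X = dsX), c("X", "Z")),
               class = "input_error")
  expect_error(shared_specimens(list(X = dsX, Y = dsY), "X"),
               class = "input_error")
})

test_that("concatenation is column-additive with a recoverable partition", {
  fx <- two_locus_fixture()
  cat_ds <- concatenate_loci(fx, c("B", "A"))  # order normalised internally
  expect_equal(cat_ds$length, fx$A$length + fx$B$length)
  parts <- attr(cat_ds, "partition")
  expect_named(parts, c("A", "B"))  # canonical sorted order
  slices <- split_concatenated(cat_ds)
  expect_identical(unname(slices$A$seqs), unname(fx$A$seqs[cat_ds$ids]))
  expect_identical(unname(slices$B$seqs), unname(fx$B$seqs[cat_ds$ids]))

  expect_error(concatenate_loci(fx, c("A", "B"), specimens = "s1_1"),
               class = "input_error")
  expect_error(concatenate_loci(fx, c("A", "B"),
                                specimens = c("s1_1", "zzz")),
               class = "input_error")
})

test_that("self-concatenation doubles counts but keeps p-distance fixed", {
  set.seed(67)
  seqs <- related_seqs(4, 80)
  ds <- make_dataset(seqs, c("A", "A", "B", "B"))
  dbl <- concatenate_loci(list(L1 = ds, L2 = `class<-`(
    modifyList(unclass(ds), list(locus = "L2")),
    class(ds))), c("L1", "L2"))
  p1 <- distance_matrix(ds, model = "p")$d
  p2 <- distance_matrix(dbl, model = "p")$d
  expect_equal(p2[rownames(p1), colnames(p1)], p1)
  k1 <- distance_matrix(ds, model = "k2p")$d
  k2 <- distance_matrix(dbl, model = "k2p")$d
  expect_equal(k2[rownames(k1), colnames(k1)], k1)
})

test_that("combination enumeration covers all subsets of an arity", {
  sim <- simulate_dataset(study_fixture(seed = 12))
  res <- evaluate_combinations(sim$datasets, arities = 2, n_reps = 0)
  analysed <- length(res)
  skipped <- nrow(attr(res, "skipped"))
  expect_equal(analysed + skipped, choose(6, 2))
  tab <- combination_table(res)
  expect_true(all(tab$arity == "di"))
  expect_true(all(tab$shared_specimens >= 3))
})

test_that("complementary loci resolve all species only when combined", {
  fx <- two_locus_fixture()
  res <- evaluate_combinations(fx, arities = 2, n_reps = 50, seed = 5)
  expect_length(res, 1)
  combo <- res[[1]]
  expect_equal(combo$shared_specimens, 8)
  mono <- combo$monophyly
  expect_true(all(mono$monophyletic))
  expect_setequal(combo$monophyletic_species, c("S1", "S2", "S3", "S4"))
  # single-locus runs cannot separate both pairs
  mA <- test_monophyly(nj_tree(distance_matrix(fx$A)), fx$A$species)
  expect_false(all(mA$monophyletic))
})

test_that("a constant second locus preserves single-locus monophyly", {
  set.seed(71)
  # three clearly separated species pairs at locus L1
  base <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  centroid <- function(from, to) {
    s <- base
    s[from:to] <- chartr("ACGT", "GTAC", s[from:to])
    s
  }
  # every species has its own stem away from the shared ancestor
  cents <- list(A = centroid(71, 80), B = centroid(1, 10), C = centroid(41, 50))
  jitter1 <- function(s, i) { s[i] <- "T"; paste(s, collapse = "") }
  seqs <- c(a1 = jitter1(cents$A, 91), a2 = jitter1(cents$A, 92),
            b1 = jitter1(cents$B, 93), b2 = jitter1(cents$B, 94),
            c1 = jitter1(cents$C, 95), c2 = jitter1(cents$C, 96))
  sp <- rep(c("A", "B", "C"), each = 2)
  ds1 <- make_dataset(seqs, sp, locus = "L1")
  const <- stats::setNames(rep(paste(rep("A", 60), collapse = ""), 6),
                           names(seqs))
  ds2 <- make_dataset(const, sp, locus = "L2")
  m1 <- test_monophyly(nj_tree(distance_matrix(ds1)), ds1$species)
  expect_true(all(m1$monophyletic))
  cat_ds <- concatenate_loci(list(L1 = ds1, L2 = ds2), c("L1", "L2"))
  m2 <- test_monophyly(nj_tree(distance_matrix(cat_ds)), cat_ds$species)
  for (s in m1$species[m1$monophyletic]) {
    expect_true(m2$monophyletic[m2$species == s])
  }
})

test_that("combination results do not depend on locus input order", {
  fx <- two_locus_fixture()
  r1 <- combination_table(evaluate_combinations(fx, arities = 2, n_reps = 0))
  r2 <- combination_table(evaluate_combinations(rev(fx), arities = 2,
                                                n_reps = 0))
  expect_equal(r1, r2)
})

test_that("subsets without enough species or specimens are skipped, logged", {
  dsX <- make_dataset(c(a = "ACGTACGT", b = "ACGAACGT", c = "AGGAACGT",
                        d = "AGGTACGT"), rep("OnlySp", 4), locus = "X")
  dsY <- make_dataset(c(a = "TTGACCGT", b = "TTGGCCGT", c = "ATGACCGT",
                        d = "ATGACCGA"), rep("OnlySp", 4), locus = "Y")
  res <- evaluate_combinations(list(X = dsX, Y = dsY), arities = 2,
                               n_reps = 0)
  expect_length(res, 0)
  expect_match(attr(res, "skipped")$reason, "species")

  dsZ <- make_dataset(c(e = "ACGT", f = "ACGA"), c("P", "Q"), locus = "Z")
  res2 <- evaluate_combinations(list(X = dsX, Z = dsZ), arities = 2,
                                n_reps = 0)
  expect_length(res2, 0)
  expect_match(attr(res2, "skipped")$reason, "shared")
})
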