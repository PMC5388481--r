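test_that("NJ solves the three-taxon case exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
})

test_that("NJ recovers a four-taxon additive tree and its path lengths", {
  tr0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr0)
  est <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D)
  # split AB|CD present
  expect_true("ab|cd" %in% vapply(oracle_splits(est), function(k) {
    tips <- sort(est$tip.label[as.integer(strsplit(k, ",")[[1]])])
    halves <- c(tolower(paste(tips, collapse = "")),
                tolower(paste(sort(setdiff(est$tip.label, tips)),
                              collapse = "")))
    paste(sort(halves), collapse = "|")
  }, character(1)))
})

test_that("NJ is deterministic on fully tied input", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length == 0))
})

test_that("NJ refuses undefined pairs and tiny inputs", {
  expect_error(nj_tree(matrix(0, 2, 2)), class = "input_error")
  seqs <- c(u = paste(rep("A", 100), collapse = ""),
            v = paste(c(rep("G", 40), rep("C", 25), rep("A", 35)),
                      collapse = ""),
            w = paste(rep("A", 100), collapse = ""))
  dm <- distance_matrix(make_dataset(seqs, c("A", "B", "A")), model = "k2p")
  expect_error(nj_tree(dm), "u~v", class = "input_error")
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    v <- runif(n * (n - 1) / 2, 0.05, 1)
    d[upper.tri(d)] <- v
    d <- d + t(d)
    ours <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ours, ape::unroot(ref)), 0, ignore_attr = TRUE)
  }
})

test_that("negative NJ branches are clamped with the deficit recorded", {
  # non-additive matrix known to produce a negative internal estimate
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 8,
                5, 5, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "neg_deficit"), 0)
})

test_that("bootstrap gives full support to a clean bipartition", {
  # two 4-specimen clusters differing at 50 of 100 sites (25 transitions,
  # 25 transversions, keeping the K2P correction well-defined), identical
  # within clusters
  base <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  other <- base
  other[1:25] <- chartr("ACGT", "GTAC", base[1:25])   # transitions
  other[26:50] <- chartr("ACGT", "CATG", base[26:50]) # transversions
  seqs <- c(stats::setNames(rep(paste(base, collapse = ""), 4),
                            paste0("x", 1:4)),
            stats::setNames(rep(paste(other, collapse = ""), 4),
                            paste0("y", 1:4)))
  ds <- make_dataset(seqs, rep(c("X sp", "Y sp"), each = 4))
  tr <- bootstrap_supports(ds, n_reps = 50, seed = 1)
  mono <- test_monophyly(tr, ds$species)
  expect_true(all(mono$monophyletic))
  expect_equal(mono$support[mono$species == "X sp"], 100)
  expect_equal(mono$support[mono$species == "Y sp"], 100)
})

test_that("bootstrap is reproducible under a fixed seed and rejects n_reps 0", {
  set.seed(41)
  seqs <- related_seqs(6, 120)
  ds <- make_dataset(seqs, rep(c("A", "B", "C"), each = 2))
  t1 <- bootstrap_supports(ds, n_reps = 30, seed = 99)
  t2 <- bootstrap_supports(ds, n_reps = 30, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(attr(t1, "supports"), attr(t2, "supports"))
  sup <- attr(t1, "supports")
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_error(bootstrap_supports(ds, n_reps = 0), class = "input_error")
})

test_that("bootstrap support increases with signal strength", {
  make_two_cluster <- function(n_diff) {
    base <- rep("A", 200)
    other <- base
    if (n_diff > 0) other[seq_len(n_diff)] <- "G"
    noise <- function(s, k) {
      i <- sample(200, k)
      s[i] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(s, collapse = "")
    }
    c(stats::setNames(replicate(3, noise(base, 4)), paste0("x", 1:3)),
      stats::setNames(replicate(3, noise(other, 4)), paste0("y", 1:3)))
  }
  set.seed(55)
  sup <- vapply(c(2, 10, 60), function(nd) {
    ds <- make_dataset(make_two_cluster(nd), rep(c("X", "Y"), each = 3))
    tr <- bootstrap_supports(ds, n_reps = 60, seed = 7)
    m <- test_monophyly(tr, ds$species)
    s <- m$support[m$species == "X"]
    if (length(s) == 0 || is.na(s)) 0 else s
  }, numeric(1))
  expect_true(sup[1] <= sup[2] + 15)  # allow bootstrap noise at the low end
  expect_lte(sup[2], sup[3])
  expect_gt(sup[3], 95)
})

test_that("monophyly matches nesting structure with an outgroup present", {
  # species A nests inside species B; C is the outgroup
  tr <- ape::read.tree(text = "(((A1:1,A2:1):1,B1:1):1,B2:1,C1:1);")
  sm <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C")
  res <- test_monophyly(tr, sm)
  expect_true(res$monophyletic[res$species == "A"])
  expect_false(res$monophyletic[res$species == "B"])
  expect_true(res$monophyletic[res$species == "C"])  # singleton, trivially
  expect_error(test_monophyly(tr, sm[-1]), class = "input_error")
})

test_that("Newick read/write round-trips topology, lengths and supports", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)90:1,(C:1,D:1)85:1);", path)
  tr <- read_tree(path)
  sup <- attr(tr, "supports")
  expect_setequal(sup[!is.na(sup)], c(90, 85))
  out <- tempfile(fileext = ".nwk")
  write_tree(tr, out)
  tr2 <- read_tree(out)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
  expect_identical(sort(attr(tr2, "supports")), sort(sup))

  expect_error(read_tree(path, ids = c("A", "B", "C")), "D",
               class = "input_error")
  bad <- tempfile()
  writeLines("not a newick ((", bad)
  expect_error(read_tree(bad), class = "input_error")
})
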