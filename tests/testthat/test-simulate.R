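small_cfg <- function(seed = 1, L = 500, div = 0.05, intra = 0.005,
                      dropout = NULL, n1 = 3, n2 = 3) {
  sim_config(
    seed = seed,
    species = data.frame(name = c("Sp one", "Sp two"),
                         n_specimens = c(n1, n2),
                         status = c("invasive", "native"),
                         stringsAsFactors = FALSE),
    species_tree = sprintf("(Sp_one:%g,Sp_two:%g);", div / 2, div / 2),
    loci = data.frame(name = "locA", length = L, rate = 1,
                      stringsAsFactors = FALSE),
    intraspecific_scale = intra,
    kappa = 3,
    dropout = dropout)
}

test_that("config validation rejects broken inputs before any output", {
  expect_error(small_cfg(seed = NA), class = "input_error")
  expect_error({
    cfg <- small_cfg()
    sim_config(seed = 1, species = cfg$species, species_tree = "((",
               loci = cfg$loci)
  }, class = "input_error")
  expect_error({
    cfg <- small_cfg()
    sim_config(seed = 1, species = cfg$species,
               species_tree = cfg$species_tree,
               loci = data.frame(name = "x", length = 10))
  }, class = "input_error")
  expect_error(small_cfg(intra = -1), class = "input_error")
})

test_that("full dropout success keeps every specimen at every locus", {
  sim <- simulate_dataset(small_cfg(seed = 4))
  expect_equal(length(sim$datasets$locA$ids), 6)
  expect_true(all(sim$truth$presence))
  expect_equal(sim$metadata$specimen_id, sprintf("ww%05d", 1:6))
})

test_that("identical seeds give byte-identical FASTA output", {
  d1 <- tempfile()
  d2 <- tempfile()
  write_simulation(simulate_dataset(small_cfg(seed = 77)), d1)
  write_simulation(simulate_dataset(small_cfg(seed = 77)), d2)
  f1 <- file.path(d1, "locA.fasta")
  f2 <- file.path(d2, "locA.fasta")
  expect_identical(readLines(f1), readLines(f2))
  d3 <- tempfile()
  write_simulation(simulate_dataset(small_cfg(seed = 78)), d3)
  expect_false(identical(readLines(f1),
                         readLines(file.path(d3, "locA.fasta"))))
})

test_that("interspecific K2P estimates recover the design divergence", {
  # 2 species, design divergence 0.05, intraspecific 0.005, 2000 nt
  ests <- vapply(1:20, function(s) {
    sim <- simulate_dataset(small_cfg(seed = 100 + s, L = 2000, div = 0.05,
                                      intra = 0.005, n1 = 2, n2 = 2))
    ds <- sim$datasets$locA
    dm <- distance_matrix(ds, model = "k2p")
    inter <- dm$d[ds$species[rownames(dm$d)] == "Sp one",
                  ds$species[colnames(dm$d)] == "Sp two"]
    mean(inter)
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.05) / 0.05, 0.2)
  se <- stats::sd(ests) / sqrt(length(ests))
  # expected pairwise divergence is design + intraspecific terminal branches
  expect_lt(abs(mean(ests) - (0.05 + 0.005)), 3 * se + 0.002)
})

test_that("designed barcode gaps are recovered; coincident designs are not", {
  hits <- vapply(1:60, function(s) {
    sim <- simulate_dataset(small_cfg(seed = 1000 + s, L = 1000, div = 0.05,
                                      intra = 0.005))
    ds <- sim$datasets$locA
    rows <- species_gap_summary(distance_matrix(ds), ds$species)
    all(rows$gap_present)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # coincident design (zero interspecific divergence, same expected pairwise
  # distance within and between): detection must not be systematic
  coin <- vapply(1:60, function(s) {
    sim <- simulate_dataset(small_cfg(seed = 2000 + s, L = 1000, div = 0,
                                      intra = 0.01))
    ds <- sim$datasets$locA
    rows <- species_gap_summary(distance_matrix(ds), ds$species)
    all(rows$gap_present)
  }, logical(1))
  expect_lt(mean(coin), 0.5)
})

test_that("dropout realisations match the emitted datasets", {
  drop <- matrix(c(1, 0.5), 2, 1,
                 dimnames = list(c("Sp one", "Sp two"), "locA"))
  sim <- simulate_dataset(small_cfg(seed = 9, dropout = drop, n1 = 4, n2 = 4))
  present <- rownames(sim$truth$presence)[sim$truth$presence[, "locA"]]
  expect_setequal(sim$datasets$locA$ids, present)
  sp1 <- sim$metadata$specimen_id[sim$metadata$species == "Sp one"]
  expect_true(all(sp1 %in% present))
})

test_that("indels appear as shared per-species gap runs", {
  cfg <- small_cfg(seed = 31)
  cfg$indel_rate <- 0.01
  sim <- simulate_dataset(cfg)
  ds <- sim$datasets$locA
  chm <- do.call(rbind, strsplit(ds$seqs, ""))
  gap_cols <- which(apply(chm == "-", 2, any))
  expect_gt(length(gap_cols), 0)
  for (cl in gap_cols) {
    who <- ds$ids[chm[, cl] == "-"]
    sps <- unique(ds$species[who])
    # gap columns cover complete species clades (shared deletions)
    expect_setequal(who, ds$ids[ds$species %in% sps])
  }
  # alignment stays rectangular and readable
  expect_equal(length(unique(nchar(ds$seqs))), 1)
})

test_that("the study-style fixture matches the published design counts", {
  cfg <- study_fixture(seed = 1)
  expect_equal(nrow(cfg$species), 12)
  expect_equal(sum(cfg$species$n_specimens), 66)
  expect_equal(sum(cfg$species$status == "invasive"), 5)
  expect_equal(cfg$species$n_specimens[
    cfg$species$name == "Eragrostis curvula"], 18)
  expect_equal(cfg$species$n_specimens[
    cfg$species$name == "Nassella neesiana"], 12)

  # amplification success structure
  expect_true(all(cfg$dropout[, "atpF"] >= 0.39))
  expect_equal(sum(cfg$dropout[, "atpF"] == 1), 10)
  expect_equal(sum(cfg$dropout[, "ITS"] == 0), 9)

  # the two congeners sit at small divergence, all else at >= 0.02
  div <- ape::cophenetic.phylo(cfg$tree)
  nas <- div["Nassella neesiana", "Nassella trichotoma"]
  expect_equal(nas, 0.005)
  offdiag <- div[upper.tri(div)]
  expect_true(all(offdiag[offdiag != nas] >= 0.02))
  expect_gte(cfg$intraspecific_scale, 0)

  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$metadata), 66)
  expect_equal(length(sim$datasets), 6)
})
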