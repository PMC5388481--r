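# Neighbour-joining trees, nonparametric bootstrap, species monophyly.
#
# Trees are ape "phylo" objects, unrooted with a basal trifurcation. Bootstrap
# supports live in tree$node.label (empty at the basal node) and, as numbers,
# in attr(tree, "supports").

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly joins the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`. Ties in Q are broken
#' by the smallest (row, column) index pair, so the result is deterministic;
#' negative branch lengths are clamped to zero with the clamped total recorded
#' in `attr(tree, "neg_deficit")`. Exact on additive distance matrices.
#'
#' @param dm A `barcode_dist` or a symmetric numeric matrix with dimnames;
#'   at least 3 taxa, no undefined (NA) entries.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "barcode_dist")) {
    if (nrow(dm$undefined_pairs) > 0)
      input_error(sprintf(
        "cannot build NJ tree: undefined distance for pair(s) %s",
        paste(apply(dm$undefined_pairs, 1, paste, collapse = "~"),
              collapse = ", ")))
    d <- dm$d
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  if (n < 3) input_error("NJ requires at least 3 taxa")
  if (anyNA(d)) input_error("NJ requires a complete distance matrix")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  res <- nj_core(unname(d))
  phy <- structure(list(edge = res$edge, edge.length = res$edge.length,
                        tip.label = labels, Nnode = res$Nnode),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "neg_deficit") <- res$neg.deficit
  if (res$neg.deficit > 0)
    be_log(sprintf("NJ clamped negative branch length(s); total deficit %.6g",
                   res$neg.deficit), verbose = FALSE)
  phy
}

# Canonical bipartition keys of an unrooted tree, mapped to internal nodes.
# Each internal node other than the basal one defines one bipartition; the
# canonical side is the one NOT containing tip 1 (tip indices refer to
# `tip_order` when given, so keys are comparable across trees that share a
# taxon set in different internal orders).
tree_splits <- function(phy, tip_order = NULL) {
  n <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  idx <- if (is.null(tip_order)) seq_len(n) else {
    m <- match(phy$tip.label, tip_order)
    if (anyNA(m)) input_error("tree tips do not match the reference taxon set")
    m
  }
  nodes <- n + seq_along(pp)
  keys <- vapply(seq_along(pp), function(i) {
    s <- sort(idx[pp[[i]]])
    if (1L %in% s) s <- setdiff(sort(idx), s)
    paste(s, collapse = ",")
  }, character(1))
  keep <- nodes != n + 1L  # the basal node carries no bipartition
  stats::setNames(nodes[keep], keys[keep])
}

#' Neighbour-joining tree with nonparametric bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times, rebuilds the tree on each resample, and
#' attaches to every internal edge of the full-data tree the percentage of
#' replicates containing the same bipartition. Replicates in which any
#' pairwise distance becomes undefined are dropped and counted; a warning is
#' issued when more than 10% are dropped. Specimens involved in undefined
#' distances on the full data are excluded before tree building (the excluded
#' roster is attached as `attr(tree, "excluded")`).
#'
#' @param dataset A `locus_dataset` (or concatenated dataset).
#' @param model `"k2p"` or `"p"`.
#' @param n_reps Number of bootstrap replicates (default 1000; must be >= 1).
#' @param seed Optional integer seed; fixing it makes the output
#'   reproducible to the byte.
#' @param deletion Site deletion mode, as in [distance_matrix()].
#' @return The full-data `phylo` tree with supports in `node.label` (percent,
#'   empty at the basal node) and numeric supports in
#'   `attr(tree, "supports")`; `attr(tree, "dropped_reps")` counts dropped
#'   replicates.
#' @export
bootstrap_supports <- function(dataset, model = c("k2p", "p"), n_reps = 1000,
                               seed = NULL, deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (n_reps < 1) input_error("n_reps must be >= 1 (use nj_tree for no bootstrap)")
  if (!is.null(seed)) set.seed(seed)

  prep <- prepare_tree_data(dataset, model, deletion)
  full <- prep$tree
  n <- length(full$tip.label)
  full_splits <- tree_splits(full, tip_order = full$tip.label)

  L <- ncol(prep$enc)
  counts <- stats::setNames(integer(length(full_splits)), names(full_splits))
  dropped <- 0L
  for (rep in seq_len(n_reps)) {
    w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    dvec <- dist_from_counts(pair_counts(prep$ind, w), model)
    if (anyNA(dvec)) {
      dropped <- dropped + 1L
      next
    }
    d <- matrix(0, n, n)
    d[prep$ind$pairs] <- dvec
    d[prep$ind$pairs[, 2:1, drop = FALSE]] <- dvec
    rownames(d) <- colnames(d) <- full$tip.label
    rep_tree <- nj_tree(d)
    ks <- names(tree_splits(rep_tree, tip_order = full$tip.label))
    hit <- ks[ks %in% names(counts)]
    counts[hit] <- counts[hit] + 1L
  }
  eff <- n_reps - dropped
  if (eff == 0) input_error("every bootstrap replicate was dropped")
  if (dropped > 0.1 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates dropped (undefined distances)",
                    dropped, n_reps))
  supports <- stats::setNames(rep(NA_real_, full$Nnode),
                              as.character(n + seq_len(full$Nnode)))
  supports[as.character(full_splits)] <- 100 * counts[names(full_splits)] / eff
  full$node.label <- ifelse(is.na(supports), "",
                            formatC(supports, format = "g", digits = 6))
  attr(full, "supports") <- supports
  attr(full, "dropped_reps") <- dropped
  attr(full, "excluded") <- prep$excluded
  full
}

# Shared preparation for tree building: exclude specimens with undefined
# full-data distances (greedy, most-involved first), encode, build the
# full-data tree and keep the site indicators for resampling.
prepare_tree_data <- function(dataset, model, deletion) {
  dm <- distance_matrix(dataset, model = model, deletion = deletion)
  excluded <- character(0)
  ids <- dataset$ids
  while (nrow(dm$undefined_pairs) > 0) {
    tallies <- sort(table(c(dm$undefined_pairs)), decreasing = TRUE)
    worst <- names(tallies)[1]
    excluded <- c(excluded, worst)
    ids <- setdiff(ids, worst)
    if (length(ids) < 3)
      input_error("fewer than 3 specimens remain after excluding undefined pairs")
    sub <- dataset
    sub$ids <- ids
    sub$seqs <- dataset$seqs[ids]
    dm <- distance_matrix(sub, model = model, deletion = deletion)
  }
  if (length(excluded) > 0)
    be_log(sprintf("excluded specimen(s) with undefined distances: %s",
                   paste(excluded, collapse = ", ")), verbose = FALSE)
  if (length(ids) < 3) input_error("NJ requires at least 3 specimens")
  seqs <- dataset$seqs[ids]
  enc <- encode_alignment(seqs)
  if (deletion == "complete") {
    keep <- colSums(is.na(enc)) == 0
    enc <- enc[, keep, drop = FALSE]
  }
  ind <- pair_site_indicators(enc)
  list(tree = nj_tree(dm), enc = enc, ind = ind, excluded = excluded)
}

#' Test species monophyly on a tree
#'
#' A species with two or more tips is monophyletic when removing a single
#' edge bipartitions the tips into exactly that species versus everything
#' else; its support is that edge's bootstrap value when present. Singleton
#' species are trivially monophyletic with support `NA`.
#'
#' @param tree A `phylo` tree (supports in `node.label` are used if present).
#' @param species_map Named character vector, specimen id to species,
#'   covering every tip.
#' @param support_threshold Percent support above which a monophyletic
#'   species is flagged `supported` (default 70).
#' @return A `data.frame` with columns `species`, `n_tips`, `monophyletic`,
#'   `support`, `supported`.
#' @export
test_monophyly <- function(tree, species_map, support_threshold = 70) {
  tips <- tree$tip.label
  sp <- unname(species_map[tips])
  if (anyNA(sp))
    input_error(sprintf("tip(s) missing from species map: %s",
                        paste(tips[is.na(sp)], collapse = ", ")))
  n <- length(tips)
  splits <- tree_splits(tree, tip_order = tips)
  supports <- attr(tree, "supports")
  if (is.null(supports) && !is.null(tree$node.label)) {
    supports <- suppressWarnings(as.numeric(tree$node.label))
    names(supports) <- as.character(n + seq_len(tree$Nnode))
  }
  all_idx <- seq_len(n)
  rows <- lapply(sort(unique(sp)), function(s) {
    own <- which(sp == s)
    if (length(own) == 1) {
      return(data.frame(species = s, n_tips = 1L, monophyletic = TRUE,
                        support = NA_real_, stringsAsFactors = FALSE))
    }
    key <- sort(own)
    if (1L %in% key) key <- setdiff(all_idx, key)
    key <- paste(key, collapse = ",")
    mono <- key %in% names(splits)
    supp <- NA_real_
    if (mono && !is.null(supports)) {
      node <- splits[[key]]
      supp <- unname(supports[as.character(node)])
    }
    data.frame(species = s, n_tips = length(own), monophyletic = mono,
               support = supp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$supported <- out$monophyletic & !is.na(out$support) &
    out$support > support_threshold
  out
}

#' Read a Newick tree
#'
#' Reads a Newick file (internal node labels are interpreted as bootstrap
#' supports where numeric), optionally validating the tip set against known
#' specimen ids — the route by which externally estimated trees (e.g. maximum
#' likelihood) enter the monophyly test.
#'
#' @param path Path to a Newick file.
#' @param ids Optional character vector of expected tip labels.
#' @return A `phylo` tree; numeric node labels are mirrored into
#'   `attr(tree, "supports")`.
#' @export
read_tree <- function(path, ids = NULL) {
  if (!file.exists(path)) input_error(sprintf("tree file not found: %s", path))
  phy <- tryCatch(suppressWarnings(ape::read.tree(path)),
                  error = function(e) input_error(sprintf(
                    "could not parse Newick '%s': %s", path,
                    conditionMessage(e))))
  if (is.null(phy)) input_error(sprintf("could not parse Newick '%s'", path))
  if (!is.null(ids)) {
    extra <- setdiff(phy$tip.label, ids)
    if (length(extra) > 0)
      input_error(sprintf("tree tip(s) absent from metadata: %s",
                          paste(extra, collapse = ", ")))
  }
  if (!is.null(phy$node.label)) {
    n <- length(phy$tip.label)
    supports <- suppressWarnings(as.numeric(phy$node.label))
    names(supports) <- as.character(n + seq_len(phy$Nnode))
    attr(phy, "supports") <- supports
  }
  phy
}

#' Write a tree as Newick
#'
#' Supports (node labels) are written as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a monophyly report
#'
#' @param rows A `data.frame` from [test_monophyly()], optionally with a
#'   `locus` column prepended by the caller.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_monophyly <- function(rows, path) {
  out <- rows
  out$support <- ifelse(is.na(out$support), "N/A", sprintf("%.1f", out$support))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
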