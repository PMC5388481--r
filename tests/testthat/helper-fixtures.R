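# Fixture builders shared across the test files. Everything is generated in
# code; no binary data.

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

make_matrix <- function(seqs, locus = "L1") {
  read_alignment(write_tmp_fasta(seqs), locus)
}

make_metadata <- function(ids, species, status = NULL) {
  data.frame(specimen_id = ids, species = species,
             status = status %||% rep("native", length(ids)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_dataset <- function(seqs, species, locus = "L1", status = NULL) {
  bind_dataset(make_matrix(seqs, locus),
               make_metadata(names(seqs), species, status))
}

# A random aligned matrix over ACGT with optional gaps / ambiguity codes.
random_seqs <- function(n, L, gap_prob = 0, amb_prob = 0) {
  pool <- c("A", "C", "G", "T")
  m <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  if (gap_prob > 0) m[runif(n * L) < gap_prob] <- "-"
  if (amb_prob > 0) {
    hit <- which(runif(n * L) < amb_prob)
    m[hit] <- sample(c("N", "R", "Y"), length(hit), replace = TRUE)
  }
  stats::setNames(apply(m, 1, paste, collapse = ""), paste0("s", seq_len(n)))
}

# Sequences at moderate divergence from a shared ancestor, so corrected
# distances stay defined.
related_seqs <- function(n, L, div = 0.15, gap_prob = 0) {
  pool <- c("A", "C", "G", "T")
  base <- sample(pool, L, replace = TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    s <- base
    hit <- which(runif(L) < div)
    s[hit] <- sample(pool, length(hit), replace = TRUE)
    s
  }, character(L)))
  if (gap_prob > 0) m[runif(n * L) < gap_prob] <- "-"
  stats::setNames(apply(m, 1, paste, collapse = ""), paste0("s", seq_len(n)))
}

# Random unrooted tree with strictly positive branch lengths and its additive
# path-length matrix.
random_additive <- function(n, min_bl = 0.1, max_bl = 2) {
  tr <- ape::unroot(ape::rtree(n))
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Independent bipartition oracle: enumerate every internal edge, collect the
# tip set on its child side by traversal of the edge matrix.
oracle_splits <- function(phy) {
  n <- length(phy$tip.label)
  E <- phy$edge
  keys <- character(0)
  for (e in seq_len(nrow(E))) {
    side <- integer(0)
    stack <- E[e, 2]
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      if (v <= n) side <- c(side, v) else stack <- c(stack, E[E[, 1] == v, 2])
    }
    if (length(side) >= 2 && length(side) <= n - 2) {
      s <- sort(side)
      if (1L %in% s) s <- setdiff(seq_len(n), s)
      keys <- c(keys, paste(s, collapse = ","))
    }
  }
  sort(unique(keys))
}

# Independent monophyly oracle: a species with >= 2 tips is monophyletic iff
# its tip set (or complement) appears among the enumerated bipartitions.
oracle_monophyly <- function(phy, species_map) {
  n <- length(phy$tip.label)
  sp <- unname(species_map[phy$tip.label])
  keys <- oracle_splits(phy)
  vapply(sort(unique(sp)), function(s) {
    own <- which(sp == s)
    if (length(own) < 2) return(TRUE)
    k <- sort(own)
    if (1L %in% k) k <- setdiff(seq_len(n), k)
    paste(k, collapse = ",") %in% keys
  }, logical(1))
}
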