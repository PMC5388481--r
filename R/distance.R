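# Pairwise p and Kimura 2-parameter distances.
#
# Sites enter a pairwise comparison only when both residues are unambiguous
# nucleotides (A/C/G/T): gaps, N and IUPAC ambiguity codes are deleted
# pairwise by default; complete deletion (drop every column containing any
# non-ACGT character) is available as an option. The K2P correction
# d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q), with P and Q the transition and
# transversion proportions, is undefined when either log argument is
# non-positive (saturation) or no comparable sites remain; such pairs are
# recorded, never silently dropped.

# A <-> G, C <-> T are transitions; encoding A=1, C=2, G=3, T=4.
.TS_PARTNER <- c(3L, 4L, 1L, 2L)

encode_alignment <- function(seqs) {
  L <- nchar(seqs[[1]])
  m <- t(vapply(strsplit(seqs, "", fixed = TRUE),
                function(x) match(x, .NT), integer(L)))
  rownames(m) <- names(seqs)
  m
}

# Per ordered pair (i < j, row-major as in combn) and per site, 0/1 indicator
# matrices for comparable sites, transitions and transversions. Stored as
# doubles so bootstrap counts reduce to a matrix-vector product with the
# column resampling weights.
pair_site_indicators <- function(enc) {
  n <- nrow(enc)
  L <- ncol(enc)
  idx <- t(utils::combn(n, 2L))
  P <- nrow(idx)
  comp <- matrix(0, P, L)
  ts <- matrix(0, P, L)
  tv <- matrix(0, P, L)
  for (k in seq_len(P)) {
    a <- enc[idx[k, 1L], ]
    b <- enc[idx[k, 2L], ]
    cc <- !is.na(a) & !is.na(b)
    tt <- cc
    tt[cc] <- .TS_PARTNER[a[cc]] == b[cc]
    vv <- cc
    vv[cc] <- a[cc] != b[cc] & !tt[cc]
    comp[k, ] <- cc
    ts[k, ] <- tt
    tv[k, ] <- vv
  }
  list(pairs = idx, comp = comp, ts = ts, tv = tv, n = n, L = L)
}

pair_counts <- function(ind, weights = NULL) {
  if (is.null(weights)) {
    list(comp = rowSums(ind$comp), ts = rowSums(ind$ts), tv = rowSums(ind$tv))
  } else {
    list(comp = drop(ind$comp %*% weights), ts = drop(ind$ts %*% weights),
         tv = drop(ind$tv %*% weights))
  }
}

# Vectorised distances from per-pair counts; NA where undefined.
dist_from_counts <- function(cnt, model) {
  ok <- cnt$comp > 0
  if (model == "p") {
    d <- rep(NA_real_, length(cnt$comp))
    d[ok] <- (cnt$ts[ok] + cnt$tv[ok]) / cnt$comp[ok]
    return(d)
  }
  P <- Q <- rep(NA_real_, length(cnt$comp))
  P[ok] <- cnt$ts[ok] / cnt$comp[ok]
  Q[ok] <- cnt$tv[ok] / cnt$comp[ok]
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- rep(NA_real_, length(P))
  def <- ok & !is.na(a1) & a1 > 0 & a2 > 0
  d[def] <- -0.5 * log(a1[def]) - 0.25 * log(a2[def])
  d
}

pairwise_counts_1 <- function(a, b) {
  if (nchar(a) != nchar(b))
    alignment_error("sequences have unequal aligned lengths")
  ea <- match(strsplit(toupper(a), "")[[1]], .NT)
  eb <- match(strsplit(toupper(b), "")[[1]], .NT)
  cc <- !is.na(ea) & !is.na(eb)
  ts <- sum(.TS_PARTNER[ea[cc]] == eb[cc])
  tv <- sum(ea[cc] != eb[cc]) - ts
  list(comp = sum(cc), ts = ts, tv = tv)
}

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among comparable sites (both residues in
#' A/C/G/T), i.e. pairwise deletion of gaps and ambiguity codes.
#'
#' @param a,b Aligned sequences (character scalars of equal length).
#' @return The p-distance as a proportion.
#' @examples
#' p_distance("ACGTACGTAC", "ACGTACGTAC")  # 0
#' p_distance("AAGTACGTAC", "ACGTACGTAT")  # 0.2
#' @export
p_distance <- function(a, b) {
  cnt <- pairwise_counts_1(a, b)
  if (cnt$comp == 0)
    undefined_distance("no comparable sites between the two sequences")
  (cnt$ts + cnt$tv) / cnt$comp
}

#' Pairwise Kimura 2-parameter distance between two aligned sequences
#'
#' Computes `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with P and Q the
#' transition and transversion proportions over comparable sites (pairwise
#' deletion, as in [p_distance()]). Raises an `undefined_distance` condition
#' when no comparable sites remain or either log argument is non-positive
#' (saturation).
#'
#' @inheritParams p_distance
#' @return The K2P distance (substitutions per site); always `>=` the
#'   p-distance of the same pair.
#' @export
k2p_distance <- function(a, b) {
  cnt <- pairwise_counts_1(a, b)
  if (cnt$comp == 0)
    undefined_distance("no comparable sites between the two sequences")
  P <- cnt$ts / cnt$comp
  Q <- cnt$tv / cnt$comp
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0)
    undefined_distance(sprintf(
      "K2P distance undefined (saturation): P = %.4f, Q = %.4f", P, Q))
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Full pairwise distance matrix for a locus dataset
#'
#' Computes all pairwise distances once under the requested model. Pairs for
#' which the model is undefined (no comparable sites, or K2P saturation) are
#' stored as `NA` and listed in `undefined_pairs` rather than raising an
#' error; summaries downstream exclude them.
#'
#' @param dataset A `locus_dataset` (or `aligned_matrix`) with at least two
#'   sequences.
#' @param model `"k2p"` (default) or `"p"`.
#' @param deletion `"pairwise"` (default) or `"complete"` (drop all columns
#'   containing any gap or ambiguity code before comparing).
#' @return An object of class `barcode_dist`: list with `ids`, `model`,
#'   `d` (symmetric numeric matrix, zero diagonal, `NA` where undefined) and
#'   `undefined_pairs` (two-column character matrix).
#' @export
distance_matrix <- function(dataset, model = c("k2p", "p"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (length(dataset$ids) < 2) input_error("need at least 2 sequences")
  enc <- encode_alignment(dataset$seqs)
  if (deletion == "complete") {
    keep <- colSums(is.na(enc)) == 0
    if (!any(keep)) input_error("complete deletion removed every column")
    enc <- enc[, keep, drop = FALSE]
  }
  ind <- pair_site_indicators(enc)
  dvec <- dist_from_counts(pair_counts(ind), model)
  dist_object(dataset$ids, model, ind$pairs, dvec)
}

dist_object <- function(ids, model, pairs, dvec) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[pairs] <- dvec
  d[pairs[, 2:1, drop = FALSE]] <- dvec
  und <- pairs[is.na(dvec), , drop = FALSE]
  undefined_pairs <- cbind(ids[und[, 1]], ids[und[, 2]])
  colnames(undefined_pairs) <- c("id_a", "id_b")
  structure(list(ids = ids, model = model, d = d,
                 undefined_pairs = undefined_pairs),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("Pairwise %s distance matrix: %d specimens", x$model,
              length(x$ids)))
  if (nrow(x$undefined_pairs) > 0)
    cat(sprintf(", %d undefined pair(s)", nrow(x$undefined_pairs)))
  cat("\n")
  invisible(x)
}

#' Write a distance matrix
#'
#' `format = "square"` writes a square TSV with ids as header row and first
#' column; `format = "long"` writes one row per unordered pair with columns
#' `id_a`, `id_b`, `model`, `distance` (empty where undefined).
#'
#' @param dm A `barcode_dist`.
#' @param path Output TSV path.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(id = dm$ids, dm$d, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- t(utils::combn(length(dm$ids), 2L))
    df <- data.frame(id_a = dm$ids[idx[, 1]], id_b = dm$ids[idx[, 2]],
                     model = dm$model, distance = dm$d[idx],
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
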