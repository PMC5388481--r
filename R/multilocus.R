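# Multilocus combination analyses: intersect shared specimens, concatenate
# alignments, rerun distances / gap / NJ + bootstrap / monophyly per subset.

.ARITY_NAMES <- c("2" = "di", "3" = "tri", "4" = "tetra", "5" = "penta",
                  "6" = "hexa")

#' Specimens shared by a set of loci
#'
#' @param datasets Named list of `locus_dataset`s (names are locus names).
#' @param loci Character vector (>= 2) of locus names to intersect.
#' @return Character vector of specimen ids sequenced at every named locus
#'   (in the specimen order of the first named locus).
#' @export
shared_specimens <- function(datasets, loci) {
  if (length(loci) < 2) input_error("need at least 2 loci to intersect")
  unknown <- setdiff(loci, names(datasets))
  if (length(unknown) > 0)
    input_error(sprintf("unknown locus name(s): %s",
                        paste(unknown, collapse = ", ")))
  Reduce(intersect, lapply(datasets[loci], function(d) d$ids))
}

#' Concatenate loci over a common specimen set
#'
#' Joins per-locus alignments column-wise in canonical (alphabetical) locus
#' order; the locus -> column-range partition map is retained as
#' `attr(x, "partition")`. Every requested specimen must be present at every
#' locus (intersect first with [shared_specimens()]).
#'
#' @param datasets Named list of `locus_dataset`s.
#' @param loci Locus names to concatenate.
#' @param specimens Specimen ids to include; default the shared set.
#' @return A `locus_dataset` whose `locus` is the `+`-joined locus names,
#'   with `attr(x, "partition")` a named list of `c(start, end)` columns.
#' @export
concatenate_loci <- function(datasets, loci, specimens = NULL) {
  loci <- sort(loci)
  if (is.null(specimens)) specimens <- shared_specimens(datasets, loci)
  if (length(specimens) < 2)
    input_error("concatenation needs at least 2 specimens")
  for (lc in loci) {
    missing <- setdiff(specimens, datasets[[lc]]$ids)
    if (length(missing) > 0)
      input_error(sprintf("specimen(s) %s not sequenced at locus %s",
                          paste(missing, collapse = ", "), lc))
  }
  parts <- list()
  offset <- 0L
  seqs <- stats::setNames(rep("", length(specimens)), specimens)
  for (lc in loci) {
    d <- datasets[[lc]]
    seqs <- paste0(seqs, d$seqs[specimens])
    parts[[lc]] <- c(start = offset + 1L, end = offset + d$length)
    offset <- offset + d$length
  }
  names(seqs) <- specimens
  first <- datasets[[loci[1]]]
  out <- structure(list(locus = paste(loci, collapse = "+"), ids = specimens,
                        seqs = seqs, length = offset,
                        species = first$species[specimens],
                        status = first$status[specimens],
                        singletons = NULL),
                   class = c("locus_dataset", "aligned_matrix"))
  counts <- table(out$species)
  out$singletons <- sort(names(counts)[counts == 1L])
  attr(out, "partition") <- parts
  out
}

#' Slice a concatenated dataset back into per-locus matrices
#'
#' Inverse of [concatenate_loci()] via the retained partition map.
#'
#' @param x A concatenated `locus_dataset` with a `partition` attribute.
#' @return Named list of `aligned_matrix` objects.
#' @export
split_concatenated <- function(x) {
  parts <- attr(x, "partition")
  if (is.null(parts)) input_error("dataset has no partition map")
  lapply(stats::setNames(names(parts), names(parts)), function(lc) {
    rng <- parts[[lc]]
    aligned_matrix(lc, x$ids, substr(x$seqs, rng["start"], rng["end"]))
  })
}

#' Evaluate multilocus combinations
#'
#' Enumerates all locus subsets of the requested arities, intersects shared
#' specimens, and for each viable subset (at least `min_shared` shared
#' specimens and `min_species` species) concatenates, computes distances,
#' builds an NJ tree with bootstrap supports, tests species monophyly and
#' summarises the barcode gap. Non-viable subsets are skipped with a logged
#' reason. Results are ordered by arity, then lexicographically by loci, and
#' are independent of the input order of `datasets`.
#'
#' @param datasets Named list of `locus_dataset`s.
#' @param arities Integer vector of subset sizes (subset of 2:6; default 2:5).
#' @param model Distance model, `"k2p"` or `"p"`.
#' @param n_reps Bootstrap replicates per combination (0 = no bootstrap).
#' @param support_threshold Percent support for confirming monophyly
#'   (default 70).
#' @param seed Optional integer seed for the bootstrap.
#' @param min_shared Minimum shared specimens for a viable subset (default 3).
#' @param min_species Minimum species among shared specimens (default 2).
#' @return An object of class `combination_results`: list of per-combination
#'   results (`loci`, `arity`, `shared_specimens`, `monophyly`,
#'   `monophyletic_species`, `gap_rows`, `locus_gap`, `tree`), with skipped
#'   subsets in `attr(x, "skipped")`.
#' @export
evaluate_combinations <- function(datasets, arities = 2:5,
                                  model = c("k2p", "p"), n_reps = 100,
                                  support_threshold = 70, seed = NULL,
                                  min_shared = 3, min_species = 2) {
  model <- match.arg(model)
  if (length(datasets) < 2) input_error("need at least 2 loci loaded")
  arities <- sort(unique(as.integer(arities)))
  if (any(arities < 2 | arities > 6))
    input_error("arities must lie in 2..6")
  if (!is.null(seed)) set.seed(seed)
  locus_names <- sort(names(datasets))
  results <- list()
  skipped <- data.frame(loci = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (arity in arities[arities <= length(locus_names)]) {
    subsets <- utils::combn(locus_names, arity, simplify = FALSE)
    for (loci in subsets) {
      label <- paste(loci, collapse = "+")
      shared <- shared_specimens(datasets, loci)
      if (length(shared) < min_shared) {
        skipped <- rbind(skipped, data.frame(
          loci = label,
          reason = sprintf("only %d shared specimen(s)", length(shared)),
          stringsAsFactors = FALSE))
        next
      }
      sp <- datasets[[loci[1]]]$species[shared]
      if (length(unique(sp)) < min_species) {
        skipped <- rbind(skipped, data.frame(
          loci = label,
          reason = sprintf("only %d species among shared specimens",
                           length(unique(sp))),
          stringsAsFactors = FALSE))
        next
      }
      cat_ds <- concatenate_loci(datasets, loci, shared)
      dm <- distance_matrix(cat_ds, model = model)
      gap_rows <- species_gap_summary(dm, cat_ds$species)
      tree <- NULL
      mono <- NULL
      res <- tryCatch({
        tree <- if (n_reps > 0)
          bootstrap_supports(cat_ds, model = model, n_reps = n_reps)
        else nj_tree_excluding(cat_ds, model)
        mono <- test_monophyly(tree, cat_ds$species, support_threshold)
        NULL
      }, barcodeEval_error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        skipped <- rbind(skipped, data.frame(loci = label, reason = res,
                                             stringsAsFactors = FALSE))
        next
      }
      confirmed <- mono$species[mono$monophyletic & mono$n_tips >= 2 &
                                  (if (n_reps > 0) !is.na(mono$support) &
                                     mono$support > support_threshold
                                   else TRUE)]
      results[[label]] <- list(
        loci = loci,
        arity = unname(.ARITY_NAMES[as.character(arity)]),
        shared_specimens = length(shared),
        monophyly = mono,
        monophyletic_species = confirmed,
        gap_rows = gap_rows,
        locus_gap = locus_gap_assessment(gap_rows),
        tree = tree)
    }
  }
  structure(results, class = "combination_results", skipped = skipped)
}

# Full-data NJ tree honouring the undefined-distance exclusion policy,
# without bootstrap.
nj_tree_excluding <- function(dataset, model, deletion = "pairwise") {
  prepare_tree_data(dataset, model, deletion)$tree
}

#' Tabulate combination results
#'
#' @param x A `combination_results` object.
#' @return A `data.frame` with one row per analysed combination: `loci`,
#'   `arity`, `shared_specimens`, `n_monophyletic`, `monophyletic_species`
#'   (comma-joined), `locus_gap`.
#' @export
combination_table <- function(x) {
  if (length(x) == 0)
    return(data.frame(loci = character(0), arity = character(0),
                      shared_specimens = integer(0),
                      n_monophyletic = integer(0),
                      monophyletic_species = character(0),
                      locus_gap = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(unname(x), function(r) data.frame(
    loci = paste(r$loci, collapse = "+"),
    arity = r$arity,
    shared_specimens = r$shared_specimens,
    n_monophyletic = length(r$monophyletic_species),
    monophyletic_species = paste(r$monophyletic_species, collapse = ", "),
    locus_gap = r$locus_gap,
    stringsAsFactors = FALSE)))
}

#' @export
print.combination_results <- function(x, ...) {
  cat(sprintf("Multilocus combination results: %d analysed, %d skipped\n",
              length(x), nrow(attr(x, "skipped"))))
  if (length(x) > 0) print(combination_table(x))
  invisible(x)
}
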