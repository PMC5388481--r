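# Orchestration: run every stage (stats -> distances -> gap -> trees ->
# monophyly -> combinations) from one configuration, with deterministic
# outputs under a fixed seed.

#' Build a run configuration
#'
#' @param loci Either a named character vector of aligned-FASTA paths
#'   (names = locus names) or a named list of `locus_dataset`s.
#' @param metadata Path to a metadata TSV or a metadata `data.frame`
#'   (ignored when `loci` are already bound datasets).
#' @param model Distance model, `"k2p"` (default) or `"p"`.
#' @param reps Bootstrap replicates (default 1000; 0 = trees without
#'   supports).
#' @param support_threshold Percent bootstrap support confirming monophyly
#'   (default 70).
#' @param arities Combination sizes to evaluate (default 2:5; `NULL` skips
#'   the combination stage).
#' @param out_dir Output directory for reports (`NULL` = no files written).
#' @param seed Integer seed driving all randomness (default 1).
#' @param deletion Site deletion mode for distances.
#' @param min_specimens Minimum specimens for tree building at a locus
#'   (default 3).
#' @param verbose Emit progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(loci, metadata = NULL, model = c("k2p", "p"),
                       reps = 1000, support_threshold = 70, arities = 2:5,
                       out_dir = NULL, seed = 1,
                       deletion = c("pairwise", "complete"),
                       min_specimens = 3, verbose = FALSE) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  if (reps < 0) input_error("reps must be >= 0")
  if (is.character(loci)) {
    if (is.null(names(loci)) || any(!nzchar(names(loci))))
      input_error("loci paths must be named by locus")
    missing <- loci[!file.exists(loci)]
    if (length(missing) > 0)
      input_error(sprintf("alignment file(s) not found: %s",
                          paste(missing, collapse = ", ")))
    if (is.character(metadata) && !file.exists(metadata))
      input_error(sprintf("metadata file not found: %s", metadata))
  }
  structure(list(loci = loci, metadata = metadata, model = model,
                 reps = reps, support_threshold = support_threshold,
                 arities = arities, out_dir = out_dir, seed = as.integer(seed),
                 deletion = deletion, min_specimens = min_specimens,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full barcode-locus evaluation
#'
#' Executes the whole pipeline: per-locus alignment statistics, distance
#' matrices, barcode-gap summaries, NJ trees with bootstrap supports, species
#' monophyly tests, then multilocus combination analyses. When `out_dir` is
#' set, writes the report bundle: per-locus stats TSV, gap TSVs, scatter
#' CSVs and plots, Newick trees, monophyly TSVs, a combination TSV, a
#' machine-readable JSON summary and a run log. Reruns with the same
#' configuration and seed produce byte-identical JSON and Newick output.
#'
#' @param cfg A `run_config`, or arguments to build one (see [run_config()]).
#' @param ... Passed to [run_config()] when `cfg` is not already one.
#' @return An object of class `barcode_eval`: list with `loci` (per-locus
#'   results), `stats`, `combinations`, `skipped`, `summary` (the JSON-ready
#'   list) and the configuration.
#' @examples
#' sim <- simulate_dataset(study_fixture(seed = 42))
#' res <- barcode_eval(sim$datasets, reps = 0, arities = NULL, seed = 42)
#' summary(res)
#' @export
run_all <- function(cfg, ...) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg, ...)
  set.seed(cfg$seed)
  log <- character(0)
  note <- function(...) {
    msg <- be_log(..., verbose = cfg$verbose)
    log <<- c(log, msg)
  }
  note("seed: ", cfg$seed, "; model: ", cfg$model, "; reps: ", cfg$reps)

  datasets <- load_datasets(cfg)
  skipped <- data.frame(stage = character(0), item = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  loci_res <- list()
  for (lc in sort(names(datasets))) {
    ds <- datasets[[lc]]
    res <- list(dataset = ds, stats = locus_stats(ds))
    if (length(ds$ids) < 2 || length(unique(ds$species)) < 2) {
      skipped <- rbind(skipped, data.frame(
        stage = "distance", item = lc,
        reason = "fewer than 2 specimens or species", stringsAsFactors = FALSE))
      loci_res[[lc]] <- res
      next
    }
    res$dist <- distance_matrix(ds, model = cfg$model, deletion = cfg$deletion)
    res$gap <- species_gap_summary(res$dist, ds$species)
    res$locus_gap <- locus_gap_assessment(res$gap)
    if (length(ds$ids) >= cfg$min_specimens) {
      tree_res <- tryCatch({
        tree <- if (cfg$reps > 0)
          bootstrap_supports(ds, model = cfg$model, n_reps = cfg$reps,
                             deletion = cfg$deletion)
        else nj_tree_excluding(ds, cfg$model, cfg$deletion)
        list(tree = tree,
             monophyly = test_monophyly(tree, ds$species,
                                        cfg$support_threshold))
      }, barcodeEval_error = function(e) conditionMessage(e))
      if (is.character(tree_res)) {
        skipped <- rbind(skipped, data.frame(stage = "tree", item = lc,
                                             reason = tree_res,
                                             stringsAsFactors = FALSE))
      } else {
        res$tree <- tree_res$tree
        res$monophyly <- tree_res$monophyly
      }
    } else {
      skipped <- rbind(skipped, data.frame(
        stage = "tree", item = lc,
        reason = sprintf("fewer than %d specimens", cfg$min_specimens),
        stringsAsFactors = FALSE))
    }
    note("locus ", lc, ": ", length(ds$ids), " specimens, gap = ",
         ifelse(is.na(res$locus_gap), "NA", res$locus_gap))
    loci_res[[lc]] <- res
  }

  combos <- NULL
  if (!is.null(cfg$arities) && length(datasets) >= 2) {
    combos <- evaluate_combinations(datasets, arities = cfg$arities,
                                    model = cfg$model, n_reps = cfg$reps,
                                    support_threshold = cfg$support_threshold)
    csk <- attr(combos, "skipped")
    if (nrow(csk) > 0)
      skipped <- rbind(skipped, data.frame(stage = "combination",
                                           item = csk$loci,
                                           reason = csk$reason,
                                           stringsAsFactors = FALSE))
    note("combinations analysed: ", length(combos),
         "; skipped: ", nrow(csk))
  }

  stats_tab <- do.call(rbind, lapply(loci_res, `[[`, "stats"))
  rownames(stats_tab) <- NULL
  obj <- structure(list(loci = loci_res, stats = stats_tab,
                        combinations = combos, skipped = skipped,
                        config = cfg, log = log),
                   class = "barcode_eval")
  obj$summary <- build_summary(obj)
  if (!is.null(cfg$out_dir)) write_bundle(obj, cfg$out_dir)
  obj
}

#' @rdname run_all
#' @export
barcode_eval <- function(cfg, ...) run_all(cfg, ...)

load_datasets <- function(cfg) {
  if (is.list(cfg$loci) && all(vapply(cfg$loci, inherits, logical(1),
                                      "locus_dataset")))
    return(cfg$loci)
  md <- if (is.character(cfg$metadata)) read_metadata(cfg$metadata)
        else validate_metadata(cfg$metadata)
  if (is.list(cfg$loci)) {
    return(lapply(cfg$loci, function(m) {
      if (inherits(m, "aligned_matrix")) bind_dataset(m, md)
      else input_error("loci list must contain aligned matrices or datasets")
    }))
  }
  out <- lapply(names(cfg$loci), function(lc)
    bind_dataset(read_alignment(cfg$loci[[lc]], lc), md))
  stats::setNames(out, names(cfg$loci))
}

# JSON-ready summary of a full run; deterministic for a fixed config + seed.
build_summary <- function(obj) {
  loci <- lapply(obj$loci, function(r) {
    out <- list(stats = r$stats)
    if (!is.null(r$gap)) {
      out$gap <- r$gap
      out$locus_gap <- r$locus_gap
      out$undefined_pairs <- nrow(r$dist$undefined_pairs)
    }
    if (!is.null(r$monophyly)) {
      out$monophyly <- r$monophyly
      out$newick <- ape::write.tree(r$tree)
    }
    out
  })
  list(
    tool = "barcodeEval",
    seed = obj$config$seed,
    model = obj$config$model,
    reps = obj$config$reps,
    support_threshold = obj$config$support_threshold,
    loci = loci,
    combinations = if (is.null(obj$combinations)) list()
                   else combination_table(obj$combinations),
    skipped = obj$skipped)
}

summary_json <- function(obj) {
  jsonlite::toJSON(obj$summary, auto_unbox = TRUE, digits = 10,
                   dataframe = "rows", na = "null", pretty = TRUE)
}

#' Validate a run summary against the shipped schema
#'
#' Performs a structural check of a JSON run summary against the schema
#' shipped at `inst/extdata/summary.schema.json`: required keys must be
#' present with the expected JSON types.
#'
#' @param x Path to a JSON summary file, a JSON string, or the parsed list.
#' @return `TRUE` invisibly; raises an `input_error` describing the first
#'   violation otherwise.
#' @export
validate_summary <- function(x) {
  if (is.character(x)) {
    x <- if (length(x) == 1 && file.exists(x)) jsonlite::fromJSON(x)
         else jsonlite::fromJSON(paste(x, collapse = "\n"))
  }
  need <- c(tool = "character", seed = "integer", model = "character",
            reps = "integer", support_threshold = "integer", loci = "list")
  for (k in names(need)) {
    if (is.null(x[[k]]))
      input_error(sprintf("summary is missing required key '%s'", k))
  }
  if (!identical(x$tool, "barcodeEval"))
    input_error("summary 'tool' must be 'barcodeEval'")
  if (!x$model %in% c("k2p", "p"))
    input_error("summary 'model' must be 'k2p' or 'p'")
  for (lc in names(x$loci)) {
    if (is.null(x$loci[[lc]]$stats))
      input_error(sprintf("locus '%s' summary lacks 'stats'", lc))
  }
  invisible(TRUE)
}

write_bundle <- function(obj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_locus_stats(obj$stats, file.path(dir, "locus_stats.tsv"))
  for (lc in names(obj$loci)) {
    r <- obj$loci[[lc]]
    if (!is.null(r$gap)) {
      write_gap_summary(r$gap, file.path(dir, paste0("gap_", lc, ".tsv")))
      sc <- gap_scatter_data(r$gap)
      utils::write.table(sc, file.path(dir, paste0("gap_scatter_", lc, ".csv")),
                         sep = ",", quote = FALSE, row.names = FALSE)
      plot_gap_scatter(r$gap, lc, file.path(dir, paste0("gap_", lc, ".png")))
    }
    if (!is.null(r$tree)) {
      write_tree(r$tree, file.path(dir, paste0("nj_", lc, ".nwk")))
      write_monophyly(cbind(locus = lc, r$monophyly),
                      file.path(dir, paste0("monophyly_", lc, ".tsv")))
    }
  }
  if (!is.null(obj$combinations))
    utils::write.table(combination_table(obj$combinations),
                       file.path(dir, "combinations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeLines(summary_json(obj), file.path(dir, "summary.json"))
  writeLines(c(obj$log,
               paste0("R version: ", R.version.string),
               paste0("finished: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' Barcode-gap scatter plot
#'
#' Plots maximum intraspecific distance against nearest-neighbour distance
#' (both percent) per species, with the identity line; points above the line
#' show a barcode gap. Species with undefined values are dropped; if none
#' remain, no file is produced and a warning is issued.
#'
#' @param rows A gap summary `data.frame` from [species_gap_summary()].
#' @param locus Locus name for the title.
#' @param file Output file (`.png` or `.svg`); `NULL` plots to the active
#'   device.
#' @return The file path (or `NULL` for an active device), invisibly; `NA`
#'   when nothing could be plotted.
#' @export
plot_gap_scatter <- function(rows, locus = "", file = NULL) {
  sc <- gap_scatter_data(rows)
  if (nrow(sc) == 0) {
    warning(sprintf("no plottable species for locus '%s' (all N/A)", locus))
    return(invisible(NA))
  }
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 6, height = 6)
    else grDevices::png(file, width = 900, height = 900, res = 150)
    on.exit(grDevices::dev.off())
  }
  lim <- c(0, max(sc$d_intra, sc$d_nn) * 1.1 + 0.1)
  graphics::plot(sc$d_intra, sc$d_nn, xlim = lim, ylim = lim, pch = 19,
                 xlab = "Maximum intraspecific distance (%)",
                 ylab = "Nearest-neighbour distance (%)",
                 main = locus)
  graphics::abline(0, 1, lty = 2)
  graphics::text(sc$d_intra, sc$d_nn, labels = sc$species, pos = 3,
                 cex = 0.6, xpd = NA)
  invisible(file)
}

#' @export
print.barcode_eval <- function(x, ...) {
  cat("Barcode locus evaluation\n")
  cat(sprintf("  loci: %s\n", paste(names(x$loci), collapse = ", ")))
  cat(sprintf("  model: %s, bootstrap reps: %d, seed: %d\n",
              x$config$model, x$config$reps, x$config$seed))
  gaps <- vapply(x$loci, function(r) isTRUE(r$locus_gap), logical(1))
  cat(sprintf("  loci with a clear barcode gap: %s\n",
              if (any(gaps)) paste(names(x$loci)[gaps], collapse = ", ")
              else "none"))
  if (!is.null(x$combinations))
    cat(sprintf("  combinations analysed: %d\n", length(x$combinations)))
  invisible(x)
}

#' @export
summary.barcode_eval <- function(object, ...) {
  tab <- object$stats
  tab$locus_gap <- vapply(object$loci[tab$locus], function(r)
    if (is.null(r$locus_gap)) NA else r$locus_gap, logical(1))
  tab$n_monophyletic <- vapply(object$loci[tab$locus], function(r)
    if (is.null(r$monophyly)) NA_integer_
    else sum(r$monophyly$monophyletic & r$monophyly$n_tips >= 2),
    integer(1))
  tab$n_supported <- vapply(object$loci[tab$locus], function(r)
    if (is.null(r$monophyly)) NA_integer_ else sum(r$monophyly$supported),
    integer(1))
  tab
}

#' @export
plot.barcode_eval <- function(x, locus = NULL, ...) {
  locus <- locus %||% names(x$loci)[1]
  r <- x$loci[[locus]]
  if (is.null(r) || is.null(r$gap))
    input_error(sprintf("no gap summary for locus '%s'", locus))
  plot_gap_scatter(r$gap, locus)
}
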