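# Barcode-gap analysis: per species, the maximum intraspecific distance
# (D_intra) against the minimum distance to any heterospecific specimen
# (D_NN, the nearest-neighbour distance). A species shows a barcode gap when
# D_NN strictly exceeds D_intra; a locus shows a clear gap when the smallest
# D_NN across species strictly exceeds the largest defined D_intra.

#' Per-species barcode-gap summary
#'
#' For every species in the dataset computes the maximum intraspecific
#' distance (`NA` for singletons), the minimum nearest-neighbour distance over
#' individual heterospecific pairs, and the species achieving it (ties broken
#' by lexicographic species name). Distances are reported in percent.
#' Undefined pairs are excluded from both maxima and minima; a species whose
#' every heterospecific distance is undefined is flagged `incomputable`.
#'
#' @param dm A `barcode_dist` from [distance_matrix()].
#' @param species_map Named character vector mapping specimen id to species
#'   (a `locus_dataset$species`), covering every id in `dm`.
#' @return A `data.frame` with columns `species`, `n_specimens`, `d_intra`
#'   (percent or `NA`), `nearest_species`, `d_nn` (percent), `gap_present`
#'   (logical or `NA`), `incomputable`.
#' @export
species_gap_summary <- function(dm, species_map) {
  ids <- dm$ids
  sp <- unname(species_map[ids])
  if (anyNA(sp))
    input_error(sprintf("specimen(s) missing from species map: %s",
                        paste(ids[is.na(sp)], collapse = ", ")))
  species <- sort(unique(sp))
  if (length(species) < 2)
    input_error("barcode-gap analysis needs at least 2 species")
  rows <- lapply(species, function(s) {
    own <- which(sp == s)
    oth <- which(sp != s)
    d_intra <- NA_real_
    if (length(own) >= 2) {
      v <- dm$d[own, own][upper.tri(matrix(0, length(own), length(own)))]
      v <- v[!is.na(v)]
      if (length(v) > 0) d_intra <- max(v)
    }
    het <- dm$d[own, oth, drop = FALSE]
    if (all(is.na(het))) {
      return(data.frame(species = s, n_specimens = length(own),
                        d_intra = 100 * d_intra, nearest_species = NA_character_,
                        d_nn = NA_real_, incomputable = TRUE,
                        stringsAsFactors = FALSE))
    }
    d_nn <- min(het, na.rm = TRUE)
    hit <- which(het == d_nn, arr.ind = TRUE)
    nearest <- sort(sp[oth][hit[, "col"]])[1]
    data.frame(species = s, n_specimens = length(own),
               d_intra = 100 * d_intra, nearest_species = nearest,
               d_nn = 100 * d_nn, incomputable = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gap_present <- gap_present(out$d_intra, out$d_nn)
  out[, c("species", "n_specimens", "d_intra", "nearest_species", "d_nn",
          "gap_present", "incomputable")]
}

#' Species-level barcode-gap flag
#'
#' A species shows a gap when its nearest-neighbour distance strictly exceeds
#' its maximum intraspecific distance. `NA` when `d_intra` is undefined
#' (singleton) or `d_nn` is incomputable.
#'
#' @param d_intra,d_nn Numeric vectors (same units, typically percent).
#' @return Logical vector with `NA` where undefined.
#' @examples
#' gap_present(0.21, 2.92)  # TRUE
#' gap_present(9.71, 0)     # FALSE
#' gap_present(1, 1)        # FALSE: strict inequality
#' @export
gap_present <- function(d_intra, d_nn) {
  ifelse(is.na(d_intra) | is.na(d_nn), NA, d_nn > d_intra)
}

#' Locus-level barcode-gap assessment
#'
#' A locus shows a clear barcode gap when the intraspecific and
#' nearest-neighbour distance ranges do not overlap: the minimum `d_nn` over
#' all species strictly exceeds the maximum `d_intra` over species where it
#' is defined. `NA` if every species is a singleton.
#'
#' @param rows A gap summary `data.frame` from [species_gap_summary()] (only
#'   `d_intra` and `d_nn` columns are used).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
locus_gap_assessment <- function(rows) {
  di <- rows$d_intra[!is.na(rows$d_intra)]
  dn <- rows$d_nn[!is.na(rows$d_nn)]
  if (length(di) == 0 || length(dn) == 0) return(NA)
  min(dn) > max(di)
}

#' Scatter data for a gap plot
#'
#' @param rows A gap summary `data.frame`.
#' @return A `data.frame` with `species`, `d_intra`, `d_nn` (percent),
#'   dropping species with undefined `d_intra` or `d_nn`.
#' @export
gap_scatter_data <- function(rows) {
  keep <- !is.na(rows$d_intra) & !is.na(rows$d_nn)
  rows[keep, c("species", "d_intra", "d_nn")]
}

#' Write a gap summary report
#'
#' Writes the per-species gap table as TSV, rendering distances with two
#' decimals and undefined values as `N/A` (singletons have no intraspecific
#' distance). Comparisons are always made at full precision; rounding happens
#' only here, at report time.
#'
#' @param rows A gap summary `data.frame`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gap_summary <- function(rows, path) {
  out <- rows
  out$d_intra <- ifelse(is.na(out$d_intra), "N/A", sprintf("%.2f", out$d_intra))
  out$d_nn <- ifelse(is.na(out$d_nn), "N/A", sprintf("%.2f", out$d_nn))
  out$gap_present <- ifelse(is.na(out$gap_present), "N/A",
                            ifelse(out$gap_present, "yes", "no"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference distance summaries for twelve Australian grass species
#'
#' Returns the per-species maximum intraspecific distance and
#' nearest-neighbour distance (percent, K2P-adjusted) reported for six
#' candidate barcode loci (atpF, ETS, ITS, matK, ndhK, psbE) across five
#' invasive and seven native grass species, shipped with the package as a
#' plain-text table. `d_intra` is `NA` for species represented by a single
#' specimen. Useful for exercising the gap logic without sequence data.
#'
#' @return A `data.frame` with columns `locus`, `species`, `d_intra`,
#'   `nearest_species`, `d_nn`.
#' @export
gap_reference <- function() {
  path <- system.file("extdata", "gap_reference_six_loci.tsv",
                      package = "barcodeEval", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "N/A")
}
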