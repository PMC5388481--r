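# Per-locus alignment summary statistics: aligned length, variable and
# parsimony-informative sites, indel events.

.NT <- c("A", "C", "G", "T")

#' Classify one alignment column
#'
#' A column is classified from its unambiguous, non-gap residues (A/C/G/T
#' only; gaps and IUPAC ambiguity codes are excluded from the state counts):
#' `variable_uninformative` if at least two distinct states occur,
#' `parsimony_informative` if at least two distinct states each occur in at
#' least two sequences, otherwise `constant`. An all-gap/ambiguous column is
#' `constant` by convention.
#'
#' @param column Character vector of single residues (one per sequence).
#' @return One of `"constant"`, `"variable_uninformative"`,
#'   `"parsimony_informative"`.
#' @examples
#' site_classification(c("A", "A", "G", "G"))  # parsimony_informative
#' site_classification(c("A", "A", "A", "G"))  # variable_uninformative
#' site_classification(c("A", "-", "A", "A"))  # constant
#' @export
site_classification <- function(column) {
  if (length(column) == 0) input_error("empty alignment column")
  states <- column[column %in% .NT]
  if (length(states) == 0) return("constant")
  tab <- table(states)
  if (length(tab) < 2) return("constant")
  if (sum(tab >= 2L) >= 2L) return("parsimony_informative")
  "variable_uninformative"
}

#' Alignment summary statistics for one locus
#'
#' Computes aligned length, counts of variable and parsimony-informative
#' sites (see [site_classification()]) and indel events. By default an indel
#' event is a distinct maximal gap run keyed by its (start, end) columns, so
#' a deletion shared by several sequences counts once; set
#' `indels = "per_sequence"` to count every per-sequence gap run instead.
#'
#' @param matrix An `aligned_matrix` or `locus_dataset`.
#' @param indels Indel counting convention, `"shared"` (default) or
#'   `"per_sequence"`.
#' @return A one-row `data.frame` with columns `locus`, `n_sequences`,
#'   `aligned_length`, `variable_sites`, `informative_sites`, `indel_events`.
#' @export
locus_stats <- function(matrix, indels = c("shared", "per_sequence")) {
  indels <- match.arg(indels)
  chm <- do.call(rbind, strsplit(matrix$seqs, "", fixed = TRUE))
  cls <- apply(chm, 2, site_classification)
  data.frame(
    locus = matrix$locus,
    n_sequences = length(matrix$ids),
    aligned_length = matrix$length,
    variable_sites = sum(cls != "constant"),
    informative_sites = sum(cls == "parsimony_informative"),
    indel_events = indel_events(chm, convention = indels),
    stringsAsFactors = FALSE
  )
}

indel_events <- function(chm, convention = "shared") {
  runs <- character(0)
  total <- 0L
  for (i in seq_len(nrow(chm))) {
    r <- rle(chm[i, ] == "-")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    total <- total + length(gi)
    runs <- c(runs, paste(starts[gi], ends[gi], sep = "-"))
  }
  if (convention == "per_sequence") total else length(unique(runs))
}

#' Write a per-locus statistics report
#'
#' @param stats A `data.frame` of stacked [locus_stats()] rows.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
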