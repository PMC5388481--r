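# Aligned FASTA + metadata I/O and dataset assembly.
#
# The unit every downstream stage consumes is a "locus_dataset": an aligned
# matrix for one locus bound to a specimen -> species map.

.IUPAC <- c("A", "C", "G", "T", "U", "M", "R", "W", "S", "Y", "K",
            "V", "H", "D", "B", "N", "-", "?")

#' Read one aligned FASTA matrix
#'
#' Reads an aligned FASTA file (gap character `-`) into an `aligned_matrix`.
#' Sequences are upper-cased on input; record order is preserved. All
#' sequences must have identical length (it is an alignment, not a raw
#' sequence set).
#'
#' @param path Path to an aligned FASTA file.
#' @param locus Locus name attached to the matrix.
#' @return An object of class `aligned_matrix`: list with elements `locus`,
#'   `ids` (character), `seqs` (named character vector of aligned sequences)
#'   and `length` (alignment column count).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "ACGA"), fa)
#' read_alignment(fa, "demo")
#' @export
read_alignment <- function(path, locus) {
  if (!file.exists(path)) input_error(sprintf("alignment file not found: %s", path))
  x <- tryCatch(seqinr::read.fasta(path, as.string = TRUE,
                                   forceDNAtolower = FALSE),
                error = function(e) input_error(sprintf(
                  "could not parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(x) == 0) input_error(sprintf("empty FASTA file: %s", path))
  seqs <- toupper(vapply(x, as.character, character(1)))
  ids <- names(x)
  if (anyDuplicated(ids))
    input_error(sprintf("duplicate specimen id(s) in '%s': %s", path,
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    alignment_error(sprintf(
      "ragged alignment in '%s': sequence lengths %s", path,
      paste(unique(lens), collapse = ", ")))
  if (lens[1] < 1L) alignment_error(sprintf("zero-length alignment in '%s'", path))
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]), .IUPAC)
  if (length(bad) > 0)
    input_error(sprintf("non-IUPAC characters in '%s': %s", path,
                        paste(bad, collapse = " ")))
  aligned_matrix(locus, ids, seqs)
}

aligned_matrix <- function(locus, ids, seqs) {
  names(seqs) <- ids
  structure(list(locus = locus, ids = ids, seqs = seqs,
                 length = nchar(seqs[[1]])),
            class = "aligned_matrix")
}

#' Write an aligned matrix to FASTA
#'
#' @param x An `aligned_matrix` or `locus_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path) {
  seqinr::write.fasta(as.list(unname(x$seqs)), names = x$ids,
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' @export
print.aligned_matrix <- function(x, ...) {
  cat(sprintf("Aligned matrix '%s': %d sequences x %d columns\n",
              x$locus, length(x$ids), x$length))
  invisible(x)
}

#' Trim an alignment to a column range
#'
#' Convenience for removing primer-read columns at the matrix edges; the
#' upstream alignment and primer identification remain the user's
#' responsibility.
#'
#' @param x An `aligned_matrix`.
#' @param start,end 1-based first and last column to keep.
#' @return A trimmed `aligned_matrix`.
#' @export
trim_alignment <- function(x, start = 1L, end = x$length) {
  if (start < 1 || end > x$length || start > end)
    input_error(sprintf("invalid trim range [%d, %d] for %d columns",
                        start, end, x$length))
  aligned_matrix(x$locus, x$ids, substr(x$seqs, start, end))
}

#' Read specimen metadata
#'
#' Reads a tab-separated metadata table with a header. Columns `specimen_id`,
#' `species` and `status` are mandatory; `status` must be `invasive` or
#' `native`. Extra columns are kept but ignored by the pipeline. Only the TSV
#' dialect is accepted.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) input_error(sprintf("metadata file not found: %s", path))
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("specimen_id", "species", "status")
  missing <- setdiff(need, names(md))
  if (length(missing) > 0)
    input_error(sprintf("metadata is missing mandatory column(s): %s",
                        paste(missing, collapse = ", ")))
  if (nrow(md) == 0) input_error("metadata table has no rows")
  if (anyDuplicated(md$specimen_id))
    input_error(sprintf("duplicate specimen_id in metadata: %s",
                        paste(unique(md$specimen_id[duplicated(md$specimen_id)]),
                              collapse = ", ")))
  if (any(!nzchar(md$species)))
    input_error("empty species name in metadata")
  bad <- which(!md$status %in% c("invasive", "native"))
  if (length(bad) > 0)
    input_error(sprintf(
      "invalid status value(s) outside {invasive, native} at row(s) %s: %s",
      paste(bad, collapse = ", "),
      paste(unique(md$status[bad]), collapse = ", ")))
  md
}

#' Bind an aligned matrix to specimen metadata
#'
#' Produces the validated per-locus dataset consumed by every analysis stage.
#' Every specimen in the matrix must appear in the metadata; species
#' represented by a single sequenced specimen are flagged as singletons (their
#' maximum intraspecific distance is undefined downstream).
#'
#' @param matrix An `aligned_matrix`.
#' @param records Metadata `data.frame` from [read_metadata()].
#' @return An object of class `locus_dataset`: the matrix fields plus
#'   `species` and `status` (named by specimen id) and `singletons`
#'   (character vector of species names).
#' @export
bind_dataset <- function(matrix, records) {
  records <- validate_metadata(records)
  unmapped <- setdiff(matrix$ids, records$specimen_id)
  if (length(unmapped) > 0)
    input_error(sprintf("specimen(s) absent from metadata: %s",
                        paste(unmapped, collapse = ", ")))
  sp <- records$species[match(matrix$ids, records$specimen_id)]
  st <- records$status[match(matrix$ids, records$specimen_id)]
  names(sp) <- matrix$ids
  names(st) <- matrix$ids
  counts <- table(sp)
  structure(list(locus = matrix$locus, ids = matrix$ids, seqs = matrix$seqs,
                 length = matrix$length, species = sp, status = st,
                 singletons = sort(names(counts)[counts == 1L])),
            class = c("locus_dataset", "aligned_matrix"))
}

#' @export
print.locus_dataset <- function(x, ...) {
  cat(sprintf("Locus dataset '%s': %d specimens, %d species, %d columns\n",
              x$locus, length(x$ids), length(unique(x$species)), x$length))
  if (length(x$singletons) > 0)
    cat("  singleton species:", paste(x$singletons, collapse = ", "), "\n")
  invisible(x)
}
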