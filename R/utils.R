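# Classed conditions used across the package: callers can distinguish bad user
# input ("input_error"), malformed alignments ("alignment_error") and distance
# model breakdown ("undefined_distance") from ordinary errors.

be_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "barcodeEval_error", "error")))
}

input_error <- function(msg) be_stop(msg, "input_error")
alignment_error <- function(msg) be_stop(msg, "alignment_error")
undefined_distance <- function(msg) be_stop(msg, "undefined_distance")

`%||%` <- function(a, b) if (is.null(a)) b else a

be_log <- function(..., verbose = TRUE, logfile = NULL) {
  msg <- paste0(...)
  if (isTRUE(verbose)) message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  invisible(msg)
}
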