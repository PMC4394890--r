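# internal helpers shared across the package

#' @keywords internal
#' @noRd
ffl_log <- function(...) {
  if (isTRUE(getOption("fflnet.verbose", FALSE))) {
    message("[fflnet] ", sprintf(...))
  }
  invisible(NULL)
}

# stable composite key for a regulation edge
edge_key <- function(regulator, target, regulator_type) {
  if (length(regulator) == 0L || length(target) == 0L) return(character(0))
  paste(regulator, target, regulator_type, sep = "\r")
}

# lexicographic order that does not depend on the session locale
radix_order <- function(...) order(..., method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
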