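# Internal helpers shared across modules.

#' Signal a classed metaomix error
#'
#' @param message error text.
#' @param class condition subclass, e.g. "metaomix_parse_error".
#' @param ... fields attached to the condition.
#' @noRd
mox_stop <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "metaomix_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Evaluate code under a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split a "a;b;c" field into a character vector (empty -> character(0))
#' @noRd
split_semicolon <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  out <- strsplit(x, ";", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

#' Collapse a character set into a "a;b" field
#' @noRd
join_semicolon <- function(x) paste(x, collapse = ";")

# Amino-acid alphabet accepted in protein sequences (X = unknown residue).
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' EC numbers: 4 dotted fields, trailing fields may be "-"
#' @noRd
is_valid_ec <- function(x) grepl("^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", x)

#' Check a protein sequence against the amino-acid alphabet
#' @noRd
is_valid_sequence <- function(x) {
  nzchar(x) & !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x)
}

#' Stable numeric formatting for TSV companions that must round-trip
#' @noRd
format_full <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 17))
}
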