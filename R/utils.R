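# Internal helpers: structured conditions and identifier validation.

pc_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "patentchem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pc_parse_error <- function(msg, ...) pc_error(msg, "patentchem_parse_error", ...)

#' Validate InChIKey strings
#'
#' A full InChIKey is 27 characters: a 14-character connectivity block, a
#' 10-character stereo/isotope block and a single protonation-flag character,
#' separated by hyphens.
#'
#' @param x Character vector of candidate keys.
#' @return Logical vector, `TRUE` where `x` is a syntactically valid key.
#' @export
#' @examples
#' is_valid_inchikey(c("BSYNRYMUTXBXSQ-UHFFFAOYSA-N", "XYZ"))
is_valid_inchikey <- function(x) {
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder rounding of n * p into integer quotas summing to n.
quota_round <- function(n, p) {
  if (n == 0) return(integer(length(p)))
  raw <- n * p / sum(p)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
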