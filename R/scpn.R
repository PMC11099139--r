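#' Parse SureChEMBL patent numbers (SCPN)
#'
#' An SCPN is `COUNTRY-SERIAL-KIND`: a two-letter jurisdiction code, a 7-11
#' digit serial number and a patent kind code (one uppercase letter with an
#' optional digit), e.g. `US-1234567-A1`.
#'
#' @param scpn Character vector of SCPN identifiers.
#' @return A tibble with columns `scpn`, `country`, `serial`, `kind`,
#'   one row per input.
#' @seealso [format_scpn()] for the inverse, [kind_group()] for grouping
#'   kind codes into filed/granted/other.
#' @export
#' @examples
#' parse_scpn("US-1234567-A1")
parse_scpn <- function(scpn) {
  stopifnot(is.character(scpn), length(scpn) > 0)
  parts <- scpn_components(scpn)
  bad <- which(!parts$ok)
  if (length(bad) > 0) {
    i <- bad[1]
    pc_parse_error(
      sprintf("invalid SCPN %s: malformed %s", encodeString(scpn[i], quote = "\""), parts$why[i]),
      scpn = scpn[i], component = parts$why[i]
    )
  }
  tibble::tibble(scpn = scpn, country = parts$country,
                 serial = parts$serial, kind = parts$kind)
}

#' Reassemble an SCPN from its components
#'
#' @param country Two-letter jurisdiction codes.
#' @param serial Serial number strings (7-11 digits).
#' @param kind Kind codes.
#' @return Character vector of SCPN strings.
#' @export
format_scpn <- function(country, serial, kind) {
  paste(country, serial, kind, sep = "-")
}

# Vectorized, non-throwing SCPN decomposition used by both parse_scpn and
# the bulk ingest path.
scpn_components <- function(scpn) {
  parts <- strsplit(ifelse(is.na(scpn), "", scpn), "-", fixed = TRUE)
  n3 <- lengths(parts) == 3
  country <- serial <- kind <- rep(NA_character_, length(scpn))
  country[n3] <- vapply(parts[n3], `[`, character(1), 1)
  serial[n3] <- vapply(parts[n3], `[`, character(1), 2)
  kind[n3] <- vapply(parts[n3], `[`, character(1), 3)
  ok_country <- n3 & grepl("^[A-Z]{2}$", country)
  ok_serial <- n3 & grepl("^[0-9]{7,11}$", serial)
  ok_kind <- n3 & grepl("^[A-Z][0-9]?$", kind)
  why <- rep(NA_character_, length(scpn))
  why[!n3] <- "structure (expected COUNTRY-SERIAL-KIND)"
  why[n3 & !ok_country] <- "country code"
  why[n3 & ok_country & !ok_serial] <- "serial (must be 7-11 digits)"
  why[n3 & ok_country & ok_serial & !ok_kind] <- "kind code"
  list(ok = ok_country & ok_serial & ok_kind, country = country,
       serial = serial, kind = kind, why = why)
}

#' Group patent kind codes into filed / granted / other
#'
#' Kind codes beginning with `A` mark filed applications and codes beginning
#' with `B` mark granted patents; `S` (design), `E` (reissue) and `P` (plant)
#' documents form the remaining "other" class. Any further leading letter is
#' also mapped to `OTHER`, with a warning.
#'
#' @param kind Character vector of kind codes (e.g. `"A1"`, `"B2"`).
#' @return Factor with levels `FILED`, `GRANTED`, `OTHER`.
#' @export
#' @examples
#' kind_group(c("A1", "B2", "P1"))
kind_group <- function(kind) {
  stopifnot(is.character(kind))
  bad <- !grepl("^[A-Z][0-9]?$", kind)
  if (any(bad)) {
    pc_parse_error(sprintf("invalid kind code %s", encodeString(kind[bad][1], quote = "\"")),
                   component = "kind code")
  }
  lead <- substr(kind, 1, 1)
  unknown <- !(lead %in% c("A", "B", "S", "E", "P"))
  if (any(unknown)) {
    warning(sprintf("kind code letter(s) %s outside the documented A/B/S/E/P set; grouped as OTHER",
                    paste(unique(lead[unknown]), collapse = ", ")))
  }
  grp <- ifelse(lead == "A", "FILED", ifelse(lead == "B", "GRANTED", "OTHER"))
  factor(grp, levels = c("FILED", "GRANTED", "OTHER"))
}

#' The six section sources of a patent document
#'
#' Compounds are annotated from four text sections (title, abstract,
#' description, claims) plus chemical images and molfile attachments.
#'
#' @return Character vector of the six section-source names.
#' @export
section_sources <- function() {
  c("TITLE", "ABSTRACT", "DESCRIPTION", "CLAIMS", "IMAGE", "MOLFILE")
}
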