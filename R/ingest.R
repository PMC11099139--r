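# Reading compound-to-patent map dumps and deduplicating compounds.

#' Default column layout of a map dump
#'
#' Map dumps are tab-separated with one row per (compound, patent, section)
#' annotation. The layout is not standardized across dump dialects, so the
#' reader takes a named positional map. The default follows the common
#' seven-column layout.
#'
#' @return Named integer vector mapping the fields `schembl_id`, `smiles`,
#'   `inchikey`, `corpus_frequency`, `patent_id`, `date` and `field_code`
#'   to column positions.
#' @export
default_column_map <- function() {
  c(schembl_id = 1L, smiles = 2L, inchikey = 3L, corpus_frequency = 4L,
    patent_id = 5L, date = 6L, field_code = 7L)
}

#' Default section field-code vocabulary
#'
#' Integer field codes 1-6 decode to description, claims, abstract, title,
#' image and molfile annotations. The encoding is dump-dialect dependent and
#' can be overridden in [read_map_dump()].
#'
#' @return Named character vector: names are the codes, values the sources.
#' @export
default_section_codes <- function() {
  c(`1` = "DESCRIPTION", `2` = "CLAIMS", `3` = "ABSTRACT",
    `4` = "TITLE", `5` = "IMAGE", `6` = "MOLFILE")
}

#' Read a compound-to-patent map dump
#'
#' Reads a tab-separated (optionally gzip-compressed) map dump, parses and
#' validates SCPN patent identifiers and InChIKeys, decodes section field
#' codes, applies the minimum-year cutoff and merges rows so that each
#' (compound, patent) pair becomes one occurrence with the union of its
#' section sources. Invalid rows are dropped, never repaired; the load
#' report (see [load_report()]) counts every drop by reason.
#'
#' @param path Path to the dump file.
#' @param column_map Named integer vector, see [default_column_map()].
#' @param section_codes Named character vector, see [default_section_codes()].
#' @param min_year Drop occurrences with application year before this
#'   (default 2015; earlier legacy dumps use a different format and carry no
#'   patent linkage). Use `-Inf` to keep everything.
#' @param header Does the file carry a header row? Default `FALSE`.
#' @return A tibble of occurrences with columns `schembl_id`, `smiles`,
#'   `inchikey`, `scpn`, `country`, `serial`, `kind`, `year` and a `sections`
#'   list-column, plus a `"load_report"` attribute.
#' @export
read_map_dump <- function(path, column_map = default_column_map(),
                          section_codes = default_section_codes(),
                          min_year = 2015, header = FALSE) {
  if (!file.exists(path)) {
    pc_error(sprintf("map dump not found: %s", path), "patentchem_io_error")
  }
  needed <- c("schembl_id", "smiles", "inchikey", "patent_id", "date", "field_code")
  missing_cols <- setdiff(needed, names(column_map))
  if (length(missing_cols) > 0) {
    pc_error(sprintf("column_map lacks required field(s): %s",
                     paste(missing_cols, collapse = ", ")), "patentchem_io_error")
  }
  raw <- readr::read_tsv(path, col_names = isTRUE(header),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    warning("map dump is empty")
    occ <- empty_occurrences()
    attr(occ, "load_report") <- list(rows_read = 0L, rows_kept = 0L,
                                     occurrences = 0L, dropped = integer())
    return(occ)
  }
  if (max(column_map[needed]) > ncol(raw)) {
    pc_error(sprintf("column_map refers to column %d but the dump has only %d columns",
                     max(column_map[needed]), ncol(raw)), "patentchem_io_error")
  }
  col <- function(field) raw[[column_map[[field]]]]
  d <- tibble::tibble(
    schembl_id = col("schembl_id"),
    smiles = col("smiles"),
    inchikey = col("inchikey"),
    patent_id = col("patent_id"),
    date = col("date"),
    field_code = col("field_code")
  )
  n0 <- nrow(d)
  drops <- c(bad_inchikey = 0L, bad_scpn = 0L, bad_year = 0L,
             bad_field_code = 0L, before_min_year = 0L)

  ok_key <- is_valid_inchikey(d$inchikey)
  drops["bad_inchikey"] <- sum(!ok_key)
  d <- d[ok_key, ]

  sc <- scpn_components(d$patent_id)
  drops["bad_scpn"] <- sum(!sc$ok)
  d$country <- sc$country; d$serial <- sc$serial; d$kind <- sc$kind
  d <- d[sc$ok, ]

  year <- suppressWarnings(as.integer(substr(d$date, 1, 4)))
  ok_year <- !is.na(year) & year >= 1900 & year <= 2200
  drops["bad_year"] <- sum(!ok_year)
  d <- d[ok_year, ]; year <- year[ok_year]

  keep_year <- year >= min_year
  drops["before_min_year"] <- sum(!keep_year)
  d <- d[keep_year, ]; year <- year[keep_year]
  d$year <- year

  section <- unname(section_codes[as.character(d$field_code)])
  ok_field <- !is.na(section) & section %in% section_sources()
  drops["bad_field_code"] <- sum(!ok_field)
  d <- d[ok_field, ]
  d$section <- section[ok_field]

  occ <- d |>
    dplyr::mutate(scpn = .data$patent_id) |>
    dplyr::group_by(.data$inchikey, .data$scpn) |>
    dplyr::summarise(
      schembl_id = .data$schembl_id[1],
      smiles = .data$smiles[1],
      country = .data$country[1],
      serial = .data$serial[1],
      kind = .data$kind[1],
      year = .data$year[1],
      sections = list(sort(unique(.data$section))),
      .groups = "drop"
    ) |>
    dplyr::select("schembl_id", "smiles", "inchikey", "scpn", "country",
                  "serial", "kind", "year", "sections") |>
    dplyr::arrange(.data$inchikey, .data$scpn)

  attr(occ, "load_report") <- list(
    rows_read = n0,
    rows_kept = n0 - sum(drops),
    occurrences = nrow(occ),
    dropped = drops
  )
  occ
}

empty_occurrences <- function() {
  tibble::tibble(schembl_id = character(), smiles = character(),
                 inchikey = character(), scpn = character(),
                 country = character(), serial = character(),
                 kind = character(), year = integer(),
                 sections = list())
}

#' Retrieve the load report attached by [read_map_dump()]
#'
#' @param occurrences An occurrence tibble from [read_map_dump()].
#' @return A list with `rows_read`, `rows_kept`, `occurrences` and a named
#'   `dropped` count vector.
#' @export
load_report <- function(occurrences) {
  attr(occurrences, "load_report")
}

#' Deduplicate occurrences into one record per compound
#'
#' Compounds are identified by their full InChIKey. Patents and section
#' sources are unioned over all occurrences of a key; `first_year` is the
#' earliest application year; the representative SMILES is the first seen
#' in input order. The operation is idempotent and order-independent up to
#' the representative SMILES of compounds whose occurrences disagree.
#'
#' @param occurrences Occurrence tibble from [read_map_dump()].
#' @return Tibble with one row per InChIKey: `inchikey`, `schembl_id`,
#'   `smiles`, `n_patents`, `first_year`, and list-columns `patents`,
#'   `years`, `sections`.
#' @export
dedupe <- function(occurrences) {
  if (nrow(occurrences) == 0) {
    return(tibble::tibble(inchikey = character(), schembl_id = character(),
                          smiles = character(), n_patents = integer(),
                          first_year = integer(), patents = list(),
                          years = list(), sections = list()))
  }
  occurrences |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(
      schembl_id = .data$schembl_id[1],
      smiles = .data$smiles[1],
      n_patents = dplyr::n_distinct(.data$scpn),
      first_year = min(.data$year),
      patents = list(sort(unique(.data$scpn))),
      years = list(sort(unique(.data$year))),
      sections = list(sort(unique(unlist(.data$sections)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$inchikey)
}

#' Promiscuity distribution of compounds over patent documents
#'
#' Bins the per-compound patent-document counts into the four classes used
#' to describe compound promiscuity: exactly one document, 2-4 documents
#' (together "fewer than 5"), 5-1000, and more than 1000 documents.
#'
#' @param records Deduplicated compound tibble from [dedupe()].
#' @return A list with `histogram` (tibble of `bin`, `count`) and `counts`
#'   (named integer vector of patent counts per InChIKey). Bin counts always
#'   sum to `nrow(records)`.
#' @export
promiscuity_distribution <- function(records) {
  counts <- stats::setNames(as.integer(records$n_patents), records$inchikey)
  brk <- c(0.5, 1.5, 4.5, 1000.5, Inf)
  lab <- c("1", "2-4", "5-1000", ">1000")
  bin_tab <- table(cut(counts, breaks = brk, labels = lab))
  hist <- tibble::tibble(bin = lab, count = as.integer(bin_tab))
  list(histogram = hist, counts = counts)
}
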