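# PAINS substructure screening.
#
# The shipped catalog is the published 480-pattern pan-assay interference
# (PAINS) SMARTS set, families A/B/C. The patterns were written for
# explicit-hydrogen structures, so molecules are hydrogen-expanded before
# matching.

#' Load a substructure alert catalog
#'
#' `"pains"` loads the built-in 480-pattern PAINS catalog. A file path loads
#' a user catalog: tab-separated with a header and columns `name`, `smarts`
#' (optionally `family`). Every pattern is compiled against the backend at
#' load time; an uncompilable pattern is an error naming it.
#'
#' @param catalog `"pains"` or a path to a SMARTS TSV.
#' @return Tibble with `name`, `family`, `smarts` in deterministic order.
#' @export
load_alert_catalog <- function(catalog = "pains") {
  path <- if (identical(catalog, "pains")) {
    system.file("extdata", "pains_smarts.tsv", package = "patentchem", mustWork = TRUE)
  } else {
    if (!file.exists(catalog)) {
      pc_error(sprintf("alert catalog not found: %s", catalog), "patentchem_io_error")
    }
    catalog
  }
  cat_df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE, show_col_types = FALSE)
  if (!all(c("name", "smarts") %in% names(cat_df)) || nrow(cat_df) == 0) {
    pc_error("alert catalog must be a non-empty TSV with columns name, smarts",
             "patentchem_io_error")
  }
  if (!"family" %in% names(cat_df)) cat_df$family <- NA_character_
  if (anyDuplicated(cat_df$name)) {
    pc_error("alert names must be unique within a catalog", "patentchem_io_error")
  }
  probe <- chem_obmols(chem_sdfset("CC"))
  for (i in seq_len(nrow(cat_df))) {
    ok <- tryCatch({
      chem_smarts_count(probe, cat_df$smarts[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      pc_error(sprintf("SMARTS pattern for alert %s (line %d) does not compile",
                       encodeString(cat_df$name[i], quote = "\""), i + 1L),
               "patentchem_catalog_error", pattern = cat_df$smarts[i])
    }
  }
  out <- tibble::as_tibble(cat_df[, c("name", "family", "smarts")])
  message(sprintf("loaded alert catalog: %d pattern(s)", nrow(out)))
  out
}

#' Screen structures against an alert catalog
#'
#' Substructure matching is performed on the (desalted) parent structure
#' with aromaticity perceived and hydrogens made explicit. Each matching
#' (structure, alert) pair is reported once; a structure may trigger many
#' alerts.
#'
#' @param smiles Character vector of desalted SMILES.
#' @param catalog Alert catalog from [load_alert_catalog()].
#' @return Tibble with `idx` (index into `smiles`), `smiles`, `alert`.
#' @export
screen_alerts <- function(smiles, catalog = load_alert_catalog()) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  mols <- chem_obmols(chem_sdfset(smiles, explicit_h = TRUE))
  hits <- lapply(seq_len(nrow(catalog)), function(i) {
    idx <- which(chem_smarts_count(mols, catalog$smarts[i]) > 0)
    if (length(idx) == 0) return(NULL)
    tibble::tibble(idx = idx, smiles = smiles[idx], alert = catalog$name[i])
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(idx = integer(), smiles = character(), alert = character()))
  }
  dplyr::arrange(out, .data$idx, .data$alert)
}

#' Summarise alert hits over a compound table
#'
#' @param records Deduplicated compound table with `inchikey` and desalted
#'   `smiles`.
#' @param catalog Alert catalog from [load_alert_catalog()].
#' @return A list: `per_alert` (tibble of `alert`, `n_compounds`, distinct
#'   compounds per alert), `n_alerts_hit` (alerts with at least one hit),
#'   `flagged_fraction` (share of compounds with >= 1 hit) and `hits` (the
#'   compound-level hit table).
#' @export
alert_summary <- function(records, catalog = load_alert_catalog()) {
  if (nrow(records) == 0) {
    return(list(per_alert = tibble::tibble(alert = character(), n_compounds = integer()),
                n_alerts_hit = 0L, flagged_fraction = 0, hits = tibble::tibble()))
  }
  hits <- screen_alerts(records$smiles, catalog)
  hits$inchikey <- records$inchikey[hits$idx]
  per_alert <- hits |>
    dplyr::distinct(.data$alert, .data$inchikey) |>
    dplyr::count(.data$alert, name = "n_compounds") |>
    dplyr::arrange(dplyr::desc(.data$n_compounds), .data$alert)
  list(
    per_alert = per_alert,
    n_alerts_hit = nrow(per_alert),
    flagged_fraction = length(unique(hits$inchikey)) / nrow(records),
    hits = hits[, c("inchikey", "smiles", "alert")]
  )
}
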