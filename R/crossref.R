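# Cross-referencing patent compounds against external compound resources by
# exact InChIKey match, with clinical-phase annotation.

#' Construct a resource table
#'
#' A resource is a named set of InChIKeys with optional per-key clinical
#' annotations (`max_phase`, `status`). Malformed keys are dropped with a
#' warning. Matching is exact on the full 27-character key, so
#' stereoisomers do not cross-match.
#'
#' @param name Resource label, e.g. `"pubchem_like"`.
#' @param keys Character vector of InChIKeys.
#' @param annotations Optional tibble with columns `inchikey` and any of
#'   `max_phase`, `status`.
#' @return A `patentchem_resource` list object.
#' @export
resource_table <- function(name, keys, annotations = NULL) {
  stopifnot(is.character(name), length(name) == 1, is.character(keys))
  ok <- is_valid_inchikey(keys)
  if (any(!ok)) {
    warning(sprintf("resource %s: dropped %d malformed InChIKey(s)", name, sum(!ok)))
  }
  keys <- unique(keys[ok])
  if (!is.null(annotations)) {
    annotations <- annotations[is_valid_inchikey(annotations$inchikey) &
                                 annotations$inchikey %in% keys, , drop = FALSE]
  }
  structure(list(name = name, keys = keys, annotations = annotations),
            class = "patentchem_resource")
}

#' @export
print.patentchem_resource <- function(x, ...) {
  cat(sprintf("<resource %s: %d key(s), %s annotations>\n", x$name, length(x$keys),
              if (is.null(x$annotations)) "no" else nrow(x$annotations)))
  invisible(x)
}

#' Read a resource file
#'
#' Tab-separated with a header: column `inchikey`, optional column
#' `annotation` holding a JSON object per row (fields `max_phase`,
#' `status`).
#'
#' @param path File path.
#' @param name Resource label; defaults to the file stem.
#' @return A `patentchem_resource`.
#' @export
read_resource_table <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) {
    pc_error(sprintf("resource file not found: %s", path), "patentchem_io_error")
  }
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  if (!"inchikey" %in% names(d)) {
    pc_error("resource file lacks an 'inchikey' column", "patentchem_io_error")
  }
  ann <- NULL
  if ("annotation" %in% names(d)) {
    has <- !is.na(d$annotation) & nzchar(d$annotation)
    if (any(has)) {
      parsed <- lapply(d$annotation[has], jsonlite::fromJSON)
      ann <- tibble::tibble(
        inchikey = d$inchikey[has],
        max_phase = vapply(parsed, function(p) as.character(p$max_phase %||% NA), character(1)),
        status = vapply(parsed, function(p) as.character(p$status %||% NA), character(1))
      )
    }
  }
  resource_table(name, d$inchikey, ann)
}

#' Match compounds against a resource by exact InChIKey
#'
#' @param records Compound table with an `inchikey` column.
#' @param resource A `patentchem_resource`.
#' @return Logical membership vector along `records`.
#' @export
match_by_inchikey <- function(records, resource) {
  stopifnot(inherits(resource, "patentchem_resource"))
  records$inchikey %in% resource$keys
}

#' Membership region counts over a set of resources
#'
#' Counts compounds in every membership combination (the regions of an
#' Euler diagram over the resources). Region counts always sum to the
#' number of compounds.
#'
#' @param records Compound table.
#' @param resources List of `patentchem_resource` objects.
#' @return Tibble with one logical column per resource plus `count`.
#' @export
overlap_summary <- function(records, resources) {
  if (length(resources) == 0) {
    return(tibble::tibble(count = nrow(records)))
  }
  mem <- lapply(resources, function(r) match_by_inchikey(records, r))
  names(mem) <- vapply(resources, function(r) r$name, character(1))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(mem)))
  names(combos) <- names(mem)
  mm <- do.call(cbind, mem)
  count <- apply(combos, 1, function(row) sum(colSums(t(mm) == row) == length(row)))
  out <- tibble::as_tibble(combos)
  out$count <- as.integer(count)
  out
}

#' Compounds found in no external resource
#'
#' @param records Compound table with `inchikey` and `first_year`.
#' @param resources List of `patentchem_resource` objects.
#' @return A list: `compounds` (the exclusive subset), `fraction`, and
#'   `by_year` (per first-application-year exclusive counts).
#' @export
exclusive_set <- function(records, resources) {
  matched_any <- if (length(resources) == 0) {
    rep(FALSE, nrow(records))
  } else {
    Reduce(`|`, lapply(resources, function(r) match_by_inchikey(records, r)))
  }
  excl <- records[!matched_any, , drop = FALSE]
  by_year <- excl |>
    dplyr::count(year = .data$first_year, name = "count") |>
    dplyr::arrange(.data$year)
  list(compounds = excl,
       fraction = if (nrow(records) > 0) nrow(excl) / nrow(records) else 0,
       by_year = by_year)
}

clinical_phases <- function() {
  c("UNKNOWN", "PRECLINICAL", "PHASE1", "PHASE2", "PHASE3", "APPROVED")
}

#' Default numeric max-phase decoding
#'
#' External resources often encode the furthest clinical stage numerically;
#' the named classes used here are decoded through this table (overridable
#' in [annotate_clinical()]). The preclinical/unknown boundary is a
#' judgement call exposed as configuration rather than hard-coded.
#'
#' @return Named character vector mapping numeric codes to phase names.
#' @export
default_phase_map <- function() {
  c(`-1` = "UNKNOWN", `0` = "PRECLINICAL", `0.5` = "PRECLINICAL",
    `1` = "PHASE1", `2` = "PHASE2", `3` = "PHASE3", `4` = "APPROVED")
}

#' Clinical-phase and approval-status distribution of matched compounds
#'
#' Compounds matched in the ChEMBL-like resource receive its `max_phase`
#' annotation (`UNKNOWN` when matched without a phase); approval statuses
#' come from the DrugBank-like resource. A compound annotated both approved
#' and withdrawn is counted under both and flagged as a conflict.
#'
#' @param records Compound table.
#' @param chembl_like Resource carrying `max_phase` annotations.
#' @param drugbank_like Resource carrying `status` annotations.
#' @param phase_map Decoding table for numeric phases, see
#'   [default_phase_map()].
#' @return A list: `phase_counts` (tibble over the six phase classes),
#'   `status_counts` (approved / investigational / withdrawn), `n_matched`,
#'   `n_unmatched` and `conflicts` (InChIKeys with contradictory status).
#' @export
annotate_clinical <- function(records, chembl_like, drugbank_like,
                              phase_map = default_phase_map()) {
  matched <- match_by_inchikey(records, chembl_like)
  phase <- rep(NA_character_, nrow(records))
  phase[matched] <- "UNKNOWN"
  ann <- chembl_like$annotations
  if (!is.null(ann) && nrow(ann) > 0 && "max_phase" %in% names(ann)) {
    hit <- match(records$inchikey, ann$inchikey)
    has <- matched & !is.na(hit) & !is.na(ann$max_phase[hit])
    raw <- ann$max_phase[hit[has]]
    decoded <- ifelse(raw %in% clinical_phases(), raw, unname(phase_map[raw]))
    if (anyNA(decoded)) {
      warning(sprintf("undecodable max_phase value(s): %s; treated as UNKNOWN",
                      paste(unique(raw[is.na(decoded)]), collapse = ", ")))
      decoded[is.na(decoded)] <- "UNKNOWN"
    }
    phase[has] <- decoded
  }
  phase_tab <- table(factor(phase, levels = clinical_phases()))
  phase_counts <- tibble::tibble(phase = clinical_phases(),
                                 count = as.integer(phase_tab))

  statuses <- c("APPROVED", "INVESTIGATIONAL", "WITHDRAWN")
  status_count <- stats::setNames(integer(length(statuses)), statuses)
  conflicts <- character()
  db_ann <- drugbank_like$annotations
  if (!is.null(db_ann) && nrow(db_ann) > 0 && "status" %in% names(db_ann)) {
    db <- db_ann[db_ann$inchikey %in% records$inchikey & !is.na(db_ann$status), , drop = FALSE]
    for (s in statuses) status_count[s] <- length(unique(db$inchikey[db$status == s]))
    by_key <- split(db$status, db$inchikey)
    conflicts <- names(by_key)[vapply(by_key, function(x) all(c("APPROVED", "WITHDRAWN") %in% x),
                                      logical(1))]
    if (length(conflicts) > 0) {
      warning(sprintf("%d compound(s) annotated both approved and withdrawn", length(conflicts)))
    }
  }
  list(
    phase_counts = phase_counts,
    status_counts = tibble::tibble(status = statuses, count = as.integer(status_count)),
    n_matched = sum(matched),
    n_unmatched = sum(!matched),
    conflicts = conflicts
  )
}
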