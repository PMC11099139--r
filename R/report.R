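# Pipeline orchestration: ingest -> desalt/descriptors -> classification ->
# scaffolds -> alerts -> crossref -> aggregation into a report bundle.

#' Section-annotation shares over compounds
#'
#' Per-source share of deduplicated compounds citing that source, plus the
#' share of compounds annotated from more than one source.
#'
#' @param records Deduplicated compound table with a `sections` list-column.
#' @return A list: `per_source` (tibble of `section`, `n`, `share`) and
#'   `multi_source_share`.
#' @export
section_annotation_shares <- function(records) {
  n <- nrow(records)
  secs <- section_sources()
  counts <- unname(vapply(secs, function(s) {
    sum(vapply(records$sections, function(x) s %in% x, logical(1)))
  }, integer(1)))
  total <- n
  multi <- if (total > 0) sum(lengths(records$sections) >= 2) / total else 0
  list(
    per_source = tibble::tibble(
      section = secs, n = counts,
      share = if (total > 0) counts / total else rep(0, length(secs))),
    multi_source_share = multi
  )
}

#' Run the full profiling pipeline on a corpus
#'
#' Executes every stage on a map dump plus optional resource files and
#' assembles the summary bundle: per-year patent/compound counts, the kind
#' code by country table, the promiscuity histogram, section-annotation
#' shares, drug-likeness label shares with top-prevalent compounds, yearly
#' descriptor means, the PAINS summary, scaffold statistics (novelty,
#' molecular-weight distribution, section attribution, top scaffolds),
#' cross-resource overlap regions and the clinical-phase distribution.
#' Compounds whose SMILES the backend cannot parse are dropped and counted
#' in `meta$dropped_structures`. The pipeline itself is deterministic:
#' re-running on the same inputs reproduces the bundle exactly.
#'
#' @param map_dump Path to the map dump TSV.
#' @param resource_paths Named character vector of resource-file paths
#'   (names become resource labels). ChEMBL-like / DrugBank-like resources
#'   are recognized by the labels `chembl_like` and `drugbank_like`.
#' @param catalog Alert catalog (default: built-in PAINS).
#' @param top_k Number of top scaffolds / top prevalent compounds to keep.
#' @param min_year Year cutoff passed to [read_map_dump()].
#' @param column_map,section_codes Dump dialect, see [read_map_dump()].
#' @return A `patentchem_report` list; see Details.
#' @export
run_pipeline <- function(map_dump, resource_paths = character(),
                         catalog = NULL, top_k = 10, min_year = 2015,
                         column_map = default_column_map(),
                         section_codes = default_section_codes()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pc_error(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
               "patentchem_stage_error", stage = name)
    })
  }

  occ <- stage("ingest", read_map_dump(map_dump, column_map = column_map,
                                       section_codes = section_codes,
                                       min_year = min_year))
  records <- stage("dedupe", dedupe(occ))

  desalted <- stage("desalt", desalt_quiet(records$smiles))
  ok <- !is.na(desalted)
  dropped_structures <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  records$smiles_raw <- records$smiles
  records$smiles <- as.character(desalted[ok])

  if (nrow(records) > 0) {
    desc <- stage("descriptors", compute_descriptors(records$smiles))
    records <- dplyr::bind_cols(records, desc[, -1])
    records$label <- stage("classify", classify_druglikeness(records))
  } else {
    records$label <- factor(character(), levels = c("RO5", "BRO5", "NEITHER"))
  }

  label_shares <- tibble::tibble(
    label = c("RO5", "BRO5", "NEITHER"),
    n = as.integer(table(records$label)),
    share_pct = if (nrow(records) > 0) 100 * as.integer(table(records$label)) / nrow(records) else rep(0, 3)
  )

  per_year <- occ |>
    dplyr::distinct(.data$scpn, .data$year) |>
    dplyr::count(.data$year, name = "patents") |>
    dplyr::full_join(
      records |> dplyr::count(year = .data$first_year, name = "compounds"),
      by = "year") |>
    dplyr::arrange(.data$year) |>
    tidyr::replace_na(list(patents = 0L, compounds = 0L))

  kind_country <- occ |>
    dplyr::distinct(.data$inchikey, .data$country, .data$kind) |>
    dplyr::mutate(kind_group = kind_group(.data$kind)) |>
    dplyr::count(.data$country, .data$kind_group, name = "compounds") |>
    dplyr::arrange(.data$country, .data$kind_group)

  promiscuity <- promiscuity_distribution(records)
  sections <- section_annotation_shares(records)

  yearly_means <- if (nrow(records) > 0) {
    stage("yearly_means", suppressMessages(yearly_property_means(records)))
  } else {
    tibble::tibble()
  }
  top_by_label <- lapply(stats::setNames(nm = c("RO5", "BRO5", "NEITHER")), function(lab) {
    suppressMessages(top_prevalent(records, lab, k = min(5, top_k)))
  })

  scaffolds <- stage("scaffolds", scaffold_table(records))
  scaffold_out <- list(
    n_scaffolds = nrow(scaffolds),
    n_acyclic_parents = attr(scaffolds, "acyclic"),
    novelty = novelty_by_year(scaffolds),
    attribution = scaffold_section_attribution(scaffolds),
    top = top_scaffolds(scaffolds, k = top_k)
  )

  if (is.null(catalog)) catalog <- suppressMessages(load_alert_catalog("pains"))
  pains <- stage("alerts", alert_summary(records, catalog))

  resources <- lapply(seq_along(resource_paths), function(i) {
    read_resource_table(resource_paths[[i]], name = names(resource_paths)[i])
  })
  crossref <- NULL
  if (length(resources) > 0) {
    regions <- stage("crossref", overlap_summary(records, resources))
    excl <- exclusive_set(records, resources)
    matched_frac <- vapply(resources, function(r) {
      if (nrow(records) > 0) mean(match_by_inchikey(records, r)) else 0
    }, numeric(1))
    clinical <- NULL
    nm <- vapply(resources, function(r) r$name, character(1))
    if (all(c("chembl_like", "drugbank_like") %in% nm)) {
      clinical <- stage("clinical", suppressWarnings(
        annotate_clinical(records, resources[[which(nm == "chembl_like")]],
                          resources[[which(nm == "drugbank_like")]])))
    }
    crossref <- list(regions = regions,
                     matched_fraction = stats::setNames(matched_frac, nm),
                     exclusive_fraction = excl$fraction,
                     exclusive_by_year = excl$by_year,
                     clinical = clinical)
  }

  bundle <- list(
    compounds = records,
    n_compounds = nrow(records),
    n_occurrences = nrow(occ),
    load_report = load_report(occ),
    per_year = per_year,
    kind_country = kind_country,
    promiscuity = promiscuity$histogram,
    sections = sections,
    label_shares = label_shares,
    top_prevalent = top_by_label,
    yearly_means = yearly_means,
    scaffolds = scaffold_out,
    pains = list(per_alert = pains$per_alert, n_alerts_hit = pains$n_alerts_hit,
                 flagged_fraction = pains$flagged_fraction),
    crossref = crossref,
    meta = list(package_version = as.character(utils::packageVersion("patentchem")),
                dropped_structures = dropped_structures)
  )
  class(bundle) <- "patentchem_report"
  bundle
}

#' @export
print.patentchem_report <- function(x, ...) {
  cat(sprintf("<patentchem report: %d compounds, %d occurrences>\n",
              x$n_compounds, x$n_occurrences))
  shares <- sprintf("%s %.1f%%", x$label_shares$label, x$label_shares$share_pct)
  cat("  drug-likeness:", paste(shares, collapse = ", "), "\n")
  cat(sprintf("  scaffolds: %d distinct (%d acyclic parents)\n",
              x$scaffolds$n_scaffolds, x$scaffolds$n_acyclic_parents))
  cat(sprintf("  PAINS-flagged: %.2f%%\n", 100 * x$pains$flagged_fraction))
  if (!is.null(x$crossref)) {
    cat(sprintf("  resource-exclusive: %.2f%%\n", 100 * x$crossref$exclusive_fraction))
  }
  invisible(x)
}

#' Write a report bundle to CSV/JSON files
#'
#' Numbers are written unrounded except percentages, which are rounded to
#' two decimals at serialization only.
#'
#' @param bundle A `patentchem_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "patentchem_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wrote <- character()
  put_csv <- function(d, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(d, p, progress = FALSE)
    wrote <<- c(wrote, p)
  }
  put_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    wrote <<- c(wrote, p)
  }
  comp <- bundle$compounds
  comp$patents <- vapply(comp$patents, paste, character(1), collapse = ";")
  comp$years <- vapply(comp$years, paste, character(1), collapse = ";")
  comp$sections <- vapply(comp$sections, paste, character(1), collapse = ";")
  put_csv(comp, "compounds.csv")
  put_csv(bundle$per_year, "per_year_counts.csv")
  put_csv(bundle$kind_country, "kind_by_country.csv")
  put_csv(bundle$promiscuity, "promiscuity_histogram.csv")
  put_csv(bundle$sections$per_source, "section_shares.csv")
  put_csv(dplyr::mutate(bundle$label_shares, share_pct = round(.data$share_pct, 2)),
          "label_shares.csv")
  put_csv(bundle$yearly_means, "yearly_property_means.csv")
  put_csv(bundle$pains$per_alert, "pains_per_alert.csv")
  scaf <- bundle$scaffolds
  put_csv(scaf$novelty, "scaffold_novelty.csv")
  put_csv(scaf$attribution, "scaffold_section_attribution.csv")
  put_json(list(top = scaf$top$top, mw_summary = scaf$top$mw_summary,
                n_scaffolds = scaf$n_scaffolds,
                n_acyclic_parents = scaf$n_acyclic_parents), "scaffolds.json")
  put_json(bundle$top_prevalent, "top_prevalent.json")
  put_json(list(multi_source_share = bundle$sections$multi_source_share,
                flagged_fraction = bundle$pains$flagged_fraction,
                n_alerts_hit = bundle$pains$n_alerts_hit,
                load_report = bundle$load_report,
                meta = bundle$meta), "summary.json")
  if (!is.null(bundle$crossref)) {
    put_csv(bundle$crossref$regions, "overlap_regions.csv")
    put_csv(bundle$crossref$exclusive_by_year, "exclusive_by_year.csv")
    cl <- bundle$crossref$clinical
    put_json(list(matched_fraction = as.list(bundle$crossref$matched_fraction),
                  exclusive_fraction = bundle$crossref$exclusive_fraction,
                  phase_counts = if (!is.null(cl)) cl$phase_counts else NULL,
                  status_counts = if (!is.null(cl)) cl$status_counts else NULL),
             "crossref.json")
  }
  invisible(wrote)
}
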