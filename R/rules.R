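# Drug-likeness rule sets: Lipinski/Veber rule of five and the
# beyond-rule-of-five (bRo5) window.

#' The default drug-likeness rule set
#'
#' Ro5 compliance requires MW <= 500, cLogP <= 5, HBD <= 5 and HBA <= 10
#' (Lipinski) together with TPSA < 140 and NRotB < 12 (Veber). The bRo5
#' space is 500 < MW < 3000 Daltons with at least one property beyond the
#' extended Ro5 bounds: cLogP > 7.5 or cLogP < 0, HBD > 5, HBA > 10,
#' TPSA > 200, or NRotB > 20. Lipinski thresholds are inclusive, Veber and
#' all bRo5 thresholds strict, as conventionally printed.
#'
#' @return A named list of thresholds; pass a modified copy to the
#'   classifiers to override (overrides are reported via a message).
#' @export
default_ruleset <- function() {
  list(
    ro5 = c(mw = 500, clogp = 5, hbd = 5, hba = 10),
    veber = c(tpsa = 140, nrotb = 12),
    bro5_window = c(lower = 500, upper = 3000),
    bro5_violation = c(clogp_hi = 7.5, clogp_lo = 0, hbd = 5, hba = 10,
                       tpsa = 200, nrotb = 20)
  )
}

check_ruleset <- function(rules) {
  if (!identical(rules, default_ruleset())) {
    message("drug-likeness thresholds overridden from defaults")
  }
  rules
}

#' Rule-of-five compliance
#'
#' @param d Data frame with columns `mw`, `clogp`, `hba`, `hbd`, `tpsa`,
#'   `nrotb` (see [compute_descriptors()]).
#' @param rules Rule set, see [default_ruleset()].
#' @return Logical vector.
#' @export
passes_ro5 <- function(d, rules = default_ruleset()) {
  rules <- check_ruleset(rules)
  d$mw <= rules$ro5[["mw"]] &
    d$clogp <= rules$ro5[["clogp"]] &
    d$hbd <= rules$ro5[["hbd"]] &
    d$hba <= rules$ro5[["hba"]] &
    d$tpsa < rules$veber[["tpsa"]] &
    d$nrotb < rules$veber[["nrotb"]]
}

#' Beyond-rule-of-five compliance
#'
#' @inheritParams passes_ro5
#' @return Logical vector.
#' @export
passes_bro5 <- function(d, rules = default_ruleset()) {
  rules <- check_ruleset(rules)
  v <- rules$bro5_violation
  violation <- d$clogp > v[["clogp_hi"]] | d$clogp < v[["clogp_lo"]] |
    d$hbd > v[["hbd"]] | d$hba > v[["hba"]] |
    d$tpsa > v[["tpsa"]] | d$nrotb > v[["nrotb"]]
  d$mw > rules$bro5_window[["lower"]] &
    d$mw < rules$bro5_window[["upper"]] &
    violation
}

#' Classify compounds as RO5, BRO5 or NEITHER
#'
#' Labels are mutually exclusive: the MW windows of the two rule sets do not
#' overlap (Ro5 requires MW <= 500, bRo5 requires MW > 500), so every
#' descriptor vector receives exactly one label.
#'
#' @inheritParams passes_ro5
#' @return Factor with levels `RO5`, `BRO5`, `NEITHER`.
#' @export
classify_druglikeness <- function(d, rules = default_ruleset()) {
  lab <- ifelse(passes_ro5(d, rules), "RO5",
                ifelse(passes_bro5(d, rules), "BRO5", "NEITHER"))
  factor(lab, levels = c("RO5", "BRO5", "NEITHER"))
}

#' Per-year means of the seven tabulated physicochemical properties
#'
#' Arithmetic means of MW, cLogP, HBA, HBD, NRotB, ring count and
#' stereocenter count, grouped by first application year. Years with no
#' compounds are omitted (with a message naming them when a year range is
#' supplied by the data).
#'
#' @param records Compound table carrying `first_year` and descriptor
#'   columns.
#' @return Tibble with one row per year, `n` compounds and the seven means.
#' @export
yearly_property_means <- function(records) {
  stopifnot(all(c("first_year", "mw", "clogp", "hba", "hbd", "nrotb",
                  "n_rings", "n_stereo") %in% names(records)))
  out <- records |>
    dplyr::group_by(year = .data$first_year) |>
    dplyr::summarise(
      n = dplyr::n(),
      mw = mean(.data$mw), clogp = mean(.data$clogp),
      hba = mean(.data$hba), hbd = mean(.data$hbd),
      nrotb = mean(.data$nrotb), n_rings = mean(.data$n_rings),
      n_stereo = mean(.data$n_stereo),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year)
  missing_years <- setdiff(seq(min(records$first_year), max(records$first_year)), out$year)
  if (length(missing_years) > 0) {
    message("years with no compounds omitted: ", paste(missing_years, collapse = ", "))
  }
  out
}

#' Most prevalent compounds within a drug-likeness class
#'
#' @param records Compound table with `label`, `inchikey` and `n_patents`.
#' @param label One of `"RO5"`, `"BRO5"`, `"NEITHER"`.
#' @param k Number of compounds to return.
#' @return Tibble of the `k` compounds with the largest patent counts,
#'   descending, ties broken by InChIKey order.
#' @export
top_prevalent <- function(records, label, k = 5) {
  label <- match.arg(label, c("RO5", "BRO5", "NEITHER"))
  stopifnot(k >= 0)
  pool <- records[as.character(records$label) == label, ]
  if (nrow(pool) < k) {
    message(sprintf("only %d %s compound(s) available for top-%d", nrow(pool), label, k))
  }
  pool |>
    dplyr::arrange(dplyr::desc(.data$n_patents), .data$inchikey) |>
    utils::head(k) |>
    dplyr::select(dplyr::any_of(c("inchikey", "schembl_id", "smiles", "n_patents", "label")))
}
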