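# Bemis-Murcko scaffolds: ring systems plus the linkers connecting them,
# side chains pruned, heteroatoms and bond orders retained. Atoms attached
# to a retained ring/linker atom through a double or triple bond are kept
# (standard Murcko behaviour for exocyclic carbonyls and the like).

#' Bemis-Murcko scaffold of desalted structures
#'
#' The scaffold is obtained from the molecular graph by (i) iteratively
#' deleting terminal atoms until only atoms lying on rings or on paths
#' between rings remain, then (ii) restoring atoms multiple-bonded directly
#' to that core. Acyclic molecules have no scaffold and yield the empty
#' string. The operation is idempotent and the scaffold's heavy-atom count
#' and weight never exceed the parent's.
#'
#' @param smiles Character vector of desalted SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @export
#' @examples
#' bm_scaffold(c("Cc1ccccc1", "CCCC"))
bm_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  sdf <- chem_sdfset(smiles)
  vapply(seq_along(sdf), function(i) {
    graph <- chem_graph(sdf[[i]])
    keep <- scaffold_atoms(graph)
    if (length(keep) == 0) return("")
    chem_subgraph_smiles(graph, keep)
  }, character(1))
}

# Indices of scaffold atoms (ring + linker core, plus atoms multiple-bonded
# to the core); integer(0) for acyclic molecules.
scaffold_atoms <- function(graph) {
  n <- graph$n
  bonds <- graph$bonds
  if (nrow(bonds) - n + 1L <= 0) return(integer()) # no rings
  alive <- rep(TRUE, n)
  repeat {
    live_bonds <- alive[bonds[, 1]] & alive[bonds[, 2]]
    deg <- tabulate(c(bonds[live_bonds, 1], bonds[live_bonds, 2]), nbins = n)
    leaves <- which(alive & deg == 1)
    if (length(leaves) == 0) break
    alive[leaves] <- FALSE
  }
  core <- which(alive)
  if (length(core) == 0) return(integer())
  multi <- bonds[, 3] >= 2
  extra <- unique(c(
    bonds[multi & bonds[, 1] %in% core & !(bonds[, 2] %in% core), 2],
    bonds[multi & bonds[, 2] %in% core & !(bonds[, 1] %in% core), 1]
  ))
  sort(c(core, extra))
}

#' Aggregate compounds into a scaffold table
#'
#' One row per distinct non-empty scaffold SMILES, with parent frequency,
#' earliest parent year, the union of parent section sources and the
#' scaffold molecular weight. Acyclic parents carry no scaffold and are
#' reported separately in the `"acyclic"` attribute.
#'
#' @param records Deduplicated compound table with columns `smiles`
#'   (desalted), `first_year`, `years` and `sections` (as from the
#'   pipeline; `years` may be absent, in which case `first_year` is used).
#' @return Tibble with `scaffold`, `mw`, `frequency`, `first_year` and
#'   list-columns `years`, `sections`; attribute `"acyclic"` holds the
#'   count of acyclic parents.
#' @export
scaffold_table <- function(records) {
  stopifnot(all(c("smiles", "first_year", "sections") %in% names(records)))
  if (nrow(records) == 0) {
    out <- tibble::tibble(scaffold = character(), mw = numeric(),
                          frequency = integer(), first_year = integer(),
                          years = list(), sections = list())
    attr(out, "acyclic") <- 0L
    return(out)
  }
  scaf <- bm_scaffold(records$smiles)
  yrs <- if ("years" %in% names(records)) records$years else as.list(records$first_year)
  d <- tibble::tibble(scaffold = scaf, first_year = records$first_year,
                      years = yrs, sections = records$sections)
  acyclic <- sum(d$scaffold == "")
  d <- d[d$scaffold != "", ]
  if (nrow(d) == 0) {
    out <- tibble::tibble(scaffold = character(), mw = numeric(),
                          frequency = integer(), first_year = integer(),
                          years = list(), sections = list())
    attr(out, "acyclic") <- acyclic
    return(out)
  }
  out <- d |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(
      frequency = dplyr::n(),
      first_year = min(.data$first_year),
      years = list(sort(unique(unlist(.data$years)))),
      sections = list(sort(unique(unlist(.data$sections)))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$scaffold)
  mw <- if (nrow(out) > 0) ChemmineR::propOB(chem_sdfset(out$scaffold))$MW else numeric()
  out <- dplyr::mutate(out, mw = mw, .after = "scaffold")
  attr(out, "acyclic") <- acyclic
  out
}

#' Scaffold novelty per year
#'
#' A scaffold is "new" in the earliest year any parent compound carries it
#' and "known" in every later year in which it recurs. Summed over years,
#' the new counts equal the number of distinct scaffolds, and the earliest
#' corpus year has no known scaffolds.
#'
#' @param table Scaffold table from [scaffold_table()] (uses the `years`
#'   list-column).
#' @return Tibble with `year`, `new`, `known`.
#' @export
novelty_by_year <- function(table) {
  if (nrow(table) == 0) return(tibble::tibble(year = integer(), new = integer(), known = integer()))
  first <- vapply(table$years, function(y) y[1], numeric(1))
  later <- unlist(lapply(table$years, function(y) y[-1]))
  years <- sort(unique(c(first, later)))
  tibble::tibble(
    year = as.integer(years),
    new = as.integer(table(factor(first, levels = years))),
    known = as.integer(table(factor(later, levels = years)))
  )
}

#' Scaffold counts per patent-document section
#'
#' For each of the six section sources, counts the distinct scaffolds whose
#' parent compounds include that source. A scaffold may be attributed to
#' several sections, so the share columns need not sum to 100: `pct_scaffolds`
#' is relative to the number of distinct scaffolds, `pct_pairs` to the
#' number of scaffold-section pairs.
#'
#' @param table Scaffold table from [scaffold_table()].
#' @return Tibble with `section`, `count`, `pct_scaffolds`, `pct_pairs`.
#' @export
scaffold_section_attribution <- function(table) {
  secs <- section_sources()
  counts <- unname(vapply(secs, function(s) {
    sum(vapply(table$sections, function(x) s %in% x, logical(1)))
  }, integer(1)))
  total_pairs <- sum(counts)
  tibble::tibble(
    section = secs,
    count = counts,
    pct_scaffolds = if (nrow(table) > 0) 100 * counts / nrow(table) else rep(0, length(secs)),
    pct_pairs = if (total_pairs > 0) 100 * counts / total_pairs else rep(0, length(secs))
  )
}

#' Highest-frequency scaffolds
#'
#' @param table Scaffold table from [scaffold_table()].
#' @param k Number of scaffolds to return; `k` larger than the table
#'   returns the whole table.
#' @return A list with `top` (tibble of the `k` most frequent scaffolds,
#'   ties broken by scaffold SMILES order) and `mw_summary` (min, quartiles,
#'   median, max of the scaffold molecular-weight distribution).
#' @export
top_scaffolds <- function(table, k = 10) {
  stopifnot(k >= 0)
  top <- table |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$scaffold) |>
    utils::head(k) |>
    dplyr::select("scaffold", "frequency", "mw", "first_year")
  mw_summary <- if (nrow(table) > 0) {
    q <- stats::quantile(table$mw, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    list(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
  } else {
    list(min = NA_real_, q25 = NA_real_, median = NA_real_, q75 = NA_real_, max = NA_real_)
  }
  list(top = top, mw_summary = mw_summary)
}
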