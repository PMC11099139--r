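# Synthetic patent-compound corpora with planted ground truth.
#
# The generator emulates the structure of a compound-to-patent map dump:
# compounds with SMILES/InChIKey, SCPN patent identifiers with kind codes,
# application years, six-valued section annotations, a heavy-tailed
# compound-to-patent promiscuity distribution, configurable drug-likeness
# class fractions, cross-resource overlaps with clinical labels, and an
# injected PAINS substructure rate. Resource memberships, phases and
# statuses are planted deterministically (quota assignment, not Bernoulli
# draws) so that downstream recovery can be asserted exactly.

#' Configuration for a synthetic corpus
#'
#' Defaults mirror the headline structure of the patent chemistry landscape
#' this package profiles: drug-likeness class shares of 55/16/29 percent
#' (Ro5/bRo5/neither), image-dominated section annotations, a discrete
#' truncated power-law promiscuity tail, external-resource overlaps of
#' 90/30/5 percent, a preclinical-dominated clinical-phase mix and a 4
#' percent PAINS injection rate.
#'
#' @param n_compounds Number of distinct compounds.
#' @param years Inclusive application-year range.
#' @param class_fractions Named fractions (`ro5`, `bro5`, `neither`)
#'   summing to 1.
#' @param section_marginals Per-source annotation probabilities (each
#'   occurrence gets at least one source).
#' @param promiscuity `list(alpha, max_count)`: patent counts per compound
#'   follow P(k) proportional to k^-alpha on 1..max_count.
#' @param resource_overlaps Named per-resource fractions of compounds
#'   planted into each resource.
#' @param exclusive_fraction Optional fraction of compounds reserved out of
#'   every resource; requires `max(resource_overlaps) == 1 -
#'   exclusive_fraction` so the planted exclusive share is exact.
#' @param phase_distribution Probabilities over the clinical phase classes,
#'   applied to ChEMBL-like members by deterministic quota.
#' @param status_distribution Probabilities over approval statuses, applied
#'   to DrugBank-like members by deterministic quota.
#' @param pains_rate Fraction of compounds carrying an injected PAINS motif.
#' @param decoy_fraction Resource-only decoy keys added per resource, as a
#'   fraction of `n_compounds`.
#' @param seed Integer seed; a fixed seed makes the corpus byte-identical.
#' @return A validated `patentchem_synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 2000,
                             years = 2015:2022,
                             class_fractions = c(ro5 = 0.55, bro5 = 0.16, neither = 0.29),
                             section_marginals = c(TITLE = 0.01, ABSTRACT = 0.03,
                                                   DESCRIPTION = 0.281, CLAIMS = 0.17,
                                                   IMAGE = 0.48, MOLFILE = 0.15),
                             promiscuity = list(alpha = 2.35, max_count = 2000),
                             resource_overlaps = c(pubchem_like = 0.9,
                                                   chembl_like = 0.3,
                                                   drugbank_like = 0.05),
                             exclusive_fraction = NULL,
                             phase_distribution = c(UNKNOWN = 0.016, PRECLINICAL = 0.80,
                                                    PHASE1 = 0.04, PHASE2 = 0.07,
                                                    PHASE3 = 0.06, APPROVED = 0.014),
                             status_distribution = c(APPROVED = 0.39,
                                                     INVESTIGATIONAL = 0.595,
                                                     WITHDRAWN = 0.015),
                             pains_rate = 0.04,
                             decoy_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds), years = as.integer(years),
              class_fractions = class_fractions, section_marginals = section_marginals,
              promiscuity = promiscuity, resource_overlaps = resource_overlaps,
              exclusive_fraction = exclusive_fraction,
              phase_distribution = phase_distribution,
              status_distribution = status_distribution,
              pains_rate = pains_rate, decoy_fraction = decoy_fraction,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "patentchem_synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  fail <- function(msg) pc_error(msg, "patentchem_config_error")
  if (cfg$n_compounds < 0) fail("n_compounds must be >= 0")
  if (length(cfg$years) == 0) fail("years must be non-empty")
  if (!setequal(names(cfg$class_fractions), c("ro5", "bro5", "neither"))) {
    fail("class_fractions must name ro5, bro5, neither")
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9) fail("class_fractions must sum to 1")
  for (nm in c("class_fractions", "section_marginals", "resource_overlaps",
               "phase_distribution", "status_distribution")) {
    v <- cfg[[nm]]
    if (any(v < 0 | v > 1)) fail(sprintf("%s must lie in [0, 1]", nm))
  }
  if (!setequal(names(cfg$section_marginals), section_sources())) {
    fail("section_marginals must name the six section sources")
  }
  if (sum(cfg$section_marginals) <= 0) fail("section_marginals must not all be zero")
  if (cfg$pains_rate < 0 || cfg$pains_rate > 1) fail("pains_rate must lie in [0, 1]")
  if (cfg$promiscuity$alpha <= 1) fail("promiscuity alpha must exceed 1")
  if (cfg$promiscuity$max_count < 1) fail("promiscuity max_count must be >= 1")
  if (!setequal(names(cfg$phase_distribution), clinical_phases())) {
    fail("phase_distribution must name the six clinical phase classes")
  }
  if (abs(sum(cfg$phase_distribution) - 1) > 1e-9) fail("phase_distribution must sum to 1")
  if (abs(sum(cfg$status_distribution) - 1) > 1e-9) fail("status_distribution must sum to 1")
  if (!is.null(cfg$exclusive_fraction)) {
    ef <- cfg$exclusive_fraction
    if (ef < 0 || ef >= 1) fail("exclusive_fraction must lie in [0, 1)")
    if (abs(max(cfg$resource_overlaps) - (1 - ef)) > 1e-9) {
      fail("exclusive_fraction requires max(resource_overlaps) == 1 - exclusive_fraction")
    }
  }
  invisible(cfg)
}

# --- molecule construction ------------------------------------------------

PAINS_MOTIFS <- c(catechol = "c1ccc(O)c(O)c1",
                  azo = "N=Nc1ccccc1",
                  quinone = "C1=CC(=O)C=CC1=O")

# Alert names (in the shipped catalog) each motif is guaranteed to trigger.
PAINS_MOTIF_ALERTS <- c(catechol = "catechol_A(92)",
                        azo = "azo_A(324)",
                        quinone = "quinone_A(370)")

# One random template SMILES aimed at the requested class. PAINS motifs are
# grafted through a single sp3 linker bond. Templates avoid hydroxyl or
# amino substitution directly on aromatic rings so that the clean pool
# stays free of catalog alerts; that property is asserted by tests.
gen_candidate <- function(label, motif = NULL) {
  graft <- if (is.null(motif)) "" else PAINS_MOTIFS[[motif]]
  if (label == "RO5") {
    core <- sample(c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1", "C1CCOCC1",
                     "c1ccc2ccccc2c1", "c1ccoc1", "c1cncnc1", "C1CCCC1", "c1ccsc1"), 1)
    pre <- sample(c("", "C", "CC", "CCC", "C(C)C"), 1)
    chain <- strrep("C", sample(1:8, 1))
    term <- if (is.null(motif)) {
      sample(c("O", "N", "OC", "C(=O)OC", "C(=O)N", "F", "Cl", "OCC", "C(C)O", "N(C)C"), 1)
    } else {
      graft
    }
    return(paste0(pre, core, chain, term))
  }
  if (label == "BRO5") {
    fam <- sample(c("polyol", "peg", "polyamide"), 1)
    core <- sample(c("c1ccccc1", "C1CCCCC1", "c1ccc2ccccc2c1", "C1CCOCC1", ""), 1)
    decor <- sample(c("", "C", "CC", "CCC", "C(C)C", "CCCC"), 1)
    unit <- switch(fam, polyol = "C(O)C", peg = "OCC", polyamide = "C(=O)NC")
    m <- switch(fam, polyol = sample(11:17, 1), peg = sample(13:18, 1),
                polyamide = sample(9:14, 1))
    term <- if (is.null(motif)) sample(c("C", "CC", "O", "N"), 1) else graft
    base <- paste0(decor, core, strrep(unit, m), term)
    if (core == "" && decor == "") base <- paste0("C", base)
    return(base)
  }
  # NEITHER: small-but-greasy chains (fail on cLogP, too light for the
  # bRo5 window) or small polyacetals with many acceptors. Positional
  # variation of the mid-chain feature keeps the pool of distinct
  # constitutions large.
  if (stats::runif(1) < 0.85) {
    pre <- sample(c("", "C(C)", "C(C)(C)"), 1)
    a <- sample(6:14, 1); b <- sample(6:14, 1)
    mid <- sample(c("", "O", "S", "C(C)", "C(CC)", "C(Cl)", "C=C", "CC(C)C"), 1)
    term <- if (is.null(motif)) {
      sample(c("", "Cl", "Br", "I", "C(C)C"), 1)
    } else {
      graft
    }
    paste0(pre, strrep("C", a), mid, strrep("C", b), term)
  } else {
    m <- sample(10:15, 1)
    term <- if (is.null(motif)) {
      sample(c("", "C", "CC", "C(C)C", "CC(C)C", "CCC"), 1)
    } else {
      graft
    }
    paste0(strrep("OC", m), strrep("C", sample(0:3, 1)), term)
  }
}

#' Generate one molecule of a requested drug-likeness class
#'
#' Draws from class-specific template pools and rejection-samples against
#' the package's own classifier until the computed descriptors carry the
#' requested label.
#'
#' @param label `"RO5"`, `"BRO5"` or `"NEITHER"`.
#' @param motif Optional PAINS motif to graft (`"catechol"`, `"azo"`,
#'   `"quinone"`).
#' @param max_tries Rejection-sampling cap.
#' @return A single SMILES string.
#' @export
make_molecule <- function(label, motif = NULL, max_tries = 100) {
  label <- match.arg(label, c("RO5", "BRO5", "NEITHER"))
  if (!is.null(motif)) motif <- match.arg(motif, names(PAINS_MOTIFS))
  for (i in seq_len(max_tries)) {
    cand <- gen_candidate(label, motif)
    if (!chem_valid(cand)) next
    if (as.character(classify_druglikeness(compute_descriptors(cand))) == label) {
      return(cand)
    }
  }
  pc_error(sprintf("could not realize a %s molecule in %d tries", label, max_tries),
           "patentchem_generation_error", label = label)
}

# Batch: `count` molecules of one label with distinct InChIKeys, avoiding
# keys in `used` (an environment used as a set). `motifs` is a list of
# per-position motif names (or NULL); positions sharing a motif are
# interchangeable and filled from a common candidate stream. Returns
# tibble(smiles, inchikey) aligned with `motifs`.
make_molecules_batch <- function(label, count, motifs = rep(list(NULL), count),
                                 used, max_rounds = 60) {
  stopifnot(length(motifs) == count)
  motif_key <- vapply(motifs, function(m) if (is.null(m)) "" else m, character(1))
  out_smiles <- character(count)
  out_keys <- character(count)
  for (mk in unique(motif_key)) {
    slots <- which(motif_key == mk)
    mot <- if (nzchar(mk)) mk else NULL
    filled <- 0
    round <- 0
    while (filled < length(slots)) {
      round <- round + 1
      if (round > max_rounds) {
        pc_error(sprintf("could not realize %d distinct %s molecule(s)",
                         length(slots) - filled, label),
                 "patentchem_generation_error", label = label)
      }
      m <- max(8L, ceiling((length(slots) - filled) * (1.2 + 0.4 * (round - 1))))
      cand <- unique(vapply(seq_len(m), function(i) gen_candidate(label, mot), character(1)))
      # templates are grammatically valid by construction; fall back to
      # explicit filtering only if the backend disagrees
      desc <- tryCatch(compute_descriptors(cand), error = function(e) NULL)
      if (is.null(desc)) {
        cand <- cand[chem_valid(cand)]
        if (length(cand) == 0) next
        desc <- compute_descriptors(cand)
      }
      cand <- cand[as.character(classify_druglikeness(desc)) == label]
      if (length(cand) == 0) next
      keys <- chem_inchikey(cand)
      for (j in seq_along(cand)) {
        if (filled >= length(slots)) break
        k <- keys[j]
        if (is.na(k) || exists(k, envir = used, inherits = FALSE)) next
        assign(k, TRUE, envir = used)
        filled <- filled + 1
        out_smiles[slots[filled]] <- cand[j]
        out_keys[slots[filled]] <- k
      }
    }
  }
  tibble::tibble(smiles = out_smiles, inchikey = out_keys)
}

# --- corpus assembly ------------------------------------------------------

#' Generate a synthetic corpus with ground truth
#'
#' Writes a map-dump TSV in the ingest dialect (`map_dump.tsv`), one
#' resource TSV per configured resource (`resource_<name>.tsv`) and a
#' ground-truth JSON (`ground_truth.json`) holding every planted label.
#' With a fixed seed the outputs are byte-identical across runs.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the output `paths`, the per-compound
#'   `truth` tibble and the occurrence-level row count.
#' @export
generate_corpus <- function(config, out_dir) {
  stopifnot(inherits(config, "patentchem_synthetic_config"))
  validate_synthetic_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_compounds

  paths <- list(
    map_dump = file.path(out_dir, "map_dump.tsv"),
    resources = stats::setNames(
      file.path(out_dir, paste0("resource_", names(config$resource_overlaps), ".tsv")),
      names(config$resource_overlaps)),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )

  if (n == 0) {
    writeLines(character(), paths$map_dump)
    for (p in paths$resources) writeLines("inchikey\tannotation", p)
    jsonlite::write_json(list(config = unclass(config), compounds = list()),
                         paths$ground_truth, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(list(paths = paths, truth = empty_truth(), n_rows = 0L)))
  }

  # 1. class labels and PAINS motif slots (deterministic quotas, shuffled)
  quota <- quota_round(n, config$class_fractions[c("ro5", "bro5", "neither")])
  labels <- sample(rep(c("RO5", "BRO5", "NEITHER"), quota))
  n_inject <- round(config$pains_rate * n)
  inject_idx <- if (n_inject > 0) sample(n, n_inject) else integer()
  motif <- rep(NA_character_, n)
  if (n_inject > 0) {
    motif[inject_idx] <- rep(names(PAINS_MOTIFS), length.out = n_inject)
  }

  # 2. molecules per class (distinct InChIKeys across the whole corpus)
  used <- new.env(parent = emptyenv())
  smiles <- character(n)
  inchikey <- character(n)
  for (lab in c("RO5", "BRO5", "NEITHER")) {
    idx <- which(labels == lab)
    if (length(idx) == 0) next
    batch <- make_molecules_batch(
      lab, length(idx),
      motifs = lapply(motif[idx], function(m) if (is.na(m)) NULL else m),
      used = used)
    smiles[idx] <- batch$smiles
    inchikey[idx] <- batch$inchikey
  }

  # 3. promiscuity: truncated discrete power law
  kmax <- config$promiscuity$max_count
  pk <- (seq_len(kmax))^(-config$promiscuity$alpha)
  n_patents <- sample.int(kmax, n, replace = TRUE, prob = pk)

  # 4. patents: fresh SCPNs per compound
  total_pat <- sum(n_patents)
  serial <- sprintf("%08d", seq_len(total_pat) + 10000000)
  country <- sample(c("US", "EP", "JP"), total_pat, replace = TRUE,
                    prob = c(0.60, 0.35, 0.05))
  kind <- sample(c("A1", "A2", "B1", "B2", "S1", "E1", "P1"), total_pat,
                 replace = TRUE, prob = c(0.40, 0.14, 0.25, 0.12, 0.03, 0.03, 0.03))
  scpn <- format_scpn(country, serial, kind)
  pat_year <- sample(config$years, total_pat, replace = TRUE)
  pat_date <- sprintf("%d-%02d-%02d", pat_year,
                      sample(1:12, total_pat, replace = TRUE),
                      sample(1:28, total_pat, replace = TRUE))
  comp_of_pat <- rep(seq_len(n), n_patents)

  # 5. sections per occurrence (>= 1 source each)
  marg <- config$section_marginals[section_sources()]
  sec_mat <- matrix(stats::runif(total_pat * 6) < rep(marg, each = total_pat),
                    nrow = total_pat)
  none <- rowSums(sec_mat) == 0
  if (any(none)) {
    forced <- sample(seq_len(6), sum(none), replace = TRUE, prob = marg)
    sec_mat[cbind(which(none), forced)] <- TRUE
  }
  colnames(sec_mat) <- section_sources()

  # 6. map-dump rows: one row per (compound, patent, section)
  field_of <- stats::setNames(names(default_section_codes()), default_section_codes())
  rows_per_pat <- rowSums(sec_mat)
  row_pat <- rep(seq_len(total_pat), rows_per_pat)
  row_section <- unlist(apply(sec_mat, 1, function(r) section_sources()[r], simplify = FALSE))
  dump <- tibble::tibble(
    schembl_id = sprintf("SCHEMBL%06d", comp_of_pat[row_pat]),
    smiles = smiles[comp_of_pat[row_pat]],
    inchikey = inchikey[comp_of_pat[row_pat]],
    corpus_frequency = n_patents[comp_of_pat[row_pat]],
    patent_id = scpn[row_pat],
    date = pat_date[row_pat],
    field_code = unname(field_of[row_section])
  )
  readr::write_tsv(dump, paths$map_dump, col_names = FALSE, progress = FALSE)

  # 7. resource planting (exact quotas, optionally with a reserved
  #    exclusive block) and per-member clinical labels
  res_names <- names(config$resource_overlaps)
  m_r <- round(config$resource_overlaps * n)
  if (!is.null(config$exclusive_fraction)) {
    n_excl <- round(config$exclusive_fraction * n)
    reserved <- sample(n, n_excl)
    pool <- setdiff(seq_len(n), reserved)
    members <- lapply(res_names, function(r) {
      if (m_r[[r]] == max(m_r)) pool else sample(pool, m_r[[r]])
    })
  } else {
    members <- lapply(res_names, function(r) sample(n, m_r[[r]]))
  }
  names(members) <- res_names

  phase <- rep(NA_character_, n)
  if ("chembl_like" %in% res_names && length(members$chembl_like) > 0) {
    ph_quota <- quota_round(length(members$chembl_like), config$phase_distribution)
    phase[members$chembl_like] <- rep(names(config$phase_distribution), ph_quota)
  }
  status <- rep(NA_character_, n)
  if ("drugbank_like" %in% res_names && length(members$drugbank_like) > 0) {
    st_quota <- quota_round(length(members$drugbank_like), config$status_distribution)
    status[members$drugbank_like] <- rep(names(config$status_distribution), st_quota)
  }

  n_decoy <- round(config$decoy_fraction * n)
  for (r in res_names) {
    keys <- inchikey[sort(members[[r]])]
    ann <- rep("", length(keys))
    if (r == "chembl_like") {
      ann <- sprintf("{\"max_phase\":\"%s\"}", phase[sort(members[[r]])])
    }
    if (r == "drugbank_like") {
      ann <- sprintf("{\"status\":\"%s\"}", status[sort(members[[r]])])
    }
    if (n_decoy > 0) {
      decoys <- random_inchikeys(n_decoy, avoid = inchikey)
      keys <- c(keys, decoys)
      ann <- c(ann, rep("", n_decoy))
    }
    readr::write_tsv(tibble::tibble(inchikey = keys, annotation = ann),
                     paths$resources[[r]], progress = FALSE,
                     quote = "none", escape = "none")
  }

  # 8. ground truth
  first_year <- vapply(split(pat_year, comp_of_pat), min, numeric(1))
  sections_union <- lapply(split(row_section, comp_of_pat[row_pat]), function(s) sort(unique(s)))
  truth <- tibble::tibble(
    schembl_id = sprintf("SCHEMBL%06d", seq_len(n)),
    inchikey = inchikey,
    smiles = smiles,
    label = labels,
    motif = motif,
    expected_alert = ifelse(is.na(motif), NA_character_, unname(PAINS_MOTIF_ALERTS[motif])),
    n_patents = n_patents,
    first_year = as.integer(first_year[as.character(seq_len(n))]),
    sections = unname(sections_union[as.character(seq_len(n))]),
    phase = phase,
    status = status
  )
  for (r in res_names) truth[[paste0("in_", r)]] <- seq_len(n) %in% members[[r]]

  jsonlite::write_json(
    list(config = unclass(config), compounds = truth),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(list(paths = paths, truth = truth, n_rows = nrow(dump)))
}

empty_truth <- function() {
  tibble::tibble(schembl_id = character(), inchikey = character(),
                 smiles = character(), label = character(), motif = character(),
                 expected_alert = character(), n_patents = integer(),
                 first_year = integer(), sections = list(),
                 phase = character(), status = character())
}

# Syntactically valid, fabricated InChIKeys distinct from `avoid`.
random_inchikeys <- function(k, avoid = character()) {
  out <- character(0)
  avoid_env <- new.env(parent = emptyenv())
  for (a in avoid) assign(a, TRUE, envir = avoid_env)
  while (length(out) < k) {
    key <- paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
                  paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-N")
    if (!exists(key, envir = avoid_env, inherits = FALSE)) {
      assign(key, TRUE, envir = avoid_env)
      out <- c(out, key)
    }
  }
  out
}
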