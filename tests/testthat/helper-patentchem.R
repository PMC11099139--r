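# Shared fixtures and independent oracles for the test suite.

# Canonical SMILES through the package's own backend (desalt is the
# canonicalizing identity on single fragments).
canon <- function(smiles) desalt(smiles)

exemplar_panel <- function() {
  path <- system.file("extdata", "druglike_exemplars.tsv", package = "patentchem")
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE, show_col_types = FALSE)
}

# The PAINS catalog load compiles 480 patterns; cache it per test run.
pains_cache <- new.env(parent = emptyenv())
pains_catalog <- function() {
  if (!exists("catalog", envir = pains_cache)) {
    assign("catalog", suppressMessages(load_alert_catalog("pains")), envir = pains_cache)
  }
  get("catalog", envir = pains_cache)
}

# Write a map dump in the default seven-column dialect.
write_dump <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  path
}

dump_row <- function(schembl = "SCHEMBL1", smiles = "c1ccccc1",
                     inchikey = "UHOVQNZJYSORNB-UHFFFAOYSA-N",
                     patent = "US-1234567-A1", date = "2016-03-02",
                     field = 5) {
  tibble::tibble(schembl_id = schembl, smiles = smiles, inchikey = inchikey,
                 corpus_frequency = 1L, patent_id = patent, date = date,
                 field_code = field)
}

# Random grammar-valid SCPN components.
random_scpns <- function(n) {
  country <- replicate(n, paste(sample(LETTERS, 2, TRUE), collapse = ""))
  serial <- vapply(sample(7:11, n, TRUE), function(k) {
    paste(sample(0:9, k, TRUE), collapse = "")
  }, character(1))
  kind <- paste0(sample(LETTERS, n, TRUE),
                 ifelse(stats::runif(n) < 0.5, "", sample(0:9, n, TRUE)))
  tibble::tibble(country = country, serial = serial, kind = kind,
                 scpn = format_scpn(country, serial, kind))
}

# Random descriptor vectors spanning both rule windows, including boundary
# values.
random_descriptor_vectors <- function(n) {
  tibble::tibble(
    mw = sample(c(stats::runif(n, 50, 3500), 500, 501, 2999, 3000), n),
    clogp = sample(c(stats::runif(n, -5, 12), 0, 5, 7.5), n),
    hba = sample(0:25, n, TRUE),
    hbd = sample(0:12, n, TRUE),
    tpsa = sample(c(stats::runif(n, 0, 400), 140, 200), n),
    nrotb = sample(0:30, n, TRUE)
  )
}

# Independent scaffold oracle: iterative pruning on the molecular graph.
# Deletes (a) terminal atoms attached through a single bond and (b)
# terminal multiple-bond pairs hanging off a two-neighbour atom, until a
# fixed point; molecules without rings have no scaffold.
oracle_scaffold_atoms <- function(graph) {
  n <- graph$n
  bonds <- graph$bonds
  if (nrow(bonds) - n + 1L <= 0) return(integer())
  alive <- rep(TRUE, n)
  repeat {
    live <- alive[bonds[, 1]] & alive[bonds[, 2]]
    deg <- tabulate(c(bonds[live, 1], bonds[live, 2]), nbins = n)
    changed <- FALSE
    # (a) single-bond leaves
    for (k in which(live)) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      if (o == 1) {
        if (deg[a] == 1 && alive[a]) { alive[a] <- FALSE; changed <- TRUE }
        if (deg[b] == 1 && alive[b]) { alive[b] <- FALSE; changed <- TRUE }
      }
    }
    if (changed) next
    # (b) terminal multiple-bond pair A=B with deg(B)=1, deg(A)=2
    for (k in which(live)) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      if (o >= 2) {
        if (deg[b] == 1 && deg[a] == 2 && alive[a] && alive[b]) {
          alive[a] <- FALSE; alive[b] <- FALSE; changed <- TRUE
        } else if (deg[a] == 1 && deg[b] == 2 && alive[a] && alive[b]) {
          alive[a] <- FALSE; alive[b] <- FALSE; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- which(alive)
  live <- bonds[alive[bonds[, 1]] & alive[bonds[, 2]], , drop = FALSE]
  if (nrow(live) - length(keep) + 1L <= 0) return(integer())
  keep
}

# A varied panel of small random molecules built from the generator's
# template pools (seeded by the caller).
random_molecule_panel <- function(n) {
  labs <- sample(c("RO5", "BRO5", "NEITHER"), n, TRUE, prob = c(0.6, 0.2, 0.2))
  smi <- vapply(labs, function(l) {
    repeat {
      s <- patentchem:::gen_candidate(l)
      if (patentchem:::chem_valid(s)) return(s)
    }
  }, character(1))
  unique(smi)
}
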