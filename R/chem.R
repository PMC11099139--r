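# Thin wrappers around the OpenBabel backend (ChemmineR / ChemmineOB).
# All structure handling in the package funnels through these so that the
# SMILES dialect, canonicalization and molecule construction are uniform.

# Convert SMILES to an SDFset. `smiles` must all be parseable; callers that
# may hold invalid input should filter with chem_valid() first.
chem_sdfset <- function(smiles, explicit_h = FALSE) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  ids <- sprintf("m%06d", seq_along(smiles))
  input <- paste0(paste(smiles, ids, collapse = "\n"), "\n")
  sdfstr <- if (explicit_h) {
    ChemmineOB::convertFormat("SMI", "SDF", input,
                              options = data.frame(names = "h", args = ""))
  } else {
    ChemmineOB::convertFormat("SMI", "SDF", input)
  }
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    bad <- smiles[!chem_valid(smiles)]
    pc_parse_error(sprintf("unparsable SMILES %s",
                           encodeString(if (length(bad)) bad[1] else smiles[1],
                                        quote = "\"")),
                   smiles = if (length(bad)) bad[1] else NA_character_)
  }
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))
  if (length(sdfset) != length(smiles)) {
    bad <- smiles[!chem_valid(smiles)]
    pc_parse_error(sprintf("unparsable SMILES %s",
                           encodeString(if (length(bad)) bad[1] else smiles[1],
                                        quote = "\"")),
                   smiles = if (length(bad)) bad[1] else NA_character_)
  }
  ChemmineR::cid(sdfset) <- ids
  sdfset
}

# Canonical SMILES. Unparsable entries come back NA.
chem_canonical <- function(smiles) {
  if (length(smiles) == 0) return(character())
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  ids <- sprintf("m%06d", which(ok))
  input <- paste0(paste(smiles[ok], ids, collapse = "\n"), "\n")
  res <- ChemmineOB::convertFormat("SMI", "CAN", input)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, character(1), 1)
  nm <- trimws(vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1)))
  hit <- match(ids, nm)
  out[which(ok)] <- smi[hit]
  out
}

# TRUE where the backend can parse the SMILES.
chem_valid <- function(smiles) {
  !is.na(chem_canonical(smiles))
}

# InChIKeys for parseable SMILES; NA elsewhere. The backend prints benign
# "Omitted undefined stereo" notes to stderr for stereo-free structures.
chem_inchikey <- function(smiles) {
  if (length(smiles) == 0) return(character())
  out <- rep(NA_character_, length(smiles))
  ok <- chem_valid(smiles)
  if (!any(ok)) return(out)
  input <- paste0(paste(smiles[ok], collapse = "\n"), "\n")
  res <- ChemmineOB::convertFormat("SMI", "INCHIKEY", input)
  keys <- trimws(strsplit(res, "\n", fixed = TRUE)[[1]])
  keys <- keys[nzchar(keys)]
  if (length(keys) != sum(ok)) {
    pc_error("InChIKey generation dropped molecules unexpectedly", "patentchem_backend_error")
  }
  out[which(ok)] <- keys
  out
}

# Count of unique substructure matches per molecule for one SMARTS pattern.
chem_smarts_count <- function(obmols, smarts) {
  res <- ChemmineOB::smartsSearch_OB(obmols, smarts, uniqueMatches = TRUE)
  as.integer(res)
}

chem_obmols <- function(sdfset) ChemmineR::obmol(sdfset)

# Molecular graph of one molecule in an SDFset: elements, bonds (Kekule
# orders as stored in the molblock) and a degree vector.
chem_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(elem)
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    matrix(integer(), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  list(elem = elem, bonds = bonds, deg = deg, n = n)
}

# Serialize an induced subgraph of a chem_graph back to a V2000 molblock.
# Coordinates are irrelevant downstream (only topology is consumed), so
# atoms are laid out on a line.
chem_subgraph_molblock <- function(graph, keep) {
  keep <- sort(keep)
  idx <- match(seq_len(graph$n), keep)
  bonds <- graph$bonds
  kb <- bonds[!is.na(idx[bonds[, 1]]) & !is.na(idx[bonds[, 2]]), , drop = FALSE]
  na <- length(keep)
  nb <- nrow(kb)
  hdr <- c("", "  patentchem", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   seq_len(na) * 1.0, 0, 0, graph$elem[keep])
  bl <- if (nb > 0) {
    sprintf("%3d%3d%3d  0", idx[kb[, 1]], idx[kb[, 2]], kb[, 3])
  } else {
    character()
  }
  paste(c(hdr, atoms, bl, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES of an induced subgraph (used for scaffold output).
chem_subgraph_smiles <- function(graph, keep) {
  block <- paste0(chem_subgraph_molblock(graph, keep), "\n")
  res <- ChemmineOB::convertFormat("SDF", "CAN", block)
  smi <- strsplit(trimws(res), "[\t\n]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) {
    pc_error("subgraph canonicalization failed", "patentchem_backend_error")
  }
  smi
}
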