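#' Desalt a SMILES string
#'
#' Splits multi-fragment SMILES at the dot separator and keeps the fragment
#' with the most heavy atoms among the carbon-containing fragments; ties go
#' to the heavier fragment by molecular weight, then to the lexicographically
#' smallest canonical SMILES. Single-fragment input is returned
#' canonicalized. No neutralization or tautomer canonicalization is applied.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES of the retained fragment.
#' @export
#' @examples
#' desalt("CC(=O)[O-].[Na+]")
desalt <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  out <- desalt_quiet(smiles)
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    i <- bad[1]
    reason <- attr(out, "reason")[i]
    if (identical(reason, "no_organic")) {
      pc_error(sprintf("no organic fragment in %s", encodeString(smiles[i], quote = "\"")),
               "patentchem_desalt_error", smiles = smiles[i])
    }
    pc_parse_error(sprintf("unparsable SMILES %s", encodeString(smiles[i], quote = "\"")),
                   smiles = smiles[i])
  }
  as.character(out)
}

# Vectorized desalting that flags failures instead of throwing: returns a
# character vector with NA for failures and a "reason" attribute
# ("invalid" or "no_organic").
desalt_quiet <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  reason <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  reason[!ok] <- "invalid"

  frags <- strsplit(smiles[ok], ".", fixed = TRUE)
  uniq <- unique(unlist(frags))
  if (length(uniq) > 0) {
    info <- fragment_info(uniq)
    pick <- vapply(frags, function(fr) {
      ii <- match(fr, uniq)
      if (anyNA(info$canonical[ii])) return(NA_character_) # unparsable fragment
      org <- ii[info$has_carbon[ii]]
      if (length(org) == 0) return("") # sentinel: no organic fragment
      o <- org[order(-info$heavy[org], -info$mw[org], info$canonical[org])]
      info$canonical[o[1]]
    }, character(1))
    res <- pick
    res[!is.na(pick) & pick == ""] <- NA_character_
    out[ok] <- res
    r <- rep(NA_character_, length(pick))
    r[is.na(pick)] <- "invalid"
    r[!is.na(pick) & pick == ""] <- "no_organic"
    reason[ok] <- r
  }
  attr(out, "reason") <- reason
  out
}

# Heavy-atom count, carbon flag, MW and canonical SMILES per unique
# fragment. Goes through the molecule iterator rather than an SDFset so
# that single-atom fragments (bare counter-ions) survive.
fragment_info <- function(frag_smiles) {
  canonical <- chem_canonical(frag_smiles)
  heavy <- rep(NA_integer_, length(frag_smiles))
  has_carbon <- rep(FALSE, length(frag_smiles))
  mw <- rep(NA_real_, length(frag_smiles))
  ok <- which(!is.na(canonical))
  if (length(ok) > 0) {
    ids <- sprintf("f%06d", ok)
    input <- paste0(paste(frag_smiles[ok], ids, collapse = "\n"), "\n")
    acc <- new.env(parent = emptyenv())
    ChemmineOB::forEachMol("SMILES", input, function(m) {
      p <- ChemmineOB::prop_OB(m)
      p <- p[nrow(p), , drop = FALSE]
      assign(p$title, p, envir = acc)
    })
    for (j in seq_along(ok)) {
      p <- if (exists(ids[j], envir = acc, inherits = FALSE)) get(ids[j], envir = acc) else NULL
      if (is.null(p)) { canonical[ok[j]] <- NA_character_; next }
      comp <- formula_composition(p$formula)
      heavy[ok[j]] <- sum(comp[setdiff(names(comp), "H")])
      has_carbon[ok[j]] <- "C" %in% names(comp)
      mw[ok[j]] <- p$MW
    }
  }
  list(canonical = canonical, heavy = heavy, has_carbon = has_carbon, mw = mw)
}

# Element counts from a molecular formula string such as "C2H3O2-".
formula_composition <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  elem <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  tapply(cnt, elem, sum)
}
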