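# Physicochemical descriptor computation.
#
# Conventions (documented in the methods vignette):
#   mw      molecular weight, Daltons (average atomic masses, implicit H in)
#   clogp   Wildman-Crippen-style atomic-contribution LogP (OpenBabel)
#   hba     Lipinski acceptor count: number of N + O atoms
#   hbd     Lipinski donor count: number of N/O atoms bearing >= 1 hydrogen
#   tpsa    Ertl fragment-based topological polar surface area, A^2
#   nrotb   rotatable bonds: acyclic single bonds between non-terminal,
#           non-triple-bonded heavy atoms
#   n_rings smallest-set-of-smallest-rings count (cyclomatic number)
#   n_stereo potential tetrahedral stereocenters, assigned or not

ROTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Compute the descriptor vector for desalted structures
#'
#' All eight descriptors are computed deterministically from the molecular
#' graph; identical input SMILES give identical rows. Inputs are expected to
#' be desalted, single-fragment SMILES (see [desalt()]).
#'
#' @param smiles Character vector of desalted SMILES.
#' @return Tibble with columns `smiles`, `mw`, `clogp`, `hba`, `hbd`,
#'   `tpsa`, `nrotb`, `n_rings`, `n_stereo`.
#' @export
#' @examples
#' compute_descriptors(c("c1ccccc1", "CO"))
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  sdf <- chem_sdfset(smiles)
  props <- ChemmineR::propOB(sdf)
  mols <- chem_obmols(sdf)
  hba <- chem_smarts_count(mols, "[#7,#8]")
  hbd <- chem_smarts_count(mols, "[#7;!H0]") + chem_smarts_count(mols, "[#8;!H0]")
  nrotb <- chem_smarts_count(mols, ROTB_SMARTS)
  graphs <- lapply(seq_along(sdf), function(i) chem_graph(sdf[[i]]))
  n_rings <- vapply(graphs, function(g) nrow(g$bonds) - g$n + 1L, integer(1))
  n_stereo <- vapply(graphs, count_stereocenters, integer(1))
  tibble::tibble(
    smiles = smiles,
    mw = props$MW,
    clogp = props$logP,
    hba = hba,
    hbd = hbd,
    tpsa = props$TPSA,
    nrotb = nrotb,
    n_rings = n_rings,
    n_stereo = n_stereo
  )
}

# --- tetrahedral stereocenter detection -----------------------------------
#
# Symmetry classes are obtained by iterative neighbourhood refinement of
# atom invariants (element, implicit H count, degree, incident bond
# orders). A carbon with four substituents (heavy neighbours plus implicit
# hydrogens) is counted as a stereocenter when all four substituent classes
# differ; implicit hydrogens share one class, so >= 2 hydrogens never
# qualify. This detects constitutionally distinguishable centres whether or
# not stereo is assigned in the input.

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, Si = 4)

count_stereocenters <- function(graph) {
  n <- graph$n
  if (n == 0 || nrow(graph$bonds) == 0) return(0L)
  bonds <- graph$bonds
  # directed edge list (both directions)
  ea <- c(bonds[, 1], bonds[, 2])
  eb <- c(bonds[, 2], bonds[, 1])
  eo <- c(bonds[, 3], bonds[, 3])
  ord <- order(ea, eb) # fixed evaluation order keeps sums deterministic
  ea <- ea[ord]; eb <- eb[ord]; eo <- eo[ord]

  valence <- STANDARD_VALENCE[graph$elem]
  bondsum <- numeric(n)
  bs <- rowsum(eo, ea)
  bondsum[as.integer(rownames(bs))] <- bs[, 1]
  hcount <- pmax(0, ifelse(is.na(valence), 0, valence) - bondsum)

  sig0 <- paste(graph$elem, hcount, graph$deg, bondsum)
  cls <- match(sig0, unique(sig0))
  # Weisfeiler-Lehman style refinement with an order-independent numeric
  # multiset hash; sums stay exact in doubles (well below 2^53)
  repeat {
    x <- cls[eb] * 137 + eo * 31
    contrib <- rowsum(x * x + 3 * x, ea)
    s <- numeric(n)
    s[as.integer(rownames(contrib))] <- contrib[, 1]
    sig <- paste(cls, s)
    new_cls <- match(sig, unique(sig))
    if (length(unique(new_cls)) == length(unique(cls))) break
    cls <- new_cls
  }

  # candidate tetrahedral carbons: all single bonds, four substituents
  # (heavy neighbours plus implicit hydrogens), at most one hydrogen
  maxord <- numeric(n)
  mo <- rowsum(eo, ea)
  maxo <- tapply(eo, ea, max)
  maxord[as.integer(names(maxo))] <- maxo
  cand <- which(graph$elem == "C" & maxord <= 1 &
                  graph$deg + hcount == 4 & hcount <= 1)
  if (length(cand) == 0) return(0L)
  nbcls <- split(cls[eb], ea)
  hit <- 0L
  for (i in cand) {
    subst <- c(nbcls[[as.character(i)]], rep(-1L, hcount[i]))
    if (!anyDuplicated(subst)) hit <- hit + 1L
  }
  hit
}
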