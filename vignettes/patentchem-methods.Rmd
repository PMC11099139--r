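---
title: "Profiling patent compound collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling patent compound collections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package does

Patent documents are a major, under-exploited source of medicinal-chemistry
information. Text- and image-mining pipelines such as SureChEMBL extract
compounds from patent corpora and publish compound-to-patent map files:
tab-separated tables in which each row links a compound (SMILES, InChIKey)
to a patent document (an SCPN identifier of the form `US-1234567-A1`), an
application date, and the section of the document the compound was mined
from (title, abstract, description, claims, chemical images, or attached
molfiles).

`patentchem` turns such map files into a reproducible profiling report:

1. **Ingest** — parse and validate SCPNs and InChIKeys, decode section
   codes, merge per-section rows into (compound, patent) occurrences, and
   deduplicate compounds by full InChIKey.
2. **Drug-likeness** — desalt each structure, compute eight descriptors,
   and classify it against the Lipinski/Veber rule of five and the
   beyond-rule-of-five (bRo5) window.
3. **Scaffolds** — reduce structures to Bemis–Murcko scaffolds and track
   scaffold frequency, first-appearance year, molecular-weight spread and
   section attribution.
4. **Alerts** — screen against the published 480-pattern PAINS catalog.
5. **Cross-reference** — map compounds into external resources by exact
   InChIKey match and summarize overlap regions, resource-exclusive
   compounds and clinical-phase annotations.
6. **Synthesis** — generate corpora with planted ground truth so that the
   entire pipeline can be validated end to end.

## The classification model

A compound's descriptor vector holds molecular weight (Da), calculated
LogP, hydrogen-bond acceptor and donor counts, topological polar surface
area (Å²), rotatable-bond count, ring count and stereocenter count.

**Ro5 (extended with the Veber criteria).** A compound complies when all of

* MW ≤ 500, cLogP ≤ 5, HBD ≤ 5, HBA ≤ 10 (Lipinski, inclusive bounds), and
* TPSA < 140 and NRotB < 12 (Veber, strict bounds as conventionally printed).

Compliance is a strict conjunction: no violations are tolerated. The
tolerant one-violation reading of Lipinski's rule is sometimes used in the
field; the stricter form is the default here and the thresholds are
carried in a `default_ruleset()` object, so a tolerant variant can be
expressed by overriding the rule set (overrides are reported).

**bRo5.** The beyond-rule-of-five window contains compounds with
500 < MW < 3000 Da showing at least one property beyond the extended
bounds: cLogP > 7.5 or cLogP < 0, HBD > 5, HBA > 10, TPSA > 200, or
NRotB > 20. All bounds strict. Because the two MW windows cannot overlap,
the labels `RO5`, `BRO5`, `NEITHER` partition any input; this mutual
exclusivity is property-tested over random descriptor vectors.

### Descriptor conventions

* **HBA** is the classic Lipinski acceptor count: the number of N and O
  atoms.
* **HBD** is the donor *atom* count: N/O atoms bearing at least one
  hydrogen. The alternative — counting donor hydrogens — makes arginine a
  Ro5 violator (seven N–H/O–H hydrogens on five donor atoms), which
  contradicts the placement of arginine and other amino acids and sugars
  inside the Ro5 class by the tooling this analysis follows. Donor-atom
  counting is therefore the package convention.
* **cLogP** and **TPSA** come from the OpenBabel backend: an
  atomic-contribution LogP model of the Wildman–Crippen family and the
  Ertl fragment-additive TPSA. Absolute LogP values differ slightly
  between implementations; all rule thresholds are far from the
  discriminating regions for the fixture panel, and the estimator is
  deterministic.
* **Rotatable bonds** are acyclic single bonds between two non-terminal
  atoms, neither of which sits in a triple bond (SMARTS
  `[!$(*#*)&!D1]-!@[!$(*#*)&!D1]`); amide C–N bonds are counted, matching
  the permissive convention.
* **Ring count** is the smallest-set-of-smallest-rings size, computed as
  the cyclomatic number (bonds − atoms + 1) of the desalted, connected
  molecular graph.
* **Stereocenters** are potential tetrahedral centres, assigned or not: a
  carbon with four single bonds and four constitutionally distinct
  substituents (implicit hydrogens sharing one class). Distinctness uses
  iterative neighbourhood refinement (Weisfeiler–Lehman style) of atom
  invariants with an order-independent numeric multiset hash. Refinement
  partitions can in rare symmetric cases merge non-equivalent branches, in
  which case the count is conservative. The corresponding column of the
  yearly property table is reported as a stereocentre count; whether the
  upstream tabulation of "stereoisomers" means centres or enumerated
  stereoisomers is ambiguous in the source material, and this package
  reports centres.

### Desalting

Multi-fragment SMILES are split at the dot and the fragment with the most
heavy atoms among carbon-containing fragments is kept; ties go to the
heavier fragment, then to the lexicographically smallest canonical SMILES.
No neutralization or tautomer canonicalization is attempted — the charge
state as deposited is profiled. An input with no carbon-containing
fragment is an error rather than silently passing an inorganic ion
downstream.

## Bemis–Murcko scaffolds

The scaffold of a molecule is its ring systems plus the linkers connecting
them, with side chains pruned; heteroatoms and bond orders are retained
(the heteroatom-collapsing "graph framework" loses exactly the chemistry
patent analyses care about). Implementation: iteratively delete terminal
atoms until only atoms on rings or on paths between rings remain, then
restore atoms attached to that core by double or triple bonds (so
benzophenone keeps its carbonyl oxygen, while acetophenone's whole acetyl
side chain is pruned). Acyclic molecules have no scaffold; they are
excluded from scaffold tables and reported as a separate count.

Scaffold identity is canonical-SMILES string equality, and novelty is
computed within the loaded corpus only: a scaffold is *new* in the
earliest year any parent compound carries it and *known* in every later
year it recurs. The test suite checks the reduction against an
independent iterative-pruning oracle on 100+ generated molecules, plus
idempotence and weight monotonicity.

Section attribution of scaffolds is multi-valued (a scaffold inherits the
union of its parents' sections), so the per-section percentages need not
sum to 100. Both normalizations — per distinct scaffold and per
scaffold–section pair — are reported.

## PAINS screening

The shipped catalog is the published 480-pattern pan-assay interference
SMARTS set (families A/B/C). The patterns were written against
explicit-hydrogen structures, so molecules are hydrogen-expanded before
matching; aromaticity is perceived by the backend. One compound may
trigger many alerts; per-alert statistics count distinct compounds, never
occurrences. Corpus-level alert counts depend on the catalog revision and
are therefore validated only against the package's own ground truth, not
against any external tally.

## Cross-referencing

Matching is exact string equality on the full 27-character InChIKey, so
stereoisomers and differently protonated forms do not cross-match — a
deliberately conservative choice for linking patent chemistry to curated
resources; connectivity-block matching can be obtained by pre-truncating
keys, but is not the default. Clinical-phase vocabularies differ between
resources; numeric max-phase codes are decoded through an explicit,
overridable table (`default_phase_map()`), with the preclinical/unknown
boundary exposed rather than hard-coded.

## The synthetic corpus generator

The generator emulates the *structure* of a patent-compound corpus with
known ground truth, not real patent chemistry:

* **Class fractions** default to 0.55/0.16/0.29 (Ro5/bRo5/neither),
  the headline drug-likeness split reported for patent corpora.
* **Molecules** are built from label-specific template pools — small
  decorated ring systems for Ro5; polyol, polyether and polyamide chains
  of 550–900 Da for bRo5 (violating via donors or acceptors, the dominant
  violations in that space); small-but-greasy alkanes and small
  polyacetals for the neither class — then rejection-sampled against the
  package's own classifier (cap 100 tries), so the planted label is
  guaranteed by construction. Template sizes were chosen once so that a
  2,000-compound corpus generates in minutes on one CPU; the bRo5 pool
  deliberately stays below 1,000 Da, which also mirrors where most real
  bRo5 chemistry lives.
* **Promiscuity** (patents per compound) follows a discrete truncated
  power law, default exponent 2.35 on 1..2000, which reproduces the
  heavy-tailed "95% of compounds in fewer than five documents" shape.
* **Sections** are drawn independently per source from configurable
  marginals (image-dominated by default), with at least one source forced
  per occurrence. A compound's section set is the union over all its
  occurrences, so promiscuous compounds accumulate sources and the
  compound-level multi-source share exceeds the per-occurrence marginals.
* **Resource overlaps, phases and statuses** are planted by deterministic
  quota (largest-remainder rounding over a seeded permutation), not by
  Bernoulli draws, so recovery checks can be exact. Decoy keys are added
  to resources so matching is non-trivial in both directions.
* **PAINS injections** graft one of three motifs (catechol, azo-aryl,
  quinone) onto a fraction of compounds through a single sp3 attachment;
  each motif is guaranteed to trigger a known alert family, and the clean
  template pools avoid aromatic hydroxyl/amine decoration precisely so
  that un-injected compounds screen clean. The flagged fraction of a
  generated corpus therefore equals the injection rate exactly.

What the generator does **not** emulate: real scaffold diversity (template
pools produce a small scaffold vocabulary), realistic descriptor
correlations, Markush enumeration, image/molfile payloads, or real
database version drift. Passing end-to-end recovery on synthetic corpora
therefore demonstrates the pipeline's bookkeeping and classification are
correct, not that any corpus-scale number from real dumps is reproduced.

## Numerical and degenerate-input choices

* Percentages are kept at full precision internally and rounded to two
  decimals only at serialization.
* Ties in top-k rankings break lexicographically (InChIKey for compounds,
  canonical SMILES for scaffolds) for determinism.
* Years with no compounds are omitted from per-year tables, with a
  message.
* An empty dump yields an empty, schema-valid report of zeros; an empty
  resource list makes the overlap table a single region.
* Map-dump rows failing validation (malformed InChIKey or SCPN, undecodable
  date or section code, pre-cutoff year) are dropped, never repaired, and
  counted by reason in the load report.
* Single-atom molecules (e.g. methane) cannot be carried through the
  descriptor and scaffold stages: the SDF container used by the backend
  requires at least one bond. Desalting handles single-atom counter-ion
  fragments; a single-atom parent structure is rejected as unparsable.
* The full pipeline contains no randomness: re-running on the same inputs
  reproduces the report bundle byte for byte. All generator randomness
  flows from the single config seed.

## Problem sizes

The reference validation corpus is 2,000 compounds (8 years, three
resources, 4% injections), which exercises every stage in a few minutes on
one CPU. Unit tests use corpora of 12–250 compounds. These sizes are the
package's choices for fast, deterministic validation; the ingest and
aggregation stages are vectorized and handle larger dumps, with the
cheminformatics backend the scaling bottleneck (canonicalization and InChI
generation grow superlinearly with atom count).

## Known limitations

* Descriptor values (LogP especially) are backend-specific; classifications
  near a threshold can differ from other toolkits' labels.
* The stereocentre count is a constitutional approximation (no CIP rules,
  no ring-stereo special cases).
* Scaffold charge states: scaffold serialization assumes neutral scaffold
  atoms; charged ring atoms (e.g. pyridinium) are rare and not specially
  handled.
* The exact column order and section-code vocabulary of real map dumps
  varies by dialect; both are configuration (`default_column_map()`,
  `default_section_codes()`) rather than assumptions, and whether the
  dump's date column is a filing or publication date is corpus-dependent —
  the package simply reports per the supplied column.
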