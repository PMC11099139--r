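test_that("side chains prune to the ring-and-linker scaffold", {
  expect_equal(bm_scaffold("Cc1ccccc1"), canon("c1ccccc1"))
  expect_equal(bm_scaffold("CCCC"), "")
  # two rings joined by a one-atom linker are retained whole
  expect_equal(bm_scaffold("C(c1ccccc1)c1ccccc1"), canon("C(c1ccccc1)c1ccccc1"))
  # a side-chain carbonyl goes, an exocyclic ring carbonyl stays
  expect_equal(bm_scaffold("CC(=O)c1ccccc1"), canon("c1ccccc1"))
  expect_equal(bm_scaffold("O=C1CCCCC1"), canon("O=C1CCCCC1"))
  # double bond into a linker keeps the attached atom
  expect_equal(bm_scaffold("O=C(c1ccccc1)c1ccccc1"), canon("O=C(c1ccccc1)c1ccccc1"))
})

test_that("bm_scaffold is idempotent and weight-monotone on random molecules", {
  set.seed(23)
  panel <- random_molecule_panel(40)
  panel <- desalt(panel)
  scaf <- bm_scaffold(panel)
  cyc <- scaf[scaf != ""]
  if (length(cyc) > 0) {
    expect_identical(bm_scaffold(cyc), cyc)
    parents <- compute_descriptors(panel[scaf != ""])
    children <- compute_descriptors(cyc)
    expect_true(all(children$mw <= parents$mw + 1e-9))
  }
  expect_true(all(scaf[grepl("^[^a-z]*$", panel) &
                         !grepl("1", panel, fixed = TRUE)] == ""))
})

test_that("bm_scaffold agrees with the iterative-pruning oracle", {
  set.seed(31)
  panel <- desalt(random_molecule_panel(60))
  extra <- c("CC(=O)c1ccccc1", "CC=C1CCCCC1", "c1ccc(CCCc2ccncc2)cc1",
             "O=C(NC1CCCCC1)c1ccccc1", "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
             exemplar_panel()$smiles[1:6])
  panel <- unique(c(panel, desalt(extra)))
  sdf <- patentchem:::chem_sdfset(panel)
  for (i in seq_along(panel)) {
    g <- patentchem:::chem_graph(sdf[[i]])
    expect_equal(patentchem:::scaffold_atoms(g), oracle_scaffold_atoms(g),
                 info = panel[i])
  }
})

test_that("scaffold table groups parents and counts acyclic ones separately", {
  rec <- tibble::tibble(
    smiles = c("Cc1ccccc1", "c1ccccc1", "CCCC", "CCCCCC", "C1CCOCC1", "CC1CCOCC1"),
    first_year = c(2016L, 2015L, 2015L, 2016L, 2017L, 2015L),
    years = list(2016L, 2015L, 2015L, 2016L, 2017L, 2015L),
    sections = list("IMAGE", "CLAIMS", "TITLE", "IMAGE", "IMAGE", c("CLAIMS", "IMAGE"))
  )
  tab <- scaffold_table(rec)
  expect_equal(attr(tab, "acyclic"), 2L)
  expect_equal(nrow(tab), 2)
  benz <- tab[tab$scaffold == canon("c1ccccc1"), ]
  expect_equal(benz$frequency, 2L)
  expect_equal(benz$first_year, 2015L)
  expect_setequal(benz$sections[[1]], c("IMAGE", "CLAIMS"))
  thp <- tab[tab$scaffold == canon("C1CCOCC1"), ]
  expect_equal(thp$frequency, 2L)
  expect_setequal(thp$years[[1]], c(2015L, 2017L))
})

test_that("an all-acyclic corpus yields no scaffolds", {
  rec <- tibble::tibble(smiles = c("CCCC", "CCCCC"), first_year = c(2015L, 2016L),
                        years = list(2015L, 2016L), sections = list("IMAGE", "IMAGE"))
  tab <- scaffold_table(rec)
  expect_equal(nrow(tab), 0)
  expect_equal(attr(tab, "acyclic"), 2L)
})

test_that("novelty marks a scaffold new once and known on recurrence", {
  tab <- tibble::tibble(scaffold = c("A", "B", "C"),
                        years = list(c(2015L, 2016L), 2016L, c(2016L, 2017L, 2018L)))
  nov <- novelty_by_year(tab)
  expect_equal(nov$year, 2015:2018)
  expect_equal(nov$new, c(1L, 2L, 0L, 0L))
  expect_equal(nov$known, c(0L, 1L, 1L, 1L))
  expect_equal(sum(nov$new), nrow(tab))
  expect_equal(nov$known[1], 0L)
  # scaffolds unique to one year are never "known"
  tab1 <- tibble::tibble(scaffold = c("A", "B"), years = list(2015L, 2017L))
  expect_equal(novelty_by_year(tab1)$known, c(0L, 0L))
})

test_that("section attribution multi-counts scaffolds across sections", {
  tab <- tibble::tibble(scaffold = c("A", "B"),
                        sections = list("IMAGE", c("CLAIMS", "IMAGE")))
  att <- scaffold_section_attribution(tab)
  expect_equal(att$count[att$section == "IMAGE"], 2L)
  expect_equal(att$count[att$section == "CLAIMS"], 1L)
  expect_equal(att$count[att$section == "TITLE"], 0L)
  expect_equal(att$pct_scaffolds[att$section == "IMAGE"], 100)
  expect_equal(sum(att$pct_pairs), 100)
})

test_that("top scaffolds rank by frequency with deterministic ties", {
  tab <- tibble::tibble(scaffold = c("d", "b", "c", "a"),
                        frequency = c(5L, 3L, 3L, 1L),
                        mw = c(100, 80, 90, 70),
                        first_year = rep(2015L, 4))
  top <- top_scaffolds(tab, 2)
  expect_equal(top$top$frequency, c(5L, 3L))
  expect_equal(top$top$scaffold, c("d", "b"))
  expect_equal(nrow(top_scaffolds(tab, 0)$top), 0)
  expect_equal(nrow(top_scaffolds(tab, 99)$top), 4)
  expect_equal(top$mw_summary$min, 70)
  expect_equal(top$mw_summary$max, 100)
})

test_that("ring-system exemplars reduce to their named scaffolds", {
  # parents decorated around benzene, cyclohexane, tetrahydropyran,
  # naphthalene and diphenylmethane
  parents <- c("CCc1ccccc1C", "CC1CCCCC1", "CCC1CCOCC1O",
               "Cc1ccc2ccccc2c1", "CC(c1ccccc1)c1ccccc1C")
  want <- canon(c("c1ccccc1", "C1CCCCC1", "C1CCOCC1",
                  "c1ccc2ccccc2c1", "C(c1ccccc1)c1ccccc1"))
  expect_equal(bm_scaffold(parents), want)
})
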