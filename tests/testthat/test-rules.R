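# A descriptor row with every property comfortably inside the Ro5 window.
benign <- function(...) {
  base <- tibble::tibble(mw = 300, clogp = 2, hba = 3, hbd = 1, tpsa = 60,
                         nrotb = 4, n_rings = 2, n_stereo = 0)
  mod <- list(...)
  for (nm in names(mod)) base[[nm]] <- mod[[nm]]
  base
}

test_that("Ro5 uses inclusive Lipinski and strict Veber thresholds", {
  expect_true(passes_ro5(benign()))
  expect_true(passes_ro5(benign(mw = 500, clogp = 5, hbd = 5, hba = 10)))
  expect_false(passes_ro5(benign(mw = 501)))
  expect_false(passes_ro5(benign(clogp = 5.01)))
  expect_false(passes_ro5(benign(hbd = 6)))
  expect_false(passes_ro5(benign(hba = 11)))
  expect_false(passes_ro5(benign(tpsa = 140)))
  expect_true(passes_ro5(benign(tpsa = 139.9)))
  expect_false(passes_ro5(benign(nrotb = 12)))
  expect_true(passes_ro5(benign(nrotb = 11)))
})

test_that("bRo5 needs the MW window plus at least one violation", {
  expect_true(passes_bro5(benign(mw = 600, hbd = 6)))
  expect_false(passes_bro5(benign(mw = 600))) # in window, no violation
  expect_false(passes_bro5(benign(mw = 500, hbd = 6))) # lower bound strict
  expect_false(passes_bro5(benign(mw = 3000, hbd = 6))) # upper bound strict
  expect_true(passes_bro5(benign(mw = 2999, hbd = 6)))
  expect_true(passes_bro5(benign(mw = 600, clogp = 7.6)))
  expect_false(passes_bro5(benign(mw = 600, clogp = 7.5)))
  expect_true(passes_bro5(benign(mw = 600, clogp = -0.1)))
  expect_false(passes_bro5(benign(mw = 600, clogp = 0)))
  expect_true(passes_bro5(benign(mw = 600, tpsa = 200.5)))
  expect_false(passes_bro5(benign(mw = 600, tpsa = 200)))
  expect_true(passes_bro5(benign(mw = 600, nrotb = 21)))
  expect_false(passes_bro5(benign(mw = 600, nrotb = 20)))
})

test_that("RO5 and BRO5 are mutually exclusive over random vectors", {
  set.seed(17)
  d <- random_descriptor_vectors(1000)
  expect_false(any(passes_ro5(d) & passes_bro5(d)))
  lab <- classify_druglikeness(d)
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), nrow(d))
})

test_that("classification follows the RO5 > BRO5 > NEITHER cascade", {
  expect_equal(as.character(classify_druglikeness(benign())), "RO5")
  expect_equal(as.character(classify_druglikeness(benign(mw = 600, hbd = 6))), "BRO5")
  # fails Ro5 on clogp but too light for the bRo5 window
  expect_equal(as.character(classify_druglikeness(benign(mw = 400, clogp = 8))), "NEITHER")
})

test_that("threshold overrides are applied and reported", {
  rules <- default_ruleset()
  rules$ro5[["mw"]] <- 400
  expect_message(ok <- passes_ro5(benign(mw = 450), rules), "overridden")
  expect_false(ok)
})

test_that("yearly means equal a brute-force per-year aggregation", {
  set.seed(9)
  rec <- tibble::tibble(
    first_year = sample(2015:2018, 40, TRUE),
    mw = runif(40, 100, 900), clogp = runif(40, -2, 8),
    hba = sample(0:15, 40, TRUE), hbd = sample(0:8, 40, TRUE),
    nrotb = sample(0:25, 40, TRUE), n_rings = sample(0:6, 40, TRUE),
    n_stereo = sample(0:10, 40, TRUE)
  )
  ym <- suppressMessages(yearly_property_means(rec))
  for (y in unique(rec$first_year)) {
    sub <- rec[rec$first_year == y, ]
    row <- ym[ym$year == y, ]
    for (p in c("mw", "clogp", "hba", "hbd", "nrotb", "n_rings", "n_stereo")) {
      expect_equal(row[[p]], mean(sub[[p]]), tolerance = 1e-9)
    }
  }
  # two compounds in one year average exactly
  two <- rec[1:2, ]; two$first_year <- 2020L; two$mw <- c(400, 500)
  expect_equal(suppressMessages(yearly_property_means(two))$mw, 450)
})

test_that("top prevalent compounds sort by patent count with InChIKey ties", {
  rec <- tibble::tibble(
    inchikey = c("CCCC", "AAAA", "BBBB", "DDDD"),
    n_patents = c(5L, 2L, 9L, 2L),
    label = factor(rep("RO5", 4), levels = c("RO5", "BRO5", "NEITHER"))
  )
  top2 <- top_prevalent(rec, "RO5", 2)
  expect_equal(top2$n_patents, c(9L, 5L))
  top4 <- top_prevalent(rec, "RO5", 4)
  expect_equal(top4$inchikey, c("BBBB", "CCCC", "AAAA", "DDDD"))
  expect_message(all_of_them <- top_prevalent(rec, "RO5", 10), "available")
  expect_equal(nrow(all_of_them), 4)
  expect_equal(nrow(suppressMessages(top_prevalent(rec, "BRO5", 3))), 0)
})
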