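benzene_key <- "UHOVQNZJYSORNB-UHFFFAOYSA-N"
toluene_key <- "YXFVVABEGXRONW-UHFFFAOYSA-N"
phenol_key <- "ISWSIDIOOBJBQZ-UHFFFAOYSA-N"

test_that("a clean dump loads one occurrence per row", {
  rows <- dplyr::bind_rows(
    dump_row(inchikey = benzene_key, patent = "US-1000001-A1"),
    dump_row(schembl = "SCHEMBL2", smiles = "Cc1ccccc1", inchikey = toluene_key,
             patent = "US-1000002-B1"),
    dump_row(schembl = "SCHEMBL3", smiles = "Oc1ccccc1", inchikey = phenol_key,
             patent = "EP-2000001-A1")
  )
  occ <- read_map_dump(write_dump(rows))
  expect_equal(nrow(occ), 3)
  rep <- load_report(occ)
  expect_equal(rep$rows_read, 3)
  expect_equal(sum(rep$dropped), 0)
  expect_equal(sort(occ$country), c("EP", "US", "US"))
})

test_that("rows with invalid InChIKey or SCPN are dropped and counted", {
  rows <- dplyr::bind_rows(
    dump_row(inchikey = benzene_key),
    dump_row(inchikey = "XYZ"),
    dump_row(inchikey = toluene_key, patent = "US-12345-A1")
  )
  occ <- read_map_dump(write_dump(rows))
  expect_equal(nrow(occ), 1)
  drops <- load_report(occ)$dropped
  expect_equal(unname(drops["bad_inchikey"]), 1L)
  expect_equal(unname(drops["bad_scpn"]), 1L)
})

test_that("multiple sections of one patent merge into one occurrence", {
  rows <- dplyr::bind_rows(
    dump_row(field = 2),
    dump_row(field = 5),
    dump_row(field = 5) # exact duplicate row collapses silently
  )
  occ <- read_map_dump(write_dump(rows))
  expect_equal(nrow(occ), 1)
  expect_setequal(occ$sections[[1]], c("CLAIMS", "IMAGE"))
})

test_that("the year cutoff excludes earlier applications", {
  rows <- dplyr::bind_rows(
    dump_row(date = "2014-12-31"),
    dump_row(date = "2015-01-01", patent = "US-1000009-A1")
  )
  occ <- read_map_dump(write_dump(rows))
  expect_equal(nrow(occ), 1)
  expect_equal(occ$year, 2015L)
  expect_equal(unname(load_report(occ)$dropped["before_min_year"]), 1L)
  occ_all <- read_map_dump(write_dump(rows), min_year = -Inf)
  expect_equal(nrow(occ_all), 2)
})

test_that("missing files are fatal and empty files warn", {
  expect_error(read_map_dump(tempfile()), class = "patentchem_io_error")
  empty <- tempfile(fileext = ".tsv"); file.create(empty)
  expect_warning(occ <- read_map_dump(empty), "empty")
  expect_equal(nrow(occ), 0)
})

test_that("dedupe unions patents and sections and takes the earliest year", {
  rows <- dplyr::bind_rows(
    dump_row(patent = "US-1000001-A1", date = "2016-05-01", field = 5),
    dump_row(patent = "EP-2000001-B1", date = "2015-04-01", field = 1),
    dump_row(schembl = "SCHEMBL2", smiles = "Cc1ccccc1", inchikey = toluene_key,
             patent = "US-1000001-A1", date = "2016-05-01", field = 2)
  )
  rec <- dedupe(read_map_dump(write_dump(rows)))
  expect_equal(nrow(rec), 2)
  benz <- rec[rec$inchikey == benzene_key, ]
  expect_equal(benz$n_patents, 2L)
  expect_setequal(benz$patents[[1]], c("US-1000001-A1", "EP-2000001-B1"))
  expect_equal(benz$first_year, 2015L)
  expect_setequal(benz$sections[[1]], c("IMAGE", "DESCRIPTION"))
})

test_that("dedupe is order-independent and grouping matches a brute-force scan", {
  set.seed(3)
  keys <- c(benzene_key, toluene_key, phenol_key)
  rows <- dplyr::bind_rows(lapply(1:12, function(i) {
    dump_row(inchikey = sample(keys, 1),
             patent = sprintf("US-%07d-A1", 1000000 + sample(5, 1)),
             date = sprintf("%d-01-15", sample(2015:2020, 1)),
             field = sample(1:6, 1))
  }))
  occ <- read_map_dump(write_dump(rows))
  rec <- dedupe(occ)
  shuffled <- dedupe(occ[sample(nrow(occ)), ])
  expect_identical(rec[, setdiff(names(rec), "smiles")],
                   shuffled[, setdiff(names(rec), "smiles")])
  # brute-force regroup from the raw occurrence table
  for (k in unique(occ$inchikey)) {
    sub <- occ[occ$inchikey == k, ]
    r <- rec[rec$inchikey == k, ]
    expect_setequal(r$patents[[1]], unique(sub$scpn))
    expect_equal(r$first_year, min(sub$year))
    expect_setequal(r$sections[[1]], unique(unlist(sub$sections)))
  }
})

test_that("promiscuity bins follow the 1 / 2-4 / 5-1000 / >1000 edges", {
  rec <- tibble::tibble(inchikey = sprintf("K%02d", 1:6),
                        n_patents = c(1L, 1L, 4L, 5L, 1000L, 1001L))
  h <- promiscuity_distribution(rec)$histogram
  expect_equal(h$count, c(2L, 1L, 2L, 1L))
  expect_equal(sum(h$count), nrow(rec))

  all_single <- tibble::tibble(inchikey = sprintf("K%02d", 1:5),
                               n_patents = rep(1L, 5))
  h1 <- promiscuity_distribution(all_single)$histogram
  expect_equal(h1$count, c(5L, 0L, 0L, 0L))
})

test_that("promiscuity histogram equals a brute-force recount on a corpus", {
  set.seed(5)
  counts <- sample.int(1500, 150, replace = TRUE, prob = (1:1500)^-2)
  rec <- tibble::tibble(inchikey = sprintf("K%04d", 1:150), n_patents = counts)
  h <- promiscuity_distribution(rec)$histogram
  expect_equal(h$count, c(sum(counts == 1), sum(counts >= 2 & counts <= 4),
                          sum(counts >= 5 & counts <= 1000), sum(counts > 1000)))
})
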