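keys <- function(n, prefix = "A") {
  vapply(seq_len(n), function(i) {
    body <- sprintf("%s%013d", prefix, i)
    body <- chartr("0123456789", "ABCDEFGHIJ", body)
    paste0(substr(body, 1, 14), "-", strrep("Q", 10), "-N")
  }, character(1))
}

test_that("membership is exact on the full InChIKey", {
  rec <- tibble::tibble(inchikey = keys(10))
  res <- resource_table("pubchem_like", keys(4))
  expect_equal(sum(match_by_inchikey(rec, res)), 4)
  # disjoint sets
  expect_equal(sum(match_by_inchikey(rec, resource_table("x", keys(3, "Z")))), 0)
  # records subset of resource
  expect_true(all(match_by_inchikey(rec[1:3, ], resource_table("y", keys(10)))))
})

test_that("changing the stereo block of a key breaks the match", {
  k <- keys(1)
  variants <- vapply(1:5, function(i) {
    s <- k
    pos <- 15 + i # inside the stereo block
    substr(s, pos, pos) <- if (substr(s, pos, pos) == "Q") "R" else "Q"
    s
  }, character(1))
  res <- resource_table("r", k)
  expect_true(match_by_inchikey(tibble::tibble(inchikey = k), res))
  expect_false(any(match_by_inchikey(tibble::tibble(inchikey = variants), res)))
  # protonation flag too
  flipped <- sub("-N$", "-M", k)
  expect_false(match_by_inchikey(tibble::tibble(inchikey = flipped), res))
})

test_that("malformed resource keys are dropped with a warning", {
  expect_warning(res <- resource_table("r", c(keys(2), "not-a-key")), "malformed")
  expect_equal(length(res$keys), 2)
})

test_that("overlap regions partition the compound set", {
  rec <- tibble::tibble(inchikey = keys(8))
  r1 <- resource_table("a", keys(4))          # 1-4
  r2 <- resource_table("b", keys(8)[3:6])     # 3-6
  r3 <- resource_table("c", keys(8)[6:8])     # 6-8
  reg <- overlap_summary(rec, list(r1, r2, r3))
  expect_equal(sum(reg$count), 8)
  # brute-force set algebra
  expect_equal(reg$count[reg$a & reg$b & !reg$c], 2L)  # 3,4
  expect_equal(reg$count[!reg$a & reg$b & reg$c], 1L)  # 6
  expect_equal(reg$count[!reg$a & !reg$b & !reg$c], 0L)
  expect_equal(reg$count[reg$a & !reg$b & !reg$c], 2L) # 1,2
  # no resources: one region holding everything
  expect_equal(overlap_summary(rec, list())$count, 8)
})

test_that("the exclusive set complements the union of matches", {
  rec <- tibble::tibble(inchikey = keys(10), first_year = rep(2015:2019, 2))
  r1 <- resource_table("a", keys(6))
  ex <- exclusive_set(rec, list(r1))
  expect_equal(nrow(ex$compounds), 4)
  expect_equal(ex$fraction, 0.4)
  expect_equal(nrow(ex$compounds) + sum(match_by_inchikey(rec, r1)), nrow(rec))
  expect_equal(sum(ex$by_year$count), 4)
  # everything planted: empty exclusive set
  ex_all <- exclusive_set(rec, list(resource_table("a", keys(10))))
  expect_equal(nrow(ex_all$compounds), 0)
})

test_that("clinical phases and statuses are recovered from annotations", {
  rec <- tibble::tibble(inchikey = keys(10))
  ch_ann <- tibble::tibble(inchikey = keys(4),
                           max_phase = c("PHASE2", "PHASE2", "PHASE2", "APPROVED"))
  ch <- resource_table("chembl_like", keys(5), ch_ann) # key 5 matched, no phase
  db <- resource_table("drugbank_like", keys(2),
                       tibble::tibble(inchikey = keys(2),
                                      status = c("APPROVED", "WITHDRAWN")))
  cl <- annotate_clinical(rec, ch, db)
  pc <- function(p) cl$phase_counts$count[cl$phase_counts$phase == p]
  expect_equal(pc("PHASE2"), 3L)
  expect_equal(pc("APPROVED"), 1L)
  expect_equal(pc("UNKNOWN"), 1L) # matched without a phase annotation
  expect_equal(cl$n_matched, 5)
  expect_equal(cl$n_unmatched, 5)
  sc <- function(s) cl$status_counts$count[cl$status_counts$status == s]
  expect_equal(sc("APPROVED"), 1L)
  expect_equal(sc("WITHDRAWN"), 1L)
  expect_equal(length(cl$conflicts), 0)
})

test_that("numeric max-phase codes decode through the phase map", {
  rec <- tibble::tibble(inchikey = keys(3))
  ch <- resource_table("chembl_like", keys(3),
                       tibble::tibble(inchikey = keys(3),
                                      max_phase = c("4", "0.5", "-1")))
  db <- resource_table("drugbank_like", character())
  cl <- annotate_clinical(rec, ch, db)
  pc <- function(p) cl$phase_counts$count[cl$phase_counts$phase == p]
  expect_equal(pc("APPROVED"), 1L)
  expect_equal(pc("PRECLINICAL"), 1L)
  expect_equal(pc("UNKNOWN"), 1L)
})

test_that("contradictory approved and withdrawn annotations are flagged", {
  rec <- tibble::tibble(inchikey = keys(2))
  db_ann <- tibble::tibble(inchikey = c(keys(1), keys(1)),
                           status = c("APPROVED", "WITHDRAWN"))
  db <- resource_table("drugbank_like", keys(2), db_ann)
  ch <- resource_table("chembl_like", character())
  expect_warning(cl <- annotate_clinical(rec, ch, db), "withdrawn")
  expect_equal(cl$conflicts, keys(1))
  sc <- function(s) cl$status_counts$count[cl$status_counts$status == s]
  expect_equal(sc("APPROVED"), 1L)
  expect_equal(sc("WITHDRAWN"), 1L)
})
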