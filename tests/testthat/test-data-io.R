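test_that("pki_from_ki converts molar Ki to pKi", {
  expect_equal(pki_from_ki(1e-6), 6)
  expect_equal(pki_from_ki(1e-8), 8)
  expect_equal(pki_from_ki(1.5e-8), 7.8239087409443189, tolerance = 1e-12)
  # strictly decreasing in ki
  ki <- sort(10^runif(20, -9, -4))
  expect_true(all(diff(pki_from_ki(ki)) < 0))
  expect_error(pki_from_ki(0), class = "sarsvr_invalid_value")
  expect_error(pki_from_ki(-1e-9), class = "sarsvr_invalid_value")
})

test_that("curation averages concordant measurements and discards the rest", {
  records <- tibble::tibble(
    compound_id = c("A", "A", "B", "B", "C"),
    ki = c(1e-8, 2e-8, 1e-8, 5e-7, 2e-4)
  )
  out <- curate_ki_records(records)
  # A: two Ki within one order of magnitude, combined on the pKi scale
  expect_equal(out$pki[out$compound_id == "A"], 7.8494850021680094,
               tolerance = 1e-12)
  # B: 50-fold spread -> discarded; C: Ki >= 100 uM -> dropped before grouping
  expect_false("B" %in% out$compound_id)
  expect_false("C" %in% out$compound_id)
  # Ki-scale averaging convention: arithmetic mean of Ki, then converted
  out_ki <- curate_ki_records(records, average = "ki")
  expect_equal(out_ki$pki[out_ki$compound_id == "A"],
               -log10(1.5e-8), tolerance = 1e-12)
})

test_that("curation is idempotent and bounded below by the Ki cutoff", {
  withr::with_seed(42, {
    records <- tibble::tibble(
      compound_id = sample(sprintf("c%02d", 1:30), 80, replace = TRUE),
      ki = 10^runif(80, -9, -3)
    )
  })
  out <- curate_ki_records(records, pki_floor = -Inf)
  expect_true(all(out$pki > -log10(1e-4)))
  # feeding the curated pKi back through (as single measurements) is a no-op
  again <- curate_ki_records(
    tibble::tibble(compound_id = out$compound_id, ki = 10^(-out$pki)),
    pki_floor = -Inf
  )
  expect_equal(again[order(again$compound_id), c("compound_id", "pki")],
               out[order(out$compound_id), c("compound_id", "pki")],
               tolerance = 1e-12)
  # default floor removes compounds weaker than pKi 5
  expect_true(all(curate_ki_records(records)$pki >= 5))
})

test_that("dataset TSV round trip is exact and byte-stable", {
  ds <- fixture_dataset(n = 25, k = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(nrow(back), 25)
  expect_identical(back$compound_id, ds$compound_id)
  expect_identical(back$pki, ds$pki)
  expect_identical(back$fingerprint, ds$fingerprint)
  expect_identical(attr(back, "target_id"), attr(ds, "target_id"))
  expect_identical(attr(back, "universe"), attr(ds, "universe"))
  expect_identical(attr(back, "tc_threshold"), attr(ds, "tc_threshold"))
  # write(read(f)) reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("malformed dataset files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- c("#target_id=x", "#scheme=ECFP4", "#universe=64", "#tc_threshold=0.56",
              "compound_id\tpki\tfingerprint")
  writeLines(c(header, "a\t6.0\t1;2;3", "a\t7.0\t2;3;4"), path)
  expect_error(read_dataset(path), class = "sarsvr_duplicate_id")

  writeLines(c(header, "a\t6.0\t1;2;3", "b\tnot_a_number\t1;2"), path)
  err <- expect_error(read_dataset(path), class = "sarsvr_parse_error")
  expect_match(conditionMessage(err), "Line 7")

  writeLines(c(header, "a\t6.0\t"), path)
  expect_error(read_dataset(path), class = "sarsvr_parse_error")
})

test_that("dataset_summary reports n/min/max/mean of pKi", {
  ds <- cmpd_dataset(tibble::tibble(
    compound_id = c("a", "b", "c"), pki = c(5, 7, 9),
    fingerprint = list(1L, 2L, 3L)
  ), universe = 8)
  expect_equal(unlist(dataset_summary(ds)[, c("n", "min_pki", "max_pki", "mean_pki")]),
               c(n = 3, min_pki = 5, max_pki = 9, mean_pki = 7))
  one <- cmpd_dataset(tibble::tibble(compound_id = "a", pki = 6.2,
                                     fingerprint = list(1L)), universe = 8)
  s <- dataset_summary(one)
  expect_equal(c(s$min_pki, s$max_pki, s$mean_pki), rep(6.2, 3))
  # loop oracle on a larger random set
  ds <- fixture_dataset(n = 100, k = 10, seed = 3)
  s <- dataset_summary(ds)
  mn <- Inf; mx <- -Inf; tot <- 0
  for (p in ds$pki) { mn <- min(mn, p); mx <- max(mx, p); tot <- tot + p }
  expect_equal(c(s$min_pki, s$max_pki, s$mean_pki), c(mn, mx, tot / 100))
})

test_that("dataset validation rejects bad records", {
  expect_error(cmpd_dataset(tibble::tibble(
    compound_id = c("a", "a"), pki = c(6, 7), fingerprint = list(1L, 2L)
  ), universe = 8), class = "sarsvr_duplicate_id")
  expect_error(cmpd_dataset(tibble::tibble(
    compound_id = "a", pki = 6, fingerprint = list(integer(0))
  ), universe = 8), class = "sarsvr_empty_fingerprint")
})
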