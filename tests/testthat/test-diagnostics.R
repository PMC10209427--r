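test_that("overlap screening implements the asterisk rule", {
  # disjoint published-style ranges: no overlap at all
  set.seed(31)
  A <- runif(12, 1.74, 1.97)
  B <- runif(10, 1.50, 1.68)
  res <- assess_overlap(A, B)
  expect_equal(res$count_A_in_B + res$count_B_in_A, 0)
  expect_true(res$asterisk)

  # identical samples: everyone overlaps
  idres <- assess_overlap(A, A)
  expect_equal(idres$count_A_in_B, length(A))
  expect_false(idres$asterisk)

  # exactly one specimen inside the other range keeps the asterisk
  # (a single B specimen nested strictly inside A's range)
  A1 <- c(1.0, 1.1, 1.2, 3.0)
  B1 <- 2.5
  r1 <- assess_overlap(A1, B1)
  expect_equal(r1$count_A_in_B, 0)
  expect_equal(r1$count_B_in_A, 1)
  expect_true(r1$asterisk)
  # two (or more) overlapping specimens lose it
  r2 <- assess_overlap(A1, c(2.5, 2.6, 7.0))
  expect_equal(r2$count_B_in_A + r2$count_A_in_B, 3)
  expect_false(r2$asterisk)
  expect_error(assess_overlap(numeric(0), B1), "empty")
})

test_that("the asterisk outcome is symmetric under swapping the species", {
  set.seed(32)
  for (i in 1:20) {
    A <- rnorm(8, 0, 1)
    B <- rnorm(8, runif(1, 0, 3), 1)
    expect_equal(assess_overlap(A, B)$asterisk,
                 assess_overlap(B, A)$asterisk)
  }
})

test_that("the shipped key classifies the printed holotype correctly", {
  key <- read_key(extdata("lucerne_key.yaml"))
  expect_setequal(key_species(key),
                  c("C.litoralis", "C.suspensus", "C.nobilis",
                    "C.muelleri", "C.intermundia"))
  holo <- holotype_mm()[["C.litoralis"]]
  vals <- key_quantities(holo, key_required_quantities(key))
  # PreD/ED from the printed percentages: (49.9% of 326) / (20% of 67.5)
  expect_equal(vals[["PreD/ED"]], (0.499 * 326) / (0.20 * 67.5),
               tolerance = 1e-12)
  expect_equal(round(vals[["PreD/ED"]], 2), 12.05)
  expect_equal(classify_with_key(key, vals), "C.litoralis")
})

test_that("the key reaches C. nobilis by two distinct paths", {
  key <- read_key(extdata("lucerne_key.yaml"))
  # deep-bodied path: couplet 1 -> 2 -> 3
  path1 <- c("PreD/ED" = 11.5, "totalGR" = 36, "PecFB/CD" = 0.48)
  expect_equal(classify_with_key(key, path1), "C.nobilis")
  # slender path: couplet 1 -> 4 -> 5 (conjunction of two conditions)
  path2 <- c("PreD/ED" = 9.5, "TL/ED" = 26, "CD/HW" = 0.70, "DFAe" = 16.5)
  expect_equal(classify_with_key(key, path2), "C.nobilis")
})

test_that("out-of-range values are undetermined, missing values error", {
  key <- read_key(extdata("lucerne_key.yaml"))
  res <- classify_with_key(key, c("PreD/ED" = 5.0))
  expect_equal(as.character(res), "undetermined")
  expect_equal(attr(res, "couplet"), 1)
  expect_error(classify_with_key(key, c("PreD/ED" = 11.0)),
               "couplet 2.*totalGR")
})

test_that("key traversal terminates and cyclic keys are rejected", {
  cyc <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("entry: 1",
               "couplets:",
               "  - id: 1",
               "    alternatives:",
               "      - conditions: [{quantity: 'CD/HW', min: 0, max: 1}]",
               "        outcome: {couplet: 2}",
               "      - conditions: [{quantity: 'CD/HW', min: 1, max: 2}]",
               "        outcome: {species: 'X'}",
               "  - id: 2",
               "    alternatives:",
               "      - conditions: [{quantity: 'ED', min: 0, max: 1}]",
               "        outcome: {couplet: 1}",
               "      - conditions: [{quantity: 'ED', min: 1, max: 2}]",
               "        outcome: {species: 'Y'}"), cyc)
  expect_error(read_key(cyc), "cycle")
})

test_that("specimens drawn inside one species' intervals always classify there", {
  key <- read_key(extdata("lucerne_key.yaml"))
  set.seed(33)
  n <- 200
  # strictly interior to the C. litoralis path intervals
  vals <- data.frame("PreD/ED" = runif(n, 10.9, 12.6),
                     "totalGR" = sample(25:31, n, replace = TRUE),
                     check.names = FALSE)
  got <- vapply(seq_len(n), function(i) {
    classify_with_key(key, as.list(vals[i, ]))
  }, character(1))
  expect_true(all(got == "C.litoralis"))
})

test_that("published gill-raker frequency rows give the printed modes", {
  tab13 <- read_freq_table(extdata("table13_gillrakers.tsv"))
  expect_false(any(tab13$inconsistent))
  lito <- meristic_modes(tab13, "C.litoralis_contemporary")
  expect_equal(lito$modes, c(26, 30))
  expect_equal(c(lito$min, lito$max), c(24, 32))
  sarn <- meristic_modes(tab13, "C.sarnensis")
  expect_equal(sarn$modes, c(35, 36))
  expect_error(meristic_modes(tab13, "C.gone"), "not in table")
})

test_that("uniform counts are fully multimodal", {
  ft <- freq_table_from_counts(list(sp = rep(10:13, each = 2)))
  m <- meristic_modes(ft, "sp")
  expect_equal(m$modes, 10:13)
})

test_that("frequency tables built from raw counts match the file reader", {
  counts <- rep(c(24, 26, 27, 28, 29, 30, 31, 32), c(1, 3, 2, 1, 1, 3, 1, 1))
  ft <- freq_table_from_counts(list(C.litoralis_contemporary = counts))
  tab13 <- read_freq_table(extdata("table13_gillrakers.tsv"))
  m1 <- meristic_modes(ft, "C.litoralis_contemporary")
  m2 <- meristic_modes(tab13, "C.litoralis_contemporary")
  expect_equal(m1$modes, m2$modes)
  expect_equal(c(m1$min, m1$max), c(m2$min, m2$max))
  expect_equal(m1$N, m2$N)
})

test_that("diagnosis reports list the planted ratio first and round-trip", {
  tab <- demo_specimens(seed = 34)
  rep1 <- compare_species_pair(tab)
  diag <- build_diagnosis(tab, rep1)
  planted <- paste(attr(planted_ratio_spec(), "planted"), collapse = "/")
  expect_equal(diag$ratios[[1]]$ratio, planted)
  expect_true(diag$ratios[[1]]$asterisk)
  path <- withr::local_tempfile(fileext = ".json")
  write_diagnosis(diag, path)
  back <- read_diagnosis(path)
  expect_equal(back$species, diag$species)
  expect_equal(back$ratios[[1]]$ratio, diag$ratios[[1]]$ratio)
  expect_equal(back$ratios[[1]]$range1, diag$ratios[[1]]$range1,
               tolerance = 1e-12)
  md <- format_diagnosis(back)
  expect_match(md, planted, fixed = TRUE)

  # empty comparison list: summaries only, no error
  d2 <- build_diagnosis(tab, report = NULL)
  expect_length(d2$ratios, 0)
  expect_gt(length(d2$nonoverlapping_characters) +
              length(d2$meristics) + 1, 0)
})
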