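test_that("variant tables parse, validate and reject bad records", {
  path <- withr::local_tempfile(fileext = ".tsv")
  v <- make_variants(2, sample_id = c("S1", "S2"),
                     mutant_reads = c(4L, 30L), total_reads = c(400L, 300L))
  write_variants(v, path)
  got <- read_variants(path)
  expect_equal(nrow(got), 2)
  expect_equal(got$vaf[1], 0.01)
  expect_false(got$is_cosmic_hotspot[1])

  # header-only file -> empty collection, no error
  write_variants(v[0, ], path)
  expect_equal(nrow(read_variants(path)), 0)

  # missing required column -> format error naming it
  bad <- v; bad$vaf <- NULL
  utils::write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variants(path), "vaf", class = "eogc_format_error")

  # mutant_reads > total_reads -> validation error with row number
  bad <- make_variants(2, mutant_reads = c(30L, 10L),
                       total_reads = c(300L, 5L), vaf = c(0.1, 1))
  write_variants(bad, path)
  expect_error(read_variants(path), "row.*2", class = "eogc_validation_error")

  # vaf inconsistent with read counts
  bad <- make_variants(1, mutant_reads = 30L, total_reads = 300L, vaf = 0.5)
  write_variants(bad, path)
  expect_error(read_variants(path), class = "eogc_validation_error")

  # ref == alt
  bad <- make_variants(1, ref = "C", alt = "C")
  write_variants(bad, path)
  expect_error(read_variants(path), class = "eogc_validation_error")
})

test_that("every table type round-trips through TSV", {
  set.seed(11)
  dir <- withr::local_tempdir()
  v <- make_variants(6, sample_id = sprintf("S%d", 1:6),
                     mutant_reads = 6:11, total_reads = 100L,
                     hotspot = c(TRUE, FALSE), driver = c(FALSE, TRUE),
                     context3 = c("ACA", NA_character_, "TCG"))
  p <- file.path(dir, "v.tsv")
  write_variants(v, p)
  got <- read_variants(p)
  expect_identical(got$mutant_reads, v$mutant_reads)
  expect_identical(got$is_known_driver, v$is_known_driver)
  expect_identical(got$context3, v$context3)
  expect_equal(got$vaf, v$vaf, tolerance = 1e-9)

  cl <- data.frame(sample_id = sprintf("P%d", 1:4),
                   age = c(44L, NA, 60L, 72L),
                   sex = c("male", "female", "male", "female"),
                   ebv_positive = c(TRUE, FALSE, FALSE, TRUE),
                   purity = c(0.5, 0.21, 0.9, 0.33),
                   stringsAsFactors = FALSE)
  p <- file.path(dir, "cl.tsv")
  write_clinical(cl, p)
  got <- read_clinical(p)
  expect_identical(got$age, cl$age)
  expect_identical(got$ebv_positive, cl$ebv_positive)
  expect_equal(got$purity, cl$purity, tolerance = 1e-9)

  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(sprintf("P%d", 1:3), sprintf("G%d", 1:4)))
  l2m <- gene_log2_matrix(m, data.frame(gene = sprintf("G%d", 1:4),
                                        chrom = c("1", "1", "2", "X"),
                                        arm = c("p", "q", "q", "q")))
  write_log2_matrix(l2m, file.path(dir, "l2.tsv"), file.path(dir, "gm.tsv"))
  got <- read_log2_matrix(file.path(dir, "l2.tsv"), file.path(dir, "gm.tsv"))
  expect_equal(got$log2ratio, m, tolerance = 1e-9)
  expect_identical(got$gene_map$chrom, c("1", "1", "2", "X"))

  calls <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), 2, 3,
                  dimnames = list(c("P1", "P2"), sprintf("site%d", 1:3)))
  write_site_calls(calls, file.path(dir, "s.tsv"))
  expect_identical(read_site_calls(file.path(dir, "s.tsv")), calls)
  expect_error(read_site_calls(file.path(dir, "s.tsv"), panel_size = 52),
               class = "eogc_validation_error")
})

test_that("cohort assembly applies the age and purity gates with audit", {
  cl <- data.frame(
    sample_id = sprintf("P%d", 1:6),
    age = c(50L, NA, 30L, 70L, NA, 44L),
    sex = "male",
    ebv_positive = FALSE,
    purity = c(0.5, 0.6, 0.20, 0.19, 0.1, 0.9),
    stringsAsFactors = FALSE
  )
  res <- assemble_cohort(cl, min_purity = 0.2)
  # P2/P5 missing age; P3 at exactly 0.2 excluded (strictly larger than)
  expect_setequal(res$eligible$sample_id, c("P1", "P6"))
  expect_equal(nrow(res$eligible) + nrow(res$excluded), nrow(cl))
  expect_equal(res$excluded$reason[res$excluded$sample_id == "P3"],
               "low_purity")
  expect_equal(res$excluded$reason[res$excluded$sample_id == "P5"],
               "missing_age")

  # all complete -> nothing excluded
  ok <- cl[c(1, 6), ]
  expect_equal(nrow(assemble_cohort(ok)$excluded), 0)

  # duplicate ids rejected
  dup <- rbind(cl, cl[1, ])
  expect_error(assemble_cohort(dup), "duplicate",
               class = "eogc_validation_error")
})
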