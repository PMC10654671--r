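test_that("annotation reader validates, keeps unknown tokens, reports errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(fixture_annotations(), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 6)
  expect_length(unrecognized_genes(ann), 0)

  # unknown symbol retained, listed in the unrecognized report
  odd <- dplyr::mutate(fixture_annotations(),
                       gene_symbol = replace(gene_symbol, 1, "xyz"))
  readr::write_tsv(odd, path)
  ann2 <- suppressMessages(read_annotations(path))
  expect_equal(nrow(ann2), 6)
  expect_equal(unrecognized_genes(ann2), "xyz")

  # missing column is a format error naming the column
  readr::write_tsv(dplyr::select(fixture_annotations(), -scaffold_length), path)
  expect_error(read_annotations(path), "scaffold_length")

  # negative length is a validation error with the row number
  bad <- dplyr::mutate(fixture_annotations(),
                       scaffold_length = replace(scaffold_length, 3, -5L))
  readr::write_tsv(bad, path)
  expect_error(read_annotations(path), "row.*3")
})

test_that("GTDB lineage parsing is total on the 7-prefix grammar", {
  tx <- parse_gtdb_lineage(
    "d__Archaea;p__Halobacterota;c__X;o__Methanosarcinales;f__Methanosarcinaceae;g__Methanosarcina;s__")
  expect_equal(tx$family, "Methanosarcinaceae")
  expect_equal(tx$species, "")

  short <- parse_gtdb_lineage("d__Bacteria")
  expect_equal(short$domain, "Bacteria")
  expect_true(all(short[, c("phylum", "class", "order", "family",
                            "genus", "species")] == ""))

  expect_error(parse_gtdb_lineage("p__X;d__Bacteria"), "prefix")
  expect_error(parse_gtdb_lineage("x__Bacteria"), "prefix")
  expect_error(parse_gtdb_lineage(""), "non-empty")
  expect_error(parse_gtdb_lineage("d__A;p__;c__C"), "unclassified")
})

test_that("completion fraction is exact, monotone and validated", {
  expect_identical(completion_fraction(6, 8), 0.75)
  expect_identical(completion_fraction(0, 8), 0)
  expect_identical(completion_fraction(2, 2), 1)
  expect_error(completion_fraction(3, 2), "exceeds")
  expect_error(completion_fraction(1, 0), "steps_total")
  for (total in c(2L, 7L, 8L)) {
    fr <- completion_fraction(0:total, total)
    expect_true(all(diff(fr) > 0))
  }
})

test_that("pathway table fills default step totals and derives fractions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(mag_id = "m1",
                   pathway_id = c("HYDROGENOTROPHIC_METHANOGENESIS", "CODH_ACS",
                                  "WOOD_LJUNGDAHL"),
                   steps_present = c(6L, 1L, 6L)),
    path)
  pw <- read_pathway_completions(path)
  expect_equal(pw$steps_total, c(8L, 2L, 7L))
  expect_equal(pw$fraction, c(0.75, 0.5, 6 / 7))
  expect_error(
    validate_pathway_completions(
      tibble::tibble(mag_id = "m1", pathway_id = "MYSTERY", steps_present = 1L)),
    "MYSTERY")
})

test_that("write-then-read round-trips validated tables exactly", {
  dir <- withr::local_tempdir()
  ann <- fixture_annotations()
  write_mag_table(ann, file.path(dir, "ann.tsv"))
  back <- read_annotations(file.path(dir, "ann.tsv"))
  expect_equal(
    dplyr::arrange(ann, mag_id, gene_symbol, scaffold_id),
    dplyr::arrange(tibble::as_tibble(back), mag_id, gene_symbol, scaffold_id),
    ignore_attr = TRUE)

  cov <- tibble::tibble(mag_id = c("m2", "m1"), scaffold_id = c("s1", "s2"),
                        coverage = c(12.25, 0))
  write_mag_table(cov, file.path(dir, "cov.tsv"))
  back_cov <- read_coverage(file.path(dir, "cov.tsv"))
  expect_equal(back_cov$mag_id, c("m1", "m2"))  # deterministic sort on write
  expect_equal(sort(back_cov$coverage), sort(cov$coverage))
})

test_that("taxonomy accepts lineage strings or rank columns, rejects dups", {
  tx <- validate_taxonomy(fixture_taxonomy())
  expect_equal(tx$family, c("Methanosarcinaceae", "Methylomonadaceae",
                            "Methanomethylophilaceae"))
  expect_equal(tx$genus[3], "")
  wide <- tx  # already rank columns
  expect_equal(validate_taxonomy(wide)$family, tx$family)
  expect_error(validate_taxonomy(dplyr::bind_rows(fixture_taxonomy(),
                                                  fixture_taxonomy())),
               "duplicate")
  expect_error(validate_taxonomy(tibble::tibble(mag_id = "m1")), "rank columns")
})

test_that("gene label aliases resolve both annotation dialects", {
  expect_equal(resolve_gene_labels(c("Acetate pt 1", "acetate pt. 1",
                                     "acetate pt. 2", "mcrA", "nonsense")),
               c("acs", "pta", "ack", "mcrA", NA))
})
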