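feat_row <- function(mcrA = FALSE, mcrB = FALSE, mcrC = FALSE, mcrD = FALSE,
                     mcrG = FALSE, hydro = 0, codh = 0, acs = FALSE,
                     ackpair = FALSE, n_methyl = 0L, mtsA = FALSE,
                     mtaA = FALSE, family = "", mag_id = "m1") {
  tibble::tibble(mag_id = mag_id, has_mcrA = mcrA, has_mcrB = mcrB,
                 has_mcrC = mcrC, has_mcrD = mcrD, has_mcrG = mcrG,
                 hydro = hydro, codh_acs = codh, has_acs = acs,
                 has_ack_and_acyltx = ackpair, has_mtsA = mtsA,
                 has_mtaA = mtaA, n_methyl = n_methyl,
                 methyl_substrates = "", family = family)
}

test_that("putative-methanogen screen partitions by mcr evidence and ANME family", {
  status <- function(...) {
    identify_putative_methanogens(feat_row(...))$status
  }
  expect_equal(status(mcrA = TRUE, hydro = 2 / 8), "candidate")
  expect_equal(status(mcrB = TRUE, hydro = 6 / 8), "candidate")
  expect_equal(status(hydro = 7 / 8), "excluded_no_mcr")
  expect_equal(status(mcrA = TRUE, hydro = 7 / 8,
                      family = "Methanoperedenaceae"), "rerouted_anme")
  expect_equal(status(hydro = 3 / 8), "not_methanogen")
  # mcrBCDG alone with low hydro completion is not enough
  expect_equal(status(mcrB = TRUE, hydro = 3 / 8), "not_methanogen")
})

test_that("guild rules assign the expected label on the worked cases", {
  lab <- function(...) classify_guild(feat_row(...))$label
  expect_equal(lab(mcrA = TRUE, hydro = 7 / 8), "STRICT_HYDROGENOTROPH")
  expect_equal(lab(mcrA = TRUE, hydro = 7 / 8, codh = 1, acs = TRUE),
               "ACETOCLASTIC")
  expect_equal(lab(mcrA = TRUE, hydro = 3 / 8, n_methyl = 1L),
               "METHYLOTROPHIC")
  expect_equal(lab(mcrA = TRUE, hydro = 1, codh = 1, acs = TRUE,
                   n_methyl = 2L), "BROAD_SUBSTRATE")
  # methylthiol transferase homolog as sole methyl evidence sets the flag
  call <- classify_guild(feat_row(mcrA = TRUE, hydro = 2 / 8, mtsA = TRUE))
  expect_equal(call$label, "METHYLOTROPHIC")
  expect_true(call$methylthiol_flag)
  expect_match(call$evidence, "methylthiol_transferase")
  # 6/8 sits exactly on the inclusive 75% boundary
  expect_equal(lab(mcrA = TRUE, hydro = 6 / 8, codh = 1, acs = TRUE),
               "ACETOCLASTIC")
  # 1/2 CODH/ACS does not clear the strictly-exclusive 50% bar
  expect_equal(lab(mcrA = TRUE, hydro = 1, codh = 0.5, acs = TRUE),
               "UNRESOLVED_METHANOGEN")
})

test_that("vectorized engine agrees with the scalar oracle on the full grid", {
  grid <- methanogen_feature_grid()
  expect_equal(nrow(grid), 32 * 9 * 3 * 4 * 16 * 4)
  got <- classify_guild(grid)$label
  expect_equal(got, grid_oracle_labels(grid))
})

test_that("classification is deterministic and idempotent", {
  grid <- methanogen_feature_grid()
  sub <- grid[seq(1, nrow(grid), by = 97), ]
  expect_identical(classify_guild(sub), classify_guild(sub))
  # exactly one label per candidate, evidence non-empty
  calls <- classify_guild(sub)
  expect_equal(nrow(calls), nrow(sub))
  expect_true(all(nzchar(calls$evidence)))
})

test_that("rule overlaps are confined to the two known rule pairs", {
  ov <- guild_rule_overlaps()
  expect_gt(nrow(ov), 0)
  expect_setequal(unique(ov$rules),
                  c("broad+acetoclastic", "methylotrophic+strict"))
  # broad-rule cells are a subset of acetoclastic-rule cells
  expect_true(all(!ov$r_broad | ov$r_aceto))
  # and the overlap set matches an independent recomputation
  grid <- methanogen_feature_grid()
  r_broad <- grid$has_mcrA & (grid$has_acs | grid$has_ack_and_acyltx) &
    grid$codh_steps == 2 & grid$hydro_steps >= 6 & grid$n_methyl >= 1
  r_methyl <- grid$has_mcrA &
    (grid$n_methyl >= 1 | grid$has_mtsA | grid$has_mtaA) &
    grid$codh_steps == 0 & grid$hydro_steps < 4
  r_aceto <- (grid$has_mcrA | grid$has_mcrB | grid$has_mcrC | grid$has_mcrD |
                grid$has_mcrG) & (grid$has_acs | grid$has_ack_and_acyltx) &
    grid$codh_steps == 2 & grid$hydro_steps >= 6
  r_strict <- (grid$has_mcrA |
                 (grid$hydro_steps >= 6 & (grid$has_mcrB | grid$has_mcrC |
                                             grid$has_mcrD | grid$has_mcrG))) &
    grid$codh_steps == 0 & !(grid$has_acs | grid$has_ack_and_acyltx)
  expect_setequal(ov$mag_id,
                  grid$mag_id[r_broad + r_methyl + r_aceto + r_strict > 1])
})

test_that("end-to-end methanogen classification labels flagged MAGs", {
  calls <- suppressMessages(classify_methanogens(
    fixture_annotations(), fixture_pathways(), fixture_taxonomy()))
  expect_equal(calls$label[calls$mag_id == "m1"], "ACETOCLASTIC")
  expect_equal(calls$label[calls$mag_id == "m3"], "METHYLOTROPHIC")
  expect_false("m2" %in% calls$mag_id)  # methanotroph, not a methanogen

  # high hydro completion, no mcr at all -> excluded and reported
  ann <- tibble::tibble(mag_id = "mx", gene_symbol = "ureC",
                        scaffold_id = "s", scaffold_length = 4000L)
  pw <- tibble::tibble(mag_id = "mx",
                       pathway_id = "HYDROGENOTROPHIC_METHANOGENESIS",
                       steps_present = 7L, steps_total = 8L)
  out <- suppressMessages(classify_methanogens(ann, pw))
  expect_equal(out$label, "EXCLUDED_NO_MCR")
})
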