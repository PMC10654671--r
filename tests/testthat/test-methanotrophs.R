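mt_ann <- function(...) {
  rows <- list(...)
  tibble::tibble(
    mag_id = purrr::map_chr(rows, 1),
    gene_symbol = purrr::map_chr(rows, 2),
    scaffold_id = purrr::map_chr(rows, 3),
    scaffold_length = as.integer(purrr::map_dbl(rows, 4)))
}

mt_tax <- function(mag_id, family) {
  tibble::tibble(mag_id = mag_id, domain = "d", phylum = "p", class = "c",
                 order = "o", family = family, genus = "", species = "")
}

test_that("pmoA/mmoX presence drives the mode call; ANME is taxonomy-driven", {
  ann <- mt_ann(list("a", "pmoA", "a_s1", 5000),
                list("b", "pmoA", "b_s1", 5000),
                list("b", "mmoX", "b_s2", 5000),
                list("c", "mmoX", "c_s1", 5000),
                list("d", "ureC", "d_s1", 5000))
  tax <- mt_tax(c("a", "b", "c", "d", "e"),
                c("Methylomonadaceae", "Methylococcaceae", "Methylococcaceae",
                  "Bacteroidaceae", "Methanoperedenaceae"))
  calls <- suppressMessages(classify_methanotrophs(ann, tax))
  mode <- setNames(calls$mode, calls$mag_id)
  expect_equal(mode[["a"]], "PMO_ONLY")
  expect_equal(mode[["b"]], "BOTH")
  expect_equal(mode[["c"]], "MMO_ONLY")
  expect_false("d" %in% calls$mag_id)
  expect_equal(mode[["e"]], "ANME")  # no pmoA/mmoX required
})

test_that("novel families need multiple genes on long scaffolds to verify", {
  th <- rule_thresholds()
  # two genes on one 3500 bp scaffold: verified
  a1 <- validate_annotations(mt_ann(list("n1", "pmoA", "s1", 3500),
                                    list("n1", "pmoB", "s1", 3500)))
  expect_true(verify_novel_family("n1", a1, th))
  # single gene on a short scaffold: not verified
  a2 <- validate_annotations(mt_ann(list("n2", "pmoA", "s1", 2000)))
  expect_false(verify_novel_family("n2", a2, th))
  # genes split across two qualifying scaffolds still verify
  a3 <- validate_annotations(mt_ann(list("n3", "pmoA", "s1", 3200),
                                    list("n3", "mmoX", "s2", 4100)))
  expect_true(verify_novel_family("n3", a3, th))
  # one long, one short scaffold: only one qualifying observation
  a4 <- validate_annotations(mt_ann(list("n4", "pmoA", "s1", 3200),
                                    list("n4", "pmoB", "s2", 2000)))
  expect_false(verify_novel_family("n4", a4, th))
})

test_that("verification decision matches brute force over gene placements", {
  # exhaustive check over 2-gene placements on scaffolds of two lengths
  th <- rule_thresholds()
  lens <- c(2000L, 3500L)
  cases <- expand.grid(l1 = lens, l2 = lens, same_scaffold = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    sc2 <- if (cs$same_scaffold) "s1" else "s2"
    l2 <- if (cs$same_scaffold) cs$l1 else cs$l2
    ann <- validate_annotations(mt_ann(list("m", "pmoA", "s1", cs$l1),
                                       list("m", "mmoX", sc2, l2)))
    want <- sum(c(cs$l1, l2) >= 3000) >= 2
    expect_identical(verify_novel_family("m", ann, th), want)
  }
})

test_that("calls in known families skip verification; novel calls are flagged", {
  ann <- mt_ann(list("k", "pmoA", "k_s1", 2000),
                list("n", "pmoA", "n_s1", 2000))
  tax <- mt_tax(c("k", "n"), c("Methylomonadaceae", "Nevskiaceae"))
  calls <- suppressMessages(classify_methanotrophs(ann, tax))
  expect_true(calls$verified[calls$mag_id == "k"])
  expect_false(calls$verified[calls$mag_id == "n"])
  expect_match(calls$evidence[calls$mag_id == "n"], "verification_failed")
  expect_true(all(calls$mode == "PMO_ONLY"))  # unverified calls retained
})

test_that("adding pmo/mmo observations never un-identifies or un-verifies", {
  set.seed(7)
  tokens <- c("pmoA", "pmoB", "pmoC", "mmoX", "mmoY", "mmoZ")
  tax <- mt_tax("m", "Nevskiaceae")
  for (i in 1:20) {
    n <- sample(1:5, 1)
    base <- tibble::tibble(
      mag_id = "m", gene_symbol = sample(tokens, n, replace = TRUE),
      scaffold_id = sample(sprintf("s%d", 1:3), n, replace = TRUE),
      scaffold_length = sample(c(1500L, 2800L, 3600L, 9000L), n, replace = TRUE))
    extra <- tibble::tibble(mag_id = "m",
                            gene_symbol = sample(tokens, 1),
                            scaffold_id = "s9",
                            scaffold_length = sample(c(1500L, 5000L), 1))
    before <- suppressMessages(classify_methanotrophs(base, tax))
    after <- suppressMessages(classify_methanotrophs(rbind(base, extra), tax))
    if (nrow(before) == 1) {
      expect_equal(nrow(after), 1)
      expect_false(before$verified && !after$verified)
    }
  }
})

test_that("aerobic mode counts add up to the planted methanotroph total", {
  b <- simulate_landfill(simulation_config(seed = 5,
                                           sites = c(P = 120, Q = 120)))
  calls <- suppressMessages(classify_methanotrophs(b$annotations, b$taxonomy))
  planted <- sum(b$truth$guild %in% c("methanotroph_pmo", "methanotroph_mmo",
                                      "methanotroph_both"))
  expect_equal(sum(calls$mode %in% c("PMO_ONLY", "MMO_ONLY", "BOTH")), planted)
  expect_equal(sum(calls$mode == "ANME"), sum(b$truth$guild == "anme"))
})

test_that("trait tallies count MAGs once regardless of gene copies", {
  calls <- tibble::tibble(mag_id = c("a", "b"), mode = c("PMO_ONLY", "BOTH"))
  ann <- mt_ann(list("a", "nirK", "s1", 5000), list("a", "nirS", "s2", 5000),
                list("b", "narG", "s1", 5000))
  pw <- tibble::tibble(mag_id = c("a", "b"),
                       pathway_id = "COMPLEX_IV_HIGH",
                       steps_present = c(4L, 2L), steps_total = c(4L, 4L))
  tt <- suppressMessages(methanotroph_trait_tally(calls, ann, pw))
  expect_equal(tt$n_with_trait[tt$trait == "nitrite_reduction"], 1L)
  expect_equal(tt$n_with_trait[tt$trait == "nitrate_reduction"], 1L)
  expect_equal(tt$n_with_trait[tt$trait == "complex_iv_high_affinity"], 1L)
  expect_true(all(tt$n_methanotrophs == 2L))
})
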