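# Independent scalar re-statements of the classification rules and of
# Bray-Curtis, used as brute-force oracles.  Deliberately written as plain
# if/else over one feature cell, independent of the package's vectorized path.

oracle_guild <- function(mcrA, mcrB, mcrC, mcrD, mcrG, hydro_steps, codh_steps,
                         acs, ackpair, n_methyl, mtsA, mtaA,
                         hydro_min = 0.75, hydro_low_max = 0.5,
                         codh_min = 0.5) {
  hydro <- hydro_steps / 8
  codh <- codh_steps / 2
  bcdg <- mcrB || mcrC || mcrD || mcrG
  acet <- acs || ackpair
  methyl <- n_methyl >= 1
  thiol <- mtsA || mtaA
  if (mcrA && acet && codh > codh_min && hydro >= hydro_min && methyl) {
    return("BROAD_SUBSTRATE")
  }
  if (mcrA && (methyl || thiol) && codh == 0 && hydro < hydro_low_max) {
    return("METHYLOTROPHIC")
  }
  if ((mcrA || bcdg) && acet && codh > codh_min && hydro >= hydro_min) {
    return("ACETOCLASTIC")
  }
  if ((mcrA || (hydro >= hydro_min && bcdg)) && codh == 0 && !acet) {
    return("STRICT_HYDROGENOTROPH")
  }
  "UNRESOLVED_METHANOGEN"
}

oracle_bray <- function(x, y) {
  sum(abs(x - y)) / sum(x + y)
}

# small well-formed fixture tables used across files
fixture_annotations <- function() {
  tibble::tribble(
    ~mag_id, ~gene_symbol, ~scaffold_id, ~scaffold_length,
    "m1", "mcrA", "m1_s1", 12000L,
    "m1", "acs",  "m1_s2", 8000L,
    "m2", "pmoA", "m2_s1", 3500L,
    "m2", "pmoB", "m2_s1", 3500L,
    "m3", "mcrA", "m3_s1", 5000L,
    "m3", "mtaB", "m3_s2", 4000L)
}

fixture_pathways <- function() {
  tibble::tribble(
    ~mag_id, ~pathway_id, ~steps_present, ~steps_total,
    "m1", "HYDROGENOTROPHIC_METHANOGENESIS", 8L, 8L,
    "m1", "CODH_ACS", 2L, 2L,
    "m3", "HYDROGENOTROPHIC_METHANOGENESIS", 3L, 8L,
    "m3", "CODH_ACS", 0L, 2L)
}

fixture_taxonomy <- function() {
  tibble::tibble(
    mag_id = c("m1", "m2", "m3"),
    classification = c(
      "d__Archaea;p__Halobacterota;c__Methanosarcinia;o__Methanosarcinales;f__Methanosarcinaceae;g__Methanosarcina;s__",
      "d__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Methylococcales;f__Methylomonadaceae;g__Methylobacter;s__",
      "d__Archaea;p__Thermoplasmatota;c__Thermoplasmata;o__Methanomassiliicoccales;f__Methanomethylophilaceae;g__;s__"))
}

# grid-feature tibble row -> arguments of oracle_guild
grid_oracle_labels <- function(grid) {
  purrr::pmap_chr(
    list(grid$has_mcrA, grid$has_mcrB, grid$has_mcrC, grid$has_mcrD,
         grid$has_mcrG, grid$hydro_steps, grid$codh_steps, grid$has_acs,
         grid$has_ack_and_acyltx, grid$n_methyl, grid$has_mtsA, grid$has_mtaA),
    oracle_guild)
}
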