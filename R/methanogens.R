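#' Derive methanogen classification features
#'
#' Collapses the per-gene annotation table, pathway completion table and
#' taxonomy into one feature row per MAG: presence of each mcr-operon gene,
#' hydrogenotrophic-methanogenesis and CODH/ACS completion fractions, acetate
#' activation routes (acetyl-CoA synthetase alone, or acetate kinase together
#' with phosphotransacetylase), methylotrophic substrate methyltransferases,
#' methylthiol transferase homologs (mtsA/mtaA) and the GTDB family. Presence
#' means at least one copy. MAGs with no completion row for a pathway are
#' treated as 0 steps present (and counted in a message).
#'
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param pathways Pathway-completion tibble ([read_pathway_completions()]).
#' @param taxonomy Taxonomy tibble ([read_taxonomy()]); optional — when
#'   absent, `family` is `""` for all MAGs.
#' @param vocabulary Vocabulary tibble ([gene_vocabulary()]).
#' @return One feature tibble row per MAG appearing in any input table.
#' @export
methanogen_features <- function(annotations, pathways, taxonomy = NULL,
                                vocabulary = gene_vocabulary()) {
  annotations <- validate_annotations(annotations, vocabulary)
  pathways <- validate_pathway_completions(pathways)
  mags <- sort(unique(c(annotations$mag_id, pathways$mag_id,
                        if (!is.null(taxonomy)) taxonomy$mag_id)))
  has_gene <- function(tok) mags %in% annotations$mag_id[annotations$gene_symbol == tok]
  frac_of <- function(pid) {
    p <- pathways[pathways$pathway_id == pid, ]
    out <- setNames(rep(0, length(mags)), mags)
    out[p$mag_id] <- p$fraction
    unname(out)
  }
  n_missing <- sum(!mags %in% pathways$mag_id[pathways$pathway_id == "HYDROGENOTROPHIC_METHANOGENESIS"])
  if (n_missing > 0) {
    rlang::inform(paste0(n_missing, " MAG(s) lack a hydrogenotrophic-methanogenesis",
                         " completion row; treated as 0 steps present"))
  }
  methyl_tokens <- vocabulary$token[vocabulary$role == "methyl_mtase"]
  methyl_sub <- setNames(vocabulary$substrate[match(methyl_tokens, vocabulary$token)],
                         methyl_tokens)
  methyl_by_mag <- annotations |>
    filter(.data$gene_symbol %in% methyl_tokens) |>
    distinct(.data$mag_id, substrate = methyl_sub[.data$gene_symbol]) |>
    group_by(.data$mag_id) |>
    summarise(methyl_substrates = paste(sort(.data$substrate), collapse = ";"),
              n_methyl = n(), .groups = "drop")
  fam <- if (is.null(taxonomy)) {
    tibble(mag_id = mags, family = "")
  } else {
    validate_taxonomy(taxonomy) |> select("mag_id", "family")
  }
  tibble(mag_id = mags,
         has_mcrA = has_gene("mcrA"), has_mcrB = has_gene("mcrB"),
         has_mcrC = has_gene("mcrC"), has_mcrD = has_gene("mcrD"),
         has_mcrG = has_gene("mcrG"),
         hydro = frac_of("HYDROGENOTROPHIC_METHANOGENESIS"),
         codh_acs = frac_of("CODH_ACS"),
         has_acs = has_gene("acs"),
         has_ack_and_acyltx = has_gene("ack") & has_gene("pta"),
         has_mtsA = has_gene("mtsA"), has_mtaA = has_gene("mtaA")) |>
    left_join(methyl_by_mag, by = "mag_id") |>
    mutate(methyl_substrates = tidyr::replace_na(.data$methyl_substrates, ""),
           n_methyl = tidyr::replace_na(.data$n_methyl, 0L)) |>
    left_join(fam, by = "mag_id") |>
    mutate(family = tidyr::replace_na(.data$family, ""))
}

#' Screen MAGs for putative methanogens
#'
#' Partitions feature rows into methanogen candidates, flagged exclusions and
#' ANME reroutes:
#' \itemize{
#'   \item `rerouted_anme` — family Methanoperedenaceae, regardless of any
#'     other predicate; these anaerobic methane oxidizers carry
#'     reverse-methanogenesis machinery and are handled by the methanotroph
#'     module.
#'   \item `candidate` — the mcrA gene is present, or the hydrogenotrophic
#'     pathway is at least `hydro_min` complete and any of mcrB/C/D/G is
#'     present.
#'   \item `excluded_no_mcr` — hydrogenotrophic completion at least
#'     `hydro_min` but no mcr-operon gene at all; reported, never classified.
#'   \item `not_methanogen` — everything else.
#' }
#'
#' @param features Feature tibble from [methanogen_features()].
#' @param thresholds [rule_thresholds()].
#' @return `features` with a `status` column prepended after `mag_id`.
#' @export
identify_putative_methanogens <- function(features, thresholds = rule_thresholds()) {
  f <- as_tibble(features)
  any_bcdg <- f$has_mcrB | f$has_mcrC | f$has_mcrD | f$has_mcrG
  any_mcr <- f$has_mcrA | any_bcdg
  hi <- .frac_ge(f$hydro, thresholds$hydro_min)
  status <- case_when(
    f$family == "Methanoperedenaceae" ~ "rerouted_anme",
    f$has_mcrA | (hi & any_bcdg) ~ "candidate",
    hi & !any_mcr ~ "excluded_no_mcr",
    .default = "not_methanogen")
  mutate(f, status = status, .after = "mag_id")
}

#' Classify methanogen candidates into substrate guilds
#'
#' Applies the guild rule ledger to candidate feature rows; the first matching
#' rule wins, in this fixed order:
#' \enumerate{
#'   \item `BROAD_SUBSTRATE` — mcrA, an acetate-activation route, CODH/ACS
#'     completion above `codh_acs_min`, hydrogenotrophic completion at least
#'     `hydro_min`, and at least one methylotrophic substrate
#'     methyltransferase: access to inorganic carbon, acetate and methylated
#'     compounds alike.
#'   \item `METHYLOTROPHIC` — mcrA plus a methyl (or methylthiol mtsA/mtaA)
#'     methyltransferase, no CODH/ACS step at all, and hydrogenotrophic
#'     completion below `hydro_low_max`, so only methylated substrates can
#'     feed methane production. `methylthiol_flag` is set when mtsA/mtaA is
#'     part of the evidence.
#'   \item `ACETOCLASTIC` — an mcr-operon gene, an acetate-activation route,
#'     CODH/ACS above `codh_acs_min` and hydrogenotrophic completion at least
#'     `hydro_min`.
#'   \item `STRICT_HYDROGENOTROPH` — mcrA (or high hydrogenotrophic
#'     completion plus another mcr gene), no CODH/ACS step, and no acetate
#'     activation.
#'   \item `UNRESOLVED_METHANOGEN` otherwise, with the partially firing
#'     predicates recorded.
#' }
#'
#' @param features Candidate feature rows (see
#'   [identify_putative_methanogens()]); rows whose `status` column (if
#'   present) is not `"candidate"` are an error.
#' @param thresholds [rule_thresholds()].
#' @return Tibble: `mag_id`, `label`, `methylthiol_flag`, `evidence`
#'   (semicolon-separated predicate names, in rule order).
#' @export
classify_guild <- function(features, thresholds = rule_thresholds()) {
  f <- as_tibble(features)
  if ("status" %in% names(f) && any(f$status != "candidate")) {
    rlang::abort("classify_guild expects candidate rows only; filter on status first")
  }
  th <- thresholds
  any_bcdg <- f$has_mcrB | f$has_mcrC | f$has_mcrD | f$has_mcrG
  any_mcr <- f$has_mcrA | any_bcdg
  acet <- f$has_acs | f$has_ack_and_acyltx
  methyl <- f$n_methyl >= 1
  thiol <- f$has_mtsA | f$has_mtaA
  hydro_hi <- .frac_ge(f$hydro, th$hydro_min)
  hydro_lo <- .frac_lt(f$hydro, th$hydro_low_max)
  codh_hi <- .frac_gt(f$codh_acs, th$codh_acs_min)
  codh_none <- .frac_zero(f$codh_acs)

  r_broad <- f$has_mcrA & acet & codh_hi & hydro_hi & methyl
  r_methyl <- f$has_mcrA & (methyl | thiol) & codh_none & hydro_lo
  r_aceto <- any_mcr & acet & codh_hi & hydro_hi
  r_strict <- (f$has_mcrA | (hydro_hi & any_bcdg)) & codh_none & !acet

  label <- case_when(r_broad ~ "BROAD_SUBSTRATE",
                     r_methyl ~ "METHYLOTROPHIC",
                     r_aceto ~ "ACETOCLASTIC",
                     r_strict ~ "STRICT_HYDROGENOTROPH",
                     .default = "UNRESOLVED_METHANOGEN")
  methylthiol_flag <- label == "METHYLOTROPHIC" & thiol

  evidence <- purrr::pmap_chr(
    list(label, f$has_mcrA, any_bcdg, acet, methyl, thiol, hydro_hi, hydro_lo,
         codh_hi, codh_none),
    function(lab, mcrA, bcdg, ac, me, thl, hhi, hlo, chi, cz) {
      ev <- switch(lab,
        BROAD_SUBSTRATE = c("has_mcrA", "acetate_activation",
                            "codh_acs>codh_acs_min", "hydro>=hydro_min",
                            "methyl_substrate"),
        METHYLOTROPHIC = c("has_mcrA", if (me) "methyl_substrate",
                           if (thl) "methylthiol_transferase",
                           "codh_acs==0", "hydro<hydro_low_max"),
        ACETOCLASTIC = c(if (mcrA) "has_mcrA" else "has_mcrBCDG",
                         "acetate_activation", "codh_acs>codh_acs_min",
                         "hydro>=hydro_min"),
        STRICT_HYDROGENOTROPH = c(if (mcrA) "has_mcrA" else c("hydro>=hydro_min", "has_mcrBCDG"),
                                  "codh_acs==0", "no_acetate_activation"),
        UNRESOLVED_METHANOGEN = c(if (mcrA) "has_mcrA", if (bcdg) "has_mcrBCDG",
                                  if (ac) "acetate_activation",
                                  if (me) "methyl_substrate",
                                  if (thl) "methylthiol_transferase",
                                  if (hhi) "hydro>=hydro_min",
                                  if (hlo) "hydro<hydro_low_max",
                                  if (chi) "codh_acs>codh_acs_min",
                                  if (cz) "codh_acs==0"))
      paste(ev, collapse = ";")
    })

  tibble(mag_id = f$mag_id, label = label,
         methylthiol_flag = methylthiol_flag, evidence = evidence)
}

#' Identify and classify methanogens in one call
#'
#' Runs [methanogen_features()], [identify_putative_methanogens()] and
#' [classify_guild()], returning one row per MAG that is methanogen-relevant:
#' candidates get a guild label, MAGs with high hydrogenotrophic completion
#' but no mcr gene are labelled `EXCLUDED_NO_MCR`, and Methanoperedenaceae
#' MAGs are labelled `REROUTED_ANME`. Ordinary non-methanogen MAGs are
#' omitted.
#'
#' @inheritParams methanogen_features
#' @param thresholds [rule_thresholds()].
#' @return Tibble: `mag_id`, `label`, `methylthiol_flag`, `evidence`,
#'   `family`.
#' @export
classify_methanogens <- function(annotations, pathways, taxonomy = NULL,
                                 thresholds = rule_thresholds(),
                                 vocabulary = gene_vocabulary()) {
  feats <- methanogen_features(annotations, pathways, taxonomy, vocabulary) |>
    identify_putative_methanogens(thresholds)
  candidates <- filter(feats, .data$status == "candidate")
  calls <- if (nrow(candidates) > 0) {
    classify_guild(select(candidates, -"status"), thresholds) |>
      left_join(select(candidates, "mag_id", "family"), by = "mag_id")
  } else {
    tibble(mag_id = character(), label = character(),
           methylthiol_flag = logical(), evidence = character(),
           family = character())
  }
  flagged <- feats |>
    filter(.data$status %in% c("excluded_no_mcr", "rerouted_anme")) |>
    transmute(.data$mag_id,
              label = if_else(.data$status == "excluded_no_mcr",
                              "EXCLUDED_NO_MCR", "REROUTED_ANME"),
              methylthiol_flag = FALSE,
              evidence = if_else(.data$status == "excluded_no_mcr",
                                 "hydro>=hydro_min;no_mcr_genes",
                                 "family==Methanoperedenaceae"),
              family = .data$family)
  bind_rows(calls, flagged) |> arrange(.data$mag_id)
}

#' Full methanogen feature grid
#'
#' Enumerates every combination of the discrete feature space the guild rules
#' see: the 5 mcr-operon booleans, hydrogenotrophic steps 0..8 (of 8),
#' CODH/ACS steps 0..2 (of 2), the two acetate-activation booleans, presence
#' of each of the four methylotrophic substrate classes, and mtsA/mtaA. Used
#' for brute-force audits of the rule engine.
#'
#' @return Feature tibble with one row per cell (221,184 rows).
#' @export
methanogen_feature_grid <- function() {
  g <- expand.grid(has_mcrA = c(FALSE, TRUE), has_mcrB = c(FALSE, TRUE),
                   has_mcrC = c(FALSE, TRUE), has_mcrD = c(FALSE, TRUE),
                   has_mcrG = c(FALSE, TRUE),
                   hydro_steps = 0:8, codh_steps = 0:2,
                   has_acs = c(FALSE, TRUE), has_ack_and_acyltx = c(FALSE, TRUE),
                   methanol = c(FALSE, TRUE), trimethylamine = c(FALSE, TRUE),
                   dimethylamine = c(FALSE, TRUE), methylamine = c(FALSE, TRUE),
                   has_mtsA = c(FALSE, TRUE), has_mtaA = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE) |>
    as_tibble()
  g |>
    mutate(mag_id = sprintf("cell_%06d", seq_len(nrow(g))),
           hydro = .data$hydro_steps / 8,
           codh_acs = .data$codh_steps / 2,
           n_methyl = .data$methanol + .data$trimethylamine +
             .data$dimethylamine + .data$methylamine,
           methyl_substrates = "", family = "") |>
    relocate("mag_id")
}

#' Rule-overlap diagnostic
#'
#' Evaluates all four guild rules independently over the full feature grid and
#' reports the cells where more than one rule matches — the cells whose label
#' depends on the fixed first-match order. By construction the broad-substrate
#' rule implies the acetoclastic rule, and the methylotrophic and
#' strict-hydrogenotroph rules can co-fire when a methyl gene is present with
#' no CODH/ACS and low hydrogenotrophic completion; no other overlaps exist at
#' the default thresholds.
#'
#' @param thresholds [rule_thresholds()].
#' @return Tibble of overlapping cells with logical columns `r_broad`,
#'   `r_methyl`, `r_aceto`, `r_strict` and a `rules` summary string.
#' @export
guild_rule_overlaps <- function(thresholds = rule_thresholds()) {
  f <- methanogen_feature_grid()
  th <- thresholds
  any_bcdg <- f$has_mcrB | f$has_mcrC | f$has_mcrD | f$has_mcrG
  acet <- f$has_acs | f$has_ack_and_acyltx
  methyl <- f$n_methyl >= 1
  thiol <- f$has_mtsA | f$has_mtaA
  hydro_hi <- .frac_ge(f$hydro, th$hydro_min)
  hydro_lo <- .frac_lt(f$hydro, th$hydro_low_max)
  codh_hi <- .frac_gt(f$codh_acs, th$codh_acs_min)
  codh_none <- .frac_zero(f$codh_acs)
  f |>
    mutate(r_broad = .data$has_mcrA & acet & codh_hi & hydro_hi & methyl,
           r_methyl = .data$has_mcrA & (methyl | thiol) & codh_none & hydro_lo,
           r_aceto = (.data$has_mcrA | any_bcdg) & acet & codh_hi & hydro_hi,
           r_strict = (.data$has_mcrA | (hydro_hi & any_bcdg)) & codh_none & !acet) |>
    filter(.data$r_broad + .data$r_methyl + .data$r_aceto + .data$r_strict > 1) |>
    mutate(rules = paste0(if_else(.data$r_broad, "broad+", ""),
                          if_else(.data$r_methyl, "methylotrophic+", ""),
                          if_else(.data$r_aceto, "acetoclastic+", ""),
                          if_else(.data$r_strict, "strict+", "")),
           rules = sub("\\+$", "", .data$rules))
}
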