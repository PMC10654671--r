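#' Identify putative methanotroph MAGs
#'
#' A MAG is called a putative aerobic (or intra-aerobic) methanotroph when it
#' carries the pmoA and/or mmoX marker genes: `PMO_ONLY` (pmoA without mmoX),
#' `MMO_ONLY` (the converse) or `BOTH`. MAGs from the family
#' Methanoperedenaceae are anaerobic methane oxidizers and are called `ANME`
#' on taxonomy alone, with no pmoA/mmoX requirement; they are tallied apart
#' from the aerobic modes. Calls in families with no previously characterized
#' methanotrophs are put through scaffold verification
#' ([verify_novel_family()]): at least `min_verify_gene_count` pmo/mmo-family
#' gene observations must sit on scaffolds of at least
#' `min_verify_scaffold_bp` bp (genes may be split across qualifying
#' scaffolds). Unverified calls are retained but flagged `verified = FALSE`.
#'
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param taxonomy Taxonomy tibble ([read_taxonomy()]); optional.
#' @param thresholds [rule_thresholds()].
#' @param known_families Families exempt from verification; defaults to
#'   [known_methanotroph_families()].
#' @param vocabulary Vocabulary tibble.
#' @return Tibble: `mag_id`, `mode`, `family`, `known_family`, `verified`,
#'   `evidence`.
#' @export
classify_methanotrophs <- function(annotations, taxonomy = NULL,
                                   thresholds = rule_thresholds(),
                                   known_families = known_methanotroph_families(),
                                   vocabulary = gene_vocabulary()) {
  annotations <- validate_annotations(annotations, vocabulary)
  fam <- if (is.null(taxonomy)) {
    tibble(mag_id = character(), family = character())
  } else {
    validate_taxonomy(taxonomy) |> select("mag_id", "family")
  }
  mags <- sort(unique(c(annotations$mag_id, fam$mag_id)))
  has_gene <- function(tok) mags %in% annotations$mag_id[annotations$gene_symbol == tok]
  family <- fam$family[match(mags, fam$mag_id)]
  family[is.na(family)] <- ""
  has_pmoA <- has_gene("pmoA")
  has_mmoX <- has_gene("mmoX")
  mode <- case_when(family == "Methanoperedenaceae" ~ "ANME",
                    has_pmoA & has_mmoX ~ "BOTH",
                    has_pmoA ~ "PMO_ONLY",
                    has_mmoX ~ "MMO_ONLY",
                    .default = NA_character_)
  calls <- tibble(mag_id = mags, mode = mode, family = family,
                  known_family = family %in% known_families) |>
    filter(!is.na(.data$mode))
  mmo_tokens <- vocabulary$token[vocabulary$role %in% c("pmmo", "smmo")]
  calls |>
    mutate(verified = if_else(.data$known_family, TRUE,
                              purrr::map_lgl(.data$mag_id, verify_novel_family,
                                             annotations = annotations,
                                             thresholds = thresholds,
                                             mmo_tokens = mmo_tokens)),
           evidence = paste0(
             case_when(.data$mode == "ANME" ~ "family==Methanoperedenaceae",
                       .data$mode == "BOTH" ~ "has_pmoA;has_mmoX",
                       .data$mode == "PMO_ONLY" ~ "has_pmoA",
                       .default = "has_mmoX"),
             if_else(.data$known_family, ";known_methanotroph_family",
                     if_else(.data$verified, ";scaffold_verified",
                             ";scaffold_verification_failed")))) |>
    arrange(.data$mag_id)
}

#' Scaffold verification for methanotroph calls in novel families
#'
#' For a family with no known methanotrophs, the call is considered verified
#' when at least `min_verify_gene_count` observations of pMMO/sMMO genes
#' (pmoA/pmoB/pmoC, mmoX/mmoY/mmoZ) occur on scaffolds each at least
#' `min_verify_scaffold_bp` bp long. Genes may be split across several
#' qualifying scaffolds; duplicate observations of the same gene on the same
#' scaffold count once.
#'
#' @param mag_id MAG to verify.
#' @param annotations Validated annotation tibble.
#' @param thresholds [rule_thresholds()].
#' @param mmo_tokens pMMO/sMMO vocabulary tokens.
#' @return Logical scalar.
#' @export
verify_novel_family <- function(mag_id, annotations,
                                thresholds = rule_thresholds(),
                                mmo_tokens = NULL) {
  if (is.null(mmo_tokens)) {
    voc <- gene_vocabulary()
    mmo_tokens <- voc$token[voc$role %in% c("pmmo", "smmo")]
  }
  hits <- annotations |>
    filter(.data$mag_id == !!mag_id,
           .data$gene_symbol %in% mmo_tokens,
           .data$scaffold_length >= thresholds$min_verify_scaffold_bp) |>
    distinct(.data$gene_symbol, .data$scaffold_id)
  nrow(hits) >= thresholds$min_verify_gene_count
}

#' Trait tallies over the aerobic methanotroph set
#'
#' For the aerobic/intra-aerobic methanotroph calls (`PMO_ONLY`, `MMO_ONLY`,
#' `BOTH`; ANME excluded), counts how many MAGs carry nitrite-reduction genes
#' (nirK or nirS), nitrate-reduction genes (narG or napA), and high completion
#' of the high- and low-affinity respiratory complex IV modules.
#'
#' @param calls Call tibble from [classify_methanotrophs()].
#' @param annotations Annotation tibble.
#' @param pathways Pathway-completion tibble (for the complex IV modules
#'   `COMPLEX_IV_HIGH` / `COMPLEX_IV_LOW`).
#' @param thresholds [rule_thresholds()]; `high_completion_min` sets the
#'   completion cutoff.
#' @return Tibble: `trait`, `n_with_trait`, `n_methanotrophs`.
#' @export
methanotroph_trait_tally <- function(calls, annotations, pathways,
                                     thresholds = rule_thresholds()) {
  aerobes <- filter(as_tibble(calls), .data$mode != "ANME")$mag_id
  annotations <- filter(validate_annotations(annotations), .data$mag_id %in% aerobes)
  pathways <- filter(validate_pathway_completions(pathways), .data$mag_id %in% aerobes)
  has_any <- function(toks) {
    length(unique(annotations$mag_id[annotations$gene_symbol %in% toks]))
  }
  complete_iv <- function(pid) {
    p <- filter(pathways, .data$pathway_id == pid,
                .frac_ge(.data$fraction, thresholds$high_completion_min))
    length(unique(p$mag_id))
  }
  tibble(trait = c("nitrite_reduction", "nitrate_reduction",
                   "complex_iv_high_affinity", "complex_iv_low_affinity"),
         n_with_trait = c(has_any(c("nirK", "nirS")),
                          has_any(c("narG", "napA")),
                          complete_iv("COMPLEX_IV_HIGH"),
                          complete_iv("COMPLEX_IV_LOW")),
         n_methanotrophs = length(aerobes))
}
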