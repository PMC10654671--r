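#' Derive acetogen screening features
#'
#' One row per MAG: Wood-Ljungdahl (7-step default) and CODH/ACS (2-step
#' default) completion fractions plus presence of phosphotransacetylase (pta)
#' and acetate kinase (ack).
#'
#' @inheritParams methanogen_features
#' @return Feature tibble: `mag_id`, `wl`, `codh_acs`, `has_pta`, `has_ack`.
#' @export
acetogen_features <- function(annotations, pathways,
                              vocabulary = gene_vocabulary()) {
  annotations <- validate_annotations(annotations, vocabulary)
  pathways <- validate_pathway_completions(pathways)
  mags <- sort(unique(c(annotations$mag_id, pathways$mag_id)))
  frac_of <- function(pid) {
    p <- pathways[pathways$pathway_id == pid, ]
    out <- setNames(rep(0, length(mags)), mags)
    out[p$mag_id] <- p$fraction
    unname(out)
  }
  tibble(mag_id = mags,
         wl = frac_of("WOOD_LJUNGDAHL"),
         codh_acs = frac_of("CODH_ACS"),
         has_pta = mags %in% annotations$mag_id[annotations$gene_symbol == "pta"],
         has_ack = mags %in% annotations$mag_id[annotations$gene_symbol == "ack"])
}

#' Classify MAGs into acetate-production categories
#'
#' Four categories capture a range of acetogenic potential:
#' \describe{
#'   \item{I}{Wood-Ljungdahl completion at least `wl_min` (6/7 by default)
#'     together with phosphotransacetylase and acetate kinase — the methyl
#'     branch of the WL pathway.}
#'   \item{II}{Complete (2/2) CODH/ACS together with phosphotransacetylase and
#'     acetate kinase — the carbonyl branch.}
#'   \item{III}{Wood-Ljungdahl at least `wl_min` but lacking the
#'     phosphotransacetylase/acetate kinase pair — flagged for further
#'     investigation.}
#'   \item{IV}{Phosphotransacetylase and acetate kinase, regardless of the
#'     pathways — acetate production from acetyl-CoA alone.}
#' }
#' Categories overlap by construction (I and II each imply IV; III excludes
#' IV); every matching category is reported, and the `primary` label is the
#' most specific in the order I > II > IV, with III standing alone.
#'
#' @param features Feature tibble from [acetogen_features()].
#' @param thresholds [rule_thresholds()].
#' @return Tibble: `mag_id`, `categories` (comma-separated, e.g. `"I,IV"`,
#'   empty when none match), `primary` (`NA` when none match).
#' @export
#' @examples
#' f <- tibble::tibble(mag_id = "m1", wl = 6 / 7, codh_acs = 0.5,
#'                     has_pta = TRUE, has_ack = TRUE)
#' classify_acetogens(f)
classify_acetogens <- function(features, thresholds = rule_thresholds()) {
  f <- as_tibble(features)
  pair <- f$has_pta & f$has_ack
  wl_hi <- .frac_ge(f$wl, thresholds$wl_min)
  cat_i <- wl_hi & pair
  cat_ii <- .frac_ge(f$codh_acs, 1) & pair
  cat_iii <- wl_hi & !pair
  cat_iv <- pair
  tibble(mag_id = f$mag_id,
         cat_I = cat_i, cat_II = cat_ii, cat_III = cat_iii, cat_IV = cat_iv) |>
    mutate(categories = purrr::pmap_chr(list(cat_i, cat_ii, cat_iii, cat_iv),
             function(a, b, c, d) paste(c("I", "II", "III", "IV")[c(a, b, c, d)],
                                        collapse = ",")),
           primary = case_when(cat_i ~ "I", cat_ii ~ "II", cat_iii ~ "III",
                               cat_iv ~ "IV", .default = NA_character_))
}

#' Full acetogen feature grid
#'
#' Every combination of Wood-Ljungdahl steps 0..7 (of 7), CODH/ACS steps 0..2
#' (of 2) and the pta/ack booleans, for brute-force audits of the category
#' containments (I and II each imply IV; III and IV are disjoint).
#'
#' @return Feature tibble with 96 rows.
#' @export
acetogen_feature_grid <- function() {
  g <- expand.grid(wl_steps = 0:7, codh_steps = 0:2,
                   has_pta = c(FALSE, TRUE), has_ack = c(FALSE, TRUE),
                   KEEP.OUT.ATTRS = FALSE) |> as_tibble()
  g |>
    mutate(mag_id = sprintf("cell_%03d", seq_len(nrow(g))),
           wl = .data$wl_steps / 7, codh_acs = .data$codh_steps / 2) |>
    relocate("mag_id")
}
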