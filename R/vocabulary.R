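#' Gene vocabulary
#'
#' The controlled vocabulary of gene symbols used by the guild rule engines.
#' Each token carries a functional role (e.g. `mcr_operon`, `pmmo`, `smmo`,
#' `methyl_mtase`, `acetate_activation`), an optional methylotrophic substrate,
#' and a comma-separated list of aliases covering the label dialects used by
#' annotation tools (e.g. both \dQuote{Acetate pt 1} for acetyl-CoA synthetase
#' and \dQuote{acetate pt. 1} for phosphotransacetylase resolve to unambiguous
#' tokens). The vocabulary ships as an editable TSV so that rule logic stays
#' decoupled from any particular annotation dialect.
#'
#' @param file Path to a vocabulary TSV (columns `token`, `role`, `substrate`,
#'   `description`, `aliases`; `.` marks missing). Defaults to the table
#'   shipped with the package.
#' @return A tibble with one row per token.
#' @export
#' @examples
#' vocab <- gene_vocabulary()
#' vocab[vocab$role == "mcr_operon", ]
gene_vocabulary <- function(file = NULL) {
  file <- file %||% system.file("extdata", "gene_vocabulary.tsv",
                                package = "methaneguilds", mustWork = TRUE)
  voc <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE)
  required <- c("token", "role")
  missing <- setdiff(required, names(voc))
  if (length(missing) > 0) {
    rlang::abort(paste0("vocabulary file lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(voc$token)) {
    rlang::abort("vocabulary tokens must be unique")
  }
  voc
}

#' Map gene labels to vocabulary tokens
#'
#' Resolves raw gene labels against the vocabulary: exact token matches pass
#' through; otherwise aliases are tried (exact match after trimming). Labels
#' matching nothing are returned as `NA` so callers can report them.
#'
#' @param labels Character vector of raw gene labels.
#' @param vocabulary A vocabulary tibble from [gene_vocabulary()].
#' @return Character vector of tokens, `NA` where unrecognized.
#' @export
resolve_gene_labels <- function(labels, vocabulary = gene_vocabulary()) {
  labels <- stringr::str_trim(labels)
  alias_map <- vocabulary |>
    filter(!is.na(.data$aliases)) |>
    mutate(alias = stringr::str_split(.data$aliases, ",")) |>
    tidyr::unnest_longer("alias") |>
    mutate(alias = stringr::str_trim(.data$alias)) |>
    select("alias", "token")
  out <- ifelse(labels %in% vocabulary$token, labels, NA_character_)
  hit <- match(labels, alias_map$alias)
  out[is.na(out) & !is.na(hit)] <- alias_map$token[hit[is.na(out) & !is.na(hit)]]
  out
}

#' Rule thresholds for guild classification
#'
#' Bundles the numeric cutoffs used across the methanogen, methanotroph and
#' acetogen rule engines.
#'
#' @param hydro_min Minimum hydrogenotrophic-methanogenesis pathway completion
#'   (inclusive) treated as "high completion"; default 0.75, i.e. 6 of 8 steps.
#' @param hydro_low_max Upper bound (exclusive) defining "low completion" of
#'   the hydrogenotrophic pathway for methylotrophs; default 0.50.
#' @param codh_acs_min Completion of the CODH/ACS complex that must be
#'   exceeded (strictly) for acetoclastic calls; default 0.50, so with the
#'   2-step module only 2/2 qualifies.
#' @param wl_min Minimum Wood-Ljungdahl completion (inclusive) for acetogen
#'   categories i and iii; default 6/7.
#' @param min_verify_scaffold_bp Minimum scaffold length (bp) for scaffold
#'   verification of methanotroph calls in families without known
#'   methanotrophs; default 3000.
#' @param min_verify_gene_count Minimum number of pmo/mmo gene observations on
#'   qualifying scaffolds for verification; default 2.
#' @param high_completion_min Completion treated as "high" for respiratory
#'   complex IV trait tallies; default 0.75.
#' @return A named list with class `mg_thresholds`.
#' @export
#' @examples
#' rule_thresholds()
#' rule_thresholds(hydro_min = 0.8)
rule_thresholds <- function(hydro_min = 0.75,
                            hydro_low_max = 0.50,
                            codh_acs_min = 0.50,
                            wl_min = 6 / 7,
                            min_verify_scaffold_bp = 3000L,
                            min_verify_gene_count = 2L,
                            high_completion_min = 0.75) {
  fracs <- c(hydro_min = hydro_min, hydro_low_max = hydro_low_max,
             codh_acs_min = codh_acs_min, wl_min = wl_min,
             high_completion_min = high_completion_min)
  if (any(fracs < 0 | fracs > 1)) {
    rlang::abort("all fractional thresholds must lie in [0, 1]")
  }
  if (hydro_low_max > hydro_min) {
    rlang::abort("hydro_low_max must not exceed hydro_min")
  }
  if (min_verify_scaffold_bp < 0 || min_verify_gene_count < 1) {
    rlang::abort("verification thresholds out of range")
  }
  structure(list(hydro_min = hydro_min,
                 hydro_low_max = hydro_low_max,
                 codh_acs_min = codh_acs_min,
                 wl_min = wl_min,
                 min_verify_scaffold_bp = as.integer(min_verify_scaffold_bp),
                 min_verify_gene_count = as.integer(min_verify_gene_count),
                 high_completion_min = high_completion_min),
            class = "mg_thresholds")
}

## fraction comparisons with a small guard against binary representation of
## ratios like 6/7; steps are small integers so 1e-9 can never cross a cell
.frac_ge <- function(x, t, tol = 1e-9) x >= t - tol
.frac_gt <- function(x, t, tol = 1e-9) x > t + tol
.frac_lt <- function(x, t, tol = 1e-9) x < t - tol
.frac_zero <- function(x, tol = 1e-9) x <= tol

#' Families with previously characterized methanotrophs
#'
#' Used to decide whether a putative methanotroph call needs scaffold-level
#' verification: calls in families on this list are taken at face value, calls
#' in any other family must pass [verify_novel_family()].
#'
#' @return Character vector of GTDB family names.
#' @export
known_methanotroph_families <- function() {
  c("Methylomonadaceae", "Methylococcaceae", "Methylacidiphilaceae",
    "Methylomirabilaceae", "Methanoperedenaceae")
}
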