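#' GTDB family synonym map
#'
#' The curated mapping from legacy taxon names (species, genera and families
#' as reported across the landfill literature, under older nomenclatures such
#' as NCBI, SILVA or Greengenes) to GTDB family names (release 89
#' convention), with a provenance note per rule. Ships as an editable TSV;
#' every key must map to exactly one family.
#'
#' @param file Path to a synonym TSV (columns `legacy_name`, `rank`,
#'   `gtdb_family`, `note`); defaults to the table shipped with the package.
#' @return Tibble of synonym rules.
#' @export
gtdb_synonyms <- function(file = NULL) {
  file <- file %||% system.file("extdata", "gtdb_family_synonyms.tsv",
                                package = "methaneguilds", mustWork = TRUE)
  map <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE)
  map <- .require_columns(map, c("legacy_name", "gtdb_family"), "synonym")
  key <- .normalize_name(map$legacy_name)
  clash <- tapply(map$gtdb_family, key, function(v) length(unique(v)) > 1)
  if (any(clash)) {
    rlang::abort(paste0("ambiguous synonym key(s): ",
                        paste(names(clash)[clash], collapse = ", ")))
  }
  map
}

.normalize_name <- function(x) {
  stringr::str_to_lower(stringr::str_squish(stringr::str_trim(x)))
}

#' Harmonize reported taxon names to GTDB families
#'
#' Exact-match lookup (after whitespace squeezing and case folding) of a
#' reported name against the synonym map; species and genus names resolve
#' through their family. A name that is already a GTDB family in the map's
#' image returns itself, so harmonization is idempotent. Names matching
#' nothing return `"UNRESOLVED"` — never a guess.
#'
#' @param name Character vector of reported taxon names.
#' @param map Synonym tibble from [gtdb_synonyms()].
#' @return Character vector of GTDB family names or `"UNRESOLVED"`.
#' @export
#' @examples
#' harmonize(c("Methanosaetaceae", "Methanotrichaceae", "Nosuchtaxon"))
harmonize <- function(name, map = gtdb_synonyms()) {
  key <- .normalize_name(name)
  hit <- map$gtdb_family[match(key, .normalize_name(map$legacy_name))]
  self <- key %in% .normalize_name(unique(map$gtdb_family))
  out <- ifelse(!is.na(hit), hit,
                ifelse(self, unique(map$gtdb_family)[match(key, .normalize_name(unique(map$gtdb_family)))],
                       "UNRESOLVED"))
  out
}

#' Read a study-report table for the occurrence meta-analysis
#'
#' @inheritParams read_annotations
#' @return Tibble with `study_id`, `method`, `taxon_name`, `rank_claimed`.
#' @export
read_study_reports <- function(path, delim = "\t") {
  .read_table(path, delim,
              required = c("study_id", "method", "taxon_name", "rank_claimed"),
              types = readr::cols(.default = readr::col_character()))
}

#' Family-by-study presence matrix
#'
#' Harmonizes every reported taxon and builds the logical presence matrix
#' (GTDB families in rows, studies in columns). A study is retained only if
#' at least one of its taxa resolves to the family level or deeper; studies
#' whose taxa all stay above family (or unresolved) are dropped and do not
#' contribute a column. Any single resolvable report marks presence —
#' abundance is deliberately not weighed.
#'
#' @param reports Study-report tibble (`study_id`, `taxon_name`, optional
#'   `method`, `rank_claimed`).
#' @param map Synonym tibble from [gtdb_synonyms()].
#' @return Logical matrix with families as rows (sorted) and retained studies
#'   as columns (sorted); attribute `dropped_studies` lists discarded study
#'   ids.
#' @export
presence_matrix <- function(reports, map = gtdb_synonyms()) {
  reports <- .require_columns(as_tibble(reports), c("study_id", "taxon_name"),
                              "study report")
  resolved <- reports |>
    mutate(family = harmonize(.data$taxon_name, map)) |>
    filter(.data$family != "UNRESOLVED") |>
    distinct(.data$study_id, .data$family)
  retained <- sort(unique(resolved$study_id))
  dropped <- setdiff(unique(reports$study_id), retained)
  if (length(retained) == 0) rlang::abort("no study retained after harmonization")
  fams <- sort(unique(resolved$family))
  m <- matrix(FALSE, nrow = length(fams), ncol = length(retained),
              dimnames = list(fams, retained))
  m[cbind(match(resolved$family, fams), match(resolved$study_id, retained))] <- TRUE
  attr(m, "dropped_studies") <- dropped
  m
}

#' Per-family occurrence counts
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @return Tibble: `family`, `n_present` (studies reporting the family),
#'   `n_studies` (retained studies, the denominator), sorted by descending
#'   occurrence.
#' @export
occurrence_counts <- function(matrix) {
  if (length(matrix) == 0) rlang::abort("presence matrix is empty")
  tibble(family = rownames(matrix),
         n_present = as.integer(rowSums(matrix)),
         n_studies = ncol(matrix)) |>
    arrange(desc(.data$n_present), .data$family)
}

#' Occurrence lollipop plot
#'
#' @param counts Tibble from [occurrence_counts()].
#' @return A ggplot object: families ordered by occurrence, one segment+point
#'   per family.
#' @export
plot_occurrence <- function(counts) {
  counts <- as_tibble(counts) |>
    mutate(family = factor(.data$family, levels = rev(unique(.data$family))))
  ggplot(counts, aes(x = .data$family, y = .data$n_present)) +
    geom_segment(aes(xend = .data$family, yend = 0), colour = "grey60") +
    geom_point(size = 3) +
    coord_flip() +
    scale_y_continuous(limits = c(0, max(counts$n_studies))) +
    labs(x = NULL, y = paste0("studies reporting family (of ",
                              max(counts$n_studies), ")")) +
    theme_minimal()
}
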