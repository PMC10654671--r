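#' Read a per-gene annotation table
#'
#' Reads the tab-separated per-gene annotation table (one row per observation
#' of a gene on a scaffold of a MAG). Gene symbols are checked against the
#' controlled vocabulary; rows with unrecognized symbols are retained and the
#' offending tokens are collected in the `unrecognized` attribute (see
#' [unrecognized_genes()]) rather than silently dropped.
#'
#' @param path Path to a TSV (or CSV with `delim = ","`) with header columns
#'   `mag_id`, `gene_symbol`, `scaffold_id`, `scaffold_length` and optionally
#'   `site_id`.
#' @param vocabulary Vocabulary tibble from [gene_vocabulary()].
#' @param delim Field delimiter; tab by default.
#' @return Tibble of validated annotation rows; attribute `unrecognized` holds
#'   the unique gene symbols not found in the vocabulary.
#' @export
read_annotations <- function(path, vocabulary = gene_vocabulary(), delim = "\t") {
  x <- .read_table(path, delim,
                   required = c("mag_id", "gene_symbol", "scaffold_id", "scaffold_length"),
                   types = readr::cols(scaffold_length = readr::col_double(),
                                       .default = readr::col_character()))
  validate_annotations(x, vocabulary)
}

#' Validate an annotation table
#'
#' @param x Data frame with annotation columns (see [read_annotations()]).
#' @inheritParams read_annotations
#' @return The validated tibble with `scaffold_length` as integer and the
#'   `unrecognized` attribute set.
#' @export
validate_annotations <- function(x, vocabulary = gene_vocabulary()) {
  x <- .require_columns(as_tibble(x),
                        c("mag_id", "gene_symbol", "scaffold_id", "scaffold_length"),
                        "annotation")
  bad <- which(is.na(x$scaffold_length) | x$scaffold_length < 0)
  if (length(bad) > 0) {
    rlang::abort(paste0("negative or missing scaffold_length at row(s): ",
                        paste(head(bad, 5), collapse = ", ")))
  }
  x$scaffold_length <- as.integer(x$scaffold_length)
  unknown <- sort(unique(x$gene_symbol[!x$gene_symbol %in% vocabulary$token]))
  if (length(unknown) > 0) {
    rlang::inform(paste0("annotation table contains ", length(unknown),
                         " gene symbol(s) outside the vocabulary: ",
                         paste(head(unknown, 10), collapse = ", ")))
  }
  attr(x, "unrecognized") <- unknown
  x
}

#' Unrecognized gene symbols collected during validation
#'
#' @param x A tibble returned by [read_annotations()] / [validate_annotations()].
#' @return Character vector (possibly empty) of out-of-vocabulary symbols.
#' @export
unrecognized_genes <- function(x) {
  attr(x, "unrecognized") %||% character(0)
}

#' Read a per-MAG pathway-completion table
#'
#' One row per (MAG, pathway) with stepwise completion held as the exact pair
#' `steps_present` / `steps_total`; the derived `fraction` column is added on
#' read. Default step totals per pathway are 8 for hydrogenotrophic
#' methanogenesis, 2 for CODH/ACS and 7 for the Wood-Ljungdahl pathway; rows
#' for other pathways must carry an explicit `steps_total`.
#'
#' @inheritParams read_annotations
#' @return Tibble with columns `mag_id`, `pathway_id`, `steps_present`,
#'   `steps_total`, `fraction`.
#' @export
read_pathway_completions <- function(path, delim = "\t") {
  x <- .read_table(path, delim,
                   required = c("mag_id", "pathway_id", "steps_present"),
                   types = readr::cols(steps_present = readr::col_double(),
                                       .default = readr::col_character()))
  if ("steps_total" %in% names(x)) x$steps_total <- as.numeric(x$steps_total)
  validate_pathway_completions(x)
}

#' Default number of steps for the stepwise pathway modules
#' @return Named integer vector keyed by pathway id.
#' @export
default_pathway_steps <- function() {
  c(HYDROGENOTROPHIC_METHANOGENESIS = 8L, CODH_ACS = 2L, WOOD_LJUNGDAHL = 7L,
    COMPLEX_IV_HIGH = 4L, COMPLEX_IV_LOW = 3L, CALVIN = 11L)
}

#' Validate a pathway-completion table
#' @param x Data frame with `mag_id`, `pathway_id`, `steps_present` and
#'   optionally `steps_total` (filled from [default_pathway_steps()] when
#'   absent).
#' @return Validated tibble with exact `fraction` column.
#' @export
validate_pathway_completions <- function(x) {
  x <- .require_columns(as_tibble(x), c("mag_id", "pathway_id", "steps_present"),
                        "pathway completion")
  if (!"steps_total" %in% names(x)) x$steps_total <- NA_real_
  defaults <- default_pathway_steps()
  fill <- is.na(x$steps_total)
  x$steps_total[fill] <- defaults[x$pathway_id[fill]]
  if (anyNA(x$steps_total)) {
    rlang::abort(paste0("steps_total missing and no default for pathway(s): ",
                        paste(unique(x$pathway_id[is.na(x$steps_total)]), collapse = ", ")))
  }
  x$steps_present <- as.integer(x$steps_present)
  x$steps_total <- as.integer(x$steps_total)
  x$fraction <- completion_fraction(x$steps_present, x$steps_total)
  x
}

#' Pathway completion as a fraction
#'
#' @param steps_present,steps_total Integer vectors, `0 <= steps_present <=
#'   steps_total`, `steps_total >= 1`.
#' @return `steps_present / steps_total`, exactly.
#' @export
#' @examples
#' completion_fraction(6, 8)  # 0.75
completion_fraction <- function(steps_present, steps_total) {
  if (any(steps_total < 1)) rlang::abort("steps_total must be >= 1")
  if (any(steps_present < 0)) rlang::abort("steps_present must be >= 0")
  if (any(steps_present > steps_total)) {
    rlang::abort("steps_present exceeds steps_total")
  }
  steps_present / steps_total
}

#' Parse GTDB lineage strings
#'
#' Splits 7-rank GTDB lineage strings (`d__...;p__...;...;s__...`) into rank
#' columns. Trailing ranks may be omitted; an empty value after a prefix means
#' unclassified at that rank, and every rank below the first unclassified rank
#' must also be unclassified. Prefixes out of order or unknown are an error.
#'
#' @param lineage Character vector of lineage strings.
#' @return Tibble with columns `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species` (empty string = unclassified).
#' @export
#' @examples
#' parse_gtdb_lineage("d__Archaea;p__Halobacterota;c__Methanosarcinia;o__Methanosarcinales;f__Methanosarcinaceae;g__Methanosarcina;s__")
parse_gtdb_lineage <- function(lineage) {
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  parse_one <- function(s) {
    if (is.na(s) || !nzchar(stringr::str_trim(s))) {
      rlang::abort("lineage string must be non-empty")
    }
    parts <- stringr::str_trim(stringr::str_split(s, ";")[[1]])
    if (length(parts) > 7) rlang::abort(paste0("too many ranks in lineage: ", s))
    got <- substr(parts, 1, 3)
    if (!identical(got, prefixes[seq_along(parts)])) {
      rlang::abort(paste0("malformed or out-of-order rank prefix in lineage: ", s))
    }
    vals <- substring(parts, 4)
    vals <- c(vals, rep("", 7 - length(vals)))
    filled <- nzchar(vals)
    if (any(filled & cumsum(!filled) > 0)) {
      rlang::abort(paste0("classified rank below an unclassified rank in lineage: ", s))
    }
    setNames(as.list(vals), ranks)
  }
  purrr::map(lineage, parse_one) |> bind_rows()
}

#' Read a MAG taxonomy table
#'
#' Accepts either a `classification` column of GTDB lineage strings or the
#' seven explicit rank columns (`domain` ... `species`), keyed by `mag_id`
#' with an optional `site_id`.
#'
#' @inheritParams read_annotations
#' @return Tibble with `mag_id`, optional `site_id`, and the 7 rank columns.
#' @export
read_taxonomy <- function(path, delim = "\t") {
  x <- .read_table(path, delim, required = "mag_id",
                   types = readr::cols(.default = readr::col_character()))
  validate_taxonomy(x)
}

#' Validate a taxonomy table
#' @param x Data frame with `mag_id` and either a `classification` lineage
#'   column or 7 rank columns.
#' @return Tibble with explicit rank columns, empty string = unclassified.
#' @export
validate_taxonomy <- function(x) {
  x <- .require_columns(as_tibble(x), "mag_id", "taxonomy")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  if ("classification" %in% names(x)) {
    parsed <- parse_gtdb_lineage(x$classification)
    x <- bind_cols(select(x, -any_of(c("classification", ranks))), parsed)
  } else if (!all(ranks %in% names(x))) {
    rlang::abort("taxonomy needs a 'classification' column or all 7 rank columns")
  }
  x <- mutate(x, across(all_of(ranks), ~ tidyr::replace_na(.x, "")))
  if (anyDuplicated(x$mag_id)) rlang::abort("duplicate mag_id in taxonomy table")
  relocate(x, any_of(c("mag_id", "site_id")), all_of(ranks))
}

#' Read a per-scaffold coverage table
#'
#' @inheritParams read_annotations
#' @return Tibble with `mag_id`, `scaffold_id`, `coverage` and optional
#'   `site_id`; coverage non-negative and scaffold ids unique within a MAG.
#' @export
read_coverage <- function(path, delim = "\t") {
  x <- .read_table(path, delim,
                   required = c("mag_id", "scaffold_id", "coverage"),
                   types = readr::cols(coverage = readr::col_double(),
                                       .default = readr::col_character()))
  validate_coverage(x)
}

#' Validate a coverage table
#' @param x Data frame with `mag_id`, `scaffold_id`, `coverage`.
#' @return The validated tibble.
#' @export
validate_coverage <- function(x) {
  x <- .require_columns(as_tibble(x), c("mag_id", "scaffold_id", "coverage"),
                        "coverage")
  if (any(is.na(x$coverage) | x$coverage < 0)) {
    rlang::abort("coverage must be non-negative and non-missing")
  }
  dup <- x |> count(.data$mag_id, .data$scaffold_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0("duplicate scaffold id(s) within MAG(s): ",
                        paste(head(unique(dup$mag_id), 5), collapse = ", ")))
  }
  x
}

#' Write a table with deterministic row order
#'
#' Writers emit a header and rows sorted by `mag_id` (then by all remaining
#' columns) so that re-runs produce byte-identical files.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_mag_table <- function(x, path) {
  keys <- intersect(c("mag_id", "site_id"), names(x))
  ord <- if (length(keys) > 0) arrange(as_tibble(x), across(all_of(c(keys, setdiff(names(x), keys))))) else as_tibble(x)
  readr::write_tsv(ord, path, progress = FALSE)
  invisible(x)
}

## ---- internal helpers -------------------------------------------------------

.read_table <- function(path, delim, required, types) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  ## a typed column may legitimately be absent: that is reported as a format
  ## error by the column check, not as a parser warning
  x <- suppressWarnings(readr::read_delim(path, delim = delim, col_types = types,
                                          na = c("", "."), progress = FALSE))
  .require_columns(x, required, basename(path))
}

.require_columns <- function(x, required, what) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0(what, " table is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  x
}
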