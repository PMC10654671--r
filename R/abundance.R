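#' Mean coverage per MAG
#'
#' A MAG's mean coverage is the unweighted arithmetic mean of the mean read
#' depths reported for its unique scaffolds. No scaffold-length weighting is
#' applied by default; set `length_weighted = TRUE` (requires a
#' `scaffold_length` column) to weight each scaffold by its length instead.
#'
#' @param coverage Data frame of per-scaffold coverage rows (`mag_id`,
#'   `scaffold_id`, `coverage`, optional `site_id`, optional
#'   `scaffold_length`).
#' @param length_weighted Weight scaffolds by length? Off by default.
#' @return Tibble with one row per MAG: `mag_id`, optional `site_id`,
#'   `mean_coverage`.
#' @export
#' @examples
#' cov <- tibble::tibble(mag_id = "m1", scaffold_id = c("s1", "s2", "s3"),
#'                       coverage = c(10, 20, 30))
#' mag_mean_coverage(cov)  # 20
mag_mean_coverage <- function(coverage, length_weighted = FALSE) {
  coverage <- validate_coverage(coverage)
  if (nrow(coverage) == 0) rlang::abort("coverage table is empty")
  keys <- intersect(c("site_id", "mag_id"), names(coverage))
  if (length_weighted) {
    if (!"scaffold_length" %in% names(coverage)) {
      rlang::abort("length_weighted = TRUE requires a scaffold_length column")
    }
    out <- coverage |>
      group_by(across(all_of(keys))) |>
      summarise(mean_coverage = sum(.data$coverage * .data$scaffold_length) /
                  sum(.data$scaffold_length), .groups = "drop")
  } else {
    out <- coverage |>
      group_by(across(all_of(keys))) |>
      summarise(mean_coverage = mean(.data$coverage), .groups = "drop")
  }
  arrange(out, across(all_of(keys)))
}

#' Relative abundance profiles from mean coverage
#'
#' Each MAG's relative abundance at a site is its mean coverage divided by the
#' summed mean coverage of all MAGs at that site, times 100. Profiles sum to
#' 100 per site by construction.
#'
#' @param mean_coverages Tibble from [mag_mean_coverage()] (`mag_id`,
#'   `mean_coverage`, optional `site_id`), or a raw coverage table, which is
#'   averaged first.
#' @param site_id Site label used when `mean_coverages` has no `site_id`
#'   column.
#' @return An abundance profile tibble: `site_id`, `rank` (`"mag"`),
#'   `unit_id`, `rel_abundance_pct`.
#' @export
relative_abundance <- function(mean_coverages, site_id = "site_1") {
  x <- as_tibble(mean_coverages)
  if (!"mean_coverage" %in% names(x) && "coverage" %in% names(x)) {
    x <- mag_mean_coverage(x)
  }
  x <- .require_columns(x, c("mag_id", "mean_coverage"), "mean coverage")
  if (!"site_id" %in% names(x)) x$site_id <- site_id
  if (nrow(x) == 0) rlang::abort("no MAGs to profile")
  totals <- x |>
    group_by(.data$site_id) |>
    summarise(total = sum(.data$mean_coverage), .groups = "drop")
  zero <- totals$site_id[totals$total <= 0]
  if (length(zero) > 0) {
    rlang::abort(paste0("site(s) with zero total coverage: ",
                        paste(zero, collapse = ", ")))
  }
  x |>
    left_join(totals, by = "site_id") |>
    transmute(site_id = .data$site_id, rank = "mag", unit_id = .data$mag_id,
              rel_abundance_pct = 100 * .data$mean_coverage / .data$total) |>
    arrange(.data$site_id, .data$unit_id)
}

#' Aggregate an abundance profile to a taxonomic rank
#'
#' Sums MAG-level relative abundance over all MAGs sharing a taxon name at the
#' requested rank. MAGs unclassified at that rank are pooled under
#' `unclassified_<rank>`. The per-site total of 100 is conserved exactly.
#'
#' @param profile MAG-level profile from [relative_abundance()].
#' @param taxonomy Taxonomy tibble from [read_taxonomy()] /
#'   [validate_taxonomy()]; every MAG in the profile must appear.
#' @param rank One of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Profile tibble at the requested rank.
#' @export
aggregate_by_rank <- function(profile, taxonomy,
                              rank = c("family", "phylum", "class", "order",
                                       "genus", "species")) {
  rank <- match.arg(rank)
  profile <- .require_columns(as_tibble(profile),
                              c("site_id", "unit_id", "rel_abundance_pct"),
                              "abundance profile")
  taxonomy <- validate_taxonomy(taxonomy)
  missing <- setdiff(profile$unit_id, taxonomy$mag_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("no taxonomy record for MAG(s): ",
                        paste(head(missing, 10), collapse = ", ")))
  }
  sentinel <- paste0("unclassified_", rank)
  tax <- taxonomy |> select("mag_id", taxon = all_of(rank))
  profile |>
    select(-any_of("rank")) |>
    left_join(tax, by = c(unit_id = "mag_id")) |>
    mutate(taxon = if_else(nzchar(.data$taxon), .data$taxon, sentinel)) |>
    group_by(.data$site_id, unit_id = .data$taxon) |>
    summarise(rel_abundance_pct = sum(.data$rel_abundance_pct), .groups = "drop") |>
    mutate(rank = rank, .after = "site_id") |>
    arrange(.data$site_id, .data$unit_id)
}

#' Stacked abundance barplot
#'
#' Bars per site, one fill per taxon; taxa below `min_pct` in every site are
#' pooled into \dQuote{other} to keep the legend readable.
#'
#' @param profile Profile tibble (any rank).
#' @param min_pct Pooling cutoff in percent; default 1.
#' @return A ggplot object.
#' @export
plot_abundance <- function(profile, min_pct = 1) {
  profile <- as_tibble(profile)
  keep <- profile |>
    group_by(.data$unit_id) |>
    summarise(mx = max(.data$rel_abundance_pct), .groups = "drop") |>
    filter(.data$mx >= min_pct)
  plotted <- profile |>
    mutate(unit_id = if_else(.data$unit_id %in% keep$unit_id, .data$unit_id, "other")) |>
    group_by(.data$site_id, .data$unit_id) |>
    summarise(rel_abundance_pct = sum(.data$rel_abundance_pct), .groups = "drop")
  ggplot(plotted, aes(x = .data$site_id, y = .data$rel_abundance_pct,
                      fill = .data$unit_id)) +
    geom_col() +
    labs(x = NULL, y = "relative abundance (%)", fill = NULL) +
    theme_minimal()
}
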