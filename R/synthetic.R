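#' Simulation configuration
#'
#' Defines the conditions a synthetic landfill community is generated under:
#' the sampling sites and numbers of MAGs per site, the per-site mixture of
#' planted functional guilds, the coverage model and the annotation noise.
#' Defaults emulate the statistical structure of a multi-cell landfill
#' leachate survey: 8 sites of 150 MAGs each, heavy-tailed (lognormal) MAG
#' coverage permitting single dominant populations, scaffolds of 2.5-50 kbp,
#' methane- and acetate-cycling guilds as minority members of a large
#' heterotrophic background, and methanotroph accessory-trait frequencies
#' (nitrite/nitrate reduction, high/low-affinity complex IV) matching rates
#' reported from landfill leachate methanotrophs.
#'
#' @param seed Integer seed; every downstream draw is derived from it.
#' @param sites Named integer vector: MAGs per site.
#' @param guild_mix Named numeric vector of per-site guild proportions over
#'   `strict`, `acetoclastic`, `methylotrophic`, `methylthiol`, `broad`,
#'   `anme`, `methanotroph_pmo`, `methanotroph_mmo`, `methanotroph_both`,
#'   `acetogen_I` ... `acetogen_IV`, `background`; must sum to 1.
#' @param coverage_meanlog,coverage_sdlog Lognormal parameters of the per-MAG
#'   mean coverage.
#' @param scaffold_jitter_sdlog Lognormal sd of the per-scaffold coverage
#'   jitter around the MAG mean.
#' @param n_scaffolds_range Integer range of scaffolds per MAG.
#' @param scaffold_length_range Scaffold length range in bp (2.5 kbp
#'   assembly inclusion floor).
#' @param noise Probability of dropping each annotation row at generation
#'   time (0 = noise-free; see [degrade()]).
#' @param trait_probs Named probabilities of methanotroph accessory traits:
#'   `nitrite`, `nitrate`, `civ_high`, `civ_low`.
#' @param n_studies Number of synthetic literature studies for the
#'   occurrence meta-analysis tables.
#' @param n_unresolved_studies How many of those report only above-family
#'   names (and are therefore dropped during harmonization).
#' @param family_occurrence Named per-family probabilities that a literature
#'   study reports the family.
#' @return A list with class `mg_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              sites = setNames(rep(150L, 8),
                                               c("A", "B", "C", "D1", "D2", "E", "F1", "F2")),
                              guild_mix = c(strict = 0.05, acetoclastic = 0.03,
                                            methylotrophic = 0.03, methylthiol = 0.01,
                                            broad = 0.02, anme = 0.01,
                                            methanotroph_pmo = 0.02,
                                            methanotroph_mmo = 0.01,
                                            methanotroph_both = 0.01,
                                            acetogen_I = 0.04, acetogen_II = 0.03,
                                            acetogen_III = 0.02, acetogen_IV = 0.05,
                                            background = 0.67),
                              coverage_meanlog = 2, coverage_sdlog = 1,
                              scaffold_jitter_sdlog = 0.1,
                              n_scaffolds_range = c(5L, 30L),
                              scaffold_length_range = c(2500L, 50000L),
                              noise = 0,
                              trait_probs = c(nitrite = 27 / 31, nitrate = 8 / 31,
                                              civ_high = 24 / 31, civ_low = 26 / 31),
                              n_studies = 20L,
                              n_unresolved_studies = 2L,
                              family_occurrence = NULL) {
  if (is.null(names(sites)) || any(!nzchar(names(sites)))) {
    rlang::abort("sites must be a named vector of MAG counts")
  }
  if (any(sites < 0)) rlang::abort("negative MAG count in sites")
  missing <- setdiff(.guild_tokens(), names(guild_mix))
  if (length(missing) > 0) {
    rlang::abort(paste0("guild_mix lacks: ", paste(missing, collapse = ", ")))
  }
  if (any(guild_mix < 0) || abs(sum(guild_mix) - 1) > 1e-8) {
    rlang::abort("guild_mix proportions must be non-negative and sum to 1")
  }
  if (noise < 0 || noise > 1) rlang::abort("noise must lie in [0, 1]")
  if (any(trait_probs < 0 | trait_probs > 1)) {
    rlang::abort("trait_probs must lie in [0, 1]")
  }
  family_occurrence <- family_occurrence %||% c(
    Methanosarcinaceae = 0.80, Methanotrichaceae = 0.70,
    Methanocullaceae = 0.62, Methanobacteriaceae = 0.62,
    Methanomicrobiaceae = 0.45, Methanoregulaceae = 0.40,
    Methanospirillaceae = 0.35, Methanocorpusculaceae = 0.30,
    Methanomethylophilaceae = 0.25, Methanomassiliicoccaceae = 0.20,
    Methylomonadaceae = 0.35, Methylococcaceae = 0.30,
    Beijerinckiaceae = 0.25, Methanoperedenaceae = 0.10)
  structure(list(seed = as.integer(seed), sites = sites,
                 guild_mix = guild_mix[.guild_tokens()],
                 coverage_meanlog = coverage_meanlog,
                 coverage_sdlog = coverage_sdlog,
                 scaffold_jitter_sdlog = scaffold_jitter_sdlog,
                 n_scaffolds_range = as.integer(n_scaffolds_range),
                 scaffold_length_range = as.integer(scaffold_length_range),
                 noise = noise, trait_probs = trait_probs,
                 n_studies = as.integer(n_studies),
                 n_unresolved_studies = as.integer(n_unresolved_studies),
                 family_occurrence = family_occurrence),
            class = "mg_sim_config")
}

.guild_tokens <- function() {
  c("strict", "acetoclastic", "methylotrophic", "methylthiol", "broad",
    "anme", "methanotroph_pmo", "methanotroph_mmo", "methanotroph_both",
    "acetogen_I", "acetogen_II", "acetogen_III", "acetogen_IV", "background")
}

## guild -> genes / pathway steps / taxonomic assignment.  Each marker gene is
## planted exactly once so label-survival under row dropout has a closed form.
.guild_templates <- function() {
  list(
    strict = list(genes = c("mcrA", "mcrB"),
                  hydro = 7L, codh = 0L, wl = 0L,
                  families = c("Methanobacteriaceae", "Methanoregulaceae")),
    acetoclastic = list(genes = c("mcrA", "acs", "pta", "ack"),
                        hydro = 8L, codh = 2L, wl = 2L,
                        families = c("Methanotrichaceae", "Methanosarcinaceae")),
    methylotrophic = list(genes = c("mcrA", "mtaB"),
                          hydro = 3L, codh = 0L, wl = 0L,
                          families = "Methanomethylophilaceae"),
    methylthiol = list(genes = c("mcrA", "mtsA"),
                       hydro = 2L, codh = 0L, wl = 0L,
                       families = NA_character_),  # order-level only, like rare fastidious methanogens
    broad = list(genes = c("mcrA", "acs", "pta", "ack", "mtaB", "mttB"),
                 hydro = 8L, codh = 2L, wl = 2L,
                 families = "Methanosarcinaceae"),
    anme = list(genes = c("mcrA", "mcrB"),
                hydro = 7L, codh = 1L, wl = 0L,
                families = "Methanoperedenaceae"),
    methanotroph_pmo = list(genes = c("pmoA", "pmoB", "pmoC"),
                            hydro = 0L, codh = 0L, wl = 0L,
                            families = "Methylomonadaceae"),
    methanotroph_mmo = list(genes = c("mmoX", "mmoY"),  # mmoZ routinely missing in the wild
                            hydro = 0L, codh = 0L, wl = 0L,
                            families = "Methylococcaceae"),
    methanotroph_both = list(genes = c("pmoA", "pmoB", "pmoC", "mmoX", "mmoY"),
                             hydro = 0L, codh = 0L, wl = 0L,
                             families = "Methylomonadaceae"),
    acetogen_I = list(genes = c("pta", "ack"),
                      hydro = 0L, codh = 1L, wl = 7L,
                      families = "Eubacteriaceae"),
    acetogen_II = list(genes = c("pta", "ack"),
                       hydro = 0L, codh = 2L, wl = 3L,
                       families = "Sporomusaceae"),
    acetogen_III = list(genes = "pta",
                        hydro = 0L, codh = 0L, wl = 6L,
                        families = "Thermoanaerobacteraceae"),
    acetogen_IV = list(genes = c("pta", "ack"),
                       hydro = 0L, codh = 1L, wl = 2L,
                       families = "Lachnospiraceae"),
    background = list(genes = character(0),  # drawn at random per MAG
                      hydro = NA_integer_, codh = 0L, wl = NA_integer_,
                      families = c("Arcobacteraceae", "Sulfurimonadaceae",
                                   "Gallionellaceae", "Cloacimonadaceae",
                                   "Anaerolineaceae", "Bacteroidaceae",
                                   "Smithellaceae", "Spirochaetaceae")))
}

## deterministic largest-remainder apportionment of n MAGs over the mix
.apportion <- function(n, mix) {
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.lineage_for <- function(family) {
  arch <- c("Methanobacteriaceae", "Methanoregulaceae", "Methanotrichaceae",
            "Methanosarcinaceae", "Methanomethylophilaceae",
            "Methanoperedenaceae", "Methanocullaceae", "Methanomicrobiaceae",
            "Methanospirillaceae", "Methanocorpusculaceae",
            "Methanomassiliicoccaceae")
  if (is.na(family)) {
    return("d__Archaea;p__Euryarchaeota;c__Methanofastidiosia;o__Methanofastidiosales;f__;g__;s__")
  }
  domain <- if (family %in% arch) "Archaea" else "Bacteria"
  phylum <- if (family %in% arch) "Halobacterota" else "Proteobacteria"
  sprintf("d__%s;p__%s;c__%s_c;o__%s_o;f__%s;g__%s_g;s__",
          domain, phylum, family, family, family, family)
}

#' Generate a synthetic landfill metagenome table bundle
#'
#' Emits the five tables the analysis consumes — per-gene annotations,
#' per-MAG pathway completions, GTDB taxonomy, per-scaffold coverage, and
#' literature study reports — together with the planted ground truth, all
#' deterministic under the configured seed. At `noise = 0` the planted guild
#' of every MAG is exactly recoverable by the classification rules at
#' default thresholds.
#'
#' @param config A [simulation_config()].
#' @return A list of class `mg_bundle` with elements `annotations`,
#'   `pathways`, `taxonomy`, `coverage`, `study_reports`, `truth` (one row
#'   per MAG: `mag_id`, `site_id`, `guild`, `family`), `study_truth`
#'   (planted family-by-study presence), and `config`.
#' @export
#' @examples
#' b <- simulate_landfill(simulation_config(seed = 42, sites = c(X = 30)))
#' b$truth
simulate_landfill <- function(config = simulation_config()) {
  if (!inherits(config, "mg_sim_config")) {
    rlang::abort("config must come from simulation_config()")
  }
  tpl <- .guild_templates()
  bundle <- .with_seed(config$seed, {
    per_site <- purrr::map(names(config$sites), function(site) {
      n <- config$sites[[site]]
      counts <- .apportion(n, config$guild_mix)
      guilds <- rep(names(config$guild_mix), counts)
      tibble(site_id = site,
             mag_id = sprintf("ST%s_%03d", site, seq_len(n)),
             guild = guilds)
    })
    mags <- bind_rows(per_site)

    rows <- purrr::pmap(mags, function(site_id, mag_id, guild) {
      t <- tpl[[guild]]
      n_scaf <- sample(seq(config$n_scaffolds_range[1],
                           config$n_scaffolds_range[2]), 1)
      scaf <- tibble(scaffold_id = sprintf("%s_scf%02d", mag_id, seq_len(n_scaf)),
                     scaffold_length = as.integer(round(runif(
                       n_scaf, config$scaffold_length_range[1],
                       config$scaffold_length_range[2]))))
      genes <- t$genes
      if (guild == "background") {
        pool <- c("ureC", "nirK", "narG", "nosZ", "coxA", "phsA", "napA", "norB")
        genes <- sample(pool, sample(2:4, 1))
      }
      hydro <- t$hydro
      wl <- t$wl
      if (guild == "background") {
        hydro <- sample(0:2, 1)
        wl <- sample(0:4, 1)
      }
      path <- tibble(pathway_id = c("HYDROGENOTROPHIC_METHANOGENESIS",
                                    "CODH_ACS", "WOOD_LJUNGDAHL"),
                     steps_present = c(hydro, t$codh, wl),
                     steps_total = c(8L, 2L, 7L))
      if (startsWith(guild, "methanotroph")) {
        tp <- config$trait_probs
        genes <- c(genes,
                   if (runif(1) < tp[["nitrite"]]) sample(c("nirK", "nirS"), 1),
                   if (runif(1) < tp[["nitrate"]]) sample(c("narG", "napA"), 1))
        path <- bind_rows(path, tibble(
          pathway_id = c("COMPLEX_IV_HIGH", "COMPLEX_IV_LOW"),
          steps_present = c(if (runif(1) < tp[["civ_high"]]) 4L else 1L,
                            if (runif(1) < tp[["civ_low"]]) 3L else 0L),
          steps_total = c(4L, 3L)))
      }
      ann <- if (length(genes) > 0) {
        idx <- sample(seq_len(n_scaf), length(genes), replace = TRUE)
        tibble(gene_symbol = genes,
               scaffold_id = scaf$scaffold_id[idx],
               scaffold_length = scaf$scaffold_length[idx])
      } else {
        tibble(gene_symbol = character(), scaffold_id = character(),
               scaffold_length = integer())
      }
      mag_mean <- rlnorm(1, config$coverage_meanlog, config$coverage_sdlog)
      cov <- tibble(scaffold_id = scaf$scaffold_id,
                    coverage = mag_mean *
                      rlnorm(n_scaf, 0, config$scaffold_jitter_sdlog))
      fams <- t$families
      family <- if (length(fams) == 1) fams else sample(fams, 1)
      list(ann = mutate(ann, mag_id = mag_id, site_id = site_id),
           path = mutate(path, mag_id = mag_id),
           cov = mutate(cov, mag_id = mag_id, site_id = site_id),
           tax = tibble(mag_id = mag_id, site_id = site_id,
                        classification = .lineage_for(family)),
           truth = tibble(mag_id = mag_id, site_id = site_id, guild = guild,
                          family = ifelse(is.na(family), "", family)))
    })

    studies <- .simulate_studies(config)
    list(annotations = bind_rows(purrr::map(rows, "ann")) |>
           relocate("mag_id", "gene_symbol", "scaffold_id", "scaffold_length"),
         pathways = bind_rows(purrr::map(rows, "path")) |> relocate("mag_id"),
         taxonomy = validate_taxonomy(bind_rows(purrr::map(rows, "tax"))),
         coverage = bind_rows(purrr::map(rows, "cov")) |>
           relocate("mag_id", "scaffold_id", "coverage"),
         study_reports = studies$reports,
         truth = bind_rows(purrr::map(rows, "truth")),
         study_truth = studies$truth,
         config = config)
  })
  class(bundle) <- "mg_bundle"
  if (config$noise > 0) {
    bundle <- degrade(bundle, config$noise, seed = config$seed + 1L)
  }
  bundle
}

## literature-like study reports: families drawn per study, each reported
## under a randomly chosen naming dialect from the synonym table
.simulate_studies <- function(config) {
  if (config$n_studies == 0) {
    return(list(reports = tibble(study_id = character(), method = character(),
                                 taxon_name = character(), rank_claimed = character()),
                truth = tibble(study_id = character(), family = character(),
                               retained = logical())))
  }
  syn <- gtdb_synonyms()
  occ <- config$family_occurrence
  methods <- c("16S", "mcrA", "metagenomics", "qPCR", "RFLP")
  ids <- sprintf("study_%02d", seq_len(config$n_studies))
  n_unres <- min(config$n_unresolved_studies, config$n_studies)
  unresolved <- if (n_unres > 0) ids[seq_len(n_unres)] else character(0)
  reports <- purrr::map(ids, function(sid) {
    method <- sample(methods, 1)
    if (sid %in% unresolved) {
      return(tibble(study_id = sid, method = method,
                    taxon_name = c("Methanomicrobiales", "Euryarchaeota"),
                    rank_claimed = c("order", "phylum")))
    }
    present <- names(occ)[runif(length(occ)) < occ]
    if (length(present) == 0) present <- sample(names(occ), 1)
    names_used <- purrr::map_chr(present, function(fam) {
      alts <- c(syn$legacy_name[syn$gtdb_family == fam], fam)
      sample(alts, 1)
    })
    bind_rows(tibble(study_id = sid, method = method, taxon_name = names_used,
                     rank_claimed = "family_or_deeper"),
              # a little above-family noise that harmonization must ignore
              tibble(study_id = sid, method = method,
                     taxon_name = "Methanomicrobiales", rank_claimed = "order"))
  }) |> bind_rows()
  truth <- reports |>
    mutate(family = harmonize(.data$taxon_name, syn)) |>
    filter(.data$family != "UNRESOLVED") |>
    distinct(.data$study_id, .data$family) |>
    mutate(retained = TRUE)
  truth <- bind_rows(truth,
                     tibble(study_id = unresolved, family = NA_character_,
                            retained = FALSE))
  list(reports = reports, truth = truth)
}

#' Degrade a synthetic bundle with annotation noise
#'
#' Independently drops each per-gene annotation row with probability `drop`,
#' and (optionally) adds one spurious random-vocabulary gene row per MAG with
#' probability `add`. Pathway-completion, taxonomy and coverage tables are
#' left untouched, so the survival probability of each guild's required gene
#' set has a closed form (see [expected_recovery()]).
#'
#' @param bundle An `mg_bundle` from [simulate_landfill()].
#' @param drop Per-row drop probability in `[0, 1]`.
#' @param seed Integer seed for the dropout draws.
#' @param add Per-MAG spurious-gene probability; default 0.
#' @return The degraded bundle.
#' @export
degrade <- function(bundle, drop, seed = 1, add = 0) {
  if (drop < 0 || drop > 1 || add < 0 || add > 1) {
    rlang::abort("noise probabilities must lie in [0, 1]")
  }
  if (drop == 0 && add == 0) return(bundle)
  .with_seed(seed, {
    keep <- runif(nrow(bundle$annotations)) >= drop
    bundle$annotations <- bundle$annotations[keep, ]
    if (add > 0) {
      voc <- gene_vocabulary()
      extra <- bundle$coverage |>
        distinct(.data$mag_id, .data$site_id) |>
        filter(runif(n()) < add) |>
        mutate(gene_symbol = sample(voc$token, n(), replace = TRUE),
               scaffold_id = paste0(.data$mag_id, "_scf01"),
               scaffold_length = 5000L)
      bundle$annotations <- bind_rows(bundle$annotations,
                                      select(extra, names(bundle$annotations)))
    }
  })
  bundle
}

#' Planted-label recovery of the classifiers on a bundle
#'
#' Runs the three classifiers on a synthetic bundle and scores, per planted
#' guild, the fraction of MAGs whose planted label is recovered: methanogen
#' guilds against [classify_methanogens()] labels (the methylthiol guild also
#' requires the methylthiol flag), methanotroph guilds against
#' [classify_methanotrophs()] modes, acetogen guilds against the primary
#' acetogen category, and background against absence from all three call
#' sets.
#'
#' @param bundle An `mg_bundle`.
#' @param thresholds [rule_thresholds()].
#' @return Tibble: `guild`, `n`, `n_recovered`, `recovery`.
#' @export
label_recovery <- function(bundle, thresholds = rule_thresholds()) {
  mg <- suppressMessages(classify_methanogens(bundle$annotations, bundle$pathways,
                                              bundle$taxonomy, thresholds))
  mt <- suppressMessages(classify_methanotrophs(bundle$annotations, bundle$taxonomy,
                                                thresholds))
  ac <- suppressMessages(
    classify_acetogens(acetogen_features(bundle$annotations, bundle$pathways),
                       thresholds))
  mg_label <- setNames(mg$label, mg$mag_id)
  mg_flag <- setNames(mg$methylthiol_flag, mg$mag_id)
  mt_mode <- setNames(mt$mode, mt$mag_id)
  ac_primary <- setNames(ac$primary, ac$mag_id)
  expect <- c(strict = "STRICT_HYDROGENOTROPH", acetoclastic = "ACETOCLASTIC",
              methylotrophic = "METHYLOTROPHIC", methylthiol = "METHYLOTROPHIC",
              broad = "BROAD_SUBSTRATE", anme = "REROUTED_ANME")
  mt_expect <- c(methanotroph_pmo = "PMO_ONLY", methanotroph_mmo = "MMO_ONLY",
                 methanotroph_both = "BOTH", anme = "ANME")
  hit <- purrr::map2_lgl(bundle$truth$mag_id, bundle$truth$guild, function(id, g) {
    if (g %in% names(expect)) {
      ok <- !is.na(mg_label[id]) && mg_label[id] == expect[[g]]
      if (g == "methylthiol") ok <- ok && isTRUE(mg_flag[[id]])
      if (g == "anme") ok <- ok && !is.na(mt_mode[id]) && mt_mode[id] == "ANME"
      ok
    } else if (g %in% names(mt_expect)) {
      !is.na(mt_mode[id]) && mt_mode[id] == mt_expect[[g]]
    } else if (startsWith(g, "acetogen_")) {
      !is.na(ac_primary[id]) && ac_primary[id] == sub("acetogen_", "", g)
    } else {
      is.na(mg_label[id]) && is.na(mt_mode[id]) && is.na(ac_primary[id])
    }
  })
  bundle$truth |>
    mutate(hit = hit) |>
    group_by(guild = .data$guild) |>
    summarise(n = n(), n_recovered = sum(.data$hit), .groups = "drop") |>
    mutate(recovery = .data$n_recovered / .data$n)
}

#' Closed-form expected label recovery under annotation dropout
#'
#' For each planted guild, the probability that its label survives when every
#' annotation row is independently dropped with probability `drop` (pathway
#' and taxonomy tables untouched), given the generator's templates plant each
#' marker gene exactly once. For example a strict hydrogenotroph (mcrA +
#' mcrB planted, high hydrogenotrophic completion) survives unless both mcr
#' rows drop; an acetoclastic methanogen needs its single mcrA row plus at
#' least one acetate-activation route (acs alone, or pta and ack together).
#'
#' @param drop Dropout probability.
#' @return Tibble: `guild`, `expected` recovery probability.
#' @export
expected_recovery <- function(drop) {
  p <- drop
  activation <- 1 - p * (1 - (1 - p)^2)  # acs survives, or both pta & ack do
  tibble(guild = .guild_tokens(),
         expected = unname(c(strict = 1 - p^2,
                      acetoclastic = (1 - p) * activation,
                      methylotrophic = (1 - p)^2,
                      methylthiol = (1 - p)^2,
                      broad = (1 - p) * activation * (1 - p^2),
                      anme = 1,
                      methanotroph_pmo = 1 - p,
                      methanotroph_mmo = 1 - p,
                      methanotroph_both = (1 - p)^2,
                      acetogen_I = (1 - p)^2,
                      acetogen_II = (1 - p)^2,
                      acetogen_III = 1,
                      acetogen_IV = (1 - p)^2,
                      background = 1)[.guild_tokens()]))
}

#' Write the tables of a bundle to a directory
#'
#' @param bundle An `mg_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("annotations", "pathways", "taxonomy", "coverage",
               "study_reports", "truth")) {
    write_mag_table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' @export
print.mg_bundle <- function(x, ...) {
  cat("synthetic landfill bundle:",
      nrow(x$truth), "MAGs across", length(unique(x$truth$site_id)), "sites\n")
  cat("annotation rows:", nrow(x$annotations),
      "| pathway rows:", nrow(x$pathways),
      "| studies:", length(unique(x$study_reports$study_id)), "\n")
  invisible(x)
}
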