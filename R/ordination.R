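#' Bray-Curtis dissimilarity between site abundance profiles
#'
#' Builds the site-by-taxon matrix from a long profile table (the union of
#' taxa across sites forms the feature space; a taxon absent from a site
#' contributes 0) and computes Bray-Curtis dissimilarity
#' \eqn{BC(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}.
#'
#' @param profiles Long profile tibble (`site_id`, `unit_id`,
#'   `rel_abundance_pct`, optional `rank`); all rows must share one rank.
#' @return A `dist` object over sites (use `as.matrix()` for the labelled
#'   square form).
#' @export
bray_curtis <- function(profiles) {
  profiles <- .require_columns(as_tibble(profiles),
                               c("site_id", "unit_id", "rel_abundance_pct"),
                               "abundance profile")
  if ("rank" %in% names(profiles) && length(unique(profiles$rank)) > 1) {
    rlang::abort("profiles mix more than one rank; aggregate first")
  }
  wide <- profiles |>
    select("site_id", "unit_id", "rel_abundance_pct") |>
    tidyr::pivot_wider(names_from = "unit_id",
                       values_from = "rel_abundance_pct",
                       values_fill = 0, values_fn = sum) |>
    arrange(.data$site_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$site_id
  if (sum(rowSums(m) <= 0) >= 2) {
    rlang::abort("two or more all-zero profiles: Bray-Curtis undefined")
  }
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Fits a k-dimensional NMDS configuration to a dissimilarity matrix by
#' monotone (Kruskal stress-1) scaling, repeated from `n_restarts` starting
#' configurations — a metric-scaling start followed by random starts — and
#' keeps the minimum-stress solution. Coordinates are centred, rotated to
#' principal axes, and sign-fixed (largest absolute coordinate positive per
#' axis) so that runs are comparable; results are deterministic given `seed`.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param k Number of ordination dimensions; default 2.
#' @param n_restarts Number of starting configurations; default 20.
#' @param seed Integer seed controlling the random starts.
#' @param maxit Maximum iterations of the inner monotone scaling; default 500.
#' @return An object of class `mg_nmds`: `points` (sites x k matrix),
#'   `stress`, `restart_stress` (per-restart stress vector), `k`,
#'   `n_restarts`, `seed`.
#' @export
#' @examples
#' sq <- dist(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE))
#' ord <- nmds(sq, k = 2, n_restarts = 5, seed = 1)
#' ord$stress  # ~0: a unit square embeds exactly in the plane
nmds <- function(d, k = 2, n_restarts = 20, seed = 1, maxit = 500) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) rlang::abort("dissimilarity matrix must be symmetric")
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) rlang::abort("d must be a dist or symmetric matrix")
  n <- attr(d, "Size")
  if (k < 1 || n_restarts < 1) rlang::abort("k and n_restarts must be >= 1")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))

  runs <- .with_seed(seed, {
    starts <- c(list(.metric_start(d, k)),
                purrr::map(seq_len(max(0, n_restarts - 1)),
                           ~ matrix(rnorm(n * k), n, k)))
    purrr::map(starts, function(y0) {
      fit <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                            maxit = maxit, smin = 1e-9, sfgrmin = 1e-10,
                            sratmax = 1 - 1e-9)
      list(points = fit$points, stress = fit$stress)
    })
  })
  stresses <- purrr::map_dbl(runs, "stress")
  best <- runs[[which.min(stresses)]]
  pts <- .orient_coords(best$points)
  dimnames(pts) <- list(labels, paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = min(stresses),
                 restart_stress = stresses, k = k,
                 n_restarts = n_restarts, seed = seed),
            class = "mg_nmds")
}

.metric_start <- function(d, k) {
  y <- suppressWarnings(cmdscale(d, k = k))
  if (ncol(y) < k) y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  y
}

## centre, rotate to principal axes, make the largest |coordinate| positive
.orient_coords <- function(y) {
  y <- scale(y, center = TRUE, scale = FALSE)
  p <- prcomp(y, center = FALSE)
  r <- y %*% p$rotation
  for (j in seq_len(ncol(r))) {
    if (r[which.max(abs(r[, j])), j] < 0) r[, j] <- -r[, j]
  }
  attr(r, "scaled:center") <- NULL
  r
}

## evaluate expr under a temporary RNG state so callers' streams are untouched
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' @export
print.mg_nmds <- function(x, ...) {
  cat("NMDS ordination (", x$k, " dimensions, ", x$n_restarts,
      " restarts, seed ", x$seed, ")\n", sep = "")
  cat("stress:", format(x$stress, digits = 4), "\n")
  cat("sites:", nrow(x$points), "\n")
  invisible(x)
}

#' Tidy site coordinates of an NMDS fit
#' @param x An `mg_nmds` object.
#' @param ... Unused.
#' @return Tibble with `site_id` and one column per ordination axis.
#' @export
tidy.mg_nmds <- function(x, ...) {
  bind_cols(tibble(site_id = rownames(x$points)), as_tibble(x$points))
}

#' One-row summary of an NMDS fit
#' @inheritParams tidy.mg_nmds
#' @return Tibble with `stress`, `k`, `n_restarts`, `n_sites`, `seed`.
#' @export
glance.mg_nmds <- function(x, ...) {
  tibble(stress = x$stress, k = x$k, n_restarts = x$n_restarts,
         n_sites = nrow(x$points), seed = x$seed)
}

#' Ordination plot
#' @param object An `mg_nmds` object.
#' @param ... Unused.
#' @return A ggplot object with one labelled point per site and the stress in
#'   the subtitle.
#' @export
autoplot.mg_nmds <- function(object, ...) {
  xy <- tidy.mg_nmds(object)
  ggplot(xy, aes(x = .data$NMDS1, y = .data$NMDS2)) +
    geom_point(size = 3) +
    geom_text(aes(label = .data$site_id), vjust = -1, size = 3) +
    labs(subtitle = paste0("stress = ", format(object$stress, digits = 3))) +
    theme_minimal()
}

#' @rdname tidy.mg_nmds
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname glance.mg_nmds
#' @export
glance <- function(x, ...) UseMethod("glance")
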