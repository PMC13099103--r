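# cache of disc stencils keyed by radius
.disc_cache <- new.env(parent = emptyenv())

#' Pixel-offset stencil of a disc
#'
#' Integer offsets (dx, dy) with `dx^2 + dy^2 <= r^2`: the pixels whose
#' center lies inside or on the interaction circle (ties included).
#'
#' @param r_px radius in pixels (>= 1).
#' @return two-column integer matrix of offsets.
#' @export
disc_offsets <- function(r_px) {
  stopifnot(r_px >= 1)
  key <- as.character(r_px)
  if (!is.null(.disc_cache[[key]])) return(.disc_cache[[key]])
  s <- seq(-floor(r_px), floor(r_px))
  g <- expand.grid(dx = s, dy = s)
  g <- as.matrix(g[g$dx^2 + g$dy^2 <= r_px^2, ])
  .disc_cache[[key]] <- g
  g
}

#' Rasterize interaction circles
#'
#' Draws a disc of radius `r_px` around every cell (centers snapped to the
#' nearest pixel; coordinates are pixel centroids) and counts, per pixel,
#' how many discs cover it. Discs are truncated at the field border.
#'
#' @param points two-column matrix of (x, y) pixel coordinates.
#' @param r_px interaction radius in pixels.
#' @param width,height field size in pixels.
#' @return object of class `interaction_raster`: integer coverage `counts`
#'   (length `width * height`, pixel (ix, iy) at index `ix + (iy-1)*width`),
#'   `dim`, `r_px`, `area` (pixels covered at least once).
#' @useDynLib spatplex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @export
rasterize_interaction <- function(points, r_px, width, height) {
  points <- matrix(as.numeric(points), ncol = 2)
  counts <- integer(width * height)
  if (nrow(points)) {
    ix <- pmin(pmax(as.integer(round(points[, 1])), 1L), width)
    iy <- pmin(pmax(as.integer(round(points[, 2])), 1L), height)
    counts <- .disc_coverage_cpp(ix, iy, as.numeric(r_px),
                                 as.integer(width), as.integer(height))
  }
  tally <- .coverage_tally_cpp(counts)
  structure(
    list(counts = counts, dim = c(width, height), r_px = r_px,
         area = tally[1], multi = tally[2]),
    class = "interaction_raster"
  )
}

#' @export
print.interaction_raster <- function(x, ...) {
  cat(sprintf(
    "interaction_raster: %d x %d px, r = %d px, area %d px, max coverage %d\n",
    x$dim[1], x$dim[2], x$r_px, x$area, max(x$counts)
  ))
  invisible(x)
}

#' Total available tissue area
#'
#' The union area, in pixels, of interaction discs over all cells of the
#' sample — the denominator A of the overlap tests' Bernoulli success
#' probability a/A.
#'
#' @param table a `cell_table` (all cells are used).
#' @param r_px interaction radius in pixels.
#' @param width,height field size; default from the table's `field_dim`.
#' @return list: `A` (pixels), `raster` (the full-coverage
#'   `interaction_raster`, whose support drives bootstrap placements).
#' @export
tissue_area <- function(table, r_px, width = NULL, height = NULL) {
  fd <- attr(table, "field_dim")
  if (is.null(width)) width <- if (!is.null(fd)) fd[1] else
    as.integer(ceiling(max(table$x_px))) + r_px
  if (is.null(height)) height <- if (!is.null(fd)) fd[2] else
    as.integer(ceiling(max(table$y_px))) + r_px
  ras <- rasterize_interaction(cbind(table$x_px, table$y_px), r_px,
                               width, height)
  list(A = ras$area, raster = ras)
}

#' Same-type double-coverage overlap test
#'
#' Observed statistic: the fraction of covered pixels hit by at least two
#' interaction circles of the population, `o_i / hit`. Its null expectation
#' treats each pixel as a Bernoulli trial with success probability
#' `p = a/A` (a = single-disc area, A = tissue area), giving
#' `P(K > 1) / P(K > 0)` with `K ~ Binomial(n_i, p)`. Significance comes
#' from a bootstrap of uniform placements of `n_i` cells on the tissue
#' support.
#'
#' @param points_i two-column matrix of the population's (x, y) pixels.
#' @param tissue result of [tissue_area()] at the same radius.
#' @param r_px interaction radius in pixels.
#' @param n_boot bootstrap placements (default 1000; < 100 warns).
#' @param seed integer seed for the bootstrap.
#' @return list: `o_i` (pixels covered >= 2), `hit` (pixels covered >= 1),
#'   `observed_ratio`, `expected_ratio`, `p` (fraction of bootstrap ratios
#'   >= observed), `boot_mean`, `boot_sd`, `n_boot`.
#' @export
self_overlap_test <- function(points_i, tissue, r_px, n_boot = 1000L,
                              seed = 1L) {
  points_i <- matrix(as.numeric(points_i), ncol = 2)
  n_i <- nrow(points_i)
  if (n_i < 2L) stop("self overlap needs at least 2 cells")
  if (n_boot < 100L) warning("n_boot < 100 gives a coarse p-value")
  A <- tissue$A
  if (A == 0) stop("tissue area is zero")
  W <- tissue$raster$dim[1]
  H <- tissue$raster$dim[2]
  obs <- rasterize_interaction(points_i, r_px, W, H)
  o_i <- obs$multi
  hit <- obs$area
  observed <- if (hit > 0) o_i / hit else 0
  p1 <- nrow(disc_offsets(r_px)) / A
  expected <- stats::pbinom(1, n_i, p1, lower.tail = FALSE) /
    stats::pbinom(0, n_i, p1, lower.tail = FALSE)
  support <- which(tissue$raster$counts > 0L)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pix <- sample(support, n_i, replace = TRUE)
      bx <- ((pix - 1L) %% W) + 1L
      by <- ((pix - 1L) %/% W) + 1L
      ras <- rasterize_interaction(cbind(bx, by), r_px, W, H)
      if (ras$area > 0) ras$multi / ras$area else 0
    }, numeric(1))
  })
  list(o_i = o_i, hit = hit, observed_ratio = observed,
       expected_ratio = expected, p = mean(boot >= observed),
       boot_mean = mean(boot), boot_sd = stats::sd(boot),
       n_boot = n_boot)
}

#' Cross-type interaction-area overlap test
#'
#' The overlap statistic is the Jaccard index of the two populations'
#' rasterized interaction areas, `o_ij = |a_i n a_j| / |a_i u a_j|`. Under
#' the null it is compared with `K ~ Binomial(n = min(n_i, n_j),
#' p = max(a_i, a_j)/A)` through the upper-tail probability
#' `P(K > floor(o_ij * min(n_i, n_j)))` (strict inequality).
#'
#' @param raster_i,raster_j `interaction_raster`s of the two populations at
#'   the same radius and field, or two-column coordinate matrices (then
#'   `width`/`height` are required).
#' @param A tissue area in pixels from [tissue_area()].
#' @param n_i,n_j population sizes; defaults to the number of points when
#'   coordinates are given (required when rasters are given).
#' @param r_px,width,height used only when coordinates are given.
#' @return list: `o_ij`, `intersection`, `union`, `a_i`, `a_j`, `n_i`,
#'   `n_j`, `k` (binomial threshold), `p`.
#' @export
cross_overlap_test <- function(raster_i, raster_j, A, n_i = NULL,
                               n_j = NULL, r_px = NULL, width = NULL,
                               height = NULL) {
  if (!inherits(raster_i, "interaction_raster")) {
    pts <- matrix(as.numeric(raster_i), ncol = 2)
    if (is.null(n_i)) n_i <- nrow(pts)
    raster_i <- rasterize_interaction(pts, r_px, width, height)
  }
  if (!inherits(raster_j, "interaction_raster")) {
    pts <- matrix(as.numeric(raster_j), ncol = 2)
    if (is.null(n_j)) n_j <- nrow(pts)
    raster_j <- rasterize_interaction(pts, r_px, width, height)
  }
  if (is.null(n_i) || is.null(n_j)) {
    stop("n_i and n_j are required when rasters are supplied")
  }
  stopifnot(identical(raster_i$dim, raster_j$dim))
  ju <- .jaccard_counts_cpp(raster_i$counts, raster_j$counts)
  inter <- ju[1]
  uni <- ju[2]
  if (uni == 0L) stop("both interaction areas are empty")
  o_ij <- inter / uni
  p_null <- max(raster_i$area, raster_j$area) / A
  if (p_null > 1) {
    warning("max(a_i, a_j) exceeds A; clamping null probability to 1")
    p_null <- 1
  }
  n <- min(n_i, n_j)
  k <- floor(o_ij * n)
  list(
    o_ij = o_ij, intersection = inter, union = uni,
    a_i = raster_i$area, a_j = raster_j$area, n_i = n_i, n_j = n_j,
    k = k, p = stats::pbinom(k, n, p_null, lower.tail = FALSE)
  )
}

#' Interaction-overlap analysis across a cohort
#'
#' For every sample and radius, rasterizes each type's interaction area,
#' computes the tissue area from all cells, runs the cross-type overlap
#' test for every unordered pair (and optionally the same-type
#' double-coverage test), then aggregates with the strict max-p consensus
#' rule shared with the neighborhood analysis.
#'
#' @param tables list of `cell_table`s.
#' @param radii_um interaction radii in micrometres (default 10 and 20).
#' @param pixel_size_um micrometres per pixel; default from the first table.
#' @param types types to analyse (default: all observed).
#' @param type_col column holding cell type labels.
#' @param alpha_family family-wise level.
#' @param n_tests Bonferroni divisor; default, number of evaluable pairs.
#' @param include_self also run [self_overlap_test()] per type (bootstrap
#'   cost; off by default).
#' @param n_boot bootstrap size for self tests.
#' @param seed seed for self-test bootstraps.
#' @return list: `per_test` long data.frame (sample, radius, i, j, o_ij,
#'   a_i, a_j, A, p, evaluable), `consensus`, `m`, `threshold`,
#'   `self` (data.frame or NULL).
#' @export
overlap_analysis <- function(tables, radii_um = c(10, 20),
                             pixel_size_um = NULL, types = NULL,
                             type_col = "true_type", alpha_family = 0.05,
                             n_tests = NULL, include_self = FALSE,
                             n_boot = 1000L, seed = 1L) {
  if (is.data.frame(tables)) tables <- list(S1 = tables)
  if (is.null(names(tables))) names(tables) <- sprintf("S%d",
                                                       seq_along(tables))
  if (is.null(pixel_size_um)) pixel_size_um <- ct_pixel_size(tables[[1]])
  if (is.null(types)) {
    types <- sort(unique(unlist(lapply(tables, function(t)
      t[[type_col]]))))
  }
  radii_px <- radius_in_pixels(radii_um, pixel_size_um)
  pair_idx <- which(upper.tri(matrix(0, length(types), length(types))),
                    arr.ind = TRUE)
  rows <- list()
  self_rows <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    fd <- attr(tab, "field_dim")
    for (r in seq_along(radii_px)) {
      r_px <- radii_px[r]
      tis <- tissue_area(tab, r_px)
      W <- tis$raster$dim[1]
      H <- tis$raster$dim[2]
      rasters <- list()
      for (ty in types) {
        sel <- tab[[type_col]] == ty
        if (any(sel)) {
          rasters[[ty]] <- rasterize_interaction(
            cbind(tab$x_px[sel], tab$y_px[sel]), r_px, W, H)
          attr(rasters[[ty]], "n") <- sum(sel)
        }
      }
      for (k in seq_len(nrow(pair_idx))) {
        i <- types[pair_idx[k, "row"]]
        j <- types[pair_idx[k, "col"]]
        ok <- !is.null(rasters[[i]]) && !is.null(rasters[[j]])
        if (!ok) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = nm, radius_um = radii_um[r], radius_px = r_px,
            i = i, j = j, o_ij = NA, a_i = NA, a_j = NA, A = tis$A,
            p = NA, evaluable = FALSE, stringsAsFactors = FALSE
          )
          next
        }
        res <- cross_overlap_test(
          rasters[[i]], rasters[[j]], tis$A,
          n_i = attr(rasters[[i]], "n"), n_j = attr(rasters[[j]], "n")
        )
        rows[[length(rows) + 1L]] <- data.frame(
          sample = nm, radius_um = radii_um[r], radius_px = r_px,
          i = i, j = j, o_ij = res$o_ij, a_i = res$a_i, a_j = res$a_j,
          A = tis$A, p = res$p, evaluable = TRUE,
          stringsAsFactors = FALSE
        )
      }
      if (include_self) {
        for (ty in types) {
          if (is.null(rasters[[ty]]) || attr(rasters[[ty]], "n") < 2L) next
          sel <- tab[[type_col]] == ty
          st <- self_overlap_test(
            cbind(tab$x_px[sel], tab$y_px[sel]), tis, r_px,
            n_boot = n_boot, seed = seed
          )
          self_rows[[length(self_rows) + 1L]] <- data.frame(
            sample = nm, radius_um = radii_um[r], type = ty,
            o_i = st$o_i, hit = st$hit,
            observed_ratio = st$observed_ratio,
            expected_ratio = st$expected_ratio, p = st$p,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  per_test <- do.call(rbind, rows)
  cons <- consensus_significance(per_test, alpha_family = alpha_family,
                                 n_tests = n_tests)
  list(
    per_test = per_test, consensus = cons,
    m = attr(cons, "m"), threshold = attr(cons, "threshold"),
    self = if (length(self_rows)) do.call(rbind, self_rows) else NULL
  )
}
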