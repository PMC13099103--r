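#' Specification of a synthetic tissue sample
#'
#' Defines everything needed to simulate a segmented multiplexed-imaging
#' sample: field geometry, cell-type abundances and spatial point processes,
#' polygonal zones, and per-(type, marker) two-component lognormal intensity
#' mixtures. A spec plus a seed fully determines a sample.
#'
#' @param field_width,field_height field size in pixels.
#' @param n_cells expected total number of cells (per-type counts are a
#'   multinomial draw at the stated abundance fractions).
#' @param cell_types data.frame with columns `name`, `fraction`,
#'   `mode` (one of `"poisson"`, `"clustered"`, `"coupled"`) and the
#'   mode parameters: `cluster_sd`, `offspring_mean`, `parent_rate`
#'   (clustered; `parent_rate` is parents per square pixel and overrides
#'   `offspring_mean` when given), `partner`, `displacement_sd` (coupled).
#'   Missing parameter columns are treated as NA.
#' @param marker_model data.frame with columns `type`, `marker`, `pos_frac`,
#'   `mu_pos`, `sd_pos`, `mu_neg`, `sd_neg`; one row per (type, marker)
#'   combination, log-scale means/sds. Intensities are drawn from the
#'   two-component lognormal mixture, clipped to \[0, 255\] after
#'   exponentiation and rounded to 8-bit integers last.
#' @param zones optional named list of polygons (two-column x,y matrices in
#'   pixel coordinates); cells outside every polygon are labeled
#'   `"interstitial"`.
#' @param pixel_size micrometres per pixel (default 0.45).
#'
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(field_width, field_height, n_cells, cell_types,
                           marker_model = NULL, zones = NULL,
                           pixel_size = 0.45) {
  stopifnot(field_width > 0, field_height > 0, n_cells >= 0)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be > 0")
  }
  cell_types <- as.data.frame(cell_types, stringsAsFactors = FALSE)
  req <- c("name", "fraction", "mode")
  if (!all(req %in% names(cell_types))) {
    stop("cell_types needs columns: ", paste(req, collapse = ", "))
  }
  for (col in c("cluster_sd", "offspring_mean", "parent_rate",
                "partner", "displacement_sd")) {
    if (!col %in% names(cell_types)) cell_types[[col]] <- NA
  }
  if (anyDuplicated(cell_types$name)) stop("duplicate cell type names")
  if (abs(sum(cell_types$fraction) - 1) > 1e-9) {
    stop("abundance fractions must sum to 1")
  }
  if (!all(cell_types$mode %in% c("poisson", "clustered", "coupled"))) {
    stop("unknown spatial mode")
  }
  cp <- cell_types[cell_types$mode == "coupled", ]
  if (nrow(cp)) {
    bad <- !cp$partner %in% cell_types$name
    if (any(bad)) stop("coupled partner type not defined: ", cp$partner[bad][1])
    pm <- cell_types$mode[match(cp$partner, cell_types$name)]
    if (any(pm == "coupled")) {
      stop("coupled types must reference a non-coupled partner")
    }
    if (any(!is.finite(cp$displacement_sd) | cp$displacement_sd < 0)) {
      stop("coupled types need displacement_sd >= 0")
    }
  }
  if (!is.null(zones)) {
    if (is.null(names(zones)) || any(names(zones) == "")) {
      stop("zones must be a named list of polygons")
    }
    for (nm in names(zones)) {
      poly <- as.matrix(zones[[nm]])
      if (ncol(poly) != 2 || nrow(poly) < 3) {
        stop("zone '", nm, "': polygon needs >= 3 (x, y) vertices")
      }
      inside <- poly[, 1] >= 0 & poly[, 1] <= field_width &
        poly[, 2] >= 0 & poly[, 2] <= field_height
      if (!all(inside)) stop("zone '", nm, "' lies outside the field")
      zones[[nm]] <- poly
    }
  }
  if (!is.null(marker_model)) {
    marker_model <- as.data.frame(marker_model, stringsAsFactors = FALSE)
    reqm <- c("type", "marker", "pos_frac", "mu_pos", "sd_pos",
              "mu_neg", "sd_neg")
    if (!all(reqm %in% names(marker_model))) {
      stop("marker_model needs columns: ", paste(reqm, collapse = ", "))
    }
    if (any(marker_model$pos_frac < 0 | marker_model$pos_frac > 1)) {
      stop("positive fractions must lie in [0, 1]")
    }
    combos <- expand.grid(type = cell_types$name,
                          marker = unique(marker_model$marker),
                          stringsAsFactors = FALSE)
    key <- paste(marker_model$type, marker_model$marker)
    if (!all(paste(combos$type, combos$marker) %in% key)) {
      stop("marker_model must cover every (type, marker) combination")
    }
  }
  structure(
    list(
      field_width = field_width, field_height = field_height,
      n_cells = n_cells, cell_types = cell_types,
      marker_model = marker_model, zones = zones, pixel_size = pixel_size
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d x %d px field (%.2f um/px), %d cells, %d types, %d zones\n",
    x$field_width, x$field_height, x$pixel_size, x$n_cells,
    nrow(x$cell_types), length(x$zones)
  ))
  invisible(x)
}

#' Convenience marker-mixture model builder
#'
#' Builds a complete (type, marker) mixture table from a named list giving,
#' for each type, the markers it expresses. Expressed markers get a dominant
#' bright lognormal component; everything else is background.
#'
#' @param type_markers named list: type name -> character vector of markers
#'   positive in that type. The marker panel is the union of all entries.
#' @param pos_frac positive fraction for expressed markers.
#' @param mu_pos,sd_pos log-scale mean/sd of the bright component.
#' @param mu_neg,sd_neg log-scale mean/sd of the background component.
#' @param bg_pos_frac residual positive fraction for non-expressed markers.
#' @return data.frame usable as `marker_model` in [synthetic_spec()].
#' @export
simple_marker_model <- function(type_markers, pos_frac = 0.9,
                                mu_pos = log(120), sd_pos = 0.35,
                                mu_neg = log(8), sd_neg = 0.5,
                                bg_pos_frac = 0.02) {
  markers <- unique(unlist(type_markers))
  types <- names(type_markers)
  grid <- expand.grid(type = types, marker = markers,
                      stringsAsFactors = FALSE)
  pos <- mapply(function(ty, mk) mk %in% type_markers[[ty]],
                grid$type, grid$marker)
  data.frame(
    type = grid$type, marker = grid$marker,
    pos_frac = ifelse(pos, pos_frac, bg_pos_frac),
    mu_pos = mu_pos, sd_pos = sd_pos, mu_neg = mu_neg, sd_neg = sd_neg,
    stringsAsFactors = FALSE
  )
}

# assign zone labels by point-in-polygon on centroids; first polygon wins
assign_zone_labels <- function(x, y, zones) {
  zone <- rep("interstitial", length(x))
  if (is.null(zones) || length(x) == 0) return(zone)
  pts <- cbind(x, y)
  for (nm in rev(names(zones))) {
    # reversed so that earlier polygons take precedence on overlap
    inside <- mgcv::in.out(rbind(zones[[nm]], zones[[nm]][1, ]), pts)
    zone[inside] <- nm
  }
  zone
}

# draw n points for one type; partners = list of already placed (x, y)
.place_type <- function(row, n, W, H, placed) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  mode <- row$mode
  if (mode == "poisson") {
    return(cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H)))
  }
  if (mode == "clustered") {
    sd <- row$cluster_sd
    if (!is.finite(sd) || sd <= 0) stop("clustered type needs cluster_sd > 0")
    if (is.finite(row$parent_rate) && row$parent_rate > 0) {
      n_par <- max(1L, stats::rpois(1L, row$parent_rate * W * H))
    } else {
      om <- row$offspring_mean
      if (!is.finite(om) || om <= 0) {
        stop("clustered type needs offspring_mean or parent_rate")
      }
      n_par <- max(1L, round(n / om))
    }
    px <- stats::runif(n_par, 0, W)
    py <- stats::runif(n_par, 0, H)
    par <- sample.int(n_par, n, replace = TRUE)
    x <- px[par] + stats::rnorm(n, 0, sd)
    y <- py[par] + stats::rnorm(n, 0, sd)
    for (it in 1:200) {
      out <- x < 0 | x > W | y < 0 | y > H
      if (!any(out)) break
      # redraw the displacement, keeping parent assignment (counts stay exact)
      x[out] <- px[par[out]] + stats::rnorm(sum(out), 0, sd)
      y[out] <- py[par[out]] + stats::rnorm(sum(out), 0, sd)
    }
    x <- pmin(pmax(x, 0), W)
    y <- pmin(pmax(y, 0), H)
    return(cbind(x = x, y = y))
  }
  # coupled: Gaussian displacement from a sampled partner cell
  partner <- placed[[row$partner]]
  if (is.null(partner) || nrow(partner) == 0) {
    stop("coupled type '", row$name, "': partner '", row$partner,
         "' has no cells")
  }
  sd <- row$displacement_sd
  idx <- sample.int(nrow(partner), n, replace = TRUE)
  x <- partner[idx, 1] + stats::rnorm(n, 0, sd)
  y <- partner[idx, 2] + stats::rnorm(n, 0, sd)
  for (it in 1:200) {
    out <- x < 0 | x > W | y < 0 | y > H
    if (!any(out)) break
    # out-of-field draws are redone from a fresh partner (counts stay exact)
    idx[out] <- sample.int(nrow(partner), sum(out), replace = TRUE)
    x[out] <- partner[idx[out], 1] + stats::rnorm(sum(out), 0, sd)
    y[out] <- partner[idx[out], 2] + stats::rnorm(sum(out), 0, sd)
  }
  x <- pmin(pmax(x, 0), W)
  y <- pmin(pmax(y, 0), H)
  cbind(x = x, y = y)
}

#' Generate one synthetic segmented-cell sample
#'
#' Draws per-type cell counts (multinomial at the spec abundances), places
#' cells by each type's spatial point process, draws 8-bit marker intensities
#' from the per-(type, marker) lognormal mixtures, and labels zones by
#' point-in-polygon on centroids. Fully reproducible from `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return a `cell_table` data.frame with columns `cell_id`, `x_px`, `y_px`,
#'   one column per marker, `true_type` and `zone`.
#' @export
generate_sample <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  W <- spec$field_width
  H <- spec$field_height
  ct <- spec$cell_types
  markers <- if (is.null(spec$marker_model)) character(0) else
    unique(spec$marker_model$marker)
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, spec$n_cells, ct$fraction))
    names(counts) <- ct$name
    # place non-coupled types first so partners exist
    ord <- order(ct$mode == "coupled")
    placed <- list()
    for (k in ord) {
      placed[[ct$name[k]]] <- .place_type(ct[k, ], counts[k], W, H, placed)
    }
    type <- rep(ct$name, counts)
    xy <- do.call(rbind, placed[ct$name])
    n <- length(type)
    inten <- matrix(0, nrow = n, ncol = length(markers),
                    dimnames = list(NULL, markers))
    if (length(markers) && n > 0) {
      mm <- spec$marker_model
      key <- paste(mm$type, mm$marker)
      for (mk in markers) {
        for (ty in ct$name) {
          rows <- which(type == ty)
          if (!length(rows)) next
          p <- mm[match(paste(ty, mk), key), ]
          pos <- stats::runif(length(rows)) < p$pos_frac
          lv <- ifelse(pos,
                       stats::rnorm(length(rows), p$mu_pos, p$sd_pos),
                       stats::rnorm(length(rows), p$mu_neg, p$sd_neg))
          inten[rows, mk] <- pmin(pmax(exp(lv), 0), 255)
        }
      }
    }
    # continuous draws are rounded to 8-bit integers last
    inten <- round(inten)
    df <- data.frame(
      cell_id = sprintf("c%06d", seq_len(n)),
      x_px = if (n) xy[, 1] else numeric(0),
      y_px = if (n) xy[, 2] else numeric(0),
      stringsAsFactors = FALSE
    )
    for (mk in markers) df[[mk]] <- inten[, mk]
    df$true_type <- type
    df$zone <- assign_zone_labels(df$x_px, df$y_px, spec$zones)
    out <- as_cell_table(df,
      markers = markers, pixel_size = spec$pixel_size,
      field_dim = c(W, H), sample_id = "S1"
    )
    attr(out, "zones") <- spec$zones
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Plant a co-localized type pair into a sample
#'
#' Relocates a stated fraction of `type_b` cells to uniform positions inside
#' discs of the given radius centred on random `type_a` cells, creating a
#' known-ground-truth neighboring pair. Moved cells get `planted = TRUE` and
#' their zone labels are refreshed when the table carries zone polygons.
#'
#' @param table a `cell_table`.
#' @param type_a,type_b anchor and relocated cell types.
#' @param radius_um disc radius in micrometres.
#' @param fraction fraction of `type_b` cells relocated; the moved count is
#'   exactly `round(fraction * n_b)`.
#' @param seed integer seed.
#' @return the modified `cell_table`.
#' @export
plant_colocalization <- function(table, type_a, type_b, radius_um, fraction,
                                 seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  a_idx <- which(table$true_type == type_a)
  b_idx <- which(table$true_type == type_b)
  if (!length(a_idx) || !length(b_idx)) {
    stop("both types must be present in the table")
  }
  if (!"planted" %in% names(table)) table$planted <- FALSE
  n_move <- round(fraction * length(b_idx))
  if (n_move == 0) return(as_cell_table(table, template = table))
  r_px <- radius_um / ct_pixel_size(table)
  fd <- attr(table, "field_dim")
  W <- if (is.null(fd)) max(table$x_px) else fd[1]
  H <- if (is.null(fd)) max(table$y_px) else fd[2]
  with_seed(seed, {
    move <- sample(b_idx, n_move)
    anchor <- sample(a_idx, n_move, replace = TRUE)
    rr <- r_px * sqrt(stats::runif(n_move))
    th <- stats::runif(n_move, 0, 2 * pi)
    x <- table$x_px[anchor] + rr * cos(th)
    y <- table$y_px[anchor] + rr * sin(th)
    for (it in 1:200) {
      out <- x < 0 | x > W | y < 0 | y > H
      if (!any(out)) break
      anchor[out] <- sample(a_idx, sum(out), replace = TRUE)
      rr <- r_px * sqrt(stats::runif(sum(out)))
      th <- stats::runif(sum(out), 0, 2 * pi)
      x[out] <- table$x_px[anchor[out]] + rr * cos(th)
      y[out] <- table$y_px[anchor[out]] + rr * sin(th)
    }
    table$x_px[move] <- pmin(pmax(x, 0), W)
    table$y_px[move] <- pmin(pmax(y, 0), H)
    table$planted[move] <- TRUE
    zones <- attr(table, "zones")
    if (!is.null(zones)) {
      table$zone[move] <- assign_zone_labels(table$x_px[move],
                                             table$y_px[move], zones)
    }
    as_cell_table(table, template = table)
  })
}

#' Generate a multi-sample synthetic cohort
#'
#' Independent samples from the same spec with per-sample seeds
#' `base_seed + i - 1`, so `n_samples = 1` reproduces
#' `generate_sample(spec, base_seed)` exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param n_samples number of samples (>= 1).
#' @param base_seed integer seed of the first sample.
#' @return named list of `cell_table`s (`S1`, `S2`, ...), each carrying a
#'   `sample_id` column.
#' @export
generate_cohort <- function(spec, n_samples, base_seed = 1L) {
  stopifnot(n_samples >= 1)
  out <- lapply(seq_len(n_samples), function(i) {
    tab <- generate_sample(spec, seed = base_seed + i - 1L)
    tab$sample_id <- sprintf("S%d", i)
    attr(tab, "sample_id") <- sprintf("S%d", i)
    tab
  })
  names(out) <- sprintf("S%d", seq_len(n_samples))
  out
}
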