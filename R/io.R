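#' Read a segmented single-cell table from CSV
#'
#' Expects one row per cell with `x_px`/`y_px` (or `x`/`y`) coordinate
#' columns and at least one numeric marker column; everything that is not a
#' reserved column is treated as a marker. Missing or non-finite
#' coordinates and non-numeric or NaN intensities are rejected with the
#' offending row index.
#'
#' @param path CSV path.
#' @param panel optional character vector; marker columns are checked
#'   against it.
#' @param pixel_size micrometres per pixel recorded on the table.
#' @return a `cell_table`.
#' @export
read_cell_table <- function(path, panel = NULL, pixel_size = 0.45) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  if ("x" %in% nm && !"x_px" %in% nm) names(df)[nm == "x"] <- "x_px"
  if ("y" %in% nm && !"y_px" %in% nm) names(df)[nm == "y"] <- "y_px"
  if (!all(c("x_px", "y_px") %in% names(df))) {
    stop("missing coordinate columns (x_px, y_px)")
  }
  for (col in c("x_px", "y_px")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop("non-numeric or missing ", col, " at row ", bad[1])
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!"cell_id" %in% names(df)) {
    df$cell_id <- sprintf("c%06d", seq_len(nrow(df)))
  }
  markers <- setdiff(names(df), .reserved_cols)
  if (!length(markers)) stop("no marker columns found")
  for (mk in markers) {
    v <- suppressWarnings(as.numeric(df[[mk]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-numeric or NaN intensity in marker '", mk, "' at row ",
           bad[1])
    }
    df[[mk]] <- v
  }
  if (!is.null(panel)) {
    extra <- setdiff(markers, panel)
    miss <- setdiff(panel, markers)
    if (length(miss)) {
      stop("panel markers missing from file: ",
           paste(miss, collapse = ", "))
    }
    if (length(extra)) {
      warning("markers not in panel: ", paste(extra, collapse = ", "))
    }
  }
  message(sprintf("read %d cells, %d markers from %s", nrow(df),
                  length(markers), path))
  as_cell_table(df, markers = markers, pixel_size = pixel_size)
}

# md5 of a canonical serialization; used to stamp outputs
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp, version = 2)
  unname(tools::md5sum(tmp))
}

# sidecar metadata next to every written file
.write_sidecar <- function(path, config = NULL, seed = NULL, extra = list()) {
  meta <- c(list(
    file = basename(path),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    seed = if (!is.null(seed)) seed else NA
  ), extra)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Write a cell table as CSV (with provenance sidecar)
#'
#' @param table a `cell_table`.
#' @param path output CSV path.
#' @param config,seed optional run provenance recorded in the
#'   `<path>.meta.yaml` sidecar.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path, config = NULL, seed = NULL) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  .write_sidecar(path, config, seed,
                 list(n_cells = nrow(table),
                      markers = as.list(ct_markers(table)),
                      pixel_size = ct_pixel_size(table)))
  invisible(path)
}

#' Run configuration
#'
#' Central container for the run constants: pixel size, dual radii,
#' mixture-component budget, shrinkage contraction, minimum cluster size,
#' family-wise alpha and seeds. All defaults are overridable and the object
#' round-trips losslessly through YAML.
#'
#' @param pixel_size micrometres per pixel (default 0.45).
#' @param radii_um neighborhood/overlap radii in micrometres, ascending
#'   (default 10, 20).
#' @param G_i Gaussian-mixture component budget (default 20).
#' @param lambda shrinkage contraction factor (default 0.8).
#' @param min_cluster_size minimum reportable cluster size (default 200).
#' @param alpha_family family-wise significance level (default 0.05).
#' @param seed master seed; every stochastic stage derives from it.
#' @param junk_ids named list, sample id -> global cluster ids to exclude.
#' @param include_self_overlap run the bootstrap same-type overlap test.
#' @param n_boot bootstrap size for the self-overlap test.
#' @param ... further named entries carried through (panel paths etc.).
#' @return object of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.45, radii_um = c(10, 20), G_i = 20L,
                       lambda = 0.8, min_cluster_size = 200L,
                       alpha_family = 0.05, seed = 1L,
                       junk_ids = list(), include_self_overlap = FALSE,
                       n_boot = 1000L, ...) {
  cfg <- c(list(
    pixel_size = pixel_size, radii_um = radii_um, G_i = G_i,
    lambda = lambda, min_cluster_size = min_cluster_size,
    alpha_family = alpha_family, seed = seed, junk_ids = junk_ids,
    include_self_overlap = include_self_overlap, n_boot = n_boot
  ), list(...))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.unsorted(cfg$radii_um) || any(cfg$radii_um <= 0)) {
    stop("radii_um must be positive and ascending")
  }
  if (cfg$lambda < 0 || cfg$lambda > 1) stop("lambda must lie in [0, 1]")
  if (cfg$G_i < 1) stop("G_i must be >= 1")
  if (cfg$alpha_family <= 0 || cfg$alpha_family >= 1) {
    stop("alpha_family must lie in (0, 1)")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml scalars come back untyped; re-coerce the numerics
  num <- c("pixel_size", "lambda", "alpha_family")
  for (f in num) cfg[[f]] <- as.numeric(cfg[[f]])
  cfg$radii_um <- as.numeric(unlist(cfg$radii_um))
  for (f in c("G_i", "min_cluster_size", "seed", "n_boot")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Read/write named zone polygons
#'
#' Long CSV with columns `zone`, `x`, `y`, vertices in order.
#'
#' @param zones named list of two-column polygon matrices.
#' @param path CSV path.
#' @return the zone list (read) or `path` (write), invisibly.
#' @export
write_zone_polygons <- function(zones, path) {
  df <- do.call(rbind, lapply(names(zones), function(nm) {
    data.frame(zone = nm, x = zones[[nm]][, 1], y = zones[[nm]][, 2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zone_polygons
#' @export
read_zone_polygons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("zone", "x", "y") %in% names(df)))
  lapply(split(df, factor(df$zone, levels = unique(df$zone))),
         function(d) cbind(x = d$x, y = d$y))
}

#' Rasterize zone polygons into a label mask
#'
#' Integer matrix indexed \[x, y\]; 0 is interstitial, positive labels
#' follow the polygon list order (earlier polygons win on overlap).
#'
#' @param zones named list of polygons.
#' @param width,height field size in pixels.
#' @return integer matrix with attribute `region_names`.
#' @export
zone_mask <- function(zones, width, height) {
  mask <- matrix(0L, width, height)
  grid <- cbind(rep(seq_len(width), height),
                rep(seq_len(height), each = width))
  for (k in rev(seq_along(zones))) {
    poly <- zones[[k]]
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), grid)
    mask[inside] <- k
  }
  attr(mask, "region_names") <- names(zones)
  mask
}

#' Write / read a zone label mask as single-channel TIFF
#'
#' Labels are stored in an 8-bit grayscale image (label value / 255);
#' requires the `tiff` package.
#'
#' @param mask integer label mask from [zone_mask()].
#' @param path TIFF path.
#' @return the mask (read) or `path` (write), invisibly.
#' @export
write_zone_mask <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write masks")
  }
  if (max(mask) > 255) stop("more than 255 zones not representable")
  img <- t(mask) / 255  # TIFF rows are y
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_zone_mask
#' @export
read_zone_mask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read masks")
  }
  img <- tiff::readTIFF(path)
  t(round(img * 255))
}
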