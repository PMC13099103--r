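#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals never perturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# columns of a cell table that are never marker intensities
.reserved_cols <- c(
  "cell_id", "x_px", "y_px", "true_type", "zone", "planted",
  "sample_id", "global_label", "broad_type", "subclass_label",
  "cell_type", "excluded"
)

#' Marker column names of a cell table
#'
#' @param table a `cell_table` (or plain data.frame with the same columns).
#' @return character vector of marker column names.
#' @export
ct_markers <- function(table) {
  m <- attr(table, "markers")
  if (!is.null(m) && all(m %in% names(table))) {
    return(m)
  }
  setdiff(names(table), .reserved_cols)
}

#' Pixel size (micrometres per pixel) of a cell table
#'
#' @param table a `cell_table`.
#' @param default value returned when the table carries no pixel size.
#' @return scalar, micrometres per pixel.
#' @export
ct_pixel_size <- function(table, default = 0.45) {
  p <- attr(table, "pixel_size")
  if (is.null(p)) default else p
}

#' Intensity matrix of a cell table
#'
#' @param table a `cell_table`.
#' @param markers optional subset of marker columns.
#' @return numeric matrix, cells in rows, markers in columns.
#' @export
ct_intensity_matrix <- function(table, markers = NULL) {
  if (is.null(markers)) markers <- ct_markers(table)
  missing <- setdiff(markers, names(table))
  if (length(missing)) {
    stop("markers not present in table: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(table[, markers, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$cell_id
  m
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf(
    "cell_table: %d cells, %d markers, %s px, %.2f um/px\n",
    nrow(x), length(ct_markers(x)),
    paste(attr(x, "field_dim"), collapse = " x "),
    ct_pixel_size(x)
  ))
  if ("true_type" %in% names(x) && nrow(x) > 0) {
    print(table(x$true_type))
  }
  invisible(x)
}

#' Construct a cell table from a data.frame
#'
#' Stamps the `cell_table` class and its metadata (marker panel, pixel
#' size, field dimensions, sample id) onto a per-cell data.frame with
#' `cell_id`, `x_px`, `y_px` columns. A `template` table donates any
#' metadata not given explicitly — handy after row/column surgery.
#'
#' @param df data.frame, one row per cell.
#' @param template optional `cell_table` supplying default metadata.
#' @param markers character vector of marker column names.
#' @param pixel_size micrometres per pixel.
#' @param field_dim integer c(width, height) in pixels.
#' @param sample_id sample identifier.
#' @return a `cell_table`.
#' @export
as_cell_table <- function(df, template = NULL, markers = NULL,
                          pixel_size = NULL, field_dim = NULL,
                          sample_id = NULL) {
  if (!is.null(template)) {
    if (is.null(markers)) markers <- attr(template, "markers")
    if (is.null(pixel_size)) pixel_size <- attr(template, "pixel_size")
    if (is.null(field_dim)) field_dim <- attr(template, "field_dim")
    if (is.null(sample_id)) sample_id <- attr(template, "sample_id")
  }
  structure(df,
    markers = markers, pixel_size = pixel_size,
    field_dim = field_dim, sample_id = sample_id,
    class = c("cell_table", "data.frame")
  )
}

# stable weighted purity of a hard clustering against ground truth,
# computed over non-noise, non-excluded cells
#' Cluster-to-truth purity
#'
#' Weighted mean, over clusters (noise label -1 excluded), of the fraction of
#' each cluster's cells belonging to its majority ground-truth class.
#'
#' @param labels integer cluster labels, -1 = noise.
#' @param truth ground-truth class per cell.
#' @return scalar in \[0, 1\]; NA when no cell is clustered.
#' @export
cluster_purity <- function(labels, truth) {
  keep <- labels != -1 & !is.na(labels)
  if (!any(keep)) return(NA_real_)
  tab <- table(labels[keep], truth[keep])
  sum(apply(tab, 1L, max)) / sum(tab)
}

#' Map cluster labels to classes by ground-truth majority vote
#'
#' Test-scaffolding stand-in for the expert cluster annotation step: each
#' non-noise cluster is assigned the class most frequent among its cells.
#'
#' @param labels integer cluster labels, -1 = noise.
#' @param truth class label per cell.
#' @return named character vector, cluster id (as character) -> class.
#' @export
majority_map <- function(labels, truth) {
  keep <- labels != -1 & !is.na(labels)
  tab <- table(labels[keep], truth[keep])
  out <- colnames(tab)[apply(tab, 1L, which.max)]
  names(out) <- rownames(tab)
  out
}
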