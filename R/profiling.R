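# significant-marker character set of one profile
.sig_markers <- function(profile) {
  profile$table$marker[profile$table$significant]
}

# clusters of each type, validated against available profiles
.clusters_by_type <- function(profiles, type_map) {
  ids <- names(profiles)
  if (is.null(names(type_map))) {
    stop("type_map must be a named vector: cluster id -> cell type")
  }
  missing <- setdiff(ids, names(type_map))
  if (length(missing)) {
    stop("clusters without a type: ", paste(missing, collapse = ", "))
  }
  split(ids, unname(type_map[ids]))
}

#' Marker frequency bands per cell type
#'
#' For each (cell type, marker), the fraction of the type's clusters in
#' which the marker is significantly expressed, assigned to the reporting
#' bands 70-100%, 50-69% and 30-49% (markers below 30% are omitted).
#'
#' @param profiles named list of `cluster_profile`s (names = cluster ids).
#' @param type_map named character vector, cluster id -> cell type; every
#'   profiled cluster must be mapped to exactly one type.
#' @return data.frame with columns `cell_type`, `marker`, `n_significant`,
#'   `n_clusters`, `fraction`, `band` (`"70-100"`, `"50-69"`, `"30-49"`).
#' @export
band_marker_frequencies <- function(profiles, type_map) {
  by_type <- .clusters_by_type(profiles, type_map)
  if (any(lengths(by_type) == 0L)) stop("cell type with zero clusters")
  out <- list()
  for (ty in names(by_type)) {
    ids <- by_type[[ty]]
    sig <- lapply(profiles[ids], .sig_markers)
    markers <- unique(unlist(sig))
    if (!length(markers)) next
    n_sig <- vapply(markers, function(mk) {
      sum(vapply(sig, function(s) mk %in% s, logical(1)))
    }, integer(1))
    frac <- n_sig / length(ids)
    band <- rep(NA_character_, length(markers))
    band[frac >= 0.70] <- "70-100"
    band[frac >= 0.50 & frac < 0.70] <- "50-69"
    band[frac >= 0.30 & frac < 0.50] <- "30-49"
    keep <- !is.na(band)
    if (!any(keep)) next
    out[[ty]] <- data.frame(
      cell_type = ty, marker = markers[keep], n_significant = n_sig[keep],
      n_clusters = length(ids), fraction = frac[keep], band = band[keep],
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_type = character(0), marker = character(0),
               n_significant = integer(0), n_clusters = integer(0),
               fraction = numeric(0), band = character(0))
  rownames(res) <- NULL
  res
}

#' Top-ranked markers per cell type by median rank position
#'
#' For each marker, the median of its positions in the ranked
#' significant-marker lists of the type's clusters; markers absent from a
#' cluster's list contribute no rank there (or, optionally, rank m+1).
#' Markers whose median rank falls in 1..5 are reported.
#'
#' @param profiles named list of `cluster_profile`s.
#' @param type_map named vector, cluster id -> cell type.
#' @param absent `"omit"` (default): clusters where the marker is not
#'   significant are skipped; `"m_plus_1"`: they contribute rank
#'   `length(ranked) + 1`.
#' @param max_rank report markers with median rank `<= max_rank` (default 5).
#' @return data.frame `cell_type`, `marker`, `median_rank`, `n_clusters_with`
#'   sorted by type then median rank.
#' @export
top_ranked_markers <- function(profiles, type_map,
                               absent = c("omit", "m_plus_1"),
                               max_rank = 5L) {
  absent <- match.arg(absent)
  by_type <- .clusters_by_type(profiles, type_map)
  out <- list()
  for (ty in names(by_type)) {
    ids <- by_type[[ty]]
    lists <- lapply(profiles[ids], function(p) p$ranked)
    markers <- unique(unlist(lists))
    if (!length(markers)) next
    rows <- lapply(markers, function(mk) {
      ranks <- vapply(lists, function(rk) {
        pos <- match(mk, rk)
        if (is.na(pos) && absent == "m_plus_1") pos <- length(rk) + 1L
        as.numeric(pos)
      }, numeric(1))
      present <- sum(vapply(lists, function(rk) mk %in% rk, logical(1)))
      data.frame(cell_type = ty, marker = mk,
                 median_rank = stats::median(ranks, na.rm = TRUE),
                 n_clusters_with = present, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[!is.na(df$median_rank) & df$median_rank <= max_rank, ,
             drop = FALSE]
    if (nrow(df)) out[[ty]] <- df[order(df$median_rank, df$marker), ]
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_type = character(0), marker = character(0),
               median_rank = numeric(0), n_clusters_with = integer(0))
  rownames(res) <- NULL
  res
}

#' Per-cell marker positivity from the shrinkage mixture
#'
#' Thresholds are never applied to raw intensities; instead a cell is
#' called positive for a marker when its value is assigned (maximum
#' responsibility) to a mixture component whose mean exceeds the marker's
#' mixture grand mean (weight-averaged component mean). Deterministic and
#' gate-free.
#'
#' @param model a [fit_shrinkage()] model.
#' @param x intensity matrix or `cell_table` on the model's marker set.
#' @return logical matrix (cells x markers).
#' @export
marker_positivity <- function(model, x) {
  stopifnot(inherits(model, "shrinkage_model"))
  if (inherits(x, "cell_table")) x <- ct_intensity_matrix(x)
  x <- as.matrix(x)
  out <- matrix(FALSE, nrow(x), length(model$markers),
                dimnames = list(rownames(x), names(model$markers)))
  for (nm in names(model$markers)) {
    m <- model$markers[[nm]]
    grand <- sum(m$weight * m$mean)
    comp <- .assign_component(log1p(x[, nm]), m)
    out[, nm] <- m$mean[comp] > grand
  }
  out
}

#' Cell-type summary tables
#'
#' Combines the frequency bands, the median-rank top markers and, when
#' per-cell positivity is supplied, the cellwise conventions: markers
#' positive in >= 30% and >= 70% of the type's cells.
#'
#' @param profiles named list of `cluster_profile`s.
#' @param type_map named vector, cluster id -> cell type.
#' @param positivity optional logical matrix from [marker_positivity()],
#'   rows aligned with `cell_types`.
#' @param cell_types optional per-cell type vector (same cells as
#'   `positivity` rows) used for the cellwise fractions.
#' @param absent passed to [top_ranked_markers()].
#' @return list of per-type summaries (class `cell_type_summary` each):
#'   `cell_type`, `n_cells`, `n_clusters`, `band_70_100`, `band_50_69`,
#'   `band_30_49`, `top5` (data.frame with cellwise flags when available),
#'   `cellwise_ge30`, `cellwise_ge70`.
#' @export
cell_type_summary <- function(profiles, type_map, positivity = NULL,
                              cell_types = NULL, absent = "omit") {
  bands <- band_marker_frequencies(profiles, type_map)
  tops <- top_ranked_markers(profiles, type_map, absent = absent)
  by_type <- .clusters_by_type(profiles, type_map)
  out <- list()
  for (ty in names(by_type)) {
    ids <- by_type[[ty]]
    b <- bands[bands$cell_type == ty, ]
    t5 <- tops[tops$cell_type == ty, ]
    ge30 <- ge70 <- character(0)
    if (!is.null(positivity) && !is.null(cell_types)) {
      rows <- which(cell_types == ty)
      if (length(rows)) {
        frac <- colMeans(positivity[rows, , drop = FALSE])
        ge30 <- names(frac)[frac >= 0.30]
        ge70 <- names(frac)[frac >= 0.70]
        t5$cellwise_ge30 <- t5$marker %in% ge30
        t5$cellwise_ge70 <- t5$marker %in% ge70
      }
    }
    out[[ty]] <- structure(
      list(
        cell_type = ty,
        n_cells = sum(vapply(profiles[ids], function(p) p$n_cells,
                             numeric(1))),
        n_clusters = length(ids),
        band_70_100 = b$marker[b$band == "70-100"],
        band_50_69 = b$marker[b$band == "50-69"],
        band_30_49 = b$marker[b$band == "30-49"],
        top5 = t5,
        cellwise_ge30 = ge30,
        cellwise_ge70 = ge70
      ),
      class = "cell_type_summary"
    )
  }
  out
}

#' @export
print.cell_type_summary <- function(x, ...) {
  cat(sprintf("%s: %d cells in %d clusters\n", x$cell_type, x$n_cells,
              x$n_clusters))
  cat("  70-100%:", paste(x$band_70_100, collapse = ", "), "\n")
  cat("  50-69%: ", paste(x$band_50_69, collapse = ", "), "\n")
  cat("  30-49%: ", paste(x$band_30_49, collapse = ", "), "\n")
  if (nrow(x$top5)) {
    cat("  top ranks:", paste(x$top5$marker, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Kappa/lambda light-chain ratio
#'
#' Count ratio of kappa- to lambda-positive cells per sample, with the
#' cohort mean and standard deviation across samples. A sample without
#' lambda cells has an undefined (NA) ratio and is excluded from the
#' cohort moments.
#'
#' @param tables list of `cell_table`s (or a single table).
#' @param kappa_type,lambda_type cell type names to count.
#' @param type_col column holding the cell type labels.
#' @return list: `per_sample` data.frame (sample, n_kappa, n_lambda,
#'   ratio), `mean`, `sd`.
#' @export
light_chain_ratio <- function(tables, kappa_type, lambda_type,
                              type_col = "true_type") {
  if (is.data.frame(tables)) tables <- list(S1 = tables)
  if (is.null(names(tables))) names(tables) <- sprintf("S%d",
                                                       seq_along(tables))
  rows <- lapply(names(tables), function(nm) {
    tt <- tables[[nm]][[type_col]]
    nk <- sum(tt == kappa_type, na.rm = TRUE)
    nl <- sum(tt == lambda_type, na.rm = TRUE)
    data.frame(sample = nm, n_kappa = nk, n_lambda = nl,
               ratio = if (nl > 0) nk / nl else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  ok <- !is.na(per_sample$ratio)
  list(
    per_sample = per_sample,
    mean = if (any(ok)) mean(per_sample$ratio[ok]) else NA_real_,
    sd = if (sum(ok) > 1) stats::sd(per_sample$ratio[ok]) else NA_real_
  )
}
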