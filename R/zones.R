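#' Zone assignment for a cell table
#'
#' Assigns each cell to the region containing its centroid. Regions come
#' either from a label mask (integer matrix indexed \[x, y\] in pixels, 0 =
#' interstitial, with `region_names` naming the positive labels) or from
#' named polygons; the mask takes precedence when both are given.
#'
#' @param table a `cell_table`.
#' @param polygons named list of two-column (x, y) polygon matrices.
#' @param mask integer matrix label mask, dimension (width, height).
#' @param region_names character vector naming mask labels 1, 2, ...
#' @return the table with its `zone` column set ("interstitial" outside
#'   every region).
#' @export
assign_zones <- function(table, polygons = NULL, mask = NULL,
                         region_names = NULL) {
  if (!is.null(mask)) {
    ix <- pmin(pmax(as.integer(round(table$x_px)), 1L), nrow(mask))
    iy <- pmin(pmax(as.integer(round(table$y_px)), 1L), ncol(mask))
    lab <- mask[cbind(ix, iy)]
    if (is.null(region_names)) {
      region_names <- as.character(sort(unique(lab[lab > 0])))
    }
    zone <- rep("interstitial", nrow(table))
    pos <- lab > 0
    zone[pos] <- region_names[lab[pos]]
    table$zone <- zone
  } else if (!is.null(polygons)) {
    table$zone <- assign_zone_labels(table$x_px, table$y_px, polygons)
  } else {
    stop("either polygons or mask must be given")
  }
  as_cell_table(table, template = table)
}

# 2x2 sample log odds ratio with Haldane-Anscombe correction when any
# cell is zero; used for the sign-consistency aggregation
.log_odds <- function(m) {
  if (any(m == 0)) m <- m + 0.5
  log((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
}

#' Zonal enrichment of cell types across regions
#'
#' Per (sample, region, type): Fisher's exact test on the 2x2 table
#' in-region/outside x type/other. Interstitial cells are never a region of
#' their own but always count toward the outside-region margin. Per
#' (region, type) the per-sample results are aggregated with the strict
#' rule: mean log odds ratio, significant only when the sign is consistent
#' across all samples having both the region and the type, and the maximum
#' p-value is below the Bonferroni-corrected threshold (m = #regions x
#' #types by default, a family separate from the pairwise analyses).
#'
#' @param tables list of `cell_table`s with `zone` set.
#' @param type_col column holding cell type labels.
#' @param zone_col column holding region labels.
#' @param alpha_family family-wise level (default 0.05).
#' @param n_tests Bonferroni divisor; default #regions x #types.
#' @return object of class `zonal_result`: `per_test` long data.frame,
#'   `aggregate` per (region, type) with `mean_log_or`, `consistent_sign`,
#'   `max_p`, `significant`, plus `m` and `threshold`.
#' @export
zone_enrichment <- function(tables, type_col = "true_type",
                            zone_col = "zone", alpha_family = 0.05,
                            n_tests = NULL) {
  if (is.data.frame(tables)) tables <- list(S1 = tables)
  if (is.null(names(tables))) names(tables) <- sprintf("S%d",
                                                       seq_along(tables))
  regions <- sort(setdiff(unique(unlist(lapply(tables, function(t)
    t[[zone_col]]))), "interstitial"))
  types <- sort(unique(unlist(lapply(tables, function(t)
    t[[type_col]]))))
  if (!length(regions)) stop("no regions besides interstitial")
  if (is.null(n_tests)) n_tests <- length(regions) * length(types)
  threshold <- alpha_family / n_tests
  rows <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    zv <- tab[[zone_col]]
    tv <- tab[[type_col]]
    for (rg in regions) {
      if (!any(zv == rg)) next  # region absent from this sample
      for (ty in types) {
        if (!any(tv == ty)) next
        m <- matrix(c(
          sum(zv == rg & tv == ty), sum(zv == rg & tv != ty),
          sum(zv != rg & tv == ty), sum(zv != rg & tv != ty)
        ), nrow = 2L, byrow = TRUE,
        dimnames = list(c("in", "out"), c("type", "other")))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = nm, region = rg, type = ty,
          in_type = m[1, 1], in_other = m[1, 2],
          out_type = m[2, 1], out_other = m[2, 2],
          log_or = .log_odds(m),
          p = stats::fisher.test(m)$p.value,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  per_test <- do.call(rbind, rows)
  agg <- list()
  for (rg in regions) {
    for (ty in types) {
      sub <- per_test[per_test$region == rg & per_test$type == ty, ,
                      drop = FALSE]
      if (!nrow(sub)) next
      signs <- sign(sub$log_or)
      consistent <- all(signs > 0) || all(signs < 0)
      mp <- max(sub$p)
      agg[[length(agg) + 1L]] <- data.frame(
        region = rg, type = ty, n_samples = nrow(sub),
        mean_log_or = mean(sub$log_or), consistent_sign = consistent,
        max_p = mp, significant = consistent && mp <= threshold,
        direction = if (!consistent) "mixed" else
          if (all(signs > 0)) "enriched" else "depleted",
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(per_test = per_test, aggregate = do.call(rbind, agg),
         m = n_tests, threshold = threshold,
         regions = regions, types = types),
    class = "zonal_result"
  )
}

#' @export
print.zonal_result <- function(x, ...) {
  sig <- x$aggregate[x$aggregate$significant %in% TRUE, ]
  cat(sprintf(
    "zonal_result: %d regions x %d types, m = %d (threshold %.3g), %d significant\n",
    length(x$regions), length(x$types), x$m, x$threshold, nrow(sig)
  ))
  invisible(x)
}

#' Zone/type composition matrices
#'
#' Two complementary descriptive matrices. The first gives, for each cell
#' type, the percentage of its cells falling in each region (cells pooled
#' over samples; every row sums to 100). The second gives the average
#' region composition in terms of cell types: per sample each region's
#' column is normalized to 100, then averaged over the samples containing
#' the region (every column sums to 100). Interstitial appears as a
#' location category in both.
#'
#' @param tables list of `cell_table`s with `zone` set.
#' @param type_col,zone_col label columns.
#' @return list: `type_by_region` (rows = types, 100-sum rows),
#'   `region_composition` (rows = types, 100-sum columns).
#' @export
composition_matrices <- function(tables, type_col = "true_type",
                                 zone_col = "zone") {
  if (is.data.frame(tables)) tables <- list(S1 = tables)
  types <- sort(unique(unlist(lapply(tables, function(t)
    t[[type_col]]))))
  regions <- sort(unique(unlist(lapply(tables, function(t)
    t[[zone_col]]))))
  pooled <- matrix(0, length(types), length(regions),
                   dimnames = list(types, regions))
  for (tab in tables) {
    tt <- table(factor(tab[[type_col]], levels = types),
                factor(tab[[zone_col]], levels = regions))
    pooled <- pooled + as.matrix(tt)
  }
  rs <- rowSums(pooled)
  type_by_region <- sweep(pooled, 1, ifelse(rs > 0, rs, 1), "/") * 100
  comp_sum <- matrix(0, length(types), length(regions),
                     dimnames = list(types, regions))
  comp_n <- integer(length(regions))
  for (tab in tables) {
    tt <- as.matrix(table(factor(tab[[type_col]], levels = types),
                          factor(tab[[zone_col]], levels = regions)))
    cs <- colSums(tt)
    for (r in seq_along(regions)) {
      if (cs[r] > 0) {
        comp_sum[, r] <- comp_sum[, r] + tt[, r] / cs[r] * 100
        comp_n[r] <- comp_n[r] + 1L
      }
    }
  }
  region_composition <- sweep(comp_sum, 2, ifelse(comp_n > 0, comp_n, 1),
                              "/")
  empty <- comp_n == 0
  if (any(empty)) {
    warning("region(s) with no cells: ",
            paste(regions[empty], collapse = ", "))
  }
  list(type_by_region = type_by_region,
       region_composition = region_composition)
}
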