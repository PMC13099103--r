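#' Convert an interaction radius from micrometres to pixels
#'
#' Single source of truth for the um -> px conversion: the radius is
#' truncated to whole pixels, so 10 um at 0.45 um/px gives 22 px and 20 um
#' gives 44 px.
#'
#' @param radius_um radius in micrometres.
#' @param pixel_size_um micrometres per pixel (default 0.45).
#' @return integer radius in pixels.
#' @export
radius_in_pixels <- function(radius_um, pixel_size_um = 0.45) {
  stopifnot(all(radius_um > 0), pixel_size_um > 0)
  as.integer(floor(radius_um / pixel_size_um))
}

# distance from each row of `query` to its nearest point of `ref`;
# drop_self uses the 2nd neighbor (a cell is not its own neighbor)
.nn_dist <- function(ref, query, drop_self = FALSE) {
  k <- if (drop_self) 2L else 1L
  if (nrow(ref) < k) return(rep(Inf, nrow(query)))
  FNN::knnx.dist(ref, query, k = k)[, k]
}

#' Near/far contingency test for one type pair
#'
#' Cells other than type `i` are split into "near" (within `radius_px` of
#' any type-`i` cell, centroid Euclidean distance) and "far"; the 2x2 table
#' near/far x (type `j` / other) is tested with a two-sided Fisher exact
#' test. The reported enrichment ratio is the proportion of `j` among near
#' cells divided by the proportion among far cells. For the self pair
#' (`i == j`) all cells are considered and a cell is never its own
#' neighbor.
#'
#' @param table a `cell_table`.
#' @param type_i,type_j focal and target cell types.
#' @param radius_px neighborhood radius in pixels (> 0).
#' @param type_col column holding cell type labels.
#' @return list: `counts` (2x2: rows near/far, cols j/other), `ratio`
#'   (enrichment; 0 when no `j` cells, `Inf` when `j` occurs only near),
#'   `log_ratio`, `odds_ratio`, `p` (NA with a flag when there are no far
#'   or no near cells), `flag`.
#' @export
neighbor_contingency <- function(table, type_i, type_j, radius_px,
                                 type_col = "true_type") {
  stopifnot(radius_px > 0)
  types <- table[[type_col]]
  xy <- cbind(table$x_px, table$y_px)
  ti <- types == type_i
  if (!any(ti)) stop("type_i has no cells")
  if (type_i == type_j) {
    d <- numeric(nrow(table))
    d[ti] <- .nn_dist(xy[ti, , drop = FALSE], xy[ti, , drop = FALSE],
                      drop_self = TRUE)
    d[!ti] <- .nn_dist(xy[ti, , drop = FALSE], xy[!ti, , drop = FALSE])
    is_j <- types == type_j
  } else {
    d <- .nn_dist(xy[ti, , drop = FALSE], xy[!ti, , drop = FALSE])
    is_j <- types[!ti] == type_j
  }
  near <- d <= radius_px
  counts <- matrix(
    c(sum(near & is_j), sum(near & !is_j),
      sum(!near & is_j), sum(!near & !is_j)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("near", "far"), c("type_j", "other"))
  )
  n_near <- sum(counts["near", ])
  n_far <- sum(counts["far", ])
  flag <- ""
  if (sum(is_j) == 0L) {
    ratio <- 0
    p <- 1
    flag <- "no type_j cells"
  } else if (n_far == 0L || n_near == 0L) {
    ratio <- NA_real_
    p <- NA_real_
    flag <- if (n_far == 0L) "no far cells" else "no near cells"
  } else {
    p_near <- counts["near", "type_j"] / n_near
    p_far <- counts["far", "type_j"] / n_far
    ratio <- if (p_far == 0) {
      if (p_near > 0) Inf else 0
    } else p_near / p_far
    p <- stats::fisher.test(counts)$p.value
  }
  odds <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  list(
    counts = counts, ratio = ratio,
    log_ratio = if (is.na(ratio)) NA_real_ else log(ratio),
    odds_ratio = odds, p = p, flag = flag
  )
}

#' Pairwise neighborhood analysis across a cohort
#'
#' Runs [neighbor_contingency()] for every ordered type pair (self pairs
#' included), sample and radius, and aggregates with
#' [consensus_significance()].
#'
#' @param tables list of `cell_table`s (one per sample).
#' @param radii_um neighborhood radii in micrometres (default 10 and 20).
#' @param pixel_size_um micrometres per pixel; default taken from the first
#'   table.
#' @param types type names to analyse (default: all observed).
#' @param type_col column holding cell type labels.
#' @param alpha_family family-wise significance level.
#' @param n_tests Bonferroni divisor m; default: the number of ordered type
#'   pairs actually tested (logged in the result so any threshold can be
#'   reproduced).
#' @param include_self evaluate self pairs (i == i)?
#' @return list: `per_test` long data.frame (sample, radius, i, j, counts,
#'   ratio, log_ratio, p, evaluable), `consensus` data.frame from
#'   [consensus_significance()], `m`, `threshold`.
#' @export
neighborhood_analysis <- function(tables, radii_um = c(10, 20),
                                  pixel_size_um = NULL, types = NULL,
                                  type_col = "true_type",
                                  alpha_family = 0.05, n_tests = NULL,
                                  include_self = FALSE) {
  if (is.data.frame(tables)) tables <- list(S1 = tables)
  if (is.null(names(tables))) names(tables) <- sprintf("S%d",
                                                       seq_along(tables))
  if (is.null(pixel_size_um)) pixel_size_um <- ct_pixel_size(tables[[1]])
  stopifnot(!is.unsorted(radii_um))
  if (is.null(types)) {
    types <- sort(unique(unlist(lapply(tables, function(t)
      t[[type_col]]))))
  }
  pairs <- expand.grid(i = types, j = types, stringsAsFactors = FALSE)
  if (!include_self) pairs <- pairs[pairs$i != pairs$j, ]
  radii_px <- radius_in_pixels(radii_um, pixel_size_um)
  rows <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    present <- table(tab[[type_col]])
    for (r in seq_along(radii_um)) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs$i[k]
        j <- pairs$j[k]
        ok <- !is.na(present[i]) && present[i] > 0 &&
          !is.na(present[j]) && present[j] > (i == j)
        if (!ok) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = nm, radius_um = radii_um[r], radius_px = radii_px[r],
            i = i, j = j, near_j = NA, near_other = NA, far_j = NA,
            far_other = NA, ratio = NA, log_ratio = NA, p = NA,
            evaluable = FALSE, stringsAsFactors = FALSE
          )
          next
        }
        res <- neighbor_contingency(tab, i, j, radii_px[r], type_col)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = nm, radius_um = radii_um[r], radius_px = radii_px[r],
          i = i, j = j,
          near_j = res$counts["near", "type_j"],
          near_other = res$counts["near", "other"],
          far_j = res$counts["far", "type_j"],
          far_other = res$counts["far", "other"],
          ratio = res$ratio, log_ratio = res$log_ratio, p = res$p,
          evaluable = !is.na(res$p), stringsAsFactors = FALSE
        )
      }
    }
  }
  per_test <- do.call(rbind, rows)
  cons <- consensus_significance(per_test, alpha_family = alpha_family,
                                 n_tests = n_tests)
  list(per_test = per_test, consensus = cons,
       m = attr(cons, "m"), threshold = attr(cons, "threshold"))
}

#' Strict multi-sample, dual-radius consensus significance
#'
#' A pair is significant only when every (sample containing both
#' populations) x (radius) test passes the Bonferroni-corrected threshold —
#' equivalently, when the maximum p over qualifying tests is at most
#' `alpha_family / m`. Pairs with no qualifying sample are not evaluable
#' (NA). Adding a sample can only remove significance, never create it.
#'
#' @param per_test long data.frame with columns `i`, `j`, `sample`,
#'   `radius_um`, `p`, `evaluable` (as produced by
#'   [neighborhood_analysis()] or [overlap_analysis()]).
#' @param alpha_family family-wise level (default 0.05).
#' @param n_tests Bonferroni divisor m; default: number of distinct
#'   evaluable pairs. The realized m and threshold are attached as
#'   attributes and returned columns so any printed threshold can be
#'   reproduced.
#' @return data.frame per pair: `i`, `j`, `n_tests_used`, `max_p`,
#'   `mean_log_ratio` (when ratios are present), `significant`, `m`,
#'   `threshold`.
#' @export
consensus_significance <- function(per_test, alpha_family = 0.05,
                                   n_tests = NULL) {
  stopifnot(all(c("i", "j", "p", "evaluable") %in% names(per_test)))
  key <- paste(per_test$i, per_test$j, sep = "\r")
  keys <- unique(key)
  evaluable_pair <- vapply(keys, function(k) {
    any(per_test$evaluable[key == k], na.rm = TRUE)
  }, logical(1))
  if (is.null(n_tests)) n_tests <- sum(evaluable_pair)
  if (n_tests < 1) stop("n_tests must be >= 1")
  threshold <- alpha_family / n_tests
  rows <- lapply(seq_along(keys), function(ki) {
    sub <- per_test[key == keys[ki], , drop = FALSE]
    q <- sub[sub$evaluable %in% TRUE, , drop = FALSE]
    has_lr <- "log_ratio" %in% names(sub)
    mlr <- if (has_lr && nrow(q)) {
      fin <- is.finite(q$log_ratio)
      if (any(fin)) mean(q$log_ratio[fin]) else NA_real_
    } else NA_real_
    if (!nrow(q)) {
      data.frame(i = sub$i[1], j = sub$j[1], n_tests_used = 0L,
                 max_p = NA_real_, mean_log_ratio = mlr,
                 significant = NA, stringsAsFactors = FALSE)
    } else {
      mp <- max(q$p)
      data.frame(i = sub$i[1], j = sub$j[1], n_tests_used = nrow(q),
                 max_p = mp, mean_log_ratio = mlr,
                 significant = mp <= threshold, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!"log_ratio" %in% names(per_test)) out$mean_log_ratio <- NULL
  out$m <- n_tests
  out$threshold <- threshold
  attr(out, "m") <- n_tests
  attr(out, "threshold") <- threshold
  out
}

#' Median nearest-neighbor distance between two cell types
#'
#' For every cell of type `i`, the Euclidean distance to its nearest cell
#' of type `j` (a cell is never its own neighbor); returns the median in
#' micrometres. The measure is directional: `i -> j` and `j -> i` are
#' computed separately.
#'
#' @param table a `cell_table`.
#' @param type_i,type_j origin and target types.
#' @param type_col column holding cell type labels.
#' @param pixel_size_um micrometres per pixel; default from the table.
#' @return median distance in micrometres (NA when `j` is absent).
#' @export
median_nearest_distance <- function(table, type_i, type_j,
                                    type_col = "true_type",
                                    pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- ct_pixel_size(table)
  types <- table[[type_col]]
  xy <- cbind(table$x_px, table$y_px)
  qi <- xy[types == type_i, , drop = FALSE]
  rj <- xy[types == type_j, , drop = FALSE]
  if (nrow(qi) == 0L) stop("type_i has no cells")
  if (nrow(rj) == 0L) return(NA_real_)
  d <- if (type_i == type_j) {
    if (nrow(rj) < 2L) return(NA_real_)
    .nn_dist(rj, qi, drop_self = TRUE)
  } else {
    .nn_dist(rj, qi)
  }
  stats::median(d) * pixel_size_um
}
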