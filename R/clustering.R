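# reporting floor on cluster size: ~20 cells or 0.005% of the sample,
# whichever is larger
cluster_size_floor <- function(n) {
  max(20L, as.integer(ceiling(5e-5 * n)))
}

#' Density-based clustering with a noise bucket
#'
#' Standard DBSCAN (radius neighborhoods, core points, components of the
#' core graph, border assignment to the nearest core point) used on the
#' low-dimensional embedding. Points in no cluster get the label -1, which
#' acts as a garbage collector for outliers.
#'
#' @param x numeric matrix of coordinates.
#' @param eps neighborhood radius.
#' @param min_pts minimum neighbors (self included) for a core point.
#' @param kmax cap on neighbors retrieved per point; only affects very dense
#'   neighborhoods and never the core/noise decision when `kmax >= min_pts`.
#' @return integer labels, clusters numbered from 1, noise -1.
#' @export
dbscan_cluster <- function(x, eps, min_pts = 10L, kmax = 64L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  k <- min(n, max(kmax, min_pts))
  nn <- RANN::nn2(x, x, k = k, searchtype = "radius", radius = eps)
  idx <- nn$nn.idx
  deg <- rowSums(idx > 0L)
  core <- deg >= min_pts
  labels <- rep(-1L, n)
  if (any(core)) {
    ii <- rep(seq_len(n), k)
    jj <- as.vector(idx)
    keep <- jj > 0L & core[ii] & core[pmax(jj, 1L)] & ii != jj
    g <- igraph::graph_from_edgelist(cbind(ii[keep], jj[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    # renumber components so that only those holding core points count
    core_comp <- sort(unique(comp[core]))
    relab <- integer(max(comp))
    relab[core_comp] <- seq_along(core_comp)
    labels[core] <- relab[comp[core]]
    # border points adopt the label of their nearest core neighbor
    border <- which(!core)
    if (length(border)) {
      for (col in seq_len(k)) {
        j <- idx[border, col]
        ok <- j > 0L & labels[border] == -1L
        ok[ok] <- core[j[ok]]
        if (any(ok)) labels[border[ok]] <- labels[j[ok]]
      }
    }
  }
  labels
}

# dissolve clusters smaller than the effective minimum size into noise and
# renumber the survivors 1..K by decreasing size
.filter_small_clusters <- function(labels, eff_min) {
  ids <- setdiff(unique(labels), -1L)
  if (!length(ids)) return(labels)
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  keep <- ids[sizes >= eff_min]
  out <- rep(-1L, length(labels))
  keep <- keep[order(-sizes[match(keep, ids)])]
  for (r in seq_along(keep)) out[labels == keep[r]] <- r
  out
}

#' Embed and density-cluster a preprocessed intensity matrix
#'
#' Runs a 2-D UMAP embedding followed by density clustering with a noise
#' (-1) bucket. Clusters smaller than the effective minimum size — the
#' larger of `min_cluster_size` and a floor of ~20 cells or 0.005% of the
#' sample — are dissolved into noise. All parameters and the seed are
#' recorded in the result.
#'
#' @param x numeric matrix (cells x markers), typically shrunk log
#'   intensities from [apply_shrinkage()].
#' @param min_cluster_size smallest reportable cluster (default 200; 100-300
#'   is the useful range for ~1e5-cell samples).
#' @param seed integer seed for the stochastic embedding.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param eps DBSCAN radius on the embedding; when NULL (default) it is set
#'   to `eps_factor` times the median `min_pts`-th nearest-neighbor distance.
#' @param eps_factor multiplier for the automatic eps.
#' @param min_pts DBSCAN core-point threshold.
#' @return an object of class `cluster_assignment` with integer `labels`
#'   (-1 = noise), the embedding, and provenance parameters.
#' @export
embed_and_cluster <- function(x, min_cluster_size = 200L, seed = 1L,
                              n_neighbors = 15L, min_dist = 0.1,
                              eps = NULL, eps_factor = 3, min_pts = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  eff_min <- max(min_cluster_size, cluster_size_floor(n))
  if (n < eff_min || n <= n_neighbors) {
    warning("fewer cells than the minimum cluster size; all cells -> noise")
    return(structure(
      list(level = "global", labels = rep(-1L, n), embedding = NULL,
           params = list(min_cluster_size = min_cluster_size,
                         eff_min = eff_min, seed = seed)),
      class = "cluster_assignment"
    ))
  }
  emb <- with_seed(seed, {
    uwot::umap(x, n_neighbors = min(n_neighbors, n - 1L),
               min_dist = min_dist, n_threads = 1L, n_sgd_threads = 0L,
               verbose = FALSE)
  })
  if (is.null(eps)) {
    dk <- FNN::get.knn(emb, k = min_pts)$nn.dist[, min_pts]
    eps <- eps_factor * stats::median(dk)
  }
  labels <- dbscan_cluster(emb, eps = eps, min_pts = min_pts)
  labels <- .filter_small_clusters(labels, eff_min)
  structure(
    list(
      level = "global", labels = labels, embedding = emb,
      params = list(min_cluster_size = min_cluster_size, eff_min = eff_min,
                    n_neighbors = n_neighbors, min_dist = min_dist,
                    eps = eps, eps_factor = eps_factor, min_pts = min_pts,
                    seed = seed)
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "cluster_assignment (%s): %d cells, %d clusters, %d noise\n",
    x$level, length(x$labels), sum(names(tab) != "-1"),
    sum(x$labels == -1L)
  ))
  invisible(x)
}

#' Two-level nested phenotype classification
#'
#' First pass: embedding + density clustering on the global marker panel;
#' each global cluster is mapped to a broad cell type by `broad_map`
#' (expert-style supervision — no automatic ontology matching). Second pass:
#' for every broad type that has a subpanel, its cells are re-clustered
#' independently on the subpanel markers only. Cells in the global noise
#' cluster (and excluded/unmapped clusters) never enter a subclass run; the
#' subclass -1 bucket means "average cell of that type" and is named
#' accordingly, not discarded.
#'
#' @param table a `cell_table`.
#' @param broad_map named character vector (global cluster id, as character,
#'   -> broad type name), or a function `(labels, table) -> named vector`
#'   evaluated after the global run. Clusters mapped to NA are treated as
#'   unassigned and excluded from subclassing.
#' @param subpanels named list: broad type -> character vector of markers
#'   for its subclass run. Broad types without a subpanel pass through with
#'   their global label only.
#' @param global_panel markers for the global run (default: all markers).
#' @param lambda shrinkage contraction factor.
#' @param G_i mixture-component budget for the shrinkage fit.
#' @param min_cluster_size,subclass_min_cluster_size minimum cluster sizes
#'   for the global and subclass runs.
#' @param seed integer seed (subclass runs derive their own seeds from it).
#' @param ... further arguments passed to [embed_and_cluster()].
#' @return an object of class `nested_assignment`: a per-cell data.frame
#'   (`cells`: cell_id, global_label, broad_type, subclass_label, cell_type,
#'   excluded) plus the global and per-type subclass `cluster_assignment`s,
#'   the shrinkage model and the shrunk matrix.
#' @export
nested_classify <- function(table, broad_map, subpanels = list(),
                            global_panel = NULL, lambda = 0.8, G_i = 20L,
                            min_cluster_size = 200L,
                            subclass_min_cluster_size = min_cluster_size,
                            seed = 1L, ...) {
  markers <- ct_markers(table)
  if (is.null(global_panel)) global_panel <- markers
  stopifnot(all(global_panel %in% markers),
            all(unlist(subpanels) %in% markers))
  model <- fit_shrinkage(ct_intensity_matrix(table), G_i = G_i, seed = seed)
  shrunk <- apply_shrinkage(model, table, lambda = lambda)
  glob <- embed_and_cluster(shrunk[, global_panel, drop = FALSE],
                            min_cluster_size = min_cluster_size,
                            seed = seed, ...)
  if (is.function(broad_map)) broad_map <- broad_map(glob$labels, table)
  broad <- rep(NA_character_, nrow(table))
  pos <- glob$labels != -1L
  broad[pos] <- unname(broad_map[as.character(glob$labels[pos])])
  cells <- data.frame(
    cell_id = table$cell_id,
    global_label = glob$labels,
    broad_type = broad,
    subclass_label = NA_integer_,
    cell_type = NA_character_,
    excluded = FALSE,
    stringsAsFactors = FALSE
  )
  sub_runs <- list()
  types <- setdiff(unique(broad), NA)
  for (k in seq_along(types)) {
    ty <- types[k]
    rows <- which(broad == ty)  # global noise/unmapped already NA here
    if (!ty %in% names(subpanels)) {
      cells$cell_type[rows] <- ty
      next
    }
    sub <- embed_and_cluster(
      shrunk[rows, subpanels[[ty]], drop = FALSE],
      min_cluster_size = subclass_min_cluster_size,
      seed = seed + 1000L * k, ...
    )
    sub$level <- "subclass"
    sub$broad_type <- ty
    sub_runs[[ty]] <- sub
    cells$subclass_label[rows] <- sub$labels
    cells$cell_type[rows] <- ifelse(
      sub$labels == -1L,
      paste("average", ty),
      sprintf("%s_%d", ty, sub$labels)
    )
  }
  cells$cell_type[cells$global_label == -1L] <- "noise"
  structure(
    list(cells = cells, global = glob, subclass = sub_runs,
         broad_map = broad_map, model = model, shrunk = shrunk,
         params = list(lambda = lambda, G_i = G_i,
                       min_cluster_size = min_cluster_size,
                       subclass_min_cluster_size = subclass_min_cluster_size,
                       seed = seed)),
    class = "nested_assignment"
  )
}

#' @export
print.nested_assignment <- function(x, ...) {
  cat(sprintf(
    "nested_assignment: %d cells, %d global clusters, %d broad types, %d subclass runs\n",
    nrow(x$cells), length(setdiff(unique(x$cells$global_label), -1L)),
    length(setdiff(unique(x$cells$broad_type), NA)), length(x$subclass)
  ))
  invisible(x)
}

#' Flag clusters as artifacts and exclude their cells downstream
#'
#' Staining or tissue artifacts surface as clusters with a unique phenotype
#' and spatial footprint; they can be excluded manually by id. Excluded
#' cells are dropped from every downstream statistic but stay in the table.
#'
#' @param assignment a `nested_assignment` (global-level cluster ids).
#' @param junk_ids integer ids of clusters to exclude; must all exist.
#' @return the assignment with `cells$excluded` set.
#' @export
flag_artifacts <- function(assignment, junk_ids) {
  stopifnot(inherits(assignment, "nested_assignment"))
  if (!length(junk_ids)) return(assignment)
  known <- unique(assignment$cells$global_label)
  bad <- setdiff(junk_ids, known)
  if (length(bad)) stop("unknown cluster id(s): ", paste(bad, collapse = ", "))
  assignment$cells$excluded <- assignment$cells$excluded |
    assignment$cells$global_label %in% junk_ids
  assignment
}

#' Characterize one cluster against the rest of the sample
#'
#' Per marker, a Welch two-sample t-test of the within-cluster distribution
#' against all other (non-excluded) cells, Bonferroni-corrected over
#' markers. The effect size is robust: difference of medians divided by the
#' pooled median absolute deviation. The profile lists the markers that are
#' significantly over-expressed (positive effect), ranked by decreasing
#' effect size.
#'
#' @param x matrix of shrunk log intensities (cells x markers).
#' @param in_cluster logical vector or integer indices of cluster cells.
#' @param alpha family significance level before Bonferroni (default 0.05).
#' @param cluster_id identifier stored in the profile.
#' @param coords optional two-column matrix of cell coordinates; the
#'   cluster's rows are stored as its spatial footprint.
#' @return an object of class `cluster_profile`: per-marker stats table,
#'   ranked significant-marker list, cell count and footprint.
#' @export
characterize_cluster <- function(x, in_cluster, alpha = 0.05,
                                 cluster_id = NULL, coords = NULL) {
  x <- as.matrix(x)
  if (!is.logical(in_cluster)) {
    idx <- rep(FALSE, nrow(x))
    idx[in_cluster] <- TRUE
    in_cluster <- idx
  }
  if (!any(in_cluster)) stop("cluster is empty")
  if (all(in_cluster)) stop("outside set is empty")
  markers <- colnames(x)
  res <- data.frame(marker = markers, p = NA_real_, effect = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (j in seq_along(markers)) {
    a <- x[in_cluster, j]
    b <- x[!in_cluster, j]
    if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12 &&
        abs(mean(a) - mean(b)) < 1e-12) {
      res$note[j] <- "zero variance in both groups; skipped"
      next
    }
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      res$note[j] <- "degenerate test; skipped"
      next
    }
    res$p[j] <- tt$p.value
    pooled_mad <- sqrt((stats::mad(a)^2 + stats::mad(b)^2) / 2)
    d <- stats::median(a) - stats::median(b)
    res$effect[j] <- if (pooled_mad > 0) d / pooled_mad else
      sign(d) * Inf
  }
  res$p_adj <- stats::p.adjust(res$p, method = "bonferroni")
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha & res$effect > 0
  ranked <- res$marker[res$significant][
    order(-res$effect[res$significant])]
  structure(
    list(
      cluster = cluster_id, n_cells = sum(in_cluster), table = res,
      ranked = ranked,
      footprint = if (!is.null(coords))
        coords[in_cluster, , drop = FALSE] else NULL
    ),
    class = "cluster_profile"
  )
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat(sprintf(
    "cluster_profile [%s]: %d cells, %d significant markers\n",
    if (is.null(x$cluster)) "?" else as.character(x$cluster),
    x$n_cells, length(x$ranked)
  ))
  if (length(x$ranked)) {
    cat("top:", paste(utils::head(x$ranked, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Profile every reported cluster of an assignment
#'
#' @param shrunk matrix of shrunk log intensities.
#' @param labels cluster labels (-1 ignored).
#' @param excluded optional logical; excluded cells are dropped entirely.
#' @param alpha significance level, Bonferroni-corrected over markers.
#' @param coords optional coordinates for footprints.
#' @return named list of `cluster_profile`s, one per non-noise cluster.
#' @export
characterize_clusters <- function(shrunk, labels, excluded = NULL,
                                  alpha = 0.05, coords = NULL) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(labels))
  keep <- !excluded
  shrunk <- shrunk[keep, , drop = FALSE]
  if (!is.null(coords)) coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- sort(setdiff(unique(labels), -1L))
  out <- lapply(ids, function(id) {
    characterize_cluster(shrunk, labels == id, alpha = alpha,
                         cluster_id = id, coords = coords)
  })
  names(out) <- as.character(ids)
  out
}
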