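# consensus aggregation applied to overlap p-values follows the exact
# scheme of the neighborhood analysis
#' @rdname consensus_significance
#' @export
overlap_consensus <- function(per_test, alpha_family = 0.05,
                              n_tests = NULL) {
  consensus_significance(per_test, alpha_family = alpha_family,
                         n_tests = n_tests)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full classification and spatial-statistics pipeline
#'
#' Executes, in order: lognormal-shrinkage preprocessing, nested two-level
#' clustering, artifact exclusion, cluster profiling and cell-type
#' summaries, dual-radius neighborhood analysis, interaction-overlap
#' analysis, and (when zone labels are present) zonal enrichment and
#' composition matrices. Deterministic given the config seed; every output
#' file carries a config-hash/seed sidecar.
#'
#' @param tables named list of `cell_table`s (one per sample).
#' @param broad_map named vector or function mapping global clusters to
#'   broad types; see [nested_classify()].
#' @param subpanels named list of subclass marker panels per broad type.
#' @param config a [run_config()].
#' @param type_map optional function `(assignment, table) -> named vector`
#'   mapping profiled cluster keys to cell type names; default: a subclass
#'   cluster belongs to its broad type.
#' @param out_dir optional output directory for CSV bundles.
#' @return list with elements `assignments`, `profiles`, `summaries`,
#'   `typed_tables`, `neighborhood`, `overlap`, `zones`, `config`, `log`.
#' @export
run_pipeline <- function(tables, broad_map, subpanels = list(),
                         config = run_config(), type_map = NULL,
                         out_dir = NULL) {
  validate_run_config(config)
  if (is.data.frame(tables)) tables <- list(S1 = tables)
  if (is.null(names(tables))) names(tables) <- sprintf("S%d",
                                                       seq_along(tables))
  log <- list()
  assignments <- list()
  typed <- list()
  profiles <- list()
  maps <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    asg <- .stage(paste0("clustering[", nm, "]"), {
      nested_classify(
        tab, broad_map = broad_map, subpanels = subpanels,
        lambda = config$lambda, G_i = config$G_i,
        min_cluster_size = config$min_cluster_size, seed = config$seed
      )
    })
    junk <- config$junk_ids[[nm]]
    if (!is.null(junk) && length(junk)) {
      asg <- .stage(paste0("artifact-exclusion[", nm, "]"),
                    flag_artifacts(asg, junk))
    }
    assignments[[nm]] <- asg
    tab$cell_type <- asg$cells$cell_type
    tab$excluded <- asg$cells$excluded
    typed[[nm]] <- as_cell_table(tab, template = tab)
    log[[nm]] <- list(
      n_cells = nrow(tab),
      n_global_clusters = length(setdiff(unique(asg$cells$global_label),
                                         -1L)),
      n_noise = sum(asg$cells$global_label == -1L),
      n_excluded = sum(asg$cells$excluded)
    )
  }
  # profiling: subclass clusters (fallback to global-only types), against
  # all non-excluded cells of the sample
  summaries <- list()
  for (nm in names(tables)) {
    asg <- assignments[[nm]]
    cells <- asg$cells
    usable <- !cells$excluded & cells$global_label != -1L &
      !is.na(cells$cell_type)
    prof <- .stage(paste0("profiling[", nm, "]"), {
      if (!any(usable)) stop("no usable cells after exclusion")
      labs <- ifelse(usable, cells$cell_type, NA_character_)
      ids <- sort(setdiff(unique(labs), NA))
      shr <- asg$shrunk
      coords <- cbind(tables[[nm]]$x_px, tables[[nm]]$y_px)
      keep <- !cells$excluded
      out <- lapply(ids, function(id) {
        characterize_cluster(
          shr[keep, , drop = FALSE],
          (labs == id)[keep] %in% TRUE,
          alpha = config$alpha_family, cluster_id = id,
          coords = coords[keep, , drop = FALSE]
        )
      })
      names(out) <- ids
      out
    })
    profiles[[nm]] <- prof
    tm <- if (is.null(type_map)) {
      # default: a subclass cluster's cell type is its broad type;
      # passthrough clusters keep their own name
      sapply(names(prof), function(id) {
        hit <- match(id, cells$cell_type)
        bt <- cells$broad_type[hit]
        if (is.na(bt)) id else bt
      })
    } else {
      type_map(asg, tables[[nm]])
    }
    maps[[nm]] <- tm
    summaries[[nm]] <- .stage(paste0("summaries[", nm, "]"), {
      pos <- marker_positivity(asg$model, tables[[nm]])
      cell_ty <- rep(NA_character_, nrow(tables[[nm]]))
      ok <- usable
      cell_ty[ok] <- unname(tm[cells$cell_type[ok]])
      cell_type_summary(prof, tm, positivity = pos, cell_types = cell_ty)
    })
  }
  # spatial statistics on classified, non-noise, non-excluded cells
  stat_tables <- lapply(typed, function(tab) {
    keep <- !tab$excluded & !is.na(tab$cell_type) &
      tab$cell_type != "noise"
    as_cell_table(tab[keep, , drop = FALSE], template = tab)
  })
  nbr <- .stage("neighborhood", neighborhood_analysis(
    stat_tables, radii_um = config$radii_um,
    pixel_size_um = config$pixel_size, type_col = "cell_type",
    alpha_family = config$alpha_family
  ))
  ovl <- .stage("overlap", overlap_analysis(
    stat_tables, radii_um = config$radii_um,
    pixel_size_um = config$pixel_size, type_col = "cell_type",
    alpha_family = config$alpha_family,
    include_self = isTRUE(config$include_self_overlap),
    n_boot = config$n_boot, seed = config$seed
  ))
  zres <- NULL
  has_zones <- all(vapply(tables, function(t) "zone" %in% names(t),
                          logical(1))) &&
    any(vapply(tables, function(t) any(t$zone != "interstitial"),
               logical(1)))
  if (has_zones) {
    zres <- .stage("zones", list(
      enrichment = zone_enrichment(
        stat_tables, type_col = "cell_type",
        alpha_family = config$alpha_family),
      composition = composition_matrices(stat_tables,
                                         type_col = "cell_type")
    ))
  }
  bundle <- list(
    assignments = assignments, profiles = profiles, summaries = summaries,
    type_maps = maps, typed_tables = typed, neighborhood = nbr,
    overlap = ovl, zones = zres, config = config, log = log
  )
  if (!is.null(out_dir)) {
    .stage("write-outputs", write_bundle(bundle, out_dir))
  }
  bundle
}

#' Write a pipeline result bundle as CSV files
#'
#' @param bundle result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  seed <- cfg$seed
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    .write_sidecar(p, cfg, seed)
  }
  for (nm in names(bundle$assignments)) {
    wr(bundle$assignments[[nm]]$cells,
       sprintf("assignment_%s.csv", nm))
    ranked <- do.call(rbind, lapply(bundle$profiles[[nm]], function(p) {
      if (!length(p$ranked)) return(NULL)
      data.frame(cluster = p$cluster, rank = seq_along(p$ranked),
                 marker = p$ranked, stringsAsFactors = FALSE)
    }))
    if (!is.null(ranked)) wr(ranked, sprintf("ranked_markers_%s.csv", nm))
  }
  wr(bundle$neighborhood$per_test, "neighborhood_per_test.csv")
  wr(bundle$neighborhood$consensus, "neighborhood_consensus.csv")
  wr(bundle$overlap$per_test, "overlap_per_test.csv")
  wr(bundle$overlap$consensus, "overlap_consensus.csv")
  if (!is.null(bundle$zones)) {
    wr(bundle$zones$enrichment$per_test, "zonal_per_test.csv")
    wr(bundle$zones$enrichment$aggregate, "zonal_aggregate.csv")
    wr(as.data.frame(bundle$zones$composition$type_by_region),
       "type_by_region.csv")
    wr(as.data.frame(bundle$zones$composition$region_composition),
       "region_composition.csv")
  }
  invisible(out_dir)
}
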