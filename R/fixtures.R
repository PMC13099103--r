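#' Reference synthetic scenarios
#'
#' Canonical generator configurations used throughout the package's test
#' bench and reproduction script. Each captures one study condition:
#' complete spatial randomness for calibration, a dense-background cohort
#' for the spatial statistics, marker panels at two noise levels for the
#' clustering stages. Their parameters are fixed design choices, not
#' tuning knobs.
#'
#' @name bench_specs
NULL

#' @describeIn bench_specs Two CSR cell types and no markers: the null
#'   condition for the neighborhood false-positive calibration
#'   (2,000 cells per type on a 2,000 px square field, ~0.45 um/px).
#' @param n_per_type cells per type.
#' @param field field side length in pixels.
#' @export
bench_csr_pair_spec <- function(n_per_type = 2000L, field = 2000L) {
  synthetic_spec(
    field, field, 2L * n_per_type,
    data.frame(name = c("A", "B"), fraction = c(0.5, 0.5),
               mode = "poisson", stringsAsFactors = FALSE)
  )
}

#' @describeIn bench_specs A dense background population (`T0`) plus four
#'   sparse focal types on a 2,250 px field: the regime where each focal
#'   type's interaction area is small against the tissue area, as in
#'   densely packed tissue. Base condition for planted-co-localization
#'   recovery and the overlap null calibration.
#' @param n_background background cells.
#' @param n_focal cells per focal type.
#' @export
bench_background_spec <- function(n_background = 3000L, n_focal = 300L,
                                  field = 2250L) {
  n <- n_background + 4L * n_focal
  fr <- c(n_background, rep(n_focal, 4)) / n
  synthetic_spec(
    field, field, n,
    data.frame(name = c("T0", paste0("T", 1:4)), fraction = fr,
               mode = "poisson", stringsAsFactors = FALSE)
  )
}

#' @describeIn bench_specs Three equally abundant CSR types with a
#'   6-marker panel, two expressed markers per type. `sd_log` sets the
#'   within-component lognormal spread: 0.35 gives well-separated
#'   phenotypes, 0.55 a moderately noisy panel where preprocessing has
#'   room to help.
#' @param n total cells.
#' @param sd_log log-scale intensity sd of both mixture components.
#' @export
bench_three_type_spec <- function(n = 4000L, field = 1200L,
                                  sd_log = 0.35) {
  tm <- list(A = c("m1", "m2"), B = c("m3", "m4"), C = c("m5", "m6"))
  mm <- simple_marker_model(tm, pos_frac = 0.95, mu_pos = log(80),
                            sd_pos = sd_log, mu_neg = log(10),
                            sd_neg = sd_log, bg_pos_frac = 0.03)
  synthetic_spec(
    field, field, n,
    data.frame(name = c("A", "B", "C"), fraction = rep(1 / 3, 3),
               mode = "poisson", stringsAsFactors = FALSE),
    marker_model = mm
  )
}

#' @describeIn bench_specs Two broad lineages (B, T) of three subtypes
#'   each, with a realistic panel layout: two shared lineage markers per
#'   broad type plus two subtype-specific markers, 16 markers total. The
#'   study condition for nested two-level classification.
#' @export
bench_nested_spec <- function(n = 6000L, field = 1500L) {
  tm <- list(
    B1 = c("CD20", "CD79a", "s1a", "s1b"),
    B2 = c("CD20", "CD79a", "s2a", "s2b"),
    B3 = c("CD20", "CD79a", "s3a", "s3b"),
    T1 = c("CD3", "CD5", "s4a", "s4b"),
    T2 = c("CD3", "CD5", "s5a", "s5b"),
    T3 = c("CD3", "CD5", "s6a", "s6b")
  )
  synthetic_spec(
    field, field, n,
    data.frame(name = names(tm), fraction = rep(1 / 6, 6),
               mode = "poisson", stringsAsFactors = FALSE),
    marker_model = simple_marker_model(tm)
  )
}

#' @describeIn bench_specs Ground-truth broad lineage of each subtype in
#'   [bench_nested_spec()].
#' @export
bench_nested_broad_truth <- function() {
  stats::setNames(rep(c("B", "T"), each = 3),
                  c("B1", "B2", "B3", "T1", "T2", "T3"))
}

#' @describeIn bench_specs Subclass marker panels for
#'   [bench_nested_spec()], one per broad lineage.
#' @export
bench_nested_subpanels <- function() {
  list(
    B = c("s1a", "s1b", "s2a", "s2b", "s3a", "s3b"),
    T = c("s4a", "s4b", "s5a", "s5b", "s6a", "s6b")
  )
}

#' @describeIn bench_specs A light-chain cohort condition: kappa and
#'   lambda plasma-cell populations at a 1.5 abundance ratio on a dense
#'   B/T background, mirroring the reported tissue kappa/lambda balance.
#' @export
bench_light_chain_spec <- function(n = 4000L, field = 1500L) {
  synthetic_spec(
    field, field, n,
    data.frame(
      name = c("Bcell", "Tcell", "PC_kappa", "PC_lambda"),
      fraction = c(0.55, 0.30, 0.09, 0.06),
      mode = "poisson", stringsAsFactors = FALSE
    )
  )
}
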