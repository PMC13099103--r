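# deterministic geometry with exact near/far composition around type "I":
# near cells sit 5 px from an I cell, far cells 500+ px away
composition_table <- function(near_j, near_o, far_j, far_o) {
  n <- near_j + near_o
  f <- far_j + far_o
  ang_n <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  ang_f <- seq(0, 2 * pi, length.out = f + 1)[seq_len(f)]
  df <- data.frame(
    cell_id = sprintf("c%04d", seq_len(1 + n + f)),
    x_px = c(3000, 3000 + 5 * cos(ang_n), 3000 + 500 * cos(ang_f)),
    y_px = c(3000, 3000 + 5 * sin(ang_n), 3000 + 500 * sin(ang_f)),
    true_type = c("I", rep(c("J", "O"), c(near_j, near_o)),
                  rep(c("J", "O"), c(far_j, far_o))),
    stringsAsFactors = FALSE
  )
  as_cell_table(df, markers = character(0), pixel_size = 0.45,
                field_dim = c(6000, 6000))
}

test_that("the worked proportion example gives an enrichment ratio of 4", {
  tab <- composition_table(40, 160, 10, 190)
  res <- neighbor_contingency(tab, "I", "J", radius_px = 22)
  expect_identical(res$counts["near", "type_j"], 40L)
  expect_identical(res$counts["far", "other"], 190L)
  expect_equal(res$ratio, 4)
  expect_equal(res$log_ratio, log(4))
})

test_that("micrometre radii convert to the printed pixel thresholds", {
  expect_identical(radius_in_pixels(10, 0.45), 22L)
  expect_identical(radius_in_pixels(20, 0.45), 44L)
  expect_identical(radius_in_pixels(10, 1.0), 10L)
  expect_identical(radius_in_pixels(c(10, 20), 0.45), c(22L, 44L))
  expect_error(radius_in_pixels(-1, 0.45))
})

test_that("Fisher p agrees with hypergeometric enumeration on small tables", {
  with_seed(31, {
    for (case in seq_len(25)) {
      counts <- sample(0:12, 4, replace = TRUE)
      if (sum(counts[c(1, 3)]) == 0) counts[1] <- 1
      tab <- composition_table(counts[1], counts[2] + 1,
                               counts[3], counts[4] + 1)
      res <- neighbor_contingency(tab, "I", "J", radius_px = 22)
      expect_equal(res$p, brute_fisher_p(res$counts), tolerance = 1e-9)
      # enrichment ratio and odds ratio always agree in direction
      if (is.finite(res$ratio) && is.finite(res$odds_ratio) &&
          res$ratio != 0) {
        expect_equal(res$ratio > 1, res$odds_ratio > 1)
      }
    }
  })
})

test_that("degenerate compositions follow the stated contracts", {
  # no type j anywhere -> ratio 0, p = 1
  tab <- composition_table(0, 100, 0, 100)
  res <- neighbor_contingency(tab, "I", "J", radius_px = 22)
  expect_equal(res$ratio, 0)
  expect_equal(res$p, 1)
  # all j near, none far -> +Inf sentinel with an exact p
  tab2 <- composition_table(30, 70, 0, 100)
  res2 <- neighbor_contingency(tab2, "I", "J", radius_px = 22)
  expect_identical(res2$ratio, Inf)
  expect_equal(res2$p, brute_fisher_p(res2$counts), tolerance = 1e-9)
  # no far cells at all -> flagged, p undefined
  tab3 <- composition_table(20, 80, 0, 0)
  res3 <- neighbor_contingency(tab3, "I", "J", radius_px = 22)
  expect_true(is.na(res3$p))
  expect_match(res3$flag, "no far")
})

test_that("consensus follows the strict max-p rule and is monotone", {
  base <- expand.grid(sample = c("S1", "S2"), radius_um = c(10, 20),
                      i = "A", j = "B", stringsAsFactors = FALSE)
  base$p <- c(1e-9, 1e-9, 1e-9, 1e-9)
  base$evaluable <- TRUE
  cons <- consensus_significance(base, alpha_family = 0.05, n_tests = 10)
  expect_true(cons$significant)
  expect_equal(cons$max_p, 1e-9)
  # one failing test anywhere kills the pair
  base$p[3] <- 0.02
  expect_false(consensus_significance(base, 0.05, 10)$significant)
  # all p = 0 -> significant
  base$p <- 0
  expect_true(consensus_significance(base, 0.05, 10)$significant)
  # monotone: adding a sample can never create significance
  with_seed(13, {
    for (k in seq_len(20)) {
      df <- expand.grid(sample = sprintf("S%d", 1:3),
                        radius_um = c(10, 20), i = "A", j = "B",
                        stringsAsFactors = FALSE)
      df$p <- stats::runif(6, 0, 2e-3)
      df$evaluable <- TRUE
      small <- consensus_significance(df[df$sample != "S3", ], 0.05, 50)
      full <- consensus_significance(df, 0.05, 50)
      expect_true(small$significant || !full$significant)
    }
  })
  # no qualifying sample -> not evaluable
  base$evaluable <- FALSE
  ne <- consensus_significance(base, 0.05, 10)
  expect_true(is.na(ne$significant))
  expect_error(consensus_significance(base, 0.05, 0), "n_tests")
})

test_that("the realized Bonferroni threshold reproduces the printed scale", {
  df <- data.frame(sample = "S1", radius_um = 10, i = "A", j = "B",
                   p = 1e-9, evaluable = TRUE)
  cons <- consensus_significance(df, alpha_family = 0.05, n_tests = 6177)
  expect_equal(attr(cons, "threshold"), 0.05 / 6177)
  expect_equal(attr(cons, "threshold"), 8.094544277157197e-06,
               tolerance = 1e-12)
  expect_equal(attr(cons, "m"), 6177)
})

test_that("median nearest distances are directional and unit-correct", {
  df <- data.frame(cell_id = c("a", "b"), x_px = c(0, 3), y_px = c(0, 4),
                   true_type = c("A", "B"), stringsAsFactors = FALSE)
  tab <- as_cell_table(df, markers = character(0), pixel_size = 0.45)
  expect_equal(median_nearest_distance(tab, "A", "B"), 5 * 0.45)
  expect_equal(median_nearest_distance(tab, "B", "A"), 5 * 0.45)
  # grid shifted by 5 px -> exactly 2.25 um
  g <- expand.grid(x = seq(100, 900, by = 50), y = seq(100, 900, by = 50))
  df2 <- data.frame(
    cell_id = sprintf("c%04d", seq_len(2 * nrow(g))),
    x_px = c(g$x, g$x + 5), y_px = c(g$y, g$y),
    true_type = rep(c("A", "B"), each = nrow(g)),
    stringsAsFactors = FALSE
  )
  tab2 <- as_cell_table(df2, markers = character(0), pixel_size = 0.45)
  expect_equal(median_nearest_distance(tab2, "A", "B"), 2.25)
  expect_true(is.na(median_nearest_distance(tab2, "A", "Z")))
})

test_that("CSR nearest-neighbor distance matches the Poisson closed form", {
  tab <- generate_sample(bench_csr_pair_spec(n_per_type = 2000,
                                             field = 1414), 23)
  rho <- sum(tab$true_type == "B") / 1414^2
  theory <- sqrt(log(2) / (pi * rho)) * 0.45
  med <- median_nearest_distance(tab, "A", "B")
  expect_lt(abs(med - theory) / theory, 0.10)
})

test_that("single-sample CSR compositions are null at the nominal level", {
  ct <- data.frame(name = c("A", "B", "C"), fraction = c(1/3, 1/3, 1/3),
                   mode = "poisson")
  sp <- synthetic_spec(1200, 1200, 750, ct)
  res <- vapply(seq_len(100), function(k) {
    tab <- generate_sample(sp, 500 + k)
    r <- neighbor_contingency(tab, "A", "B", radius_px = 22)
    c(p = r$p, lr = r$log_ratio)
  }, numeric(2))
  expect_gte(sum(res["p", ] > 0.05), 94)
  expect_lt(abs(mean(res["lr", ][is.finite(res["lr", ])])), 0.05)
})
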