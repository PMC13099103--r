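test_that("rasterized discs match the analytic area and disjoint additivity", {
  one <- rasterize_interaction(cbind(300, 300), 22, 600, 600)
  expect_lt(abs(one$area - pi * 22^2) / (pi * 22^2), 0.02)
  two <- rasterize_interaction(rbind(c(150, 150), c(450, 450)), 22,
                               600, 600)
  expect_equal(two$area, 2L * one$area)
  coincident <- rasterize_interaction(rbind(c(300, 300), c(300, 300)),
                                      22, 600, 600)
  expect_equal(coincident$area, one$area)
  expect_equal(max(coincident$counts), 2L)
  empty <- rasterize_interaction(matrix(numeric(0), ncol = 2), 22, 50, 50)
  expect_equal(empty$area, 0L)
  expect_true(all(empty$counts == 0L))
})

test_that("production rasterization equals per-pixel brute force exactly", {
  with_seed(71, {
    for (case in seq_len(20)) {
      W <- sample(40:128, 1)
      H <- sample(40:128, 1)
      n <- sample(1:20, 1)
      r <- sample(5:22, 1)
      pts <- cbind(stats::runif(n, 1, W), stats::runif(n, 1, H))
      ras <- rasterize_interaction(pts, r, W, H)
      brute <- brute_coverage(pts, r, W, H)
      expect_identical(as.integer(ras$counts), as.integer(brute))
      expect_identical(ras$area, sum(brute > 0L))
      expect_identical(ras$multi, sum(brute > 1L))
    }
  })
})

test_that("tissue area dominates population areas and fills dense fields", {
  df <- data.frame(cell_id = "c1", x_px = 100, y_px = 100,
                   true_type = "A", stringsAsFactors = FALSE)
  tab <- as_cell_table(df, markers = character(0), pixel_size = 0.45,
                       field_dim = c(200, 200))
  tis <- tissue_area(tab, 22)
  expect_equal(tis$A, rasterize_interaction(cbind(100, 100), 22, 200,
                                            200)$area)
  dense <- generate_sample(synthetic_spec(500, 500, 2000,
    data.frame(name = c("A", "B"), fraction = c(0.5, 0.5),
               mode = "poisson")), 3)
  tis2 <- tissue_area(dense, 22)
  a_pop <- rasterize_interaction(
    cbind(dense$x_px, dense$y_px)[dense$true_type == "A", ], 22, 500, 500)
  expect_gte(tis2$A, a_pop$area)
  expect_gt(tis2$A / (500 * 500), 0.95)
})

test_that("same-type double coverage follows the stated degeneracies", {
  pts <- rbind(c(100, 100), c(100, 100), c(100, 100))
  df <- data.frame(cell_id = as.character(1:3), x_px = pts[, 1],
                   y_px = pts[, 2], true_type = "A",
                   stringsAsFactors = FALSE)
  tab <- as_cell_table(df, markers = character(0),
                       field_dim = c(300, 300))
  tis <- tissue_area(tab, 15)
  res <- suppressWarnings(self_overlap_test(pts, tis, 15, n_boot = 50,
                                            seed = 1))
  expect_equal(res$observed_ratio, 1)
  far <- rbind(c(50, 50), c(250, 250))
  df2 <- df[1:2, ]
  df2$x_px <- far[, 1]
  df2$y_px <- far[, 2]
  tab2 <- as_cell_table(df2, markers = character(0),
                        field_dim = c(300, 300))
  tis2 <- tissue_area(tab2, 15)
  res2 <- suppressWarnings(self_overlap_test(far, tis2, 15, n_boot = 50,
                                             seed = 1))
  expect_equal(res2$o_i, 0L)
  expect_equal(res2$observed_ratio, 0)
  expect_warning(self_overlap_test(far, tis2, 15, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("CSR double coverage sits near its binomial expectation", {
  sp <- synthetic_spec(900, 900, 1200,
    data.frame(name = c("A", "B"), fraction = c(0.25, 0.75),
               mode = "poisson"))
  tab <- generate_sample(sp, 5)
  tis <- tissue_area(tab, 22)
  a_pts <- cbind(tab$x_px, tab$y_px)[tab$true_type == "A", ]
  res <- self_overlap_test(a_pts, tis, 22, n_boot = 300, seed = 2)
  expect_lt(abs(res$observed_ratio - res$expected_ratio),
            3 * max(res$boot_sd, 1e-3))
  expect_gt(res$p, 0.01)
})

test_that("cross overlap is a symmetric Jaccard with a binomial tail p", {
  pts_a <- rbind(c(60, 60), c(120, 60), c(60, 120))
  ras_a <- rasterize_interaction(pts_a, 15, 400, 400)
  same <- cross_overlap_test(ras_a, ras_a, A = 150000, n_i = 3, n_j = 3)
  expect_equal(same$o_ij, 1)
  pts_b <- pts_a + 200
  ras_b <- rasterize_interaction(pts_b, 15, 400, 400)
  apart <- cross_overlap_test(ras_a, ras_b, A = 150000, n_i = 3, n_j = 3)
  expect_equal(apart$o_ij, 0)
  expect_equal(apart$k, 0)
  expect_equal(apart$p,
               stats::pbinom(0, 3, max(ras_a$area, ras_b$area) / 150000,
                             lower.tail = FALSE))
  # symmetry: same rasters, same statistic
  ab <- cross_overlap_test(ras_a, ras_b, A = 150000, n_i = 3, n_j = 5)
  ba <- cross_overlap_test(ras_b, ras_a, A = 150000, n_i = 5, n_j = 3)
  expect_equal(ab$o_ij, ba$o_ij)
  expect_equal(ab$p, ba$p)
  # the k threshold is the floor of o_ij * min(n), exceeded strictly
  mixed <- cross_overlap_test(ras_a,
    rasterize_interaction(pts_a + 10, 15, 400, 400),
    A = 150000, n_i = 3, n_j = 7)
  expect_equal(mixed$k, floor(mixed$o_ij * 3))
})

test_that("coupled populations overlap more than CSR ones, pairwise", {
  better <- 0
  for (k in seq_len(12)) {
    ct_coupled <- data.frame(
      name = c("bg", "P", "C"), fraction = c(0.6, 0.2, 0.2),
      mode = c("poisson", "poisson", "coupled"),
      partner = c(NA, NA, "P"), displacement_sd = c(NA, NA, 3)
    )
    ct_csr <- ct_coupled
    ct_csr$mode <- "poisson"
    sp_c <- synthetic_spec(1500, 1500, 1500, ct_coupled)
    sp_0 <- synthetic_spec(1500, 1500, 1500, ct_csr)
    run <- function(sp, seed) {
      tab <- generate_sample(sp, seed)
      tis <- tissue_area(tab, 22)
      xy <- cbind(tab$x_px, tab$y_px)
      cross_overlap_test(xy[tab$true_type == "P", ],
                         xy[tab$true_type == "C", ], tis$A,
                         r_px = 22, width = 1500, height = 1500)
    }
    rc <- run(sp_c, 900 + k)
    r0 <- run(sp_0, 900 + k)
    better <- better + (rc$o_ij > r0$o_ij && rc$p < r0$p)
  }
  expect_gte(better, 11)
})

test_that("overlap consensus obeys the shared max-p rule", {
  df <- expand.grid(sample = c("S1", "S2"), radius_um = c(10, 20),
                    i = "A", j = "B", stringsAsFactors = FALSE)
  df$p <- 0
  df$evaluable <- TRUE
  expect_true(overlap_consensus(df, 0.05, 5)$significant)
  df$p[2] <- 0.2
  expect_false(overlap_consensus(df, 0.05, 5)$significant)
})
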