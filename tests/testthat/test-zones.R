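# cohort of samples with two square regions; type X lives in Z1,
# type Y is uniform, interstitial space remains between regions
zone_polys <- list(
  Z1 = cbind(c(50, 250, 250, 50), c(50, 50, 250, 250)),
  Z2 = cbind(c(350, 550, 550, 350), c(350, 350, 550, 550))
)

zoned_sample <- function(seed, n_x = 120, n_y = 400, x_in_z1 = TRUE) {
  with_seed(seed, {
    xy_x <- if (x_in_z1) runif_rect(n_x, 55, 245, 55, 245) else
      runif_rect(n_x, 1, 599, 1, 599)
    xy_y <- runif_rect(n_y, 1, 599, 1, 599)
    df <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n_x + n_y)),
      x_px = c(xy_x[, 1], xy_y[, 1]), y_px = c(xy_x[, 2], xy_y[, 2]),
      true_type = rep(c("X", "Y"), c(n_x, n_y)),
      stringsAsFactors = FALSE
    )
    tab <- as_cell_table(df, markers = character(0), pixel_size = 0.45,
                         field_dim = c(600, 600))
    assign_zones(tab, polygons = zone_polys)
  })
}

test_that("composition matrices have exact normalizations", {
  one <- data.frame(true_type = "X", zone = "Z1")
  cm <- composition_matrices(one)
  expect_equal(unname(cm$type_by_region[1, 1]), 100)
  expect_equal(unname(cm$region_composition[1, 1]), 100)
  # 30/70 split across two regions
  two <- data.frame(true_type = "X",
                    zone = rep(c("Z1", "Z2"), c(30, 70)))
  cm2 <- composition_matrices(two)
  expect_equal(unname(cm2$type_by_region["X", c("Z1", "Z2")]), c(30, 70))
  # random multi-sample case against a brute-force recount
  tabs <- lapply(1:3, function(k) zoned_sample(400 + k))
  cm3 <- composition_matrices(tabs, type_col = "true_type")
  expect_equal(unname(rowSums(cm3$type_by_region)), rep(100, 2),
               tolerance = 1e-6)
  expect_equal(unname(colSums(cm3$region_composition)), rep(100, 3),
               tolerance = 1e-6)
  pooled <- do.call(rbind, lapply(tabs, function(t)
    as.data.frame(t)[c("true_type", "zone")]))
  brute <- 100 * sum(pooled$true_type == "X" & pooled$zone == "Z1") /
    sum(pooled$true_type == "X")
  expect_equal(unname(cm3$type_by_region["X", "Z1"]), brute)
})

test_that("a type planted inside one region is enriched there only", {
  tabs <- lapply(1:6, function(k) zoned_sample(500 + k))
  res <- zone_enrichment(tabs)
  agg <- res$aggregate
  z1x <- agg[agg$region == "Z1" & agg$type == "X", ]
  expect_true(z1x$significant)
  expect_equal(z1x$direction, "enriched")
  z2x <- agg[agg$region == "Z2" & agg$type == "X", ]
  expect_true(z2x$significant)
  expect_equal(z2x$direction, "depleted")
  expect_equal(res$m, 4L)  # 2 regions x 2 types, separate family
  expect_equal(res$threshold, 0.05 / 4)
})

test_that("uniform types yield no significant zonal enrichment", {
  tabs <- lapply(1:6, function(k) zoned_sample(600 + k, x_in_z1 = FALSE))
  res <- zone_enrichment(tabs)
  expect_false(any(res$aggregate$significant))
})

test_that("a sign flip in one sample vetoes significance", {
  tabs <- lapply(1:5, function(k) zoned_sample(700 + k))
  # sixth sample: X entirely outside Z1 (depleted there)
  flip <- with_seed(99, {
    xy_x <- runif_rect(120, 300, 599, 300, 340)
    xy_y <- runif_rect(400, 1, 599, 1, 599)
    df <- data.frame(
      cell_id = sprintf("c%04d", 1:520),
      x_px = c(xy_x[, 1], xy_y[, 1]), y_px = c(xy_x[, 2], xy_y[, 2]),
      true_type = rep(c("X", "Y"), c(120, 400)),
      stringsAsFactors = FALSE
    )
    assign_zones(as_cell_table(df, markers = character(0),
                               field_dim = c(600, 600)),
                 polygons = zone_polys)
  })
  res <- zone_enrichment(c(tabs, list(flip)))
  z1x <- res$aggregate[res$aggregate$region == "Z1" &
                         res$aggregate$type == "X", ]
  expect_false(z1x$significant)
  expect_false(z1x$consistent_sign)
  # despite tiny p values in the five planted samples
  p5 <- res$per_test$p[res$per_test$region == "Z1" &
                         res$per_test$type == "X"][1:5]
  expect_true(all(p5 < 1e-10))
})

test_that("interstitial cells count only toward the outside margin", {
  df <- data.frame(
    cell_id = as.character(1:6),
    x_px = c(100, 100, 400, 500, 580, 300),
    y_px = c(100, 200, 400, 500, 10, 300),
    true_type = c("X", "Y", "X", "Y", "X", "Y"),
    stringsAsFactors = FALSE
  )
  tab <- assign_zones(as_cell_table(df, markers = character(0),
                                    field_dim = c(600, 600)),
                      polygons = zone_polys)
  expect_equal(tab$zone, c("Z1", "Z1", "Z2", "Z2", "interstitial",
                           "interstitial"))
  res <- zone_enrichment(list(tab))
  row <- res$per_test[res$per_test$region == "Z1" &
                        res$per_test$type == "X", ]
  # outside margin = Z2 cells + interstitial cells
  expect_equal(row$in_type, 1)
  expect_equal(row$in_other, 1)
  expect_equal(row$out_type, 2)
  expect_equal(row$out_other, 2)
  expect_false("interstitial" %in% res$regions)
})

test_that("permuting type labels destroys all zonal calls", {
  tabs <- lapply(1:6, function(k) zoned_sample(800 + k))
  expect_true(any(zone_enrichment(tabs)$aggregate$significant))
  n_sig <- with_seed(41, {
    sum(vapply(seq_len(50), function(perm) {
      shuffled <- lapply(tabs, function(t) {
        t$true_type <- sample(t$true_type)
        t
      })
      sum(zone_enrichment(shuffled)$aggregate$significant)
    }, numeric(1)))
  })
  expect_equal(n_sig, 0)
})

test_that("label masks agree with polygons and take precedence", {
  mask <- zone_mask(zone_polys, 600, 600)
  tabs <- zoned_sample(900)
  by_poly <- assign_zones(tabs, polygons = zone_polys)
  by_mask <- assign_zones(tabs, mask = mask,
                          region_names = names(zone_polys))
  # mask and polygon assignment may differ only within a pixel of an edge
  edges <- c(50, 250, 350, 550)
  off_edge <- apply(abs(outer(tabs$x_px, edges, "-")), 1, min) > 1 &
    apply(abs(outer(tabs$y_px, edges, "-")), 1, min) > 1
  expect_equal(by_mask$zone[off_edge], by_poly$zone[off_edge])
  both <- assign_zones(tabs, polygons = list(bogus = zone_polys$Z1),
                       mask = mask, region_names = names(zone_polys))
  expect_equal(both$zone[off_edge], by_poly$zone[off_edge])
  expect_error(assign_zones(tabs), "polygons or mask")
  # TIFF round trip preserves the label image
  tmp <- withr::local_tempfile(fileext = ".tiff")
  write_zone_mask(mask, tmp)
  back <- read_zone_mask(tmp)
  expect_equal(unname(back), unname(mask), ignore_attr = TRUE)
})
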