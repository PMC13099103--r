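test_that("density clustering separates blobs and buckets outliers", {
  pts <- with_seed(1, rbind(
    matrix(rnorm(600, 0, 0.3), ncol = 2),
    matrix(rnorm(600, 8, 0.3), ncol = 2),
    c(4, 4)  # lone outlier between the blobs
  ))
  lab <- dbscan_cluster(pts, eps = 1, min_pts = 5)
  expect_equal(length(setdiff(unique(lab), -1L)), 2L)
  expect_equal(lab[601], -1L)
  # labels partition into clusters and the -1 bucket
  expect_true(all(lab %in% c(-1L, 1L, 2L)))
})

test_that("three separated phenotypes are recovered deterministically", {
  tab <- generate_sample(bench_three_type_spec(n = 3000), 11)
  model <- fit_shrinkage(tab, G_i = 20, seed = 1)
  sh <- apply_shrinkage(model, tab, 0.8)
  a1 <- embed_and_cluster(sh, min_cluster_size = 150, seed = 3)
  a2 <- embed_and_cluster(sh, min_cluster_size = 150, seed = 3)
  expect_identical(a1$labels, a2$labels)
  expect_gte(length(setdiff(unique(a1$labels), -1L)), 3L)
  expect_gte(cluster_purity(a1$labels, tab$true_type), 0.9)
})

test_that("tiny inputs and small clusters fall back to noise", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_warning(a <- embed_and_cluster(x, min_cluster_size = 100),
                 "noise")
  expect_true(all(a$labels == -1L))
  expect_error(embed_and_cluster(x, min_cluster_size = 1), ">= 2")
  # requesting a minimum below the reporting floor still enforces ~20 cells
  tab <- generate_sample(bench_three_type_spec(n = 1500), 2)
  sh <- apply_shrinkage(fit_shrinkage(tab, G_i = 10, seed = 1), tab, 0.8)
  a <- embed_and_cluster(sh, min_cluster_size = 5, seed = 1)
  sizes <- table(a$labels[a$labels != -1L])
  expect_true(all(sizes >= 20))
})

test_that("characterization ranks planted shifts and skips degeneracies", {
  n <- 2000
  m <- 5
  x <- with_seed(7, matrix(rnorm(n * m), n, m,
                           dimnames = list(NULL, paste0("mk", 1:m))))
  inc <- seq_len(200)
  # identical distributions -> nothing significant
  p0 <- characterize_cluster(x, inc, cluster_id = 0)
  expect_length(p0$ranked, 0)
  # planted shifts of +3 and +1.5 pooled-MADs -> ranks 1 and 2
  x2 <- x
  x2[inc, "mk2"] <- x2[inc, "mk2"] + 3 * mad(x[, "mk2"])
  x2[inc, "mk4"] <- x2[inc, "mk4"] + 1.5 * mad(x[, "mk4"])
  p <- characterize_cluster(x2, inc, cluster_id = 1)
  expect_equal(p$ranked[1], "mk2")
  expect_equal(p$ranked[2], "mk4")
  expect_equal(p$n_cells, 200)
  # effect sizes roughly match the planted magnitudes
  eff <- p$table$effect[match(c("mk2", "mk4"), p$table$marker)]
  expect_equal(eff, c(3, 1.5), tolerance = 0.35)
  # zero variance in both groups -> skipped with note
  x3 <- cbind(x2, flat = rep(1, n))
  p3 <- characterize_cluster(x3, inc)
  expect_match(p3$table$note[p3$table$marker == "flat"], "zero variance")
  expect_error(characterize_cluster(x, rep(TRUE, n)), "outside")
  expect_error(characterize_cluster(x, rep(FALSE, n)), "empty")
})

test_that("characterization rank order survives marker rescaling", {
  n <- 1500
  x <- with_seed(8, matrix(rexp(n * 4, rate = 1 / 60), n, 4,
                           dimnames = list(NULL, paste0("mk", 1:4))))
  inc <- seq_len(150)
  x[inc, "mk1"] <- x[inc, "mk1"] * 6
  x[inc, "mk3"] <- x[inc, "mk3"] * 2.5
  ranks <- function(xx) characterize_cluster(log1p(xx), inc)$ranked
  r1 <- ranks(x)
  x_scaled <- x
  x_scaled[, "mk1"] <- x_scaled[, "mk1"] * 10
  r2 <- ranks(x_scaled)
  expect_equal(match("mk1", r1), match("mk1", r2))
  expect_equal(match("mk3", r1), match("mk3", r2))
})

test_that("nested classification honors exclusion and reduction contracts", {
  tab <- generate_sample(bench_nested_spec(n = 2500), 4)
  broad_truth <- bench_nested_broad_truth()
  bm <- function(labels, table) majority_map(labels, broad_truth[table$true_type])
  sub <- bench_nested_subpanels()
  na <- nested_classify(tab, bm, sub, min_cluster_size = 80, seed = 2)
  cells <- na$cells
  # global noise never enters a subclass run
  expect_true(all(is.na(cells$subclass_label[cells$global_label == -1L])))
  expect_true(all(cells$cell_type[cells$global_label == -1L] == "noise"))
  # subclass -1 reads as the average cell of its type
  avg <- cells$subclass_label == -1L & !is.na(cells$subclass_label)
  expect_true(all(grepl("^average ", cells$cell_type[avg])))
  # every subclassed cell belongs to a broad type with a subpanel
  expect_true(all(cells$broad_type[!is.na(cells$subclass_label)] %in%
                    names(sub)))

  # collapsing the broad map reduces nesting to one subpanel run
  markers <- ct_markers(tab)
  one <- function(labels, table) {
    ids <- setdiff(unique(labels), -1L)
    stats::setNames(rep("X", length(ids)), as.character(ids))
  }
  na1 <- nested_classify(tab, one, list(X = sub$B),
                         min_cluster_size = 80, seed = 2)
  keep <- na1$cells$global_label != -1L
  direct <- embed_and_cluster(na1$shrunk[keep, sub$B, drop = FALSE],
                              min_cluster_size = 80, seed = 2 + 1000L)
  expect_identical(na1$cells$subclass_label[keep], direct$labels)
})

test_that("artifact flagging excludes exactly the flagged cells", {
  tab <- generate_sample(bench_nested_spec(n = 2500), 4)
  broad_truth <- bench_nested_broad_truth()
  bm <- function(labels, table) majority_map(labels, broad_truth[table$true_type])
  na <- nested_classify(tab, bm, list(), min_cluster_size = 80, seed = 2)
  expect_error(flag_artifacts(na, 999L), "unknown cluster")
  expect_identical(flag_artifacts(na, integer(0)), na)
  junk <- na$cells$global_label[which(na$cells$global_label != -1L)[1]]
  n_junk <- sum(na$cells$global_label == junk)
  fl <- flag_artifacts(na, junk)
  expect_equal(sum(fl$cells$excluded), n_junk)
  # excluded cells are dropped from downstream characterization entirely
  prof <- characterize_clusters(na$shrunk, fl$cells$global_label,
                                excluded = fl$cells$excluded)
  expect_false(as.character(junk) %in% names(prof))
  n_used <- sum(vapply(prof, function(p) p$n_cells, numeric(1)))
  n_noise <- sum(na$cells$global_label == -1L & !fl$cells$excluded)
  expect_equal(n_used + n_noise + n_junk, nrow(tab))
})
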