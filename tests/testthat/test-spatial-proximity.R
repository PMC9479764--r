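test_that("pairwise proximity matches hand-computed distances", {
  tcells <- data.frame(x_um = 0, y_um = 0)
  tregs <- data.frame(x_um = c(30, 200), y_um = c(40, 0))
  res <- proximity_pairs(tcells, tregs, proximity_config(radius_um = 100))
  expect_equal(res$n_pairs, 1L)
  expect_equal(res$mean_distance_um, 50)  # 3-4-5 triangle

  coincident <- proximity_pairs(data.frame(x_um = 30, y_um = 40), tregs,
                                proximity_config(radius_um = 100))
  expect_true(0 %in% coincident$distances)

  far <- proximity_pairs(tcells, data.frame(x_um = 500, y_um = 500),
                         proximity_config(radius_um = 100))
  expect_equal(far$n_pairs, 0L)
  expect_true(is.na(far$mean_distance_um))

  none <- proximity_pairs(tcells, data.frame(x_um = numeric(0),
                                             y_um = numeric(0)),
                          proximity_config())
  expect_equal(none$n_pairs, 0L)
  expect_true(is.na(none$mean_distance_um))
})

test_that("grid search equals the exhaustive pairwise oracle bit-exactly", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(1:120, 1); m <- sample(0:80, 1)
    w <- runif(1, 100, 600)
    tc <- data.frame(x_um = runif(n, 0, w), y_um = runif(n, 0, w))
    tr <- data.frame(x_um = runif(m, 0, w), y_um = runif(m, 0, w))
    r <- runif(1, 20, 150)
    for (mode in c("pairwise", "nearest")) {
      mine <- proximity_pairs(tc, tr, proximity_config(radius_um = r,
                                                       mode = mode))
      oracle <- brute_proximity(tc, tr, r, mode)
      expect_identical(mine$distances, oracle$distances)
      expect_identical(mine$mean_distance_um, oracle$mean_distance_um)
    }
  }
})

test_that("distance statistics are translation and rotation invariant", {
  set.seed(102)
  tc <- data.frame(x_um = runif(60, 0, 500), y_um = runif(60, 0, 500))
  tr <- data.frame(x_um = runif(25, 0, 500), y_um = runif(25, 0, 500))
  cfg <- proximity_config(radius_um = 120)
  base <- proximity_pairs(tc, tr, cfg)$mean_distance_um
  shift <- proximity_pairs(transform(tc, x_um = x_um + 37, y_um = y_um - 12),
                           transform(tr, x_um = x_um + 37, y_um = y_um - 12),
                           cfg)$mean_distance_um
  expect_equal(shift, base, tolerance = 1e-12)
  th <- 0.7
  rot <- function(d) data.frame(x_um = cos(th) * d$x_um - sin(th) * d$y_um,
                                y_um = sin(th) * d$x_um + cos(th) * d$y_um)
  expect_equal(proximity_pairs(rot(tc), rot(tr), cfg)$mean_distance_um,
               base, tolerance = 1e-9)
})

test_that("nearest-mode mean never exceeds pairwise-mode mean", {
  set.seed(103)
  for (rep in 1:20) {
    tc <- data.frame(x_um = runif(50, 0, 400), y_um = runif(50, 0, 400))
    tr <- data.frame(x_um = runif(20, 0, 400), y_um = runif(20, 0, 400))
    pw <- proximity_pairs(tc, tr, proximity_config(mode = "pairwise"))
    nn <- proximity_pairs(tc, tr, proximity_config(mode = "nearest"))
    if (pw$n_pairs > 0 && nn$n_pairs > 0) {
      expect_lte(nn$mean_distance_um, pw$mean_distance_um + 1e-12)
    }
  }
})

test_that("distance distributions are normalized histograms", {
  d <- rep(23, 50)
  dist <- distance_distribution(d, bin_width_um = 5, radius_um = 100)
  expect_equal(sum(dist$probability), 1)
  expect_equal(dist$probability[dist$bin_center_um == 22.5], 1)

  set.seed(104)
  u <- runif(20000, 0, 100)
  flat <- distance_distribution(u, bin_width_um = 10, radius_um = 100)
  expect_equal(sum(flat$probability), 1)
  expect_lt(max(abs(flat$probability - 0.1)), 0.01)  # flat within sampling error

  empty <- distance_distribution(numeric(0))
  expect_equal(nrow(empty), 0L)

  smoothed <- distance_distribution(u, bin_width_um = 5, radius_um = 100,
                                    smooth_bw = 10)
  expect_equal(sum(smoothed$probability), 1)
})

test_that("proximity shift is the log2 ratio of mean distances with sentinels", {
  mk <- function(mean, n = 10) list(n_pairs = n, mean_distance_um = mean,
                                    distances = rep(mean, n))
  expect_equal(proximity_shift(mk(60), mk(60)), 0)
  expect_equal(proximity_shift(mk(80), mk(40)), -1)
  expect_true(is.na(proximity_shift(mk(80), mk(40, n = 0))))
})

test_that("planted Treg exclusion raises the Ki67+ mean distance; labels are exchangeable without it", {
  params <- slide_pattern_params(treg_exclusion_radius_um = 40)
  cells <- assign_phenotypes(generate_cell_slide(params, seed = 9))
  cfg <- proximity_config(mode = "nearest")
  md <- mean_distance_by_class(proximity_by_class(cells, cfg))
  pos <- md$mean_distance_um[md$class %in% c("Ki67+CD8", "Ki67+CD4")]
  neg <- md$mean_distance_um[md$class %in% c("Ki67-CD8", "Ki67-CD4")]
  expect_gt(mean(pos), mean(neg))

  # permuting Ki67 labels destroys the difference (within resampling error)
  set.seed(105)
  tcell_idx <- which(cells$phenotype %in% c("CD8 T cell", "CD4 T cell"))
  diffs <- replicate(30, {
    perm <- cells
    perm$ki67[tcell_idx] <- sample(perm$ki67[tcell_idx])
    m <- mean_distance_by_class(proximity_by_class(perm, cfg))
    mean(m$mean_distance_um[grepl("\\+", m$class)]) -
      mean(m$mean_distance_um[grepl("-", m$class)])
  })
  observed <- mean(pos) - mean(neg)
  expect_gt(observed, quantile(diffs, 0.95))
  expect_lt(abs(mean(diffs)), observed)
})

test_that("single pair mean and per-class table layout", {
  res <- list("Ki67+CD8" = list(n_pairs = 1L, mean_distance_um = 42,
                                distances = 42))
  tab <- mean_distance_by_class(res)
  expect_equal(tab$mean_distance_um, 42)
  expect_equal(tab$class, "Ki67+CD8")
})
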