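test_that("phenotype gating follows the marker definitions", {
  cells <- rbind(
    make_cell(cd3 = TRUE, cd8 = TRUE),                      # CD8 T cell
    make_cell(cd3 = TRUE, cd4 = TRUE),                      # CD4 T cell
    make_cell(cd3 = TRUE, cd4 = TRUE, foxp3 = TRUE),        # Treg
    make_cell(pmn_marker = TRUE),                           # PMN
    make_cell(macro_marker = TRUE),                         # Macrophage
    make_cell(ck = TRUE),                                   # tumor via CK rule
    make_cell())                                            # nothing -> other
  out <- assign_phenotypes(cells)
  expect_equal(out$phenotype,
               c("CD8 T cell", "CD4 T cell", "Treg", "PMN", "Macrophage",
                 "tumor cell", "other"))
})

test_that("jointly satisfiable phenotype definitions are rejected", {
  bad <- list(list(name = "A", pos = "cd3", neg = character(0)),
              list(name = "B", pos = "cd8", neg = character(0)))
  expect_error(assign_phenotypes(make_cell(), bad), "satisfiable")
})

test_that("cell density is the exact count/area quotient", {
  cells <- do.call(rbind, replicate(120, make_cell(cd3 = TRUE, cd4 = TRUE,
                                                   foxp3 = TRUE),
                                    simplify = FALSE))
  cells <- assign_phenotypes(cells)
  d <- cell_density(cells, "Treg", "stroma", 2.0)
  expect_equal(d$count, 120)
  expect_equal(d$density, 60)
  expect_equal(cell_density(cells, "PMN", "stroma", 2.0)$density, 0)
  expect_error(cell_density(cells, "Treg", "stroma", 0), "degenerate")
})

test_that("densities are additive over disjoint compartments", {
  cells <- assign_phenotypes(generate_cell_slide(slide_pattern_params(),
                                                 seed = 5))
  at <- attr(cells, "tumor_area_mm2")
  as_ <- attr(cells, "stroma_area_mm2")
  for (ph in c("CD8 T cell", "Treg", "tumor cell")) {
    expect_equal(cell_density(cells, ph, "tumor", at)$count +
                   cell_density(cells, ph, "stroma", as_)$count,
                 cell_density(cells, ph, "whole", at + as_)$count)
  }
})

test_that("H-score is the intensity-weighted sum, bounded and monotone", {
  expect_equal(h_score(c(0, 0, 100)), 300)
  expect_equal(h_score(c(50, 25, 10)), 130)
  expect_equal(h_score(c(0, 0, 0)), 0)
  expect_error(h_score(c(60, 30, 20)), "sum")
  expect_error(h_score(c(-1, 0, 0)))

  set.seed(21)
  for (rep in 1:50) {
    f <- runif(3)
    f <- f / sum(f) * runif(1, 0, 100)  # valid triple, sum <= 100
    h <- h_score(f)
    expect_gte(h, 0)
    expect_lte(h, 300)
    # monotone in each fraction (shrink one component)
    j <- sample(3, 1)
    f2 <- f
    f2[j] <- f2[j] * 0.5
    expect_lte(h_score(f2), h)
  }
})

test_that("H-score from bins matches direct enumeration", {
  bins <- c(0, 0, 1, 1, 2, 3, 3, 3)  # 25% 1+, 12.5% 2+, 37.5% 3+
  expect_equal(h_score_from_bins(bins), 25 * 1 + 12.5 * 2 + 37.5 * 3)
  expect_true(is.na(h_score_from_bins(integer(0))))
  expect_error(h_score_from_bins(c(0, 5)))
})

test_that("stromal immune fraction applies the CK-/rounded/<=15um rule", {
  cells <- rbind(
    make_cell(ck = FALSE, roundness = 0.9, diameter_um = 10),
    make_cell(ck = FALSE, roundness = 0.95, diameter_um = 12),
    make_cell(ck = FALSE, roundness = 0.5, diameter_um = 10),   # not round
    make_cell(ck = FALSE, roundness = 0.9, diameter_um = 8))
  expect_equal(stromal_immune_fraction(cells), 0.75)

  all_ck <- rbind(make_cell(ck = TRUE), make_cell(ck = TRUE))
  expect_equal(stromal_immune_fraction(all_ck), 0)
  tumor_only <- make_cell(compartment = "tumor")
  expect_true(is.na(stromal_immune_fraction(tumor_only)))
})

test_that("log2 fold change uses the zero-guard pseudocount and is antisymmetric", {
  expect_equal(log2_fc(50, 50), 0)
  expect_equal(log2_fc(50, 100), 1)
  expect_equal(log2_fc(0, 7), 3)        # eps = 1 engaged: log2(8/1)
  expect_equal(log2_fc(50, 100, pseudocount = 0), 1)
  expect_error(log2_fc(-1, 5))
  set.seed(31)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  expect_equal(log2_fc(a, b), -log2_fc(b, a))
})

test_that("CD8/Treg ratio guards zero denominators with the pseudocount", {
  expect_equal(cd8_treg_ratio(60, 60), 1)
  expect_equal(cd8_treg_ratio(90, 30), 3)
  expect_equal(cd8_treg_ratio(10, 0), 11)  # eps = 1 engaged
  expect_error(cd8_treg_ratio(-1, 5))
})
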