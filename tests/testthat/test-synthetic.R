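# Synthetic-data generator: determinism, sampling behaviour and the exact
# covariance scaling of true genetic effects.

test_that("genotype simulation is deterministic and honours missing_rate", {
  p <- sim_params(n_lines = 30, n_markers = 50, missing_rate = 0, n_sites = 1,
                  site_means = matrix(1, 1), T_target = matrix(1),
                  R_target = matrix(1), traits = "Y", seed = 11)
  g1 <- simulate_genotypes(p)
  g2 <- simulate_genotypes(p)
  expect_identical(g1, g2)
  expect_false(any(g1$missing_mask))
  expect_true(all(g1$dosages %in% 0:2))

  p2 <- sim_params(n_lines = 200, n_markers = 100, missing_rate = 0.3,
                   n_sites = 1, site_means = matrix(1, 1),
                   T_target = matrix(1), R_target = matrix(1),
                   traits = "Y", seed = 12)
  g3 <- simulate_genotypes(p2)
  expect_gt(mean(g3$missing_mask), 0.25)
  expect_lt(mean(g3$missing_mask), 0.35)
})

test_that("realized allele frequencies track the drawn frequencies", {
  # binomial sampling: at n = 1000 lines the realized frequency of a marker
  # with p = 0.3 lies within +/- 0.05 (~ 3.5 binomial SDs)
  p <- sim_params(n_lines = 1000, n_markers = 40, maf_range = c(0.3, 0.3),
                  missing_rate = 0, n_sites = 1, site_means = matrix(1, 1),
                  T_target = matrix(1), R_target = matrix(1),
                  traits = "Y", seed = 13)
  g <- simulate_genotypes(p)
  freq <- colMeans(g$dosages) / 2
  expect_true(all(abs(freq - 0.3) < 0.05))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(sim_params(n_lines = 10, n_markers = 5, maf_range = c(0, 0.5),
                          site_means = matrix(1, 1), T_target = matrix(1),
                          R_target = matrix(1), traits = "Y", seed = 1),
               "maf_range")
  expect_error(sim_params(n_lines = 1, n_markers = 5,
                          site_means = matrix(1, 1), T_target = matrix(1),
                          R_target = matrix(1), traits = "Y", seed = 1),
               "n_lines")
  Tbad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(sim_params(n_lines = 10, n_markers = 5,
                          site_means = matrix(c(1, 1), 1), T_target = Tbad,
                          R_target = diag(2), seed = 1),
               "positive-definite")
  expect_error(sim_params(n_lines = 10, n_markers = 5,
                          site_means = matrix(1, 1), T_target = matrix(1),
                          R_target = matrix(1), traits = "Y", seed = 1,
                          n_reps = 2, layout_rows = 2, layout_cols = 4),
               "layout too small")
})

test_that("true additive effects hit the target covariance exactly", {
  Tm <- matrix(c(4, 3, 3, 9), 2)
  p <- sim_params(n_lines = 120, n_markers = 300, missing_rate = 0.1,
                  n_sites = 2, site_means = matrix(0, 2, 2), T_target = Tm,
                  R_target = diag(2), sigma2_gxe = c(0.5, 0), traits = c("A", "B"),
                  seed = 14)
  g <- simulate_genotypes(p)
  ef <- simulate_true_effects(g, p)
  expect_equal(unname(cov(ef$g)), Tm, tolerance = 1e-10)
  expect_equal(mean(ef$g[, 1]), 0, tolerance = 1e-12)
  # gE: exact per-trait variance, zero when sigma2_gxe is zero
  expect_equal(var(ef$gE[[1]][, "A"]), 0.5, tolerance = 1e-10)
  expect_true(all(ef$gE[[1]][, "B"] == 0))
  expect_true(all(ef$gE[[2]][, "B"] == 0))
  # deterministic
  expect_identical(ef, simulate_true_effects(g, p))
})

test_that("realized genetic moments stay on target across many seeds", {
  # exact in-sample scaling: variances and covariance match to rounding error
  Tm <- matrix(c(4, 1, 1, 9), 2)
  devs <- sapply(1:25, function(s) {
    p <- sim_params(n_lines = 500, n_markers = 200, missing_rate = 0,
                    n_sites = 1, site_means = matrix(0, 1, 2), T_target = Tm,
                    R_target = diag(2), traits = c("A", "B"), seed = 7000 + s)
    g <- simulate_genotypes(p)
    ef <- simulate_true_effects(g, p)
    max(abs(cov(ef$g) - Tm) / abs(Tm))
  })
  expect_true(mean(devs < 0.2) >= 0.95)
})

test_that("trial simulation: degenerate variances give the site mean exactly", {
  eps <- 1e-12  # positive-definiteness requires tiny nonzero variances
  p <- sim_params(n_lines = 6, n_markers = 10, missing_rate = 0, n_sites = 1,
                  site_means = matrix(5, 1), T_target = matrix(eps),
                  R_target = matrix(eps), sigma2_row = 0, sigma2_col = 0,
                  sigma2_gxe = 0, n_reps = 2, layout_rows = 3, layout_cols = 4,
                  traits = "Y", seed = 15)
  g <- simulate_genotypes(p)
  ef <- simulate_true_effects(g, p)
  tr <- simulate_trial(g, ef, p)
  expect_equal(tr$Y, rep(5, nrow(tr)), tolerance = 1e-5)
  # layout/uniqueness invariants
  expect_false(anyDuplicated(paste(tr$site, tr$row, tr$col)) > 0)
  expect_true(all(tr$accession %in% g$line_ids))
  expect_equal(nrow(tr), 12)
})

test_that("zero AR1 correlation gives uncorrelated spatial residuals", {
  p <- sim_params(n_lines = 500, n_markers = 10, missing_rate = 0, n_sites = 1,
                  site_means = matrix(0, 1), T_target = matrix(1e-10),
                  R_target = matrix(1), rho_row = 0, rho_col = 0,
                  sigma2_row = 0, sigma2_col = 0, sigma2_gxe = 0,
                  n_reps = 2, layout_rows = 25, layout_cols = 40,
                  traits = "Y", seed = 16)
  g <- simulate_genotypes(p)
  ef <- simulate_true_effects(g, p)
  tr <- simulate_trial(g, ef, p)
  # neighbouring plots within a column
  tr <- tr[order(tr$col, tr$row), ]
  by_col <- split(tr$Y, tr$col)
  pairs <- do.call(rbind, lapply(by_col, function(v) {
    if (length(v) > 1) cbind(v[-length(v)], v[-1])
  }))
  expect_lt(abs(cor(pairs[, 1], pairs[, 2])), 0.1)
})

test_that("trial randomization differs between replicates but is seeded", {
  p <- sim_params(n_lines = 20, n_markers = 10, missing_rate = 0, n_sites = 1,
                  site_means = matrix(0, 1), T_target = matrix(1),
                  R_target = matrix(1), n_reps = 2, layout_rows = 5,
                  layout_cols = 8, traits = "Y", seed = 17)
  g <- simulate_genotypes(p)
  ef <- simulate_true_effects(g, p)
  tr1 <- simulate_trial(g, ef, p)
  tr2 <- simulate_trial(g, ef, p)
  expect_identical(tr1, tr2)
  r1 <- tr1$accession[tr1$rep == 1][order(tr1$row[tr1$rep == 1], tr1$col[tr1$rep == 1])]
  r2 <- tr1$accession[tr1$rep == 2][order(tr1$row[tr1$rep == 2], tr1$col[tr1$rep == 2])]
  expect_false(identical(r1, r2))
})
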