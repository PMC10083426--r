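# REML GBLUP fits: heritability arithmetic, oracle equivalence, recovery,
# invariances, and the g x E model.

test_that("heritability and correlation arithmetic", {
  expect_equal(heritability(9.621, 3.594), 0.728, tolerance = 5e-4)
  expect_equal(heritability(0, 1), 0)
  expect_equal(heritability(1, 1), 0.5)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-1, 1), ">= 0")

  expect_equal(correlation_from_cov(0, 4, 9), 0)
  expect_equal(correlation_from_cov(3, 4, 9), 0.5)
  expect_equal(correlation_from_cov(6.5, 4, 9), 0.999)   # clipped from 1.083
  expect_equal(correlation_from_cov(-6.5, 4, 9), -0.999)
  expect_error(correlation_from_cov(1, 0, 1), "positive")
})

test_that("univariate REML log-likelihood matches a dense grid oracle", {
  p <- sim_params(n_lines = 20, n_markers = 100, missing_rate = 0, n_sites = 1,
                  site_means = matrix(5, 1), T_target = matrix(1),
                  R_target = matrix(1), sigma2_gxe = 0, traits = "Y", seed = 8)
  sim <- sim_blues_grm(p)
  y <- sim$blues$estimate
  G <- sim$grm$values
  fit <- gsresp:::uv_reml_eigen(y, G)
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 200))
  lls <- vapply(grid, dense_uv_reml_ll, numeric(1), y = y, G = G)
  expect_gte(fit$loglik, max(lls) - 1e-10)   # optimum no worse than the grid
  expect_lt(fit$loglik - max(lls), 1e-4)     # and the grid gets this close
})

test_that("constant phenotypes collapse to floor variances and zero GEBVs", {
  set.seed(41)
  G <- condition_grm(vanraden_grm(toy_geno(matrix(rbinom(300, 2, .4), 15))))
  bl <- data.frame(site = "S1", accession = G$line_ids, trait = "Y",
                   estimate = 3.3, se = NA)
  f <- fit_univariate(bl, G, trait = "Y")
  expect_true(all(abs(f$gebv$gebv) < 1e-8))
  expect_lt(f$components$sigma2_A, 1e-10)
})

test_that("univariate h2 is recovered on average at study-like scale", {
  h2 <- sapply(1:20, function(s) {
    p <- bivar_params(c(0.5, 0.5), 0, n_lines = 300, n_markers = 2000,
                      seed = 4200 + s)
    sim <- sim_blues_grm(p)
    fit_univariate(sim$blues, sim$grm, trait = "GY")$components$h2
  })
  expect_lt(abs(mean(h2) - 0.5), 0.1)
})

test_that("REML estimates are scale-equivariant", {
  p <- bivar_params(c(0.4, 0.6), 0.3, n_lines = 80, n_markers = 400, seed = 43)
  sim <- sim_blues_grm(p)
  f1 <- fit_multitrait(sim$blues, sim$grm, traits = c("GY", "PH"))
  bl2 <- sim$blues; bl2$estimate <- bl2$estimate * 10
  f2 <- fit_multitrait(bl2, sim$grm, traits = c("GY", "PH"))
  expect_equal(f2$components$T, f1$components$T * 100, tolerance = 1e-4)
  expect_equal(unname(f2$h2), unname(f1$h2), tolerance = 1e-5)
  expect_equal(f2$correlations$r_A, f1$correlations$r_A, tolerance = 1e-5)

  fu1 <- fit_univariate(sim$blues, sim$grm, trait = "GY")
  fu2 <- fit_univariate(bl2, sim$grm, trait = "GY")
  expect_equal(fu2$components$sigma2_A, fu1$components$sigma2_A * 100,
               tolerance = 1e-5)
  expect_equal(fu2$components$h2, fu1$components$h2, tolerance = 1e-6)
})

test_that("GEBVs are shrunken, centred predictions", {
  p <- bivar_params(c(0.4, 0.6), 0.3, n_lines = 100, n_markers = 500, seed = 44)
  sim <- sim_blues_grm(p)
  f <- fit_univariate(sim$blues, sim$grm, trait = "GY")
  g <- f$gebv$gebv
  expect_lt(abs(mean(g)), 1e-6 * sd(g))
  expect_lte(var(g), f$components$sigma2_A * max(diag(sim$grm$values)))
})

test_that("duplicated trait drives the genetic correlation to the boundary", {
  p <- bivar_params(c(0.5, 0.5), 0, n_lines = 60, n_markers = 300, seed = 45)
  sim <- sim_blues_grm(p)
  bl <- sim$blues
  bl$estimate[bl$trait == "PH"] <- bl$estimate[bl$trait == "GY"]
  f <- fit_multitrait(bl, sim$grm, traits = c("GY", "PH"))
  expect_gte(f$correlations$r_A, 0.99)
})

test_that("independent traits give near-zero genetic correlation", {
  rs <- sapply(1:5, function(s) {
    p <- bivar_params(c(0.5, 0.5), 0, n_lines = 300, n_markers = 1000,
                      seed = 4600 + s)
    sim <- sim_blues_grm(p)
    fit_multitrait(sim$blues, sim$grm, traits = c("GY", "PH"))$correlations$r_A
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("diagonal-constrained multi-trait fit reproduces univariate fits", {
  p <- bivar_params(c(0.4, 0.6), 0.3, n_lines = 80, n_markers = 400, seed = 47)
  sim <- sim_blues_grm(p)
  fd <- fit_multitrait(sim$blues, sim$grm, traits = c("GY", "PH"),
                       diagonal = TRUE)
  f1 <- fit_univariate(sim$blues, sim$grm, trait = "GY")
  f2 <- fit_univariate(sim$blues, sim$grm, trait = "PH")
  expect_equal(unname(diag(fd$components$T)),
               c(f1$components$sigma2_A, f2$components$sigma2_A),
               tolerance = 1e-3)
  expect_equal(unname(diag(fd$components$Rres)),
               c(f1$components$sigma2_e, f2$components$sigma2_e),
               tolerance = 1e-3)
})

test_that("multi-trait fit handles records missing for a subset of traits", {
  p <- bivar_params(c(0.4, 0.6), 0.5, n_lines = 60, n_markers = 300, seed = 48)
  sim <- sim_blues_grm(p)
  bl <- sim$blues[-c(3, 17, 80), ]    # drop a few single-trait records
  f <- fit_multitrait(bl, sim$grm, traits = c("GY", "PH"))
  expect_true(all(is.finite(f$components$T)))
  # every accession in the GRM still gets a GEBV for both traits
  expect_equal(nrow(f$gebv), 2 * 60)
  # balanced subset agreement: dense path on complete records equals the
  # rotated path within optimizer tolerance
  fb <- fit_multitrait(sim$blues, sim$grm, traits = c("GY", "PH"))
  obs <- expand.grid(acc_idx = 1:60, trait_idx = 1:2)
  Y <- matrix(sim$blues$estimate, 60)
  obs$value <- Y[cbind(obs$acc_idx, obs$trait_idx)]
  lld <- gsresp:::mt_dense_eval(obs, sim$grm$values, fb$components$T,
                                fb$components$Rres)$loglik
  expect_equal(lld, fb$components$log_likelihood, tolerance = 1e-6)
})

test_that("optimum log-likelihood is no worse than the initialization", {
  p <- bivar_params(c(0.3, 0.7), 0.5, n_lines = 100, n_markers = 500, seed = 49)
  sim <- sim_blues_grm(p)
  al <- gsresp:::align_blues_grm(sim$blues, sim$grm, c("GY", "PH"))
  fit <- gsresp:::mt_reml_balanced(al$Y, al$G)
  expect_gte(fit$loglik, fit$loglik_init)
})

test_that("g x E model: no interaction signal in duplicated sites", {
  p <- bivar_params(c(0.5, 0.5), 0, n_lines = 60, n_markers = 300, seed = 50)
  sim <- sim_blues_grm(p)
  b1 <- sim$blues[sim$blues$trait == "GY", ]
  b2 <- b1; b2$site <- "S2"
  f <- fit_gxe(rbind(b1, b2), sim$grm, trait = "GY")
  expect_lt(f$components$sigma2_gxe, 1e-4 * f$components$sigma2_A)
  expect_error(fit_gxe(b1, sim$grm, trait = "GY"), "fit_univariate")
})

test_that("g x E model nests the univariate model", {
  p <- sim_params(n_lines = 50, n_markers = 300, missing_rate = 0, n_sites = 2,
                  site_means = matrix(c(3, 2), 2), T_target = matrix(1),
                  R_target = matrix(1), sigma2_gxe = 0.5, traits = "GY",
                  seed = 51)
  sim <- sim_blues_grm(p)
  b1 <- sim$blues[sim$blues$site == "S1", ]
  # with sigma2_gxe fixed at 0 and a single site's records, the "g x E"
  # structure reduces to the univariate model: same maximized likelihood
  f_uv <- fit_univariate(b1, sim$grm, trait = "GY")
  al <- gsresp:::align_blues_grm(b1, sim$grm, "GY")
  f_g0 <- gsresp:::gxe_reml_balanced(al$Y, al$G, fix_s2g = 0)
  expect_equal(f_g0$loglik, f_uv$components$log_likelihood, tolerance = 1e-6)
})

test_that("g x E interaction-to-additive ratio is recovered on average", {
  ratios <- sapply(1:10, function(s) {
    p <- sim_params(n_lines = 300, n_markers = 2000, missing_rate = 0,
                    n_sites = 3, site_means = matrix(c(3, 2, 1), 3),
                    T_target = matrix(1), R_target = matrix(1),
                    sigma2_gxe = 0.5, traits = "GY", seed = 6000 + s)
    sim <- sim_blues_grm(p)
    f <- fit_gxe(sim$blues, sim$grm, trait = "GY")
    f$components$sigma2_gxe / f$components$sigma2_A
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.2)
})

test_that("plot-level multi-trait fit with row/column effects runs and is sane", {
  p <- sim_params(n_lines = 24, n_markers = 200, missing_rate = 0, n_sites = 1,
                  site_means = matrix(c(3, 50), 1),
                  T_target = matrix(c(1, .5, .5, 2), 2),
                  R_target = diag(c(1, 2)), rho_row = 0, rho_col = 0,
                  sigma2_row = c(0.4, 0.8), sigma2_col = c(0.4, 0.8),
                  sigma2_gxe = 0, n_reps = 2, layout_rows = 6, layout_cols = 8,
                  traits = c("GY", "PH"), seed = 52)
  sim <- sim_blues_grm(p)
  tr <- simulate_trial(sim$geno, sim$effects, p)
  f <- fit_multitrait(NULL, sim$grm, traits = c("GY", "PH"),
                      include_rowcol = TRUE, plots = tr)
  expect_true(all(is.finite(f$components$T)))
  expect_true(all(f$components$sigma2_row >= 0))
  expect_equal(dim(f$components$T), c(2L, 2L))
  expect_equal(nrow(f$gebv), 48)
})
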