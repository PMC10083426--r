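# Selection indices, differentials and responses.

test_that("standardization is exact, idempotent and affine-invariant", {
  expect_equal(standardize_scores(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize_scores(c(0.2, 1.5, -0.7, 3.1))
  expect_equal(standardize_scores(z), z, tolerance = 1e-12)
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(standardize_scores(3 + 2 * x), standardize_scores(x))
  expect_error(standardize_scores(rep(1, 5)), "zero standard deviation")
})

test_that("Smith-Hazel weights solve P b = g", {
  expect_equal(smith_hazel_weights(diag(2), c(0.5, 0.2)), c(0.5, 0.2))
  expect_equal(smith_hazel_weights(diag(c(2, 4)), c(1, 2)), c(0.5, 0.5))
  P <- matrix(c(1, 0.5, 0.5, 1), 2)
  b <- smith_hazel_weights(P, c(1, 0))
  expect_equal(b, solve(P) %*% c(1, 0) |> as.vector(), tolerance = 1e-12)
  expect_equal(b, c(4 / 3, -2 / 3), tolerance = 1e-10)
  expect_error(smith_hazel_weights(matrix(1, 2, 2), c(1, 0)), "singular")
})

test_that("index construction is a (optionally standardized) weighted sum", {
  scores <- cbind(A = c(1, 2, 3), B = c(9, 5, 1))
  rownames(scores) <- c("x", "y", "z")
  expect_equal(unname(build_index(scores, c(1, 0))), c(1, 2, 3))
  # equal weights on standardized traits: z-scores add
  idx <- build_index(scores, c(1, 1), standardized = TRUE)
  expect_equal(unname(idx), unname(standardize_scores(scores[, 1]) +
                                     standardize_scores(scores[, 2])))
  # linearity: doubling weights doubles the index (rank-invariant)
  expect_equal(build_index(scores, c(2, 4)), 2 * build_index(scores, c(1, 2)))
  expect_error(build_index(rbind(scores, c(NA, 1)), c(1, 1)), "complete")
})

test_that("top-fraction selection counts and tie-breaking are deterministic", {
  v <- stats::setNames(1:5, sprintf("A%d", 1:5))
  expect_equal(select_top_fraction(v, 0.2), "A5")
  v349 <- stats::setNames(rnorm(349), sprintf("A%03d", 1:349))
  expect_length(select_top_fraction(v349, 0.2), 69)   # floor(69.8)
  # tie at the cut-off: lexicographically smaller id wins
  vt <- stats::setNames(c(3, 1, 2, 2), c("d", "a", "c", "b"))
  expect_equal(sort(select_top_fraction(vt, 0.5)), c("b", "d"))
  expect_error(select_top_fraction(v, 0.1), "empty")
})

test_that("selection differential, response and percentage gain identities", {
  pop <- stats::setNames(c(1, 2, 3, 4, 5), sprintf("A%d", 1:5))
  rep1 <- selection_response(pop, "A5", h2 = 0.5)
  expect_equal(rep1$S, 2)
  expect_equal(rep1$R, 1)
  rep2 <- selection_response(pop, names(pop), h2 = 0.7)
  expect_equal(rep2$S, 0)
  expect_equal(rep2$R, 0)
  rep3 <- selection_response(pop, "A5", h2 = 0.5, site_mean = 3)
  expect_equal(rep3$percent_gain, 100 * 1 / 3, tolerance = 1e-12)
  expect_error(selection_response(pop, character(0), 0.5), "empty")
  expect_error(selection_response(pop, "A9", 0.5), "missing")
})

test_that("cross-site evaluation reuses the same candidates", {
  set.seed(71)
  ids <- sprintf("A%02d", 1:50)
  v1 <- stats::setNames(rnorm(50, 10), ids)
  sel <- select_top_fraction(v1, 0.2)
  # evaluation site = selection site: identical to selection_response
  r_self <- cross_site_response(sel, list(S1 = v1), c(S1 = 0.5),
                                selection_site = "S1")
  r_direct <- selection_response(v1, sel, 0.5, selection_site = "S1",
                                 evaluation_site = "S1")
  expect_equal(r_self$S, r_direct$S)
  expect_equal(r_self$percent_gain, r_direct$percent_gain)
  # shifted evaluation values: same differential
  r_shift <- cross_site_response(sel, list(S2 = v1 + 4), c(S2 = 0.5))
  expect_equal(r_shift$S, r_direct$S, tolerance = 1e-12)
  # missing accessions are excluded with a warning
  expect_warning(
    cross_site_response(sel, list(S3 = v1[-match(sel[1], ids)]), c(S3 = 0.5)),
    "excluded")
})

test_that("uncorrelated evaluation values give near-zero cross-site response", {
  devs <- sapply(1:20, function(s) {
    set.seed(7100 + s)
    ids <- sprintf("A%03d", 1:300)
    v_sel <- stats::setNames(rnorm(300), ids)
    v_eval <- stats::setNames(rnorm(300), ids)
    sel <- select_top_fraction(v_sel, 0.2)
    selection_response(v_eval, sel, h2 = 1)$S
  })
  # S under independence: mean 0, SE ~ sd/sqrt(60)
  expect_lt(abs(mean(devs)), 2 * stats::sd(devs) / sqrt(length(devs)) + 0.05)
})

test_that("phenotypic selection maximizes the within-site differential", {
  p <- bivar_params(c(0.4, 0.6), 0.5, n_lines = 100, n_markers = 500, seed = 72)
  sim <- sim_blues_grm(p)
  b <- sim$blues[sim$blues$trait == "GY", ]
  vals <- stats::setNames(b$estimate, b$accession)
  s_ps <- selection_response(vals, select_top_fraction(vals, 0.2), 1)$S
  # any other index (here: the univariate GEBV ranking) cannot beat PS on
  # the selection criterion itself
  f <- fit_univariate(sim$blues, sim$grm, trait = "GY")
  gebv <- stats::setNames(f$gebv$gebv, f$gebv$accession)
  s_gs <- selection_response(vals, select_top_fraction(gebv, 0.2), 1)$S
  expect_gte(s_ps, s_gs)
})

test_that("diagonal-P Smith-Hazel weights rank like variance-weighted sums", {
  set.seed(73)
  scores <- cbind(GY = rnorm(40), OL = rnorm(40))
  rownames(scores) <- sprintf("A%02d", 1:40)
  g <- c(0.6, 0.3)
  b <- smith_hazel_weights(diag(c(2, 2)), g)
  i1 <- build_index(scores, b)
  i2 <- build_index(scores, g)
  expect_equal(order(i1), order(i2))
})
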