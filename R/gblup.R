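#' Heritability from variance components
#'
#' `h2 = sigma2_A / (sigma2_A + sigma2_e)` — narrow-sense when the additive
#' (genomic) variance is used, broad-sense when the genetic variance from an
#' identity-relationship model is used.
#'
#' @param sigma2_A Additive (or total genetic) variance, >= 0.
#' @param sigma2_e Residual variance, >= 0.
#' @return Ratio in [0, 1]. Vectorized.
#' @export
heritability <- function(sigma2_A, sigma2_e) {
  if (any(sigma2_A < 0) || any(sigma2_e < 0)) stop("variances must be >= 0")
  tot <- sigma2_A + sigma2_e
  if (any(tot == 0)) stop("heritability undefined: both variances zero")
  sigma2_A / tot
}

#' Correlation from a covariance and two variances
#'
#' `cov / sqrt(var_x * var_y)`, clipped to `[-0.999, 0.999]` so that
#' near-boundary REML estimates stay usable downstream.
#'
#' @param cov Covariance between the traits.
#' @param var_x,var_y Positive variances.
#' @return Correlation in `[-0.999, 0.999]`.
#' @export
correlation_from_cov <- function(cov, var_x, var_y) {
  if (any(var_x <= 0) || any(var_y <= 0)) stop("variances must be positive")
  pmin(pmax(cov / sqrt(var_x * var_y), -0.999), 0.999)
}

# Align a long BLUE table with a GRM: returns wide matrix (accessions in GRM
# order that have records) and the trimmed G.
align_blues_grm <- function(blues, grm, traits, site = NULL) {
  stopifnot(inherits(grm, "grm"))
  b <- blues
  if (!is.null(site)) b <- b[b$site %in% site, , drop = FALSE]
  b <- b[b$trait %in% traits, , drop = FALSE]
  acc <- intersect(grm$line_ids, unique(b$accession))
  if (length(acc) == 0L) stop("no accession ids shared between BLUEs and GRM")
  Y <- matrix(NA_real_, length(acc), length(traits),
              dimnames = list(acc, traits))
  idx <- cbind(match(b$accession, acc), match(b$trait, traits))
  ok <- !is.na(idx[, 1])
  Y[idx[ok, , drop = FALSE]] <- b$estimate[ok]
  list(Y = Y, G = grm$values[acc, acc], acc = acc)
}

#' Univariate GBLUP by REML
#'
#' Fits `y = mu + g + e` with `g ~ N(0, G sigma2_A)`, `e ~ N(0, I sigma2_e)`
#' to one trait's accession BLUEs. The relationship matrix is
#' eigendecomposed once and the restricted likelihood is profiled over the
#' variance ratio, so the optimization is one-dimensional.
#'
#' @param blues A long `blue_table` (`site, accession, trait, estimate, se`).
#' @param grm A `grm` object.
#' @param trait Trait to fit (required if the table holds several).
#' @param site Optional site filter.
#' @param min_n Minimum number of overlapping accessions.
#' @return List with `components` (`sigma2_A`, `sigma2_e`, `h2`,
#'   `log_likelihood`) and `gebv` (data.frame `accession, trait, gebv`).
#' @export
fit_univariate <- function(blues, grm, trait = NULL, site = NULL, min_n = 10L) {
  if (is.null(trait)) {
    trait <- unique(blues$trait)
    if (length(trait) != 1L) stop("specify `trait`: table holds several")
  }
  al <- align_blues_grm(blues, grm, trait, site)
  keep <- is.finite(al$Y[, 1])
  y <- al$Y[keep, 1]; G <- al$G[keep, keep]
  if (length(y) < min_n) stop("fewer than ", min_n, " accessions overlap BLUEs and GRM")
  fit <- tryCatch(uv_reml_eigen(y, G),
                  error = function(e) stop("univariate REML failed (is G positive-definite? ",
                                           "see condition_grm): ", conditionMessage(e)))
  gebv <- data.frame(accession = rownames(G), trait = trait,
                     gebv = fit$gebv, stringsAsFactors = FALSE)
  list(components = list(trait = trait, sigma2_A = fit$sigma2_A,
                         sigma2_e = fit$sigma2_e,
                         h2 = heritability(fit$sigma2_A, fit$sigma2_e),
                         relationship = "genomic",
                         log_likelihood = fit$loglik),
       gebv = gebv)
}

#' Multi-trait GBLUP by REML
#'
#' Estimates the genetic covariance `T` and residual covariance `R` of 2-3
#' traits jointly, with genetic effects `vec(g) ~ N(0, T (x) G)` and
#' residuals i.i.d. `N(0, R)` per accession. Complete (balanced) data use a
#' closed-form rotated likelihood (eigendecomposition of `G` plus
#' simultaneous diagonalization of `T` and `R`); records missing for a
#' subset of traits fall back on a dense restricted likelihood over the
#' observed records, which is also the conditional-prediction path used by
#' the CV1 cross-validation scenario. With `include_rowcol = TRUE` and a
#' plot-level `plots` table, random row and column effects (per-trait
#' variances) are added and the model is fitted at plot level.
#'
#' @param blues Long `blue_table` of the traits at one site.
#' @param grm A `grm`.
#' @param traits Character vector (2-3 trait names).
#' @param site Optional site filter.
#' @param diagonal Constrain `T` and `R` to diagonal (independent traits).
#' @param include_rowcol Fit plot-level model with row/column random effects.
#' @param plots `trial_table` with the plot records (required when
#'   `include_rowcol = TRUE`).
#' @return List with `components` (`traits`, `T`, `Rres`, optionally
#'   `sigma2_row`/`sigma2_col`, `log_likelihood`), `gebv` (long data.frame)
#'   and `correlations` (per pair: `r_A`, `r_P`).
#' @export
fit_multitrait <- function(blues, grm, traits = NULL, site = NULL,
                           diagonal = FALSE, include_rowcol = FALSE,
                           plots = NULL) {
  if (include_rowcol) {
    if (is.null(plots)) stop("include_rowcol = TRUE requires plot-level `plots`")
    return(fit_multitrait_plots(plots, grm, traits))
  }
  if (is.null(traits)) traits <- unique(blues$trait)
  if (length(traits) < 2L) stop("multi-trait fit needs >= 2 traits")
  al <- align_blues_grm(blues, grm, traits, site)
  Y <- al$Y; G <- al$G
  all_missing <- rowSums(is.finite(Y)) == 0L
  Y <- Y[!all_missing, , drop = FALSE]; G <- G[!all_missing, !all_missing]
  n <- nrow(Y); t <- ncol(Y)

  if (!anyNA(Y)) {
    fit <- mt_reml_balanced(Y, G, diagonal = diagonal)
    gebv_mat <- fit$gebv
  } else {
    obs <- which(is.finite(Y), arr.ind = TRUE)
    records <- data.frame(acc_idx = obs[, 1], trait_idx = obs[, 2],
                          value = Y[obs])
    fit <- mt_reml_dense(records, G, t, diagonal = diagonal)
    pr <- mt_dense_predict(records, G, fit$T, fit$R)
    gebv_mat <- pr$gebv
    dimnames(gebv_mat) <- dimnames(Y)
  }
  Tm <- fit$T; Rm <- fit$R
  dimnames(Tm) <- dimnames(Rm) <- list(traits, traits)
  pairs <- utils::combn(traits, 2)
  correlations <- data.frame(
    trait_x = pairs[1, ], trait_y = pairs[2, ],
    r_A = apply(pairs, 2, function(pp)
      correlation_from_cov(Tm[pp[1], pp[2]], Tm[pp[1], pp[1]], Tm[pp[2], pp[2]])),
    r_P = apply(pairs, 2, function(pp) {
      P <- Tm + Rm
      correlation_from_cov(P[pp[1], pp[2]], P[pp[1], pp[1]], P[pp[2], pp[2]])
    }), stringsAsFactors = FALSE)
  gebv <- data.frame(accession = rep(rownames(Y), t),
                     trait = rep(traits, each = nrow(Y)),
                     gebv = as.vector(gebv_mat), stringsAsFactors = FALSE)
  list(components = list(traits = traits, T = Tm, Rres = Rm,
                         log_likelihood = fit$loglik),
       gebv = gebv, correlations = correlations,
       h2 = stats::setNames(diag(Tm) / (diag(Tm) + diag(Rm)), traits))
}

fit_multitrait_plots <- function(plots, grm, traits) {
  stopifnot(is.data.frame(plots), all(traits %in% names(plots)))
  acc <- intersect(grm$line_ids, unique(plots$accession))
  if (!length(acc)) stop("no accession ids shared between plots and GRM")
  plots <- plots[plots$accession %in% acc, , drop = FALSE]
  G <- grm$values[acc, acc]
  t <- length(traits)
  plots$plot_idx <- seq_len(nrow(plots))
  recs <- do.call(rbind, lapply(seq_along(traits), function(j) {
    v <- plots[[traits[j]]]
    ok <- is.finite(v)
    data.frame(acc_idx = match(plots$accession[ok], acc), trait_idx = j,
               plot_idx = plots$plot_idx[ok], row_idx = plots$row[ok],
               col_idx = plots$col[ok], rep_idx = plots$rep[ok],
               value = v[ok])
  }))
  fit <- mt_reml_plot(recs, G, t)
  Tm <- fit$T; Rm <- fit$R
  dimnames(Tm) <- dimnames(Rm) <- list(traits, traits)
  gebv <- data.frame(accession = rep(acc, t),
                     trait = rep(traits, each = length(acc)),
                     gebv = as.vector(fit$gebv), stringsAsFactors = FALSE)
  pairs <- utils::combn(traits, 2)
  correlations <- data.frame(
    trait_x = pairs[1, ], trait_y = pairs[2, ],
    r_A = apply(pairs, 2, function(pp)
      correlation_from_cov(Tm[pp[1], pp[2]], Tm[pp[1], pp[1]], Tm[pp[2], pp[2]])),
    stringsAsFactors = FALSE)
  list(components = list(traits = traits, T = Tm, Rres = Rm,
                         sigma2_row = stats::setNames(fit$s2row, traits),
                         sigma2_col = stats::setNames(fit$s2col, traits),
                         log_likelihood = fit$loglik),
       gebv = gebv, correlations = correlations)
}

#' Genotype-by-environment GBLUP across sites
#'
#' Fits, for one trait over two or more sites, `y = site + g + gE + e` with
#' main additive effects `g ~ N(0, G sigma2_A)` shared across sites and
#' interaction deviations `gE` independent across sites with covariance
#' `G sigma2_gxe` within site. Site enters as a fixed effect. Accessions not
#' observed at every requested site are dropped (with a warning) so the
#' rotated balanced likelihood applies.
#'
#' @param blues Long `blue_table` covering >= 2 sites for `trait`.
#' @param grm A `grm`.
#' @param trait Trait name.
#' @param sites Optional site subset (default: all sites present).
#' @param fix_sigma2_gxe Optionally fix the interaction variance (e.g. 0 for
#'   a no-interaction null fit).
#' @return List with `components` (`sigma2_A`, `sigma2_gxe`, `sigma2_e`,
#'   `log_likelihood`) and `gebv` (long data.frame with the across-site main
#'   effect per accession, `site = NA`, plus per-site interaction deviations).
#' @export
fit_gxe <- function(blues, grm, trait, sites = NULL, fix_sigma2_gxe = NULL) {
  b <- blues[blues$trait == trait, , drop = FALSE]
  if (is.null(sites)) sites <- unique(b$site)
  if (length(sites) < 2L) {
    stop("g x E model needs >= 2 sites; use fit_univariate() for a single site")
  }
  b <- b[b$site %in% sites, , drop = FALSE]
  acc_all <- intersect(grm$line_ids, unique(b$accession))
  if (!length(acc_all)) stop("no accession ids shared between BLUEs and GRM")
  Y <- matrix(NA_real_, length(acc_all), length(sites),
              dimnames = list(acc_all, sites))
  Y[cbind(match(b$accession, acc_all), match(b$site, sites))] <- b$estimate
  complete <- rowSums(is.finite(Y)) == length(sites)
  if (!all(complete)) {
    warning(sum(!complete), " accession(s) not observed at every site; dropped")
  }
  Y <- Y[complete, , drop = FALSE]
  G <- grm$values[rownames(Y), rownames(Y)]
  fit <- gxe_reml_balanced(Y, G, fix_s2g = fix_sigma2_gxe)
  gebv <- rbind(
    data.frame(accession = rownames(Y), trait = trait, site = NA_character_,
               gebv = fit$gebv_main, stringsAsFactors = FALSE),
    data.frame(accession = rep(rownames(Y), length(sites)), trait = trait,
               site = rep(sites, each = nrow(Y)),
               gebv = as.vector(fit$gebv_site), stringsAsFactors = FALSE))
  list(components = list(trait = trait, sites = sites,
                         sigma2_A = fit$sigma2_A,
                         sigma2_gxe = fit$sigma2_gxe,
                         sigma2_e = fit$sigma2_e,
                         log_likelihood = fit$loglik),
       gebv = gebv)
}
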