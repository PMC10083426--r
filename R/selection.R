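#' Standardize per-accession scores to z-scores
#'
#' @param values Named numeric vector (>= 2 distinct values).
#' @return Vector with mean 0 and sample SD 1 (n-1 denominator).
#' @export
standardize_scores <- function(values) {
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate scores: zero standard deviation")
  (values - mean(values)) / s
}

#' Smith-Hazel index weights
#'
#' Solves `P b = g` where `P` is the phenotypic variance-covariance matrix of
#' the traits and `g` the vector of their additive genetic variances, giving
#' the index weights `b = P^-1 g`.
#'
#' @param P Symmetric positive-definite phenotypic covariance matrix.
#' @param g Per-trait additive genetic variances (length `nrow(P)`).
#' @return Numeric weight vector `b`.
#' @export
smith_hazel_weights <- function(P, g) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || length(g) != nrow(P)) stop("P and g dimensions differ")
  if (max(abs(P - t(P))) > 1e-8) stop("P must be symmetric")
  b <- tryCatch(solve(P, g), error = function(e) stop("P is singular: ", conditionMessage(e)))
  as.vector(b)
}

#' Linear selection index over per-accession trait scores
#'
#' `index = sum_j w_j * score_j`, with each trait's scores standardized first
#' when `standardized = TRUE` (the convention for equally weighted GEBV
#' indices); Smith-Hazel weights are applied to raw scores since `b = P^-1 g`
#' already carries the units.
#'
#' @param scores Matrix or data.frame, accessions x traits, complete.
#' @param weights Numeric weights, one per trait column.
#' @param standardized Standardize each trait column before weighting.
#' @return Named vector of index values.
#' @export
build_index <- function(scores, weights, standardized = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(weights)) stop("one weight per trait required")
  if (anyNA(scores)) stop("missing trait score(s); index requires complete records")
  if (standardized) scores <- apply(scores, 2, standardize_scores)
  stats::setNames(as.vector(scores %*% weights), rownames(scores))
}

#' Select the top fraction of accessions on an index
#'
#' Picks the `floor(fraction * n)` highest-index accessions; ties at the
#' cut-off are broken deterministically towards the lexicographically
#' smaller accession id.
#'
#' @param index Named numeric vector of index values.
#' @param fraction Selected proportion in (0, 1].
#' @return Character vector of selected ids (in selection order).
#' @export
select_top_fraction <- function(index, fraction = 0.2) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(names(index))) stop("index must be named by accession id")
  n_sel <- floor(fraction * length(index))
  if (n_sel < 1L) stop("empty selection: floor(fraction * n) is zero")
  ord <- order(-index, names(index))
  names(index)[ord[seq_len(n_sel)]]
}

#' Selection differential, response and percentage gain
#'
#' `S = mean(selected) - mean(population)` on the evaluation values,
#' `R = h2 * S` (the breeder's equation with narrow-sense heritability), and
#' `percent_gain = 100 * R / site_mean`.
#'
#' @param population Named vector of evaluation values (e.g. a site's BLUEs)
#'   for the full population.
#' @param selected Ids of the selected candidates (subset of names).
#' @param h2 Narrow-sense heritability at the evaluation site.
#' @param site_mean Population mean used for the percentage gain; defaults
#'   to `mean(population)`.
#' @param index_label,selection_site,evaluation_site Optional labels carried
#'   into the report.
#' @return A one-row `selection_report` data.frame with columns
#'   `index, selection_site, evaluation_site, n_selected, S, R, percent_gain`.
#' @export
selection_response <- function(population, selected, h2,
                               site_mean = mean(population),
                               index_label = NA_character_,
                               selection_site = NA_character_,
                               evaluation_site = NA_character_) {
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% names(population))) {
    stop("selected ids missing from the evaluation population")
  }
  S <- mean(population[selected]) - mean(population)
  R <- h2 * S
  out <- data.frame(index = index_label, selection_site = selection_site,
                    evaluation_site = evaluation_site,
                    n_selected = length(selected), S = S, R = R,
                    percent_gain = 100 * R / site_mean,
                    stringsAsFactors = FALSE)
  class(out) <- c("selection_report", "data.frame")
  out
}

#' Score one selected set against several evaluation sites
#'
#' The same candidates (chosen at the selection site) are evaluated against
#' each site's values with that site's heritability — the cross-site
#' transferability check of a selection decision. Candidates without a value
#' at an evaluation site are excluded from that site's means with a warning.
#'
#' @param selected Ids of the selected candidates.
#' @param eval_values Named list: per evaluation site, a named vector of
#'   population evaluation values.
#' @param h2_by_site Named numeric: heritability per evaluation site.
#' @param site_means Optional named numeric of per-site population means
#'   (defaults to the mean of each site's values).
#' @param index_label,selection_site Labels for the report.
#' @return A `selection_report` data.frame, one row per evaluation site.
#' @export
cross_site_response <- function(selected, eval_values, h2_by_site,
                                site_means = NULL,
                                index_label = NA_character_,
                                selection_site = NA_character_) {
  out <- lapply(names(eval_values), function(s) {
    vals <- eval_values[[s]]
    sel <- selected[selected %in% names(vals)]
    n_miss <- length(selected) - length(sel)
    if (n_miss > 0) {
      warning(n_miss, " selected accession(s) missing at site ", s,
              "; excluded from its means")
    }
    m <- if (!is.null(site_means)) site_means[[s]] else mean(vals)
    selection_response(vals, sel, h2_by_site[[s]], site_mean = m,
                       index_label = index_label,
                       selection_site = selection_site,
                       evaluation_site = s)
  })
  out <- do.call(rbind, out)
  class(out) <- c("selection_report", "data.frame")
  out
}
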