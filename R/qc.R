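#' Per-marker missingness and minor allele frequency
#'
#' @param geno A `genotype_matrix`.
#' @return data.frame with columns `marker`, `missing_rate`, `maf`. The MAF is
#'   computed from non-missing calls only, as `min(p, 1 - p)` with
#'   `p = sum(dosage) / (2 * n_called)`. An all-missing marker is flagged with
#'   `missing_rate = 1` and `maf = NA`, never silently dropped.
#' @export
compute_marker_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  n_called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  maf[n_called == 0L] <- NA_real_
  data.frame(marker = geno$marker_ids,
             missing_rate = 1 - n_called / nrow(d),
             maf = maf, stringsAsFactors = FALSE)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Retains exactly the markers with `missing_rate < max_missing` and
#' `maf > min_maf` — both inequalities strict, matching the conventional
#' "missing < 50%, MAF > 0.01" GBS filter. Line set and marker order are
#' preserved.
#'
#' @param geno A `genotype_matrix`.
#' @param max_missing Strict upper bound on per-marker missing rate.
#' @param min_maf Strict lower bound on minor allele frequency.
#' @return The filtered `genotype_matrix`, with attribute `"qc"` holding the
#'   per-rule removal counts.
#' @export
filter_markers <- function(geno, max_missing = 0.5, min_maf = 0.01) {
  st <- compute_marker_stats(geno)
  maf_ok <- !is.na(st$maf) & st$maf > min_maf
  miss_ok <- st$missing_rate < max_missing
  keep <- maf_ok & miss_ok
  if (!any(keep)) stop("no markers survive QC: empty marker panel")
  out <- genotype_matrix(geno$line_ids, geno$marker_ids[keep],
                         geno$dosages[, keep, drop = FALSE],
                         geno$missing_mask[, keep, drop = FALSE])
  attr(out, "qc") <- list(n_in = length(st$marker), n_out = sum(keep),
                          removed_missing = sum(!miss_ok),
                          removed_maf = sum(miss_ok & !maf_ok),
                          max_missing = max_missing, min_maf = min_maf)
  out
}

#' Impute missing genotype calls
#'
#' `mean_dosage` fills each gap with the marker's mean observed dosage (a
#' continuous value); `knn` fills with the modal dosage among the `k` lines
#' most similar to the target line over their shared non-missing markers
#' (ties in the mode broken towards the lower dosage). Observed calls are
#' never altered.
#'
#' @param geno A `genotype_matrix`.
#' @param method `"mean_dosage"` (default) or `"knn"`.
#' @param k Number of neighbours for `"knn"`.
#' @return A complete `genotype_matrix` (no missing calls).
#' @export
impute_missing <- function(geno, method = c("mean_dosage", "knn"), k = 5L) {
  method <- match.arg(method)
  d <- geno$dosages
  if (!anyNA(d)) return(geno)
  all_missing <- colSums(!is.na(d)) == 0L
  if (any(all_missing)) {
    stop("cannot impute all-missing marker(s): ",
         paste(geno$marker_ids[all_missing], collapse = ", "))
  }
  if (method == "mean_dosage") {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  } else {
    n <- nrow(d)
    obs <- !is.na(d)
    for (i in seq_len(n)) {
      gaps <- which(is.na(d[i, ]))
      if (!length(gaps)) next
      shared <- obs & matrix(obs[i, ], n, ncol(d), byrow = TRUE)
      diffs <- abs(sweep(geno$dosages, 2, geno$dosages[i, ], "-"))
      diffs[!shared] <- NA
      n_shared <- rowSums(shared)
      dist <- rowSums(diffs, na.rm = TRUE) / pmax(n_shared, 1L)
      dist[i] <- Inf
      dist[n_shared == 0L] <- Inf
      ord <- order(dist)
      for (j in gaps) {
        donors <- ord[!is.na(geno$dosages[ord, j])]
        donors <- donors[seq_len(min(k, length(donors)))]
        calls <- geno$dosages[donors, j]
        tab <- table(factor(calls, levels = 0:2))
        d[i, j] <- as.numeric(names(tab)[which.max(tab)])
      }
    }
  }
  genotype_matrix(geno$line_ids, geno$marker_ids, d,
                  matrix(FALSE, nrow(d), ncol(d)))
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `G = W W' / (2 * sum p_j (1 - p_j))` with `W` the dosage matrix centred at
#' twice the observed allele frequencies. Monomorphic markers contribute
#' nothing to either numerator or denominator.
#'
#' @param geno A complete (imputed) `genotype_matrix`.
#' @return A `grm` object: list with `line_ids` and `values` (symmetric
#'   matrix, diagonal expectation about 1 under Hardy-Weinberg).
#' @export
vanraden_grm <- function(geno) {
  d <- geno$dosages
  if (anyNA(d)) stop("GRM requires a complete panel; impute first")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero GRM denominator")
  W <- sweep(d, 2, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(geno$line_ids, geno$line_ids)
  structure(list(line_ids = geno$line_ids, values = G), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d lines, mean diagonal %.3f\n",
              length(x$line_ids), mean(diag(x$values))))
  invisible(x)
}

#' Condition a GRM for inversion
#'
#' Adds `epsilon` to the diagonal so the smallest eigenvalue is at least
#' `epsilon` above the raw minimum; off-diagonal entries are untouched.
#'
#' @param grm A `grm` object (or bare symmetric matrix).
#' @param epsilon Small positive ridge.
#' @return A `grm` with the ridged matrix.
#' @export
condition_grm <- function(grm, epsilon = 1e-6) {
  G <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  if (max(abs(G - t(G))) > 1e-8) stop("GRM must be symmetric")
  ids <- if (inherits(grm, "grm")) grm$line_ids else rownames(G)
  if (is.null(ids)) ids <- paste0("L", seq_len(nrow(G)))
  G <- G + diag(epsilon, nrow(G))
  dimnames(G) <- list(ids, ids)
  structure(list(line_ids = ids, values = G), class = "grm")
}
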