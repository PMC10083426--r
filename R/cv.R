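#' Build a repeated k-fold cross-validation plan
#'
#' Per repeat, accessions are shuffled with the seeded RNG and split into `k`
#' folds whose sizes differ by at most one (e.g. 349 accessions into five
#' folds of 70, 70, 70, 70 and 69).
#'
#' @param accessions Character vector of ids.
#' @param k Folds per repeat.
#' @param repeats Number of repeats.
#' @param seed Integer seed; the plan is fully determined by it.
#' @return A `fold_plan`: list of integer vectors (one per repeat), each
#'   named by accession and giving the fold index 1..k.
#' @export
make_folds <- function(accessions, k = 5L, repeats = 5L, seed) {
  n <- length(accessions)
  if (anyDuplicated(accessions)) stop("accession ids must be unique")
  if (n < k) stop("need at least k accessions for k folds")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  plan <- lapply(seq_len(repeats), function(r) {
    ord <- sample.int(n)
    fold <- integer(n)
    fold[ord] <- rep(seq_len(k), times = sizes)
    stats::setNames(fold, accessions)
  })
  structure(plan, class = "fold_plan", k = k, repeats = repeats, seed = seed)
}

#' Cross-validated genomic prediction accuracy
#'
#' For every (repeat, fold) the target trait's BLUEs are masked in the
#' validation fold; variance components are re-estimated on the training
#' fold only (no leakage), and validation GEBVs are the conditional means of
#' the additive effects given the visible records. Under the `MT` model with
#' scenario `CV1` the secondary traits stay observed in the validation fold
#' and enter the conditional prediction; under `CV2` they are masked too, so
#' prediction uses only the genomic relationship to the training fold.
#' Accuracy is the Pearson correlation between validation GEBVs and the
#' held-out target BLUEs, aggregated over all `k * repeats` validation sets.
#'
#' @param blues Long `blue_table` for one site.
#' @param grm A `grm`.
#' @param plan A `fold_plan` from [make_folds()].
#' @param model `"UV"` (univariate) or `"MT"` (multi-trait).
#' @param scenario `"CV1"` or `"CV2"` (ignored for `"UV"`).
#' @param target Target trait (e.g. grain yield).
#' @param secondary Secondary trait names for the `MT` model.
#' @return An `accuracy_result`: list with `model`, `scenario`,
#'   `accuracies` (data.frame `repeat, fold, accuracy`), `mean`, `sd`.
#' @export
run_cv <- function(blues, grm, plan, model = c("UV", "MT"),
                   scenario = c("CV1", "CV2"), target,
                   secondary = character(0)) {
  model <- match.arg(model); scenario <- match.arg(scenario)
  if (model == "MT" && !length(secondary)) stop("MT model needs secondary traits")
  traits <- c(target, if (model == "MT") secondary)
  al <- align_blues_grm(blues, grm, traits)
  ok <- is.finite(al$Y[, target])
  Y <- al$Y[ok, , drop = FALSE]; G <- al$G[ok, ok]
  acc <- rownames(Y)
  t <- ncol(Y)

  res <- list(); i <- 0L
  for (r in seq_along(plan)) {
    fold <- plan[[r]][acc]
    if (anyNA(fold)) stop("fold plan does not cover all accessions with target BLUEs")
    for (f in seq_len(attr(plan, "k"))) {
      val <- which(fold == f); tr <- which(fold != f)
      if (length(val) < 3L) stop("validation fold with fewer than 3 accessions")
      if (model == "UV") {
        fit <- uv_reml_eigen(Y[tr, target], G[tr, tr])
        pred <- uv_predict(Y[tr, target], G, tr, val,
                           fit$sigma2_A, fit$sigma2_e)
      } else {
        fit <- mt_reml_balanced(Y[tr, , drop = FALSE], G[tr, tr],
                                maxit = 2000, restarts = 1L)
        obs <- expand.grid(acc_idx = tr, trait_idx = seq_len(t))
        if (scenario == "CV1") {
          sec <- expand.grid(acc_idx = val, trait_idx = seq(2L, t))
          obs <- rbind(obs, sec)
        }
        obs$value <- Y[cbind(obs$acc_idx, obs$trait_idx)]
        pr <- mt_dense_predict(obs, G, fit$T, fit$R)
        pred <- pr$gebv[val, 1]
      }
      i <- i + 1L
      res[[i]] <- data.frame(rep = r, fold = f,
                             accuracy = stats::cor(pred, Y[val, target]))
    }
  }
  accs <- do.call(rbind, res)
  sm <- summarize_accuracy(accs$accuracy)
  structure(list(model = model,
                 scenario = if (model == "UV") "UV" else paste0("MT-", scenario),
                 target = target, secondary = secondary,
                 accuracies = accs, mean = sm[["mean"]], sd = sm[["sd"]]),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("%s (%s) prediction accuracy for %s: mean %.3f, SD %.3f over %d validation sets\n",
              x$model, x$scenario, x$target, x$mean, x$sd, nrow(x$accuracies)))
  invisible(x)
}

#' Evaluate UV, MT-CV1 and MT-CV2 accuracy in one pass
#'
#' Runs the univariate model and both multi-trait cross-validation scenarios
#' over the same fold plan, re-using the multi-trait training-fold fit for
#' both scenarios (CV1 and CV2 differ only in which validation records are
#' visible at prediction time). Equivalent to three [run_cv()] calls but
#' roughly twice as fast.
#'
#' @inheritParams run_cv
#' @return Named list of `accuracy_result`s: `UV`, `CV1`, `CV2`.
#' @export
run_cv_scenarios <- function(blues, grm, plan, target, secondary) {
  traits <- c(target, secondary)
  al <- align_blues_grm(blues, grm, traits)
  ok <- is.finite(al$Y[, target])
  Y <- al$Y[ok, , drop = FALSE]; G <- al$G[ok, ok]
  acc <- rownames(Y); t <- ncol(Y)
  k <- attr(plan, "k")
  out <- list(UV = list(), CV1 = list(), CV2 = list())
  i <- 0L
  for (r in seq_along(plan)) {
    fold <- plan[[r]][acc]
    for (f in seq_len(k)) {
      val <- which(fold == f); tr <- which(fold != f)
      if (length(val) < 3L) stop("validation fold with fewer than 3 accessions")
      i <- i + 1L
      fu <- uv_reml_eigen(Y[tr, target], G[tr, tr])
      pu <- uv_predict(Y[tr, target], G, tr, val, fu$sigma2_A, fu$sigma2_e)
      fit <- mt_reml_balanced(Y[tr, , drop = FALSE], G[tr, tr],
                              maxit = 2000, restarts = 1L)
      obs_tr <- expand.grid(acc_idx = tr, trait_idx = seq_len(t))
      obs_tr$value <- Y[cbind(obs_tr$acc_idx, obs_tr$trait_idx)]
      sec <- expand.grid(acc_idx = val, trait_idx = seq(2L, t))
      sec$value <- Y[cbind(sec$acc_idx, sec$trait_idx)]
      p1 <- mt_dense_predict(rbind(obs_tr, sec), G, fit$T, fit$R)$gebv[val, 1]
      p2 <- mt_dense_predict(obs_tr, G, fit$T, fit$R)$gebv[val, 1]
      held <- Y[val, target]
      out$UV[[i]] <- data.frame(rep = r, fold = f, accuracy = stats::cor(pu, held))
      out$CV1[[i]] <- data.frame(rep = r, fold = f, accuracy = stats::cor(p1, held))
      out$CV2[[i]] <- data.frame(rep = r, fold = f, accuracy = stats::cor(p2, held))
    }
  }
  wrap <- function(lst, model, scen) {
    accs <- do.call(rbind, lst)
    sm <- summarize_accuracy(accs$accuracy)
    structure(list(model = model, scenario = scen, target = target,
                   secondary = secondary, accuracies = accs,
                   mean = sm[["mean"]], sd = sm[["sd"]]),
              class = "accuracy_result")
  }
  list(UV = wrap(out$UV, "UV", "UV"),
       CV1 = wrap(out$CV1, "MT", "MT-CV1"),
       CV2 = wrap(out$CV2, "MT", "MT-CV2"))
}

#' Mean and sample standard deviation of fold accuracies
#'
#' @param accs Numeric vector (length >= 2) of per-fold accuracies.
#' @return Named vector `c(mean, sd)`; the SD uses the n-1 denominator.
#' @export
summarize_accuracy <- function(accs) {
  if (length(accs) < 2L) stop("need at least 2 accuracy values")
  c(mean = mean(accs), sd = stats::sd(accs))
}
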