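#' Read and validate a pipeline run configuration
#'
#' A flat YAML (or list) of run settings. `seed` is mandatory and validated
#' before any computation; referenced input paths must exist.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config validation: `seed` is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  for (p in c("genotypes", "phenotypes")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config validation: path for `", p, "` does not exist: ", cfg[[p]])
    }
  }
  defaults <- list(out_dir = "gsresp_out", max_missing = 0.5, min_maf = 0.01,
                   impute = "mean_dosage", cv_k = 5L, cv_repeats = 5L,
                   selection_fraction = 0.2, stage1 = FALSE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load) genotypes and
#' phenotypes, marker QC and imputation, GRM, optional stage-one spatial
#' BLUEs, univariate GBLUP per trait, cross-validated prediction accuracy
#' for the target trait, and top-fraction selection responses — writing every
#' artifact under `config$out_dir` together with a JSON manifest of file
#' hashes.
#'
#' @param config A `run_config` (or path / list accepted by
#'   [read_run_config()]).
#' @return Invisibly, the manifest list (stage timings, artifact paths and
#'   md5 hashes).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, artifacts = list(), stages = list())
  t_start <- proc.time()[["elapsed"]]
  emit <- function(stage, path) {
    manifest$artifacts[[basename(path)]] <<- list(
      path = path, stage = stage, md5 = unname(tools::md5sum(path)))
    message(sprintf("[%s] %.1fs wrote %s (seed %d)", stage,
                    proc.time()[["elapsed"]] - t_start, path, cfg$seed))
  }

  # -- inputs -----------------------------------------------------------
  if (!is.null(cfg$genotypes)) {
    geno <- if (grepl("\\.vcf$", cfg$genotypes)) read_vcf_dosage(cfg$genotypes)
            else read_dosage_tsv(cfg$genotypes)
    blues <- read_table_csv(cfg$phenotypes, class_out = "blue_table")
    params <- NULL
  } else {
    params <- do.call(default_sim_params, c(
      cfg$sim[!vapply(cfg$sim, is.null, TRUE)], list(seed = cfg$seed)))
    geno <- simulate_genotypes(params)
    eff <- simulate_true_effects(geno, params)
    write_dosage_tsv(geno, file.path(cfg$out_dir, "genotypes.tsv"))
    emit("simulate", file.path(cfg$out_dir, "genotypes.tsv"))
    if (isTRUE(cfg$stage1)) {
      trial <- simulate_trial(geno, eff, params)
      write_table_csv(trial, file.path(cfg$out_dir, "plots.csv"))
      emit("simulate", file.path(cfg$out_dir, "plots.csv"))
    }
    blues <- simulate_blues(geno, eff, params)
    write_table_csv(data.frame(accession = rownames(eff$g), eff$g),
                    file.path(cfg$out_dir, "true_effects.csv"))
    emit("simulate", file.path(cfg$out_dir, "true_effects.csv"))
  }

  # -- QC + GRM ---------------------------------------------------------
  filt <- filter_markers(geno, cfg$max_missing, cfg$min_maf)
  if (cfg$impute != "none") filt <- impute_missing(filt, method = cfg$impute)
  write_components_json(attr(filt, "qc") %||% list(n_in = length(geno$marker_ids)),
                        file.path(cfg$out_dir, "qc_report.json"))
  emit("qc", file.path(cfg$out_dir, "qc_report.json"))
  grm <- condition_grm(vanraden_grm(filt))
  write_grm_tsv(grm, file.path(cfg$out_dir, "grm.tsv"))
  emit("grm", file.path(cfg$out_dir, "grm.tsv"))

  # -- stage 1 (optional, from plot data) -------------------------------
  if (isTRUE(cfg$stage1) && exists("trial", inherits = FALSE)) {
    traits <- cfg$traits %||% unique(blues$trait)
    b1 <- list()
    for (s in unique(trial$site)) for (tr in traits) {
      f <- fit_trial_blues(trial[trial$site == s, ], tr,
                           grid_step = cfg$blues_grid_step %||% 0.1)
      b1[[paste(s, tr)]] <- f$blues
    }
    blues <- do.call(rbind, b1)
    class(blues) <- c("blue_table", "data.frame")
    write_table_csv(blues, file.path(cfg$out_dir, "blues.csv"))
    emit("blues", file.path(cfg$out_dir, "blues.csv"))
  }

  # -- univariate fits per trait/site -----------------------------------
  traits <- cfg$traits %||% unique(blues$trait)
  sites <- cfg$sites %||% unique(blues$site)
  comps <- list()
  for (s in sites) for (tr in traits) {
    fit <- fit_univariate(blues, grm, trait = tr, site = s)
    comps[[paste(s, tr, sep = ".")]] <- fit$components
  }
  write_components_json(comps, file.path(cfg$out_dir, "components.json"))
  emit("fit", file.path(cfg$out_dir, "components.json"))

  # -- cross-validation for the target trait ----------------------------
  target <- cfg$target %||% traits[1]
  cv_site <- sites[1]
  bsite <- blues[blues$site == cv_site, ]
  acc <- intersect(grm$line_ids,
                   bsite$accession[bsite$trait == target & is.finite(bsite$estimate)])
  plan <- make_folds(acc, k = cfg$cv_k, repeats = cfg$cv_repeats,
                     seed = cfg$seed + 10L)
  cv_uv <- run_cv(bsite, grm, plan, model = "UV", target = target)
  cv_tab <- data.frame(site = cv_site, model = "UV", scenario = "UV",
                       cv_uv$accuracies)
  secondary <- setdiff(traits, target)
  if (length(secondary)) {
    cv1 <- run_cv(bsite, grm, plan, model = "MT", scenario = "CV1",
                  target = target, secondary = secondary[1])
    cv_tab <- rbind(cv_tab,
                    data.frame(site = cv_site, model = "MT", scenario = "MT-CV1",
                               cv1$accuracies))
  }
  write_table_csv(cv_tab, file.path(cfg$out_dir, "cv_accuracy.csv"))
  emit("cv", file.path(cfg$out_dir, "cv_accuracy.csv"))

  # -- selection response (phenotypic index at first site) --------------
  vals <- stats::setNames(bsite$estimate[bsite$trait == target],
                          bsite$accession[bsite$trait == target])
  vals <- vals[is.finite(vals)]
  sel <- select_top_fraction(vals, cfg$selection_fraction)
  h2 <- comps[[paste(cv_site, target, sep = ".")]]$h2
  rep_sel <- selection_response(vals, sel, h2, index_label = "PS",
                                selection_site = cv_site,
                                evaluation_site = cv_site)
  write_table_csv(rep_sel, file.path(cfg$out_dir, "selection_report.csv"))
  emit("select", file.path(cfg$out_dir, "selection_report.csv"))

  manifest$elapsed_s <- proc.time()[["elapsed"]] - t_start
  write_components_json(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
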