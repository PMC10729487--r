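required_cohort_columns <- c("participant_id", "family_id", "site_id",
                             "group", "age", "eyo", "sex", "education",
                             "apoe4")

known_variant_levels <- c("APP", "PSEN1<200", "PSEN1 200+", "PSEN2")

#' Read a cohort table from CSV
#'
#' Comma-delimited, UTF-8, header row, `NA` as the missing-value token.
#' Validates the field structure (malformed rows are reported with their line
#' numbers) and the presence of the required columns, and restores the
#' canonical factor codings (`group`, `sex`, `variant`, identifiers).
#'
#' @param path CSV file path.
#' @return Cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  counts <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(counts) < 1) stop("empty file", call. = FALSE)
  if (counts[1] < 2)
    stop("parse error at line 1: expected a comma-delimited header with multiple fields",
         call. = FALSE)
  bad <- which(counts != counts[1])
  if (length(bad))
    stop(sprintf("malformed row(s) at line(s): %s (expected %d fields)",
                 paste(utils::head(bad, 10), collapse = ", "), counts[1]),
         call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         check.names = FALSE)
  missing_cols <- setdiff(required_cohort_columns, names(tab))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tab$group <- factor(tab$group, levels = cohort_groups)
  tab$sex <- factor(tab$sex, levels = c("F", "M"))
  for (v in c("family_id", "site_id", "scanner_id"))
    if (!is.null(tab[[v]])) tab[[v]] <- factor(tab[[v]])
  if (!is.null(tab$variant)) {
    levs <- if (all(tab$variant %in% known_variant_levels))
      known_variant_levels else sort(unique(tab$variant))
    tab$variant <- factor(tab$variant, levels = levs)
  }
  tab
}

#' Write a cohort table to CSV
#'
#' @param table cohort table.
#' @param path output path.
#' @param blind drop generator ground-truth columns (those prefixed `true_`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, blind = FALSE) {
  if (blind) table <- table[!startsWith(names(table), "true_")]
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' When `cohort_csv` is `NULL` the cohort is generated from `spec` at `seed`.
#'
#' @param cohort_csv optional path to a cohort CSV (otherwise synthetic).
#' @param retest_csv optional path to a retest CSV with `visit1`/`visit2`
#'   columns (otherwise a retest pair is generated at `spec$icc_target`).
#' @param spec a [cohort_spec()]; used to generate data and the retest pair.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory for [write_bundle()] (`NULL`: no files).
#' @param harmonization list: `batch`, `covariates`, `eb`, `then_scanner`.
#' @param gamm list: `k`, `grid_step`, `level`, `n_draws`, `n_boot`
#'   (0 disables the bootstrap), `boot_grid_step`, `boot_n_draws`,
#'   `measures` (response columns for the bootstrap comparison).
#' @param associations list: `biomarkers`, `covariates`,
#'   `n_boot_mediation`, `mediation_x`, `log_sensitivity`.
#' @param verbose log stage progress with [message()].
#' @return Object of class `bag_config`.
#' @export
analysis_config <- function(cohort_csv = NULL, retest_csv = NULL,
                            spec = cohort_spec(), seed = 1L, out_dir = NULL,
                            harmonization = list(), gamm = list(),
                            associations = list(), verbose = TRUE) {
  harm_def <- list(batch = "site_id",
                   covariates = c("age", "sex", "education", "group", "eyo",
                                  "apoe4", "variant"),
                   eb = TRUE, then_scanner = FALSE)
  gamm_def <- list(k = 4L, grid_step = 0.05, level = 0.834, n_draws = 10000L,
                   n_boot = 0L, boot_grid_step = 0.1, boot_n_draws = 1000L,
                   measures = "bag")
  assoc_def <- list(biomarkers = names(spec$biomarker_params),
                    covariates = c("sex", "education", "apoe4"),
                    n_boot_mediation = 1000L, mediation_x = "csf_ptau_ab40",
                    log_sensitivity = FALSE)
  cfg <- list(cohort_csv = cohort_csv, retest_csv = retest_csv, spec = spec,
              seed = as.integer(seed), out_dir = out_dir,
              harmonization = utils::modifyList(harm_def, harmonization),
              gamm = utils::modifyList(gamm_def, gamm),
              associations = utils::modifyList(assoc_def, associations),
              verbose = isTRUE(verbose))
  class(cfg) <- "bag_config"
  cfg
}

stage_msg <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(fmt, ...))
}

#' Run the full BAG analysis pipeline
#'
#' Executes the stages in order: load/generate cohort -> slice aggregation
#' (if needed) -> regression-dilution calibration (NC) -> pre-harmonization
#' site/scanner checks -> ComBat harmonization of predicted age -> BAG ->
#' performance and reliability -> nonparametric group tests and effect size
#' -> GAMM trajectory, simultaneous bands, divergence (optionally
#' bootstrapped) -> biomarker mixed models, within-group correlations and
#' mediation. All stochastic stages derive their seeds from `config$seed`.
#' If `config$out_dir` is set, results are written with [write_bundle()]; on
#' a stage failure the partial outputs plus a failure manifest are written
#' before the error propagates.
#'
#' @param config an [analysis_config()].
#' @return Object of class `bag_results` (named list of stage outputs plus a
#'   reproducibility manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "bag_config"))
  res <- list()
  stage <- "load"
  out <- tryCatch({
    ## ---- load -------------------------------------------------------------
    cohort <- if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else generate_cohort(config$spec, seed = config$seed)
    missing_cols <- setdiff(required_cohort_columns, names(cohort))
    if (length(missing_cols))
      stop(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    slice_cols <- grep("^slice_", names(cohort), value = TRUE)
    if (is.null(cohort$raw_predicted_age) && length(slice_cols)) {
      cohort$raw_predicted_age <-
        apply(as.matrix(cohort[slice_cols]), 1, aggregate_slices)
    }
    if (is.null(cohort$raw_predicted_age))
      stop("missing required column(s): raw_predicted_age (or slice_* columns)",
           call. = FALSE)
    stage_msg(config, "loaded cohort: %d rows (%s), seed %d", nrow(cohort),
              paste(sprintf("%s=%d", levels(cohort$group), table(cohort$group)),
                    collapse = ", "), config$seed)
    res$cohort <- cohort

    ## ---- calibration ------------------------------------------------------
    stage <- "calibration"
    nc <- cohort[cohort$group == "NC", , drop = FALSE]
    calib <- fit_calibration(nc)
    cohort$corrected_age <- apply_calibration(calib, cohort$raw_predicted_age)
    bag_pre <- compute_bag(cohort$corrected_age, cohort$age)
    res$calibration <- calib
    stage_msg(config, "calibration: alpha = %.3f, beta = %.3f (n = %d NC)",
              calib$intercept, calib$slope, calib$n_fit)

    ## ---- harmonization ----------------------------------------------------
    stage <- "harmonization"
    nc_idx <- cohort$group == "NC"
    pre_site <- batch_difference_test(bag_pre[nc_idx], cohort$site_id[nc_idx])
    pre_scanner <- if (!is.null(cohort$scanner_id))
      batch_difference_test(bag_pre[nc_idx], cohort$scanner_id[nc_idx]) else NULL
    harm <- harmonize_predicted_age(
      cohort, value_col = "corrected_age",
      batch_col = config$harmonization$batch,
      covariate_cols = config$harmonization$covariates,
      eb = config$harmonization$eb,
      then_scanner = config$harmonization$then_scanner)
    cohort$harmonized_age <- harm$values
    cohort$bag <- compute_bag(cohort$harmonized_age, cohort$age)
    post_site <- batch_difference_test(cohort$bag[nc_idx], cohort$site_id[nc_idx])
    post_scanner <- if (!is.null(cohort$scanner_id))
      batch_difference_test(cohort$bag[nc_idx], cohort$scanner_id[nc_idx]) else NULL
    res$harmonization <- list(model = harm$model,
                              scanner_model = harm$scanner_model,
                              pre_site = pre_site, post_site = post_site,
                              pre_scanner = pre_scanner,
                              post_scanner = post_scanner)
    res$cohort <- cohort
    stage_msg(config, "harmonization: site KW p %.3f -> %.3f (NC BAG)",
              pre_site$p.value, post_site$p.value)

    ## ---- performance & reliability -----------------------------------------
    stage <- "performance"
    res$performance <- performance_metrics(nc$raw_predicted_age, nc$age)
    retest <- if (!is.null(config$retest_csv)) {
      utils::read.csv(config$retest_csv, stringsAsFactors = FALSE)
    } else {
      generate_retest(cohort, config$spec$icc_target,
                      seed = config$seed + 1L)
    }
    res$reliability <- icc_a1(retest$visit1, retest$visit2)
    stage_msg(config, "performance: r = %.3f, MAE = %.2f; ICC(A,1) = %.3f",
              res$performance$r, res$performance$mae, res$reliability$icc)

    ## ---- group tests -------------------------------------------------------
    stage <- "group_tests"
    res$group_tests <- list(
      kruskal = group_comparison(cohort$bag, cohort$group),
      levene = levene_test(cohort$bag, cohort$group),
      cohens_d_sym_nc = cohens_d(cohort$bag[cohort$group == "sym_MC"],
                                 cohort$bag[cohort$group == "NC"]))
    stage_msg(config, "group tests: KW chi2(%d) = %.2f, d(sym vs NC) = %.2f",
              res$group_tests$kruskal$df, res$group_tests$kruskal$statistic,
              res$group_tests$cohens_d_sym_nc$d)

    ## ---- trajectory --------------------------------------------------------
    stage <- "trajectory"
    set.seed(config$seed + 2L)
    div <- divergence_point(cohort, response = "bag", k = config$gamm$k,
                            grid_step = config$gamm$grid_step,
                            level = config$gamm$level,
                            n_draws = config$gamm$n_draws)
    res$trajectory <- list(
      fit = div$fit, band_nc = div$band_nc, band_mc = div$band_mc,
      eyo_star = div$eyo_star,
      smooth_nc = smooth_term_test(div$fit, "NC"),
      smooth_mc = smooth_term_test(div$fit, "MC"))
    stage_msg(config, "trajectory: MC smooth EDF = %.2f, divergence EYO = %s",
              res$trajectory$smooth_mc[["edf"]],
              ifelse(is.na(div$eyo_star), "none", sprintf("%.2f", div$eyo_star)))
    if (config$gamm$n_boot > 0) {
      res$bootstrap <- bootstrap_divergence(
        cohort, measures = config$gamm$measures,
        n_boot = config$gamm$n_boot, seed = config$seed + 3L,
        grid_step = config$gamm$boot_grid_step,
        n_draws = config$gamm$boot_n_draws, level = config$gamm$level,
        k = config$gamm$k)
      stage_msg(config, "bootstrap: %d replicates, median divergence %.2f",
                config$gamm$n_boot, res$bootstrap$summary$median[1])
    }

    ## ---- associations ------------------------------------------------------
    stage <- "associations"
    bms <- intersect(config$associations$biomarkers, names(cohort))
    res$associations <- lapply(bms, function(bm) {
      lme <- fit_lme_biomarker(cohort, bm,
                               covariates = config$associations$covariates)
      list(lme = lme,
           r_sym = group_correlations(cohort, bm, "sym_MC"),
           r_asym = group_correlations(cohort, bm, "asym_MC"))
    })
    names(res$associations) <- bms
    if (isTRUE(config$associations$log_sensitivity))
      res$log_sensitivity <- log_sensitivity(
        cohort, bms, covariates = config$associations$covariates)
    stage <- "mediation"
    if (config$associations$mediation_x %in% names(cohort)) {
      res$mediation <- mediate(cohort, x = config$associations$mediation_x,
                               covariates = config$associations$covariates,
                               n_boot = config$associations$n_boot_mediation,
                               seed = config$seed + 4L)
      stage_msg(config, "mediation (%s): indirect = %.3f [%.3f, %.3f] (%s)",
                res$mediation$x, res$mediation$indirect, res$mediation$ci_low,
                res$mediation$ci_high, res$mediation$label)
    }

    res$manifest <- build_manifest(config)
    class(res) <- "bag_results"
    res
  }, error = function(e) {
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      res$manifest <- build_manifest(config)
      res$failure <- list(stage = stage, message = conditionMessage(e))
      class(res) <- "bag_results"
      try(write_bundle(res, config$out_dir), silent = TRUE)
    }
    stop(e)
  })
  if (!is.null(config$out_dir)) write_bundle(out, config$out_dir)
  out
}

build_manifest <- function(config) {
  cfg <- config
  cfg$spec <- unclass(cfg$spec)
  cfg$out_dir <- NULL   # not part of the reproducibility state
  list(package = "bagtraj",
       version = as.character(utils::packageVersion("bagtraj")),
       seed = config$seed,
       stage_seeds = list(cohort = config$seed, retest = config$seed + 1L,
                          bands = config$seed + 2L, bootstrap = config$seed + 3L,
                          mediation = config$seed + 4L),
       config = unclass(cfg))
}

#' @export
print.bag_results <- function(x, ...) {
  cat("BAG pipeline results\n")
  if (!is.null(x$failure)) {
    cat(sprintf("  FAILED at stage '%s': %s\n", x$failure$stage, x$failure$message))
    return(invisible(x))
  }
  cat(sprintf("  cohort: %d rows; calibration beta = %.3f\n",
              nrow(x$cohort), x$calibration$slope))
  print(x$performance)
  print(x$reliability)
  cat(sprintf("  divergence EYO: %s\n",
              ifelse(is.na(x$trajectory$eyo_star), "none",
                     sprintf("%.2f", x$trajectory$eyo_star))))
  invisible(x)
}

#' Write a results bundle to disk
#'
#' Emits the pipeline outputs as plain-text CSV/JSON files: the analyzed
#' cohort and BAG table, performance/reliability reports, the per-batch
#' harmonization report and pre/post batch tests, per-group band tables, the
#' divergence summary (plus bootstrap summary when run), tidy association and
#' mediation tables, and a reproducibility manifest.
#'
#' @param bundle a `bag_results` object from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "bag_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null")
  files <- character(0)
  add <- function(f) files <<- c(files, file.path(dir, f))

  if (!is.null(bundle$failure)) {
    wj(c(bundle$failure, list(manifest = bundle$manifest)), "failure_manifest.json")
    return(invisible(file.path(dir, "failure_manifest.json")))
  }

  write_cohort(bundle$cohort, file.path(dir, "cohort.csv")); add("cohort.csv")
  keep <- intersect(c("participant_id", "family_id", "site_id", "scanner_id",
                      "group", "age", "eyo", "raw_predicted_age",
                      "corrected_age", "harmonized_age", "bag"),
                    names(bundle$cohort))
  utils::write.csv(bundle$cohort[keep], file.path(dir, "bag_table.csv"),
                   row.names = FALSE, na = "NA"); add("bag_table.csv")

  wj(unclass(bundle$performance), "performance.json"); add("performance.json")
  wj(unclass(bundle$reliability), "reliability.json"); add("reliability.json")

  hm <- bundle$harmonization$model
  utils::write.csv(data.frame(batch = hm$levels, n = hm$n_batch,
                              gamma_star = hm$gamma_star,
                              delta_star = hm$delta_star),
                   file.path(dir, "harmonization_report.csv"),
                   row.names = FALSE); add("harmonization_report.csv")
  wj(list(pre_site = bundle$harmonization$pre_site,
          post_site = bundle$harmonization$post_site,
          pre_scanner = bundle$harmonization$pre_scanner,
          post_scanner = bundle$harmonization$post_scanner),
     "batch_tests.json"); add("batch_tests.json")

  gt <- bundle$group_tests
  wj(list(kruskal = list(statistic = gt$kruskal$statistic, df = gt$kruskal$df,
                         p = gt$kruskal$p.value,
                         pairwise = gt$kruskal$pairwise),
          levene = gt$levene,
          cohens_d_sym_nc = gt$cohens_d_sym_nc),
     "group_tests.json"); add("group_tests.json")

  bands <- merge(bundle$trajectory$band_nc$band,
                 bundle$trajectory$band_mc$band,
                 by = "eyo", suffixes = c("_nc", "_mc"))
  utils::write.csv(bands, file.path(dir, "bands_bag.csv"), row.names = FALSE)
  add("bands_bag.csv")
  wj(list(eyo_star = bundle$trajectory$eyo_star,
          smooth_nc = as.list(bundle$trajectory$smooth_nc),
          smooth_mc = as.list(bundle$trajectory$smooth_mc),
          m_nc = bundle$trajectory$band_nc$m,
          m_mc = bundle$trajectory$band_mc$m,
          level = bundle$trajectory$band_nc$level,
          family_sd = bundle$trajectory$fit$family_sd),
     "divergence.json"); add("divergence.json")
  if (!is.null(bundle$bootstrap)) {
    wj(list(summary = bundle$bootstrap$summary,
            pairwise_p = as.data.frame(bundle$bootstrap$pairwise_p),
            n_boot = bundle$bootstrap$n_boot, seed = bundle$bootstrap$seed),
       "bootstrap_divergence.json"); add("bootstrap_divergence.json")
  }

  if (length(bundle$associations)) {
    assoc <- do.call(rbind, lapply(names(bundle$associations), function(bm) {
      a <- bundle$associations[[bm]]
      tt <- a$lme$terms
      tt$biomarker <- bm
      tt$n <- a$lme$n
      tt$r_sym <- a$r_sym$r
      tt$r_asym <- a$r_asym$r
      tt
    }))
    utils::write.csv(assoc, file.path(dir, "associations.csv"),
                     row.names = FALSE); add("associations.csv")
  }
  if (!is.null(bundle$mediation)) {
    m <- bundle$mediation
    wj(list(x = m$x, m = m$m, y = m$y, a = m$a, b = m$b,
            indirect = m$indirect, direct = m$direct, total = m$total,
            ci = c(m$ci_low, m$ci_high), label = m$label,
            n = m$n, n_boot = m$n_boot), "mediation.json"); add("mediation.json")
  }
  wj(bundle$manifest, "manifest.json"); add("manifest.json")
  invisible(files)
}
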