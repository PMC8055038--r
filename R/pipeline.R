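#' Read a cohort CSV
#'
#' Tolerant reader for the tabular cohort format: a header with at least
#' `id` and `province`, empty strings read as missing, unknown extra
#' columns carried through. Duplicate ids are an integrity error.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  for (col in c("id", "province"))
    if (!col %in% names(dat)) stopf("missing required column '%s'", col)
  dup <- dat$id[duplicated(dat$id)]
  if (length(dup))
    stopf("duplicate id(s): %s", paste(unique(dup), collapse = ", "))
  dat
}

#' Write a cohort CSV
#'
#' Missing cells are written as empty strings, matching [read_cohort()].
#'
#' @param data cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Full-pipeline run configuration
#'
#' Exactly one of `input` (a cohort CSV path) or `synthetic` (a
#' [cohort_config()]) must be given.
#'
#' @param input path to a cohort CSV in raw or dichotomized form.
#' @param synthetic a [cohort_config()] to simulate from.
#' @param items final item set for the index model.
#' @param raw_input whether `input`/synthetic data are raw survey columns
#'   needing [dichotomize()] (synthetic configs are generated raw when all
#'   19 candidates are present).
#' @param variants model variants to fit.
#' @param run_varselect run the chi-squared/MCA screen.
#' @param min_n province-size filter threshold.
#' @param mcmc an [mcmc_control()].
#' @param outdir output directory for stage artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       items = core9_items(), raw_input = NULL,
                       variants = c("pooled", "hierarchical"),
                       run_varselect = TRUE, min_n = 100,
                       mcmc = mcmc_control(), outdir = tempfile("depriv_run_")) {
  if (is.null(input) == is.null(synthetic))
    stopf("exactly one of input, synthetic must be given")
  structure(list(input = input, synthetic = synthetic, items = items,
                 raw_input = raw_input, variants = variants,
                 run_varselect = run_varselect, min_n = min_n,
                 mcmc = mcmc, outdir = outdir),
            class = "run_config")
}

#' Run the deprivation-index pipeline end to end
#'
#' Sequence: load or simulate the cohort, dichotomize raw variables if
#' needed, filter small provinces, take complete cases on the final item
#' set, optionally run the variable screen, fit the requested model
#' variants, compare them by WAIC, export the index and ICC curves, and
#' run the outcome analysis (index-only vs all components) when an
#' `outcome` column is present. All stage artifacts are written under
#' `config$outdir`; identical config + seed yields identical outputs.
#' A hierarchical request on a single-province dataset falls back to the
#' pooled model with a warning.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress.
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # ---- load / simulate ----
  truth <- NULL
  if (!is.null(config$synthetic)) {
    say("simulating synthetic cohort")
    raw <- is.null(config$raw_input) || isTRUE(config$raw_input)
    sim <- stage("simulate", if (raw) simulate_raw_cohort(config$synthetic)
                             else simulate_cohort(config$synthetic))
    dat <- sim$data; truth <- sim$truth
    write_cohort(dat, file.path(config$outdir, "cohort.csv"))
    is_raw <- raw
  } else {
    say("reading cohort from %s", config$input)
    dat <- stage("read", read_cohort(config$input))
    is_raw <- isTRUE(config$raw_input) ||
      (is.null(config$raw_input) && !all(config$items %in% names(dat)))
  }

  # ---- preprocess ----
  if (is_raw) {
    rules <- ccc_rules()
    rules <- rules[vapply(rules, function(r) r$variable %in% names(dat), NA)]
    dat <- stage("dichotomize", dichotomize(dat, rules))
  }
  candidates <- intersect(attr(dat, "items") %||%
                            setdiff(names(dat), c("id", "province", "outcome")),
                          names(dat))
  pf <- stage("province_filter", filter_small_provinces(dat, config$min_n))
  cc <- stage("complete_cases", complete_cases(pf$data, config$items))
  exclusion <- new_exclusion_report(
    pf$report$n_input, pf$report$n_after_province_filter,
    cc$report$n_complete, pf$report$excluded_provinces,
    cc$report$per_item_missing)
  say("complete cases: %d of %d", exclusion$n_complete, exclusion$n_input)

  # ---- variable screen ----
  selection <- NULL
  if (isTRUE(config$run_varselect)) {
    say("variable screen (chi-squared + MCA)")
    screen_cc <- complete_cases(pf$data, candidates)$data
    chi2 <- stage("chi2", pairwise_chi2(screen_cc, candidates))
    mca_sol <- stage("mca", mca(screen_cc, candidates))
    selection <- selection_report(chi2, mca_sol, config$items)
    utils::write.csv(chi2, file.path(config$outdir, "chi2.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(category = rownames(mca_sol$category_coordinates),
                 mca_sol$category_coordinates[, 1:2]),
      file.path(config$outdir, "mca_coordinates.csv"), row.names = FALSE)
    jsonlite::write_json(selection$summary,
                         file.path(config$outdir, "selection_report.json"),
                         digits = NA)
  }

  # ---- fit models ----
  variants <- config$variants
  K <- length(unique(cc$data$province))
  if ("hierarchical" %in% variants && K < 2L) {
    warning("single province: falling back to pooled model")
    variants <- unique(sub("hierarchical", "pooled", variants))
  }
  fits <- list()
  waics <- list()
  for (v in variants) {
    say("fitting %s model", v)
    fits[[v]] <- stage(paste0("fit_", v),
                       irt_deprivation(cc$data, config$items, variant = v,
                                       mcmc = config$mcmc))
    waics[[v]] <- waic(fits[[v]])
  }
  waic_tab <- data.frame(
    model = names(waics),
    waic = vapply(waics, `[[`, 0, "waic"),
    se = vapply(waics, `[[`, 0, "se"),
    p_waic = vapply(waics, `[[`, 0, "p_waic"),
    row.names = NULL, stringsAsFactors = FALSE)
  comparison <- if (length(waics) == 2L)
    compare_waic(waics[[1L]], waics[[2L]], labels = names(waics)) else NULL
  preferred <- if (!is.null(comparison) && !is.na(comparison$preferred))
    comparison$preferred else names(waics)[which.min(waic_tab$waic)]
  jsonlite::write_json(waic_tab, file.path(config$outdir, "waic.json"),
                       digits = NA)

  # ---- exports from the preferred fit ----
  best <- fits[[preferred]]
  index <- posterior_index(best)
  utils::write.csv(index, file.path(config$outdir, "index.csv"),
                   row.names = FALSE)
  icc_long <- do.call(rbind, lapply(config$items, function(it) {
    provs <- c(best$provinces, if (length(best$provinces) > 1L) "overall")
    do.call(rbind, lapply(provs, function(p)
      as.data.frame(icc_curve(best, it, p))))
  }))
  utils::write.csv(icc_long, file.path(config$outdir, "icc.csv"),
                   row.names = FALSE)

  # ---- outcome analysis ----
  outcome <- NULL
  if ("outcome" %in% names(cc$data) && !all(is.na(cc$data$outcome))) {
    say("outcome analysis (index vs components)")
    ok <- !is.na(cc$data$outcome)
    y <- cc$data$outcome[ok]
    comp <- as.matrix(cc$data[ok, config$items])
    o_mcmc <- mcmc_control(iterations = config$mcmc$iterations,
                           burn_in = config$mcmc$burn_in,
                           thin = config$mcmc$thin, chains = 2L,
                           seed = child_seed(config$mcmc$seed, "outcome-stage"))
    outcome <- stage("outcome",
                     compare_index_vs_components(y, index$theta_mean[ok],
                                                 comp, mcmc = o_mcmc))
    uni <- stage("univariable",
                 univariable_table(y, data.frame(index = index$theta_mean[ok],
                                                 comp), mcmc = o_mcmc))
    uni$analysis <- c("index", rep("univariable", ncol(comp)))
    multi <- outcome$fit_components$or
    multi$analysis <- "multivariable"
    utils::write.csv(rbind(uni, multi),
                     file.path(config$outdir, "outcome_or.csv"),
                     row.names = FALSE)
  }

  report <- structure(list(
    exclusion = exclusion, selection = selection, waic = waic_tab,
    comparison = comparison, preferred = preferred,
    index_file = file.path(config$outdir, "index.csv"),
    outcome = outcome, truth = truth, fits = fits,
    seed = config$mcmc$seed, outdir = config$outdir
  ), class = "run_report")
  jsonlite::write_json(
    list(n_input = exclusion$n_input, n_complete = exclusion$n_complete,
         waic = waic_tab, preferred = preferred, seed = config$mcmc$seed),
    file.path(config$outdir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Deprivation-index pipeline run\n")
  print(x$exclusion)
  cat("WAIC table:\n"); print(x$waic, digits = 1, row.names = FALSE)
  cat(sprintf("Preferred model: %s\n", x$preferred))
  if (!is.null(x$outcome)) print(x$outcome$comparison)
  invisible(x)
}

#' Path to the packaged fictitious sample
#'
#' A synthetic, scaled-down (n = 400) cohort in raw survey form generated
#' from the frozen calibrated configuration; no real participant data.
#'
#' @return file path.
#' @export
fictitious_sample_path <- function() {
  p <- system.file("extdata", "fictitious_cohort_synthetic.csv",
                   package = "deprivindex")
  if (p == "") p <- file.path("inst", "extdata",
                              "fictitious_cohort_synthetic.csv")
  p
}
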