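#' Pipeline configuration
#'
#' Bundles everything a full simulate-measure-model run needs: the cohort
#' spec, the per-index phenotype generators (whose names must be the
#' [geometry_targets()] fields), the geometry perturbation, the morphometry
#' parameters, the model set and the two covariate sets (the age/sex-only
#' "Model 1" and the fully risk-factor-adjusted "Model 2"). All randomness
#' derives from `seed`.
#'
#' @param cohort a [cohort_spec()].
#' @param phenotypes named list of [phenotype_spec()]s for the geometry
#'   target indices.
#' @param noise list with `noise_sd_point`, `noise_sd_radius`,
#'   `spur_probability` (see [perturb_network()]).
#' @param morphometry list of [vessel_morphometry()] parameters.
#' @param models structured model labels to fit.
#' @param model1_covariates,model2_covariates mean-model covariate column
#'   names; model 1 must be a subset of model 2.
#' @param out_dir output directory.
#' @param seed master seed; overrides `cohort$seed`.
#' @param write_networks write one centerline file per subject?
#' @param network_format `"csv"` or `"vtp"`.
#' @param make_plots write the correlation heat map (PNG)?
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            phenotypes = default_phenotype_specs(),
                            noise = list(noise_sd_point = 0.03,
                                         noise_sd_radius = 0.02,
                                         spur_probability = 0.15),
                            morphometry = list(spacing = 0.5,
                                               lambda_pass = 0.5,
                                               mu_pass = -0.53,
                                               smooth_iterations = 20L,
                                               min_branch_length = 3,
                                               dominance_threshold = 0.3),
                            models = c("ACE", "AE", "CE", "E"),
                            model1_covariates = c("age", "sex"),
                            model2_covariates = c("age", "sex", "exercise",
                                                  "alcohol", "smoking",
                                                  "diabetes", "hypertension",
                                                  "dyslipidemia", "height_cm",
                                                  "weight_kg", "bmi"),
                            out_dir = tempfile("vertebrotwin_run_"),
                            seed = 1L,
                            write_networks = TRUE,
                            network_format = c("csv", "vtp"),
                            make_plots = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!all(vapply(phenotypes, inherits, TRUE, "phenotype_spec")))
    stop_named("validation_error", "phenotypes must be phenotype_spec objects")
  tnames <- names(formals(geometry_targets))
  bad <- setdiff(vapply(phenotypes, `[[`, "", "name"), tnames)
  if (length(bad))
    stop_named("validation_error",
               "phenotype names must be geometry target fields; offending: %s",
               paste(bad, collapse = ", "))
  if (!all(model1_covariates %in% model2_covariates))
    stop_named("validation_error", "model 1 covariates must nest in model 2")
  check_scalar(seed, "seed", integer = TRUE)
  network_format <- match.arg(network_format)
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, phenotypes = phenotypes, noise = noise,
                 morphometry = morphometry, models = models,
                 model1_covariates = model1_covariates,
                 model2_covariates = model2_covariates,
                 out_dir = out_dir, seed = as.integer(seed),
                 write_networks = isTRUE(write_networks),
                 network_format = network_format,
                 make_plots = isTRUE(make_plots)),
            class = "pipeline_config")
}

#' Default phenotype generators for the vertebrobasilar indices
#'
#' One [phenotype_spec()] per geometry target, with means and dispersions at
#' the scale of an adult vertebrobasilar system and standardized A/C/E
#' shares taken from the most parsimonious published twin models of these
#' indices (moderate additive-genetic influence on basilar length,
#' shared+unique environment on the diameters and curvatures, unique
#' environment only on the torsions). Covariate effects: smoking on the
#' basilar and left vertebral diameters and height on the basilar diameter,
#' the two effects consistently reported; all other betas zero.
#'
#' @return named list of [phenotype_spec()]s.
#' @export
default_phenotype_specs <- function() {
  mk <- function(name, mean, sd, A, C, E, betas = numeric(0))
    phenotype_spec(name, mean = mean, var_a = A * sd^2, var_c = C * sd^2,
                   var_e = E * sd^2, covariate_betas = betas)
  specs <- list(
    mk("ba_length",          24.08, 4.41, 0.63, 0,     0.37),
    mk("ba_mean_diameter",    3.42, 0.57, 0,    0.354, 0.646,
       betas = c(smoking = 0.212, height_cm = 0.025)),
    mk("ba_bend",             2.57, 2.29, 0,    0.164, 0.836),
    mk("ba_tortuosity",       6.37, 2.20, 0,    0.475, 0.525),
    mk("left_va_diameter",    2.44, 0.72, 0,    0.232, 0.768,
       betas = c(smoking = 0.22)),
    mk("right_va_diameter",   2.36, 0.61, 0,    0.410, 0.590),
    mk("left_va_curvature",   7.79, 2.00, 0,    0.329, 0.671),
    mk("right_va_curvature",  8.10, 2.00, 0.216, 0,    0.784),
    mk("left_va_tortuosity", 11.77, 3.50, 0.476, 0,    0.524),
    mk("right_va_tortuosity", 11.57, 3.50, 0.557, 0,   0.443),
    mk("left_va_torsion",    12.34, 3.80, 0,    0,     1),
    mk("right_va_torsion",   12.62, 3.80, 0,    0,     1))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; anything omitted keeps its
#' default. Phenotypes are given as a map of geometry-target name to
#' `{mean, sd, A, C, E, betas}` where A/C/E are standardized shares applied
#' to `sd^2`.
#'
#' @param path YAML file.
#' @param out_dir,seed optional overrides.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  if (!file.exists(path)) stop_named("io_error", "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  co_args <- y$cohort %||% list()
  for (nm in c("age_mean_by_zygosity", "age_sd_by_zygosity",
               "risk_factor_prevalences", "height_mean_by_sex",
               "height_sd_by_sex"))
    if (!is.null(co_args[[nm]])) co_args[[nm]] <- unlist(co_args[[nm]])
  cohort <- do.call(cohort_spec, co_args)
  phen <- if (is.null(y$phenotypes)) default_phenotype_specs() else {
    specs <- lapply(names(y$phenotypes), function(nm) {
      p <- y$phenotypes[[nm]]
      v <- (p$sd %||% 1)^2
      phenotype_spec(nm, mean = p$mean %||% 0,
                     var_a = (p$A %||% 0) * v, var_c = (p$C %||% 0) * v,
                     var_e = (p$E %||% 1) * v,
                     covariate_betas = unlist(p$betas) %||% numeric(0))
    })
    stats::setNames(specs, names(y$phenotypes))
  }
  args <- list(cohort = cohort, phenotypes = phen)
  for (nm in c("noise", "morphometry"))
    if (!is.null(y[[nm]])) args[[nm]] <- utils::modifyList(
      formals(pipeline_config)[[nm]] |> eval(), y[[nm]])
  for (nm in c("models", "model1_covariates", "model2_covariates",
               "write_networks", "network_format", "make_plots"))
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  args$out_dir <- out_dir %||% y$out_dir %||% tempfile("vertebrotwin_run_")
  args$seed <- as.integer(seed %||% y$seed %||% 1L)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

measured_index_columns <- function() c(
  "ba_length_mm", "ba_equivalent_diameter_mm", "ba_mean_area_mm2",
  "ba_volume_mm3", "ba_bend_mm", "ba_tortuosity_pct", "ba_torsion_index_pct",
  "left_va_equivalent_diameter_mm", "right_va_equivalent_diameter_mm",
  "va_difference_mm", "left_va_curvature_index_pct",
  "right_va_curvature_index_pct", "left_va_tortuosity_pct",
  "right_va_tortuosity_pct", "left_va_torsion_index_pct",
  "right_va_torsion_index_pct")

write_csv_exact <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- fmt_dbl(df[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Pipeline stages
#'
#' Each stage reads the previous stage's files from `config$out_dir`, so any
#' stage can be re-run standalone; outputs are deterministic functions of
#' (config, seed) and re-running a stage reproduces byte-identical CSVs.
#' `pipeline_simulate()` writes the subject table with simulated geometry
#' targets (`cohort.csv`); `pipeline_morphometry()` builds, perturbs,
#' re-identifies and measures one network per subject (`morphometry.csv`,
#' plus per-subject centerline files under `networks/`);
#' `pipeline_heritability()` fits the twin models per measured index and
#' writes the model table (`heritability.csv`), the covariate LRT table
#' (`covariate_lrt.csv`) and the covariate effect table
#' (`covariate_effects.csv`).
#'
#' @param config a [pipeline_config()].
#' @return each stage returns its main data.frame invisibly.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$cohort)
  for (ps in config$phenotypes)
    cohort[[ps$name]] <- simulate_ace_phenotype(cohort, ps,
                                                seed = split_seed(config$seed, ps$name))
  write_csv_exact(cohort, file.path(config$out_dir, "cohort.csv"))
  invisible(cohort)
}

#' @rdname pipeline_simulate
#' @export
pipeline_morphometry <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- utils::read.csv(file.path(config$out_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  tnames <- vapply(config$phenotypes, `[[`, "", "name")
  netdir <- file.path(config$out_dir, "networks")
  if (config$write_networks)
    dir.create(netdir, showWarnings = FALSE, recursive = TRUE)
  mp <- config$morphometry
  records <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    tg <- clamp_geometry_targets(as.list(cohort[i, tnames]))
    sseed <- split_seed(config$seed, "network", i)
    net <- build_vessel_network(tg, seed = sseed)
    pert <- perturb_network(net, config$noise$noise_sd_point,
                            config$noise$noise_sd_radius,
                            config$noise$spur_probability, seed = sseed)
    if (config$write_networks)
      write_network(pert, file.path(netdir, paste0(cohort$subject_id[i], ".",
                                                   config$network_format)),
                    format = config$network_format)
    rec <- vessel_morphometry(pert, spacing = mp$spacing,
                              lambda_pass = mp$lambda_pass,
                              mu_pass = mp$mu_pass,
                              smooth_iterations = mp$smooth_iterations,
                              min_branch_length = mp$min_branch_length,
                              dominance_threshold = mp$dominance_threshold)
    records[[i]] <- cbind(data.frame(subject_id = cohort$subject_id[i],
                                     stringsAsFactors = FALSE), rec)
  }
  morpho <- do.call(rbind, records)
  write_csv_exact(morpho, file.path(config$out_dir, "morphometry.csv"))
  invisible(morpho)
}

#' @rdname pipeline_simulate
#' @export
pipeline_heritability <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- utils::read.csv(file.path(config$out_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  morpho <- utils::read.csv(file.path(config$out_dir, "morphometry.csv"),
                            stringsAsFactors = FALSE)
  dat <- merge(cohort, morpho, by = "subject_id", sort = FALSE)
  dat <- dat[order(match(dat$subject_id, cohort$subject_id)), ]
  idx <- intersect(measured_index_columns(), names(dat))
  ## covariates with no variation in this cohort (possible at small n for
  ## low-prevalence binary factors) cannot enter a mean model
  varying <- function(v) length(unique(dat[[v]])) > 1L
  cov1 <- Filter(varying, config$model1_covariates)
  cov2 <- Filter(varying, config$model2_covariates)
  f1 <- function(v) stats::reformulate(cov1, response = v)
  f2 <- function(v) stats::reformulate(cov2, response = v)
  herit_rows <- list(); lrt_rows <- list(); eff_rows <- list()
  for (v in idx) {
    set1 <- fit_twin_models(f1(v), dat, models = config$models)
    best <- set1$best
    ci <- stats::confint(best)
    pick <- function(tab, cm, col) if (cm %in% rownames(tab)) tab[cm, col] else NA_real_
    sel <- set1$selection
    herit_rows[[v]] <- data.frame(
      phenotype = v, best_model = best$model,
      AIC = stats::AIC(best), BIC = stats::BIC(best),
      A = best$std[["A"]], A_lower = pick(ci, "A", 1), A_upper = pick(ci, "A", 2),
      C = best$std[["C"]], C_lower = pick(ci, "C", 1), C_upper = pick(ci, "C", 2),
      E = best$std[["E"]], E_lower = pick(ci, "E", 1), E_upper = pick(ci, "E", 2),
      rMZ = set1$correlations$r[set1$correlations$zygosity == "MZ"],
      rDZ = set1$correlations$r[set1$correlations$zygosity == "DZ"],
      p_vs_saturated = sel$p_vs_saturated[sel$model == best$model],
      row.names = NULL)
    ## covariate adjustment: full risk-factor model vs age/sex only,
    ## same covariance structure as the best-fitting model. A cohort too
    ## small to support the full design is flagged, not fatal.
    adj <- tryCatch({
      full <- twin_ace(f2(v), dat, model = best$model)
      red <- twin_ace(f1(v), dat, model = best$model)
      lrt <- deviance_lrt(-2 * full$logLik, -2 * red$logLik,
                          df = full$npar - red$npar)
      list(lrt = data.frame(
             phenotype = v, minus2LL_base = -2 * full$logLik,
             minus2LL_reduced = -2 * red$logLik, df = lrt$df,
             chi_square = lrt$chi_square, p_value = lrt$p_value,
             flag = "", row.names = NULL),
           eff = cbind(data.frame(phenotype = v, stringsAsFactors = FALSE),
                       covariate_effects(full)))
    }, vertebrotwin_error = function(e) list(
      lrt = data.frame(phenotype = v, minus2LL_base = NA_real_,
                       minus2LL_reduced = NA_real_, df = NA_real_,
                       chi_square = NA_real_, p_value = NA_real_,
                       flag = conditionMessage(e), row.names = NULL),
      eff = NULL))
    lrt_rows[[v]] <- adj$lrt
    if (!is.null(adj$eff)) eff_rows[[v]] <- adj$eff
  }
  herit <- do.call(rbind, herit_rows)
  write_csv_exact(herit, file.path(config$out_dir, "heritability.csv"))
  write_csv_exact(do.call(rbind, lrt_rows),
                  file.path(config$out_dir, "covariate_lrt.csv"))
  eff_tab <- if (length(eff_rows)) do.call(rbind, eff_rows) else
    data.frame(phenotype = character(0), covariate = character(0),
               estimate = numeric(0), se = numeric(0),
               lower = numeric(0), upper = numeric(0))
  write_csv_exact(eff_tab, file.path(config$out_dir, "covariate_effects.csv"))
  invisible(herit)
}

#' Run the full simulate-measure-model pipeline
#'
#' Executes [pipeline_simulate()], [pipeline_morphometry()] and
#' [pipeline_heritability()], then adds the zygosity-group descriptive
#' comparison and the Spearman correlation matrix of risk factors and
#' measured indices, and writes a run log (resolved seed, versions) to the
#' output directory. The whole bundle is a deterministic function of the
#' configuration and its master seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `report_bundle`: `descriptives`, `heritability`,
#'   `covariate_lrt`, `covariate_effects`, `spearman`, `cohort`,
#'   `morphometry`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  bundle <- tryCatch({
    cohort <- pipeline_simulate(config)
    stage <- "morphometry"
    morpho <- pipeline_morphometry(config)
    stage <- "heritability"
    herit <- pipeline_heritability(config)
    stage <- "reports"
    dat <- merge(cohort, morpho, by = "subject_id", sort = FALSE)
    desc_vars <- c("age", "sex", names(config$cohort$risk_factor_prevalences),
                   "height_cm", "weight_kg", "bmi",
                   intersect(measured_index_columns(), names(dat)))
    desc <- descriptives_compare(dat, variables = desc_vars)
    write_csv_exact(desc, file.path(config$out_dir, "descriptives.csv"))
    sp_vars <- c("age", "bmi", "height_cm", "weight_kg",
                 names(config$cohort$risk_factor_prevalences),
                 intersect(measured_index_columns(), names(dat)))
    sp <- spearman_matrix(dat, sp_vars)
    utils::write.csv(round(sp, 6), file.path(config$out_dir, "spearman.csv"))
    if (config$make_plots) plot_spearman(sp, file.path(config$out_dir, "spearman.png"))
    log <- list(seed = config$seed,
                n_mz_pairs = config$cohort$n_mz_pairs,
                n_dz_pairs = config$cohort$n_dz_pairs,
                models = config$models,
                r_version = as.character(getRversion()),
                package_version = tryCatch(
                  as.character(utils::packageVersion("vertebrotwin")),
                  error = function(e) "dev"),
                timestamp_utc = format(Sys.time(), tz = "UTC"))
    writeLines(yaml::as.yaml(log), file.path(config$out_dir, "run_log.yaml"))
    list(descriptives = desc, heritability = herit,
         covariate_lrt = utils::read.csv(file.path(config$out_dir, "covariate_lrt.csv")),
         covariate_effects = utils::read.csv(file.path(config$out_dir, "covariate_effects.csv")),
         spearman = sp, cohort = cohort, morphometry = morpho,
         out_dir = config$out_dir)
  }, vertebrotwin_error = function(e) {
    stop_named("pipeline_error", "pipeline failed at stage '%s': %s",
               stage, conditionMessage(e))
  })
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle: %d subjects, %d phenotypes, output %s>\n",
              nrow(x$cohort), nrow(x$heritability), x$out_dir))
  invisible(x)
}

#' Zygosity-group descriptive comparison
#'
#' Compares MZ and DZ groups variable by variable: continuous variables by
#' Welch two-sample t-test, binary (or two-level) variables by chi-square
#' test without continuity correction. Pair-level variables (by default age
#' and sex, which are shared within a pair by design) are counted once per
#' pair; everything else is compared at the subject level. Constant
#' variables are skipped with a flag.
#'
#' @param data subject table with `pair_id` and `zygosity` columns.
#' @param variables columns to compare.
#' @param pair_level variables to collapse to one value per pair.
#' @return data.frame with per-group summaries (`mean (sd)` or percent),
#'   test name, statistic and p-value.
#' @export
descriptives_compare <- function(data, variables,
                                 pair_level = c("age", "sex")) {
  for (col in c("pair_id", "zygosity"))
    if (!col %in% names(data))
      stop_named("validation_error", "data lacks column '%s'", col)
  if (!all(c("MZ", "DZ") %in% data$zygosity))
    stop_named("validation_error", "both zygosity groups must be non-empty")
  rows <- lapply(variables, function(v) {
    if (!v %in% names(data))
      stop_named("validation_error", "variable '%s' not in data", v)
    d <- data[, c("pair_id", "zygosity", v)]
    if (v %in% pair_level) d <- d[!duplicated(d$pair_id), ]
    x <- d[[v]]
    g <- factor(d$zygosity, levels = c("MZ", "DZ"))
    is_binary <- is.character(x) || is.factor(x) ||
      (is.numeric(x) && all(x %in% c(0, 1)))
    if (length(unique(x)) < 2L)
      return(data.frame(variable = v, mz = NA_character_, dz = NA_character_,
                        test = NA_character_, statistic = NA_real_,
                        p_value = NA_real_, flag = "constant"))
    if (is_binary) {
      xb <- if (is.numeric(x)) x else as.integer(x == sort(unique(as.character(x)))[1])
      tb <- table(g, xb)
      ct <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
      pct <- tapply(xb, g, mean) * 100
      data.frame(variable = v,
                 mz = sprintf("%.1f%%", pct["MZ"]),
                 dz = sprintf("%.1f%%", pct["DZ"]),
                 test = "chi-square", statistic = unname(ct$statistic),
                 p_value = ct$p.value, flag = "")
    } else {
      tt <- stats::t.test(x ~ g)
      m <- tapply(x, g, mean); s <- tapply(x, g, stats::sd)
      data.frame(variable = v,
                 mz = sprintf("%.2f (%.2f)", m["MZ"], s["MZ"]),
                 dz = sprintf("%.2f (%.2f)", m["DZ"], s["DZ"]),
                 test = "Welch t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, flag = "")
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Spearman rank-correlation matrix
#'
#' Pairwise-complete Spearman correlations with average ranks for ties;
#' symmetric with unit diagonal. Constant variables give `NA` cells.
#'
#' @param data data.frame.
#' @param variables columns to include; character/factor two-level columns
#'   are coded 0/1.
#' @return symmetric correlation matrix.
#' @export
spearman_matrix <- function(data, variables) {
  if (nrow(data) < 3L)
    stop_named("validation_error", "need at least 3 rows")
  m <- sapply(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop_named("validation_error", "variable '%s' not in data", v)
    if (is.character(x) || is.factor(x))
      x <- as.numeric(factor(x)) - 1
    as.numeric(x)
  })
  rho <- suppressWarnings(stats::cor(m, method = "spearman",
                                     use = "pairwise.complete.obs"))
  diag(rho) <- ifelse(apply(m, 2, function(x) length(unique(x[is.finite(x)])) > 1),
                      1, NA_real_)
  rho
}

plot_spearman <- function(rho, path) {
  grDevices::png(path, width = 900, height = 900)
  on.exit(grDevices::dev.off())
  n <- ncol(rho)
  op <- graphics::par(mar = c(10, 10, 2, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(rho[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(41, "Blue-Red 3"))
  graphics::axis(1, seq_len(n), colnames(rho), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(rho)), las = 2, cex.axis = 0.8)
  invisible(path)
}
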