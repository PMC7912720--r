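#' Specification of a synthetic twin cohort
#'
#' Cohort-level parameters of the generator. Defaults reproduce the study
#' conditions of a mid-sized adult twin registry sample: 67 monozygotic and
#' 33 dizygotic same-sex pairs, MZ ages 49.57 (SD 14.42) years and DZ ages
#' 56.0 (SD 15.23), two thirds female, and typical adult prevalences of the
#' recorded cardiovascular risk factors.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts (>= 1).
#' @param age_mean_by_zygosity,age_sd_by_zygosity named numeric
#'   (`c(MZ = , DZ = )`), years; SDs > 0.
#' @param prop_female probability that a pair is female (same-sex design).
#' @param risk_factor_prevalences named fractions for the binary factors
#'   smoking, hypertension, diabetes, dyslipidemia, exercise, alcohol.
#' @param height_mean_by_sex,height_sd_by_sex named numeric (`c(F = , M = )`),
#'   cm.
#' @param bmi_mean,bmi_sd body-mass-index distribution (kg/m^2).
#' @param seed integer master seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 67L, n_dz_pairs = 33L,
                        age_mean_by_zygosity = c(MZ = 49.57, DZ = 56.0),
                        age_sd_by_zygosity = c(MZ = 14.42, DZ = 15.23),
                        prop_female = 0.66,
                        risk_factor_prevalences = c(smoking = 0.27,
                                                    hypertension = 0.305,
                                                    diabetes = 0.085,
                                                    dyslipidemia = 0.245,
                                                    exercise = 0.63,
                                                    alcohol = 0.54),
                        height_mean_by_sex = c(F = 163.5, M = 176.5),
                        height_sd_by_sex = c(F = 6.5, M = 7.0),
                        bmi_mean = 25.74, bmi_sd = 4.59,
                        seed = 1L) {
  check_scalar(n_mz_pairs, "n_mz_pairs", lower = 1, integer = TRUE)
  check_scalar(n_dz_pairs, "n_dz_pairs", lower = 1, integer = TRUE)
  for (z in c("MZ", "DZ")) {
    check_scalar(age_mean_by_zygosity[[z]], paste0("age_mean_by_zygosity[", z, "]"),
                 lower = 0, upper = 120)
    check_scalar(age_sd_by_zygosity[[z]], paste0("age_sd_by_zygosity[", z, "]"),
                 lower = 1e-9)
  }
  check_fraction(prop_female, "prop_female")
  need <- c("smoking", "hypertension", "diabetes", "dyslipidemia",
            "exercise", "alcohol")
  if (!all(need %in% names(risk_factor_prevalences)))
    stop_named("validation_error", "risk_factor_prevalences must name: %s",
               paste(need, collapse = ", "))
  for (nm in need) check_fraction(risk_factor_prevalences[[nm]], nm)
  check_scalar(bmi_mean, "bmi_mean", lower = 10, upper = 60)
  check_scalar(bmi_sd, "bmi_sd", lower = 1e-9)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 age_mean_by_zygosity = age_mean_by_zygosity,
                 age_sd_by_zygosity = age_sd_by_zygosity,
                 prop_female = prop_female,
                 risk_factor_prevalences = risk_factor_prevalences[need],
                 height_mean_by_sex = height_mean_by_sex,
                 height_sd_by_sex = height_sd_by_sex,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a twin cohort subject table
#'
#' Draws pair-level covariates (age, sex — identical within a pair in the
#' same-sex twin design) and subject-level anthropometrics and binary risk
#' factors. Height is sex-conditional Gaussian; BMI is Gaussian (truncated at
#' 15) and weight derived as `bmi * (height/100)^2`, so BMI is consistent
#' with height and weight by construction. Ages are truncated at 18 years.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per subject: `subject_id`, `pair_id`,
#'   `zygosity` ("MZ"/"DZ"), `age`, `sex` ("F"/"M"), the six binary risk
#'   factors (0/1), `height_cm`, `weight_kg`, `bmi`.
#' @examples
#' head(simulate_cohort(cohort_spec(seed = 42)))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_pairs <- spec$n_mz_pairs + spec$n_dz_pairs
  zyg_pair <- rep(c("MZ", "DZ"), c(spec$n_mz_pairs, spec$n_dz_pairs))
  with_seed(split_seed(spec$seed, "cohort"), {
    age_pair <- stats::rnorm(n_pairs,
                             spec$age_mean_by_zygosity[zyg_pair],
                             spec$age_sd_by_zygosity[zyg_pair])
    age_pair <- pmax(age_pair, 18)
    sex_pair <- ifelse(stats::runif(n_pairs) < spec$prop_female, "F", "M")
    n <- 2L * n_pairs
    subj <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      pair_id = sprintf("P%03d", rep(seq_len(n_pairs), each = 2L)),
      zygosity = rep(zyg_pair, each = 2L),
      age = rep(age_pair, each = 2L),
      sex = rep(sex_pair, each = 2L),
      stringsAsFactors = FALSE)
    for (rf in names(spec$risk_factor_prevalences))
      subj[[rf]] <- as.integer(stats::runif(n) < spec$risk_factor_prevalences[[rf]])
    subj$height_cm <- stats::rnorm(n, spec$height_mean_by_sex[subj$sex],
                                   spec$height_sd_by_sex[subj$sex])
    subj$bmi <- pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), 15)
    subj$weight_kg <- subj$bmi * (subj$height_cm / 100)^2
    subj
  })
}

#' Specification of one ACE-structured phenotype
#'
#' Describes how a phenotype is generated: an overall mean, raw
#' additive-genetic (`var_a`), shared-environment (`var_c`) and unique-
#' environment (`var_e`) variance components, and optional linear covariate
#' effects on the mean.
#'
#' @param name phenotype (column) name.
#' @param mean intercept in phenotype units.
#' @param var_a,var_c,var_e non-negative variance components; their sum must
#'   be positive.
#' @param covariate_betas named numeric vector of slopes (phenotype units per
#'   covariate unit); `sex` is coded 0 = F, 1 = M.
#' @return list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, mean = 0, var_a = 0, var_c = 0, var_e = 1,
                           covariate_betas = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1L)
  check_scalar(mean, "mean")
  check_scalar(var_a, "var_a", lower = 0)
  check_scalar(var_c, "var_c", lower = 0)
  check_scalar(var_e, "var_e", lower = 0)
  if (var_a + var_c + var_e <= 0)
    stop_named("validation_error", "total variance of '%s' must be > 0", name)
  if (length(covariate_betas) && is.null(names(covariate_betas)))
    stop_named("validation_error", "covariate_betas must be named")
  structure(list(name = name, mean = mean, var_a = var_a, var_c = var_c,
                 var_e = var_e, covariate_betas = covariate_betas),
            class = "phenotype_spec")
}

#' Simulate an ACE-structured phenotype on a twin cohort
#'
#' The phenotype of subject j in pair i is
#' `mean + sum(beta * x_ij) + A_ij + C_i + E_ij` with `C_i ~ N(0, var_c)`
#' shared within the pair, `E_ij ~ N(0, var_e)` independent, and the
#' additive-genetic deviate `A_ij ~ N(0, var_a)` identical within MZ pairs
#' and correlated 0.5 within DZ pairs (built as
#' `sqrt(0.5) * shared + sqrt(0.5) * unique` standard-normal parts scaled by
#' `sqrt(var_a)`), the classical-twin covariance structure under random
#' mating with no dominance.
#'
#' @param cohort subject table from [simulate_cohort()] (or any data.frame
#'   with `pair_id`, `zygosity` and the covariates named in the spec).
#' @param pheno a [phenotype_spec()].
#' @param seed integer seed.
#' @return numeric vector, one value per cohort row.
#' @export
simulate_ace_phenotype <- function(cohort, pheno, seed = 1L) {
  stopifnot(inherits(pheno, "phenotype_spec"))
  for (col in c("pair_id", "zygosity"))
    if (!col %in% names(cohort))
      stop_named("validation_error", "cohort lacks column '%s'", col)
  miss <- setdiff(names(pheno$covariate_betas), names(cohort))
  if (length(miss))
    stop_named("missing_covariate_error",
               "cohort lacks covariate column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(cohort)
  pair_f <- factor(cohort$pair_id, levels = unique(cohort$pair_id))
  pair_idx <- as.integer(pair_f)
  n_pairs <- nlevels(pair_f)
  zyg_pair <- cohort$zygosity[!duplicated(pair_idx)]
  with_seed(split_seed(seed, paste0("pheno_", pheno$name)), {
    a_shared <- stats::rnorm(n_pairs)[pair_idx]
    a_unique <- stats::rnorm(n)
    w <- ifelse(cohort$zygosity == "MZ", 1, sqrt(0.5))
    a_std <- w * a_shared + sqrt(1 - w^2) * a_unique
    c_comp <- sqrt(pheno$var_c) * stats::rnorm(n_pairs)[pair_idx]
    e_comp <- sqrt(pheno$var_e) * stats::rnorm(n)
    y <- pheno$mean + sqrt(pheno$var_a) * a_std + c_comp + e_comp
    for (nm in names(pheno$covariate_betas)) {
      x <- cohort[[nm]]
      if (nm == "sex" || is.character(x) || is.factor(x))
        x <- as.numeric(as.character(x) == "M")
      y <- y + pheno$covariate_betas[[nm]] * as.numeric(x)
    }
    y
  })
}
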