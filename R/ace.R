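#' Maximum-likelihood variance-component models for twin pairs
#'
#' Fits the classical twin-design structural equation models by full-information
#' maximum likelihood on bivariate-normal pair likelihoods. The phenotypic
#' variance is decomposed into additive-genetic (A), shared-environment (C)
#' and unique-environment (E) components through the differing MZ/DZ
#' covariance structure: both zygosity groups share the total variance
#' \eqn{\sigma^2 = a^2 + c^2 + e^2}, while the within-pair covariance is
#' \eqn{a^2 + c^2} for MZ pairs and \eqn{0.5 a^2 + c^2} for DZ pairs
#' (MZ twins share all, DZ on average half of their segregating genes; both
#' share their common environment). Sub-models (AE, CE, E) fix the excluded
#' components at zero; `"saturated"` frees, per zygosity group, both
#' within-order variances and the covariance (6 covariance parameters,
#' order-symmetric means) as the goodness-of-fit reference.
#'
#' Mean-model covariates enter both twins' means with common coefficients;
#' given the covariance parameters the coefficients are profiled out by
#' generalised least squares, and the remaining (path-coefficient)
#' parameters are maximised by multi-start quasi-Newton iterations, started
#' from Falconer estimates (\eqn{A = 2(r_{MZ} - r_{DZ})},
#' \eqn{C = 2 r_{DZ} - r_{MZ}}, clipped to be non-negative) plus jittered
#' restarts. Non-negativity of the variance components is enforced by
#' optimising unconstrained path coefficients whose squares are the
#' components; \eqn{e^2} carries a floor of `1e-8` times the phenotypic
#' variance so the pair covariance matrix stays positive definite.
#'
#' @param formula model formula, `phenotype ~ covariates` (use `~ 1` for no
#'   covariates).
#' @param data subject-level data.frame, one row per twin.
#' @param pair,zygosity names of the pair-identifier and zygosity columns;
#'   zygosity values must be `"MZ"`/`"DZ"`.
#' @param model one of `"ACE"`, `"AE"`, `"CE"`, `"E"`, `"saturated"`.
#' @param n_starts number of optimizer starts (1 Falconer + jittered).
#' @return An object of class `twin_ace` with (among others) elements
#'   `varcomp` (raw a2/c2/e2), `std` (standardized A/C/E shares summing to
#'   1), `coefficients` (mean model), `logLik`, `npar`, `implied_r`
#'   (model-implied rMZ/rDZ), `n_pairs`, `n_dropped` (incomplete pairs
#'   excluded). Methods: [print.twin_ace()], [summary.twin_ace()],
#'   [confint.twin_ace()] (profile-likelihood CIs), `coef`, `logLik`,
#'   `vcov`, `anova` (likelihood-ratio tests), `residuals`, `fitted`,
#'   `predict`, `simulate`.
#' @examples
#' co <- simulate_cohort(cohort_spec(seed = 1))
#' co$y <- simulate_ace_phenotype(co, phenotype_spec("y", mean = 24,
#'   var_a = 12, var_e = 7, covariate_betas = c(age = 0.05)), seed = 2)
#' fit <- twin_ace(y ~ age + sex, co, model = "AE")
#' fit
#' @export
twin_ace <- function(formula, data, pair = "pair_id", zygosity = "zygosity",
                     model = c("ACE", "AE", "CE", "E", "saturated"),
                     n_starts = 5L) {
  model <- match.arg(model)
  pd <- build_pair_data(formula, data, pair, zygosity)
  fit <- if (model == "saturated") fit_saturated_ml(pd) else
    fit_structured_ml(pd, model, n_starts = n_starts)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

## ---- pair data + sufficient statistics ------------------------------------

build_pair_data <- function(formula, data, pair, zygosity) {
  for (col in c(pair, zygosity))
    if (!col %in% names(data))
      stop_named("validation_error", "data lacks column '%s'", col)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  pid <- as.character(data[[pair]])
  zyg <- as.character(data[[zygosity]])
  if (!all(zyg[!is.na(zyg)] %in% c("MZ", "DZ")))
    stop_named("validation_error", "zygosity must be 'MZ' or 'DZ'")
  keep_pair <- names(which(tapply(ok, pid, function(v) length(v) == 2L && all(v))))
  n_dropped <- length(unique(pid)) - length(keep_pair)
  sel <- pid %in% keep_pair
  y <- y[sel]; X <- X[sel, , drop = FALSE]; pid <- pid[sel]; zyg <- zyg[sel]
  ord <- order(match(pid, unique(pid)))
  y <- y[ord]; X <- X[ord, , drop = FALSE]; pid <- pid[ord]; zyg <- zyg[ord]
  i1 <- seq(1, length(y), by = 2); i2 <- i1 + 1L
  if (any(pid[i1] != pid[i2]))
    stop_named("validation_error", "pair ids do not come in complete pairs")
  zp <- zyg[i1]
  if (sum(zp == "MZ") < 2 || sum(zp == "DZ") < 2)
    stop_named("validation_error", "need at least 2 complete pairs per zygosity group")
  ## rank check on the pooled design (collinear covariates are an error,
  ## not something to silently absorb)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_named("collinearity_error", "mean-model covariates are collinear: %s",
               paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  suff <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    j <- which(zp == z)
    X1 <- X[i1[j], , drop = FALSE]; X2 <- X[i2[j], , drop = FALSE]
    y1 <- y[i1[j]]; y2 <- y[i2[j]]
    list(n = length(j),
         S11 = sum(y1 * y1), S22 = sum(y2 * y2), S12 = sum(y1 * y2),
         X1X1 = crossprod(X1), X2X2 = crossprod(X2), X1X2 = crossprod(X1, X2),
         X1y1 = crossprod(X1, y1), X2y2 = crossprod(X2, y2),
         X1y2 = crossprod(X1, y2), X2y1 = crossprod(X2, y1))
  })
  list(y1 = y[i1], y2 = y[i2], X1 = X[i1, , drop = FALSE],
       X2 = X[i2, , drop = FALSE], zyg = zp, pair_id = pid[i1],
       p = ncol(X), coef_names = colnames(X), suff = suff,
       n_dropped = n_dropped, var_y = stats::var(y), terms = stats::terms(formula))
}

## log-likelihood + GLS mean profile for a given covariance parametrisation;
## cov_z: list per zygosity with elements a11, a22, b (inverse entries) and
## logdet — everything reduces to the stored sufficient statistics
pair_gls_loglik <- function(pd, inv) {
  p <- pd$p
  XtOX <- matrix(0, p, p); XtOy <- numeric(p)
  for (z in c("MZ", "DZ")) {
    s <- pd$suff[[z]]; iv <- inv[[z]]
    XtOX <- XtOX + iv$a11 * s$X1X1 + iv$a22 * s$X2X2 +
      iv$b * (s$X1X2 + t(s$X1X2))
    XtOy <- XtOy + iv$a11 * s$X1y1 + iv$a22 * s$X2y2 +
      iv$b * (s$X1y2 + s$X2y1)
  }
  beta <- tryCatch(solve(XtOX, XtOy), error = function(e)
    stop_named("collinearity_error", "GLS normal equations are singular"))
  ll <- 0
  for (z in c("MZ", "DZ")) {
    s <- pd$suff[[z]]; iv <- inv[[z]]
    Q11 <- s$S11 - 2 * sum(beta * s$X1y1) + drop(crossprod(beta, s$X1X1 %*% beta))
    Q22 <- s$S22 - 2 * sum(beta * s$X2y2) + drop(crossprod(beta, s$X2X2 %*% beta))
    Q12 <- s$S12 - sum(beta * (s$X1y2 + s$X2y1)) +
      drop(crossprod(beta, s$X1X2 %*% beta))
    ll <- ll - s$n * log(2 * pi) - 0.5 * s$n * iv$logdet -
      0.5 * (iv$a11 * Q11 + iv$a22 * Q22 + 2 * iv$b * Q12)
  }
  list(loglik = ll, beta = beta, XtOX = XtOX)
}

inv_structured <- function(a2, c2, e2, floor_e) {
  e2f <- e2 + floor_e
  s2 <- a2 + c2 + e2f
  lapply(c(MZ = 1, DZ = 0.5), function(w) {
    cz <- w * a2 + c2
    det <- s2^2 - cz^2
    if (!is.finite(det) || det <= 0 || !is.finite(s2) || s2 <= 0) return(NULL)
    list(a11 = s2 / det, a22 = s2 / det, b = -cz / det, logdet = log(det))
  })
}

structured_loglik <- function(pd, a2, c2, e2, floor_e) {
  inv <- inv_structured(a2, c2, e2, floor_e)
  if (any(vapply(inv, is.null, TRUE))) return(list(loglik = -Inf))
  pair_gls_loglik(pd, inv)
}

## Falconer method-of-moments start on OLS residuals
falconer_start <- function(pd) {
  beta0 <- stats::coef(stats::lm.fit(rbind(pd$X1, pd$X2), c(pd$y1, pd$y2)))
  r1 <- pd$y1 - drop(pd$X1 %*% beta0)
  r2 <- pd$y2 - drop(pd$X2 %*% beta0)
  v <- stats::var(c(r1, r2))
  rz <- vapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    j <- pd$zyg == z
    suppressWarnings(stats::cor(c(r1[j], r2[j]), c(r2[j], r1[j])))
  }, 1)
  rz[!is.finite(rz)] <- 0
  A <- min(max(2 * (rz["MZ"] - rz["DZ"]), 0), 0.9)
  C <- min(max(2 * rz["DZ"] - rz["MZ"], 0), 0.9 - A)
  E <- max(1 - A - C, 0.05)
  v * c(A = unname(A), C = unname(C), E = unname(E)) / (A + C + E)
}

fit_structured_ml <- function(pd, model, n_starts = 5L) {
  free <- switch(model,
                 ACE = c("a", "c", "e"), AE = c("a", "e"),
                 CE = c("c", "e"), E = "e")
  floor_e <- 1e-8 * pd$var_y
  objective <- function(par) {
    th <- stats::setNames(numeric(3), c("a", "c", "e"))
    th[free] <- par
    ## an ill-conditioned GLS system at extreme covariance parameters is a
    ## bad region of the parameter space, not a user error
    res <- tryCatch(structured_loglik(pd, th["a"]^2, th["c"]^2, th["e"]^2, floor_e),
                    vertebrotwin_error = function(e) list(loglik = -Inf))
    if (!is.finite(res$loglik)) return(1e10)
    -res$loglik
  }
  st <- falconer_start(pd)
  base <- sqrt(c(a = st[["A"]], c = st[["C"]], e = st[["E"]]))
  starts <- list(base[free])
  with_seed(split_seed(1L, paste0("starts_", model)), {
    for (k in seq_len(max(0L, n_starts - 1L)))
      starts[[k + 1L]] <- base[free] * stats::runif(length(free), 0.4, 1.8) +
        stats::rnorm(length(free), 0, 0.05 * sqrt(pd$var_y))
  })
  best <- NULL
  for (s0 in starts) {
    opt <- try(stats::optim(s0, objective, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_named("convergence_error",
               "all optimizer starts failed for the %s model", model)
  th <- stats::setNames(numeric(3), c("a", "c", "e"))
  th[free] <- best$par
  vc <- c(a2 = unname(th["a"]^2), c2 = unname(th["c"]^2), e2 = unname(th["e"]^2))
  res <- structured_loglik(pd, vc[["a2"]], vc[["c2"]], vc[["e2"]], floor_e)
  s2 <- sum(vc) + floor_e
  std <- c(A = unname(vc["a2"]), C = unname(vc["c2"]),
           E = unname(vc["e2"] + floor_e)) / s2
  npar <- length(free) + pd$p
  N <- 2L * length(pd$y1)
  structure(list(
    model = model, varcomp = vc, std = std, sigma2 = s2,
    coefficients = stats::setNames(drop(res$beta), pd$coef_names),
    logLik = unname(res$loglik), npar = npar, n_subjects = N,
    n_pairs = c(MZ = pd$suff$MZ$n, DZ = pd$suff$DZ$n),
    n_dropped = pd$n_dropped,
    implied_r = c(rMZ = unname((vc["a2"] + vc["c2"]) / s2),
                  rDZ = unname((0.5 * vc["a2"] + vc["c2"]) / s2)),
    beta_vcov = solve(res$XtOX),
    floor_e = floor_e, pair_data = pd,
    convergence = best$convergence), class = "twin_ace")
}

fit_saturated_ml <- function(pd) {
  objective <- function(par) {
    inv <- list()
    for (k in 1:2) {
      v1 <- exp(par[3 * k - 2]); v2 <- exp(par[3 * k - 1])
      rho <- tanh(par[3 * k])
      cz <- rho * sqrt(v1 * v2)
      det <- v1 * v2 - cz^2
      if (!is.finite(det) || det <= 0) return(1e10)
      inv[[k]] <- list(a11 = v2 / det, a22 = v1 / det, b = -cz / det,
                       logdet = log(det))
    }
    names(inv) <- c("MZ", "DZ")
    ll <- tryCatch(pair_gls_loglik(pd, inv)$loglik,
                   vertebrotwin_error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- unlist(lapply(c("MZ", "DZ"), function(z) {
    j <- pd$zyg == z
    c(log(stats::var(pd$y1[j])), log(stats::var(pd$y2[j])),
      atanh(min(max(suppressWarnings(stats::cor(pd$y1[j], pd$y2[j])), -0.95), 0.95)))
  }))
  start[!is.finite(start)] <- 0
  opt <- stats::optim(start, objective, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  par <- opt$par
  grp <- lapply(1:2, function(k) {
    v1 <- exp(par[3 * k - 2]); v2 <- exp(par[3 * k - 1])
    ## tiny groups can push the ML correlation onto the +/-1 boundary;
    ## keep the fitted covariance matrix invertible
    rho <- min(max(tanh(par[3 * k]), -1 + 1e-9), 1 - 1e-9)
    c(var1 = v1, var2 = v2, cov = rho * sqrt(v1 * v2), r = rho)
  })
  names(grp) <- c("MZ", "DZ")
  inv <- lapply(grp, function(g) {
    det <- g[["var1"]] * g[["var2"]] - g[["cov"]]^2
    list(a11 = g[["var2"]] / det, a22 = g[["var1"]] / det,
         b = -g[["cov"]] / det, logdet = log(det))
  })
  res <- pair_gls_loglik(pd, inv)
  structure(list(
    model = "saturated", sat_par = grp,
    varcomp = c(a2 = NA_real_, c2 = NA_real_, e2 = NA_real_),
    std = c(A = NA_real_, C = NA_real_, E = NA_real_),
    sigma2 = mean(c(grp$MZ[c("var1", "var2")], grp$DZ[c("var1", "var2")])),
    coefficients = stats::setNames(drop(res$beta), pd$coef_names),
    logLik = res$loglik, npar = 6L + pd$p,
    n_subjects = 2L * length(pd$y1),
    n_pairs = c(MZ = pd$suff$MZ$n, DZ = pd$suff$DZ$n),
    n_dropped = pd$n_dropped,
    implied_r = c(rMZ = unname(grp$MZ[["r"]]), rDZ = unname(grp$DZ[["r"]])),
    beta_vcov = solve(res$XtOX),
    floor_e = 0, pair_data = pd,
    convergence = opt$convergence), class = "twin_ace")
}

## ---- S3 methods ------------------------------------------------------------

#' @export
print.twin_ace <- function(x, digits = 3, ...) {
  cat(sprintf("Twin %s model: %s\n", x$model, deparse(x$formula)))
  cat(sprintf("  %d MZ + %d DZ complete pairs (%d incomplete pairs dropped)\n",
              x$n_pairs["MZ"], x$n_pairs["DZ"], x$n_dropped))
  if (x$model != "saturated") {
    cat("  standardized components:\n")
    print(round(x$std, digits))
  } else {
    cat(sprintf("  saturated: rMZ = %.3f, rDZ = %.3f\n",
                x$implied_r["rMZ"], x$implied_r["rDZ"]))
  }
  cat(sprintf("  logLik %.3f  AIC %.3f  BIC %.3f\n",
              x$logLik, stats::AIC(x), stats::BIC(x)))
  invisible(x)
}

#' @export
logLik.twin_ace <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
coef.twin_ace <- function(object, ...) object$coefficients

#' @export
vcov.twin_ace <- function(object, ...) object$beta_vcov

#' @export
nobs.twin_ace <- function(object, ...) object$n_subjects

#' @export
fitted.twin_ace <- function(object, ...) {
  pd <- object$pair_data
  cbind(twin1 = drop(pd$X1 %*% object$coefficients),
        twin2 = drop(pd$X2 %*% object$coefficients))
}

#' @export
residuals.twin_ace <- function(object, ...) {
  pd <- object$pair_data
  f <- fitted(object)
  cbind(twin1 = pd$y1 - f[, 1], twin2 = pd$y2 - f[, 2])
}

#' @export
predict.twin_ace <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  X <- stats::model.matrix(stats::delete.response(object$pair_data$terms), newdata)
  drop(X %*% object$coefficients)
}

#' @export
simulate.twin_ace <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pd <- object$pair_data
  f <- fitted(object)
  covs <- if (object$model == "saturated") {
    lapply(object$sat_par, function(g)
      matrix(c(g[["var1"]], g[["cov"]], g[["cov"]], g[["var2"]]), 2))
  } else {
    vc <- object$varcomp; s2 <- object$sigma2
    lapply(c(MZ = 1, DZ = 0.5), function(w) {
      cz <- w * vc[["a2"]] + vc[["c2"]]
      matrix(c(s2, cz, cz, s2), 2)
    })
  }
  chols <- lapply(covs, chol)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    zmat <- matrix(stats::rnorm(2 * length(pd$y1)), ncol = 2)
    y <- matrix(NA_real_, length(pd$y1), 2)
    for (z in c("MZ", "DZ")) {
      j <- pd$zyg == z
      y[j, ] <- zmat[j, , drop = FALSE] %*% chols[[z]]
    }
    out[[s]] <- f + y
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
summary.twin_ace <- function(object, conf_level = 0.95, profile = TRUE, ...) {
  se <- sqrt(diag(object$beta_vcov))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 z = object$coefficients / se,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)),
                 lower = object$coefficients - zq * se,
                 upper = object$coefficients + zq * se)
  comp <- NULL
  if (object$model != "saturated") {
    comp <- data.frame(estimate = object$std)
    if (profile) {
      ci <- stats::confint(object, level = conf_level)
      comp$lower <- ci[, 1]; comp$upper <- ci[, 2]
    }
  }
  structure(list(fit = object, coefficients = coefs, components = comp,
                 conf_level = conf_level),
            class = "summary.twin_ace")
}

#' @export
print.summary.twin_ace <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$components)) {
    cat(sprintf("\nStandardized components (%g%% profile CI):\n",
                100 * x$conf_level))
    print(round(as.matrix(x$components), digits))
  }
  cat("\nMean model:\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = digits)
  invisible(x)
}

#' Profile-likelihood confidence intervals for standardized components
#'
#' For a component share t (A, C or E on the standardized scale) the profile
#' log-likelihood re-maximises over the total variance, the split of the
#' remaining components and the mean coefficients with the share held fixed;
#' the interval is the set where twice the profile deviance stays below the
#' chi-square(1) quantile. Bounds are truncated to \\[0, 1\\] — an estimate on
#' the zero boundary yields a lower bound of exactly 0.
#'
#' @param object a fitted [twin_ace()] model (not saturated).
#' @param parm components to profile, subset of `c("A", "C", "E")` present in
#'   the model.
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with one row per component, columns `lower`, `upper`.
#' @export
confint.twin_ace <- function(object, parm, level = 0.95, ...) {
  if (object$model == "saturated")
    stop_named("validation_error", "profile CIs apply to structured models only")
  present <- switch(object$model, ACE = c("A", "C", "E"), AE = c("A", "E"),
                    CE = c("C", "E"), E = "E")
  if (missing(parm)) parm <- present
  parm <- match.arg(parm, present, several.ok = TRUE)
  crit <- stats::qchisq(level, df = 1)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (cm in parm) out[cm, ] <- profile_component_ci(object, cm, crit)
  out
}

## profile log-likelihood of the model with the standardized share of
## `component` fixed at t; remaining freedom: total variance sigma2 and
## (for three-component models) the split u of the complement
profile_loglik <- function(object, component, t) {
  pd <- object$pair_data
  model <- object$model
  floor_e <- object$floor_e
  others <- setdiff(switch(model, ACE = c("A", "C", "E"), AE = c("A", "E"),
                           CE = c("C", "E"), E = "E"), component)
  comp_of <- function(shares, s2) {
    g <- function(nm) if (nm %in% names(shares)) shares[[nm]] * s2 else 0
    tryCatch(structured_loglik(pd, g("A"), g("C"), g("E"), floor_e)$loglik,
             vertebrotwin_error = function(e) -Inf)
  }
  neg <- function(par) {
    s2 <- exp(par[1])
    shares <- stats::setNames(numeric(0), character(0))
    shares[component] <- t
    if (length(others) == 2L) {
      u <- stats::plogis(par[2])
      shares[others] <- (1 - t) * c(u, 1 - u)
    } else if (length(others) == 1L) {
      shares[others] <- 1 - t
    }
    ll <- comp_of(as.list(shares), s2)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  s2_0 <- max(object$sigma2, 1e-12)
  start <- log(s2_0)
  if (length(others) == 2L) {
    o1 <- object$std[[others[1]]]; o2 <- object$std[[others[2]]]
    u0 <- if (o1 + o2 > 0) o1 / (o1 + o2) else 0.5
    start <- c(start, stats::qlogis(min(max(u0, 1e-6), 1 - 1e-6)))
  }
  opt <- stats::optim(start, neg, method = if (length(start) == 1L) "Brent" else "BFGS",
                      lower = if (length(start) == 1L) start - 20 else -Inf,
                      upper = if (length(start) == 1L) start + 20 else Inf,
                      control = list(reltol = 1e-12))
  -opt$value
}

profile_component_ci <- function(object, component, crit) {
  if (object$model == "E") return(c(1, 1))   # single component: share fixed at 1
  t_hat <- object$std[[component]]
  ll_max <- object$logLik
  dev <- function(t) 2 * (ll_max - profile_loglik(object, component, t)) - crit
  lower <- if (t_hat <= 1e-8) 0 else {
    d0 <- dev(0)
    if (d0 <= 0) 0 else
      stats::uniroot(dev, c(0, t_hat), tol = 1e-5, f.lower = d0,
                     f.upper = -crit)$root
  }
  upper <- if (t_hat >= 1 - 1e-8) 1 else {
    d1 <- dev(1)
    if (d1 <= 0) 1 else
      stats::uniroot(dev, c(t_hat, 1), tol = 1e-5, f.lower = -crit,
                     f.upper = d1)$root
  }
  c(lower, upper)
}

#' Likelihood-ratio tests between nested twin models
#'
#' Compares two or more fits on the same data by the likelihood-ratio
#' chi-square on the deviance difference, with degrees of freedom equal to
#' the difference in free-parameter counts. Covers both covariance-structure
#' nesting (e.g. AE vs ACE vs saturated) and mean-model nesting (a fit whose
#' covariates are a subset of another's, as in risk-factor adjustment
#' testing).
#'
#' @param object,... two or more `twin_ace` fits, any order.
#' @return data.frame of class `anova` with `-2LL`, df, chi-square and
#'   p-value rows.
#' @export
anova.twin_ace <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2L)
    stop_named("validation_error", "anova needs at least two twin_ace fits")
  ord <- order(vapply(fits, function(f) f$npar, 1))
  fits <- fits[ord]
  labs <- make.unique(vapply(fits, function(f) f$model, ""))
  tab <- data.frame(npar = vapply(fits, function(f) f$npar, 1),
                    minus2LL = vapply(fits, function(f) -2 * f$logLik, 1),
                    df = NA_real_, chisq = NA_real_, p_value = NA_real_,
                    row.names = labs)
  for (k in 2:length(fits)) {
    chi <- tab$minus2LL[k - 1] - tab$minus2LL[k]
    df <- tab$npar[k] - tab$npar[k - 1]
    if (chi < -1e-6)
      stop_named("nesting_error",
                 "larger model fits worse (chi-square %.4g < 0); models are not nested",
                 chi)
    chi <- max(chi, 0)
    tab$df[k] <- df
    tab$chisq[k] <- chi
    tab$p_value[k] <- stats::pchisq(chi, df, lower.tail = FALSE)
  }
  class(tab) <- c("anova", "data.frame")
  attr(tab, "heading") <- "Likelihood-ratio tests"
  tab
}

#' Likelihood-ratio test from printed deviances
#'
#' Computes the chi-square test for nested models directly from their
#' deviances (-2 log-likelihoods), as reported in covariate-adjustment
#' tables: the test statistic is `deviance_reduced - deviance_base` on
#' `df` degrees of freedom.
#'
#' @param deviance_base -2LL of the larger model (all covariates).
#' @param deviance_reduced -2LL of the reduced model.
#' @param df number of dropped parameters.
#' @return list with `chi_square`, `df`, `p_value`.
#' @examples
#' deviance_lrt(1144.393, 1165.349, df = 9)  # p ~ 0.013
#' @export
deviance_lrt <- function(deviance_base, deviance_reduced, df) {
  check_scalar(deviance_base, "deviance_base", finite = TRUE)
  check_scalar(deviance_reduced, "deviance_reduced", finite = TRUE)
  check_scalar(df, "df", lower = 1, integer = TRUE)
  chi <- deviance_reduced - deviance_base
  if (chi < -1e-6)
    stop_named("nesting_error", "reduced model has smaller deviance; not nested")
  chi <- max(chi, 0)
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Covariate effects with Wald confidence intervals
#'
#' @param fit a converged [twin_ace()] fit.
#' @param names covariate (design-column) names; default all but the
#'   intercept.
#' @param level confidence level.
#' @return data.frame with estimate, standard error and Wald interval per
#'   covariate.
#' @export
covariate_effects <- function(fit, names = NULL, level = 0.95) {
  stopifnot(inherits(fit, "twin_ace"))
  all_nm <- base::names(fit$coefficients)
  if (is.null(names)) names <- setdiff(all_nm, "(Intercept)")
  bad <- setdiff(names, all_nm)
  if (length(bad))
    stop_named("validation_error", "covariate(s) not in the model: %s",
               paste(bad, collapse = ", "))
  se <- sqrt(diag(fit$beta_vcov))[names]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients[names]
  data.frame(covariate = names, estimate = unname(est), se = unname(se),
             lower = unname(est - zq * se), upper = unname(est + zq * se),
             row.names = NULL)
}

#' Fit and compare the standard twin model set
#'
#' Convenience wrapper: fits the saturated reference plus the requested
#' structured models on identical data, compares each structured model to the
#' saturated one by LRT and selects the best structured fit by AIC.
#'
#' @inheritParams twin_ace
#' @param models structured models to fit.
#' @return list of class `twin_ace_set`: `fits` (named list including
#'   `saturated`), `selection` (model comparison table), `best` (AIC-optimal
#'   structured fit), `correlations` (intrapair correlations).
#' @export
fit_twin_models <- function(formula, data, pair = "pair_id",
                            zygosity = "zygosity",
                            models = c("ACE", "AE", "CE", "E")) {
  fits <- lapply(stats::setNames(models, models), function(m)
    twin_ace(formula, data, pair, zygosity, model = m))
  sat <- twin_ace(formula, data, pair, zygosity, model = "saturated")
  tab <- data.frame(
    model = models,
    AIC = vapply(fits, stats::AIC, 1),
    BIC = vapply(fits, stats::BIC, 1),
    logLik = vapply(fits, function(f) f$logLik, 1),
    npar = vapply(fits, function(f) f$npar, 1),
    A = vapply(fits, function(f) f$std[["A"]], 1),
    C = vapply(fits, function(f) f$std[["C"]], 1),
    E = vapply(fits, function(f) f$std[["E"]], 1),
    p_vs_saturated = vapply(fits, function(f) {
      chi <- max(0, 2 * (sat$logLik - f$logLik))
      stats::pchisq(chi, sat$npar - f$npar, lower.tail = FALSE)
    }, 1),
    row.names = NULL)
  best <- select_model(fits)
  structure(list(fits = c(fits, list(saturated = sat)), selection = tab,
                 best = best,
                 correlations = intrapair_correlation(formula, data, pair, zygosity)),
            class = "twin_ace_set")
}

#' @export
print.twin_ace_set <- function(x, digits = 3, ...) {
  cat("Twin variance-component model comparison\n")
  print(cbind(x$selection[, "model", drop = FALSE],
              round(x$selection[, -1], digits)))
  cat(sprintf("best by AIC: %s\n", x$best$model))
  invisible(x)
}

#' Select the best-fitting model by information criteria
#'
#' Minimal AIC wins; ties are broken by minimal BIC, then by fewer free
#' parameters. Accepts either a list of [twin_ace()] fits or a data.frame
#' with columns `model`, `AIC` and optionally `BIC`/`npar` (so selection can
#' be replayed from a printed model table).
#'
#' @param fits list of fits or data.frame.
#' @return the selected fit (for a list) or model label (for a data.frame).
#' @examples
#' select_model(data.frame(model = c("ACE", "AE", "CE"),
#'                         AIC = c(1179.85, 1177.11, 1182.74)))  # "AE"
#' @export
select_model <- function(fits) {
  if (is.data.frame(fits)) {
    if (!all(c("model", "AIC") %in% names(fits)) || nrow(fits) == 0L)
      stop_named("validation_error", "need a non-empty table with model and AIC")
    tab <- fits
    tab$BIC <- if ("BIC" %in% names(tab)) tab$BIC else 0
    tab$npar <- if ("npar" %in% names(tab)) tab$npar else 0
    ord <- order(tab$AIC, tab$BIC, tab$npar)
    return(tab$model[ord[1]])
  }
  if (!length(fits))
    stop_named("validation_error", "empty fit list")
  aic <- vapply(fits, stats::AIC, 1)
  bic <- vapply(fits, stats::BIC, 1)
  np <- vapply(fits, function(f) f$npar, 1)
  fits[[order(aic, bic, np)[1]]]
}

#' Intrapair (intraclass) correlations by zygosity
#'
#' One-way ANOVA intraclass correlation of the two members of each pair,
#' computed per zygosity group on the residuals of an ordinary
#' least-squares adjustment for the formula covariates (age and sex in the
#' standard design): `ICC = (MSB - MSW) / (MSB + MSW)` with pairs as groups.
#' Confidence intervals use the Fisher z transform with effective n equal to
#' the pair count.
#'
#' @inheritParams twin_ace
#' @param level confidence level.
#' @return data.frame with one row per zygosity: `r`, `lower`, `upper`,
#'   `n_pairs`, `flag` (non-empty when the correlation is undefined).
#' @export
intrapair_correlation <- function(formula, data, pair = "pair_id",
                                  zygosity = "zygosity", level = 0.95) {
  pd <- build_pair_data(formula, data, pair, zygosity)
  beta0 <- stats::coef(stats::lm.fit(rbind(pd$X1, pd$X2), c(pd$y1, pd$y2)))
  r1 <- pd$y1 - drop(pd$X1 %*% beta0)
  r2 <- pd$y2 - drop(pd$X2 %*% beta0)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(c(MZ = "MZ", DZ = "DZ"), function(z) {
    j <- which(pd$zyg == z)
    n <- length(j)
    if (n < 3L)
      return(data.frame(zygosity = z, r = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_pairs = n, flag = "too few pairs"))
    a <- r1[j]; b <- r2[j]
    gm <- (a + b) / 2
    msb <- 2 * sum((gm - mean(gm))^2) / (n - 1)
    msw <- sum((a - b)^2 / 2) / n
    if (msb + msw <= 0)
      return(data.frame(zygosity = z, r = NA_real_, lower = NA_real_,
                        upper = NA_real_, n_pairs = n,
                        flag = "zero between-pair variance"))
    r <- (msb - msw) / (msb + msw)
    se <- 1 / sqrt(n - 3)
    zr <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
    data.frame(zygosity = z, r = r, lower = tanh(zr - zq * se),
               upper = tanh(zr + zq * se), n_pairs = n, flag = "")
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
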