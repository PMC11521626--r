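#' Statistical layer: path analysis, mixed models, subject centring
#'
#' Recursive (acyclic) path analysis over observed variables with
#' covariance-based fit indices; random-intercept mixed models with
#' likelihood-ratio tests and parametric-bootstrap confidence intervals (via
#' lme4); the van de Pol & Wright subject-centring decomposition of a
#' covariate into between- and within-individual effects; and a binomial GLM
#' for skipped breeding with a Firth-penalised fallback under separation.
#'
#' @name inference
NULL

#' Path model specification
#'
#' A directed acyclic graph over observed variables. With no arguments,
#' returns the default annual-cycle graph: the OND climate index drives
#' January (non-breeding) latitude; latitude drives January foraging effort;
#' the previous August's foraging carries over into January foraging, which
#' carries over into the next August's foraging and thence colony visits;
#' southbound departure date predicts northbound departure, which predicts
#' colony return; plus the tested-but-weak edges (index and January foraging
#' to northbound start, previous August foraging to southbound start).
#'
#' @param edges data.frame with columns `from`, `to`; NULL for the default
#'   graph.
#' @return object of class `path_model_spec` with elements `edges`,
#'   `variables`.
#' @export
path_model_spec <- function(edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(
      from = c("soi_ond", "january_latitude", "august_foraging_prev",
               "january_foraging", "august_foraging",
               "august_foraging_prev", "soi_ond", "january_foraging",
               "southbound_start", "northbound_start"),
      to = c("january_latitude", "january_foraging", "january_foraging",
             "august_foraging", "august_visits",
             "southbound_start", "northbound_start", "northbound_start",
             "northbound_start", "northbound_end")
    )
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  spec <- structure(list(edges = edges,
                         variables = unique(c(edges$from, edges$to))),
                    class = "path_model_spec")
  .topological_order(spec) # errors if cyclic
  spec
}

# topological order; errors when the graph has a cycle (non-recursive)
.topological_order <- function(spec) {
  vars <- spec$variables
  edges <- spec$edges
  ord <- character(0)
  remaining <- vars
  while (length(remaining)) {
    # nodes with no incoming edge from remaining nodes
    free <- remaining[vapply(remaining, function(v)
      !any(edges$to == v & edges$from %in% remaining), logical(1))]
    if (!length(free)) stop("path model specification is not acyclic")
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
  }
  ord
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("path_model_spec:", length(x$variables), "variables,",
      nrow(x$edges), "edges\n")
  cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Fit a recursive path model
#'
#' Maximum-likelihood estimation of a recursive linear system over observed
#' variables. In a recursive system the ML coefficient estimates coincide
#' with equation-wise least squares, with information-matrix standard errors
#' (residual variance RSS/n). Fit indices compare the model-implied
#' covariance to the saturated sample covariance:
#' chi^2 = (n-1) F_ML, CFI and TLI against the independence baseline,
#' RMSEA = sqrt(max(chi^2 - df, 0) / (df (n-1))), and SRMR as the root mean
#' squared standardised residual covariance.
#'
#' @param spec a [path_model_spec()].
#' @param data data.frame containing every variable in `spec`; complete
#'   cases are used.
#' @param standardize z-score variables before fitting (default TRUE, so
#'   coefficients are on the standardised-beta scale).
#' @return object of class `path_model_result`: `coefficients` (data.frame
#'   from, to, beta, se, z, p), `fit` (list chisq, df, chisq_df, cfi, tli,
#'   rmsea, srmr), `n`, `resid_var`.
#' @export
fit_path_model <- function(spec, data, standardize = TRUE) {
  vars <- spec$variables
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("data lacks variables: ", paste(missing_vars, collapse = ", "))
  }
  d <- data[stats::complete.cases(data[, vars]), vars, drop = FALSE]
  n <- nrow(d)
  if (n <= length(vars) + 1) stop("too few complete cases")
  if (standardize) d[] <- lapply(d, function(x) as.numeric(scale(x)))
  p <- length(vars)
  S <- stats::cov(d) * (n - 1) / n       # ML covariance
  if (abs(det(S)) < 1e-12) stop("singular sample covariance")

  endo <- unique(spec$edges$to)
  exo <- setdiff(vars, endo)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi[exo, exo] <- S[exo, exo]

  coefs <- NULL
  for (v in endo) {
    parents <- spec$edges$from[spec$edges$to == v]
    fml <- stats::reformulate(parents, response = v)
    fit <- stats::lm(fml, data = d)
    np <- length(stats::coef(fit))
    # ML residual variance and information-matrix SEs
    sigma2_ml <- sum(stats::residuals(fit)^2) / n
    V <- stats::vcov(fit) * (n - np) / n
    b <- stats::coef(fit)[parents]
    se <- sqrt(diag(V))[parents]
    z <- b / se
    coefs <- rbind(coefs, data.frame(
      from = parents, to = v, beta = unname(b), se = unname(se),
      z = unname(z), p = 2 * stats::pnorm(-abs(z))))
    B[v, parents] <- b
    Psi[v, v] <- sigma2_ml
  }

  I_B <- diag(p) - B
  Sigma <- solve(I_B) %*% Psi %*% t(solve(I_B))
  dimnames(Sigma) <- dimnames(S)

  fml_discrepancy <- function(Smat, Sig) {
    as.numeric(log(det(Sig)) + sum(diag(Smat %*% solve(Sig))) -
                 log(det(Smat)) - nrow(Smat))
  }
  q <- length(exo)
  n_free <- nrow(spec$edges) + length(endo) + q * (q + 1) / 2
  df <- p * (p + 1) / 2 - n_free
  chisq <- max((n - 1) * fml_discrepancy(S, Sigma), 0)

  # independence baseline
  Sigma_b <- diag(diag(S))
  df_b <- p * (p + 1) / 2 - p
  chisq_b <- (n - 1) * fml_discrepancy(S, Sigma_b)

  if (df > 0) {
    cfi <- 1 - max(chisq - df, 0) / max(chisq_b - df_b, chisq - df, .Machine$double.eps)
    tli <- ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
    tli <- min(max(tli, 0), 1)
    rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  } else {
    cfi <- 1; tli <- 1; rmsea <- 0
  }
  dS <- sqrt(diag(S))
  res_std <- (S - Sigma) / tcrossprod(dS)
  srmr <- sqrt(mean(res_std[lower.tri(res_std, diag = TRUE)]^2))

  structure(list(
    coefficients = coefs,
    fit = list(chisq = chisq, df = df,
               chisq_df = if (df > 0) chisq / df else NA_real_,
               cfi = min(max(cfi, 0), 1), tli = tli, rmsea = rmsea,
               srmr = srmr),
    n = n, standardized = standardize,
    implied = Sigma, sample_cov = S
  ), class = "path_model_result")
}

#' @export
print.path_model_result <- function(x, ...) {
  cat("Recursive path model, n =", x$n,
      if (x$standardized) "(standardised variables)\n" else "\n")
  stats::printCoefmat(
    `rownames<-`(as.matrix(x$coefficients[, c("beta", "se", "z", "p")]),
                 paste(x$coefficients$from, "->", x$coefficients$to)),
    P.values = TRUE, has.Pvalue = TRUE)
  f <- x$fit
  cat(sprintf(
    "chi^2 = %.3f on %d df (chi^2/df = %s); CFI = %.3f TLI = %.3f RMSEA = %.3f SRMR = %.3f\n",
    f$chisq, f$df, ifelse(is.na(f$chisq_df), "NA", sprintf("%.2f", f$chisq_df)),
    f$cfi, f$tli, f$rmsea, f$srmr))
  invisible(x)
}

#' Bonferroni adjustment for structural equation models
#'
#' Per-test alpha = 0.05 / k^(1 - r), where k is the number of tests and r
#' the mean absolute correlation among the tested variables. With perfectly
#' correlated tests (r = 1) no adjustment is made; with independent tests
#' (r = 0) this is the ordinary Bonferroni 0.05/k.
#'
#' @param k number of tests (>= 1).
#' @param mean_r mean absolute correlation in [0, 1].
#' @return the per-test significance level.
#' @export
sem_bonferroni_alpha <- function(k, mean_r) {
  if (k < 1) stop("k must be >= 1")
  if (is.na(mean_r) || mean_r < 0 || mean_r > 1) {
    stop("mean_r must lie in [0, 1]")
  }
  0.05 / k^(1 - mean_r)
}

#' Random-intercept mixed model with LRT and bootstrap CIs
#'
#' Fits `response ~ fixed + (1 | group)` by REML for estimation; the focal
#' fixed effect is tested by a likelihood-ratio chi-square between ML fits
#' with and without it, and confidence intervals for all fixed effects come
#' from a seeded parametric bootstrap (percentile 2.5/97.5).
#'
#' @param data data.frame.
#' @param response,fixed,group column names; `fixed` a character vector.
#' @param focal the fixed effect tested by LRT (default the first).
#' @param nboot parametric bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return object of class `lmm_fit`: `coefficients` (term, estimate,
#'   ci_lo, ci_hi), `lrt` (chisq, df, p, focal), `singular`, `nboot`,
#'   `model` (the REML merMod).
#' @export
fit_lmm <- function(data, response, fixed, group, focal = fixed[1],
                    nboot = 1000, seed = 1, conf = 0.95) {
  if (length(unique(data[[group]])) < 2) stop("need >= 2 groups")
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = data, REML = TRUE)
  singular <- lme4::isSingular(fit)

  full_ml <- lme4::lmer(fml, data = data, REML = FALSE)
  reduced_terms <- setdiff(fixed, focal)
  fml0 <- stats::as.formula(paste(
    response, "~",
    if (length(reduced_terms)) paste(reduced_terms, collapse = " + ") else "1",
    "+ (1 |", group, ")"))
  null_ml <- lme4::lmer(fml0, data = data, REML = FALSE)
  lrt_chisq <- max(0, 2 * (as.numeric(stats::logLik(full_ml)) -
                             as.numeric(stats::logLik(null_ml))))
  lrt_p <- stats::pchisq(lrt_chisq, df = 1, lower.tail = FALSE)

  bb <- suppressWarnings(suppressMessages(
    lme4::bootMer(fit, FUN = lme4::fixef, nsim = nboot, seed = seed,
                  type = "parametric")))
  a <- (1 - conf) / 2
  ci <- apply(bb$t, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  est <- lme4::fixef(fit)
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              ci_lo = ci[1, ], ci_hi = ci[2, ],
                              row.names = NULL),
    lrt = list(focal = focal, chisq = lrt_chisq, df = 1, p = lrt_p),
    singular = singular, nboot = nboot, seed = seed, model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept mixed model", if (x$singular) "(singular fit)", "\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("LRT (%s): chi^2_1 = %.3f, p = %.4g; bootstrap CIs from %d draws (seed %d)\n",
              x$lrt$focal, x$lrt$chisq, x$lrt$p, x$nboot, x$seed))
  invisible(x)
}

#' Within/between subject centring
#'
#' Decomposes a covariate into per-individual means (between effect) and
#' deviations from them (within effect) and fits
#' `y ~ between + within + (1 | id)`. The between-minus-within difference is
#' estimated by the reparametrised model `y ~ x + xbar + (1 | id)`, in which
#' the coefficient on the individual mean equals (between - within); both
#' models get seeded parametric-bootstrap CIs, and the within effect a
#' likelihood-ratio test.
#'
#' @param data data.frame.
#' @param x,y,id column names of the covariate, response and individual id.
#' @param nboot,seed,conf as in [fit_lmm()].
#' @return object of class `centring_result`: `between`, `within`,
#'   `difference` (each estimate + ci), `lrt_within`, `lrt_between`, `n`,
#'   `n_birds`.
#' @export
subject_centring <- function(data, x = "x", y = "y", id = "bird",
                             nboot = 1000, seed = 1, conf = 0.95) {
  d <- data[stats::complete.cases(data[, c(x, y, id)]), , drop = FALSE]
  d$.id <- factor(d[[id]])
  xbar <- tapply(d[[x]], d$.id, mean)
  d$.between <- as.numeric(xbar[d$.id])
  d$.within <- d[[x]] - d$.between
  if (all(abs(d$.within) < 1e-12)) {
    stop("within-individual slope inestimable: no within-individual ",
         "variation in ", x)
  }
  d$.x <- d[[x]]
  d$.y <- d[[y]]

  main <- fit_lmm(d, ".y", c(".between", ".within"), ".id",
                  focal = ".within", nboot = nboot, seed = seed, conf = conf)
  lrt_between <- fit_lmm(d, ".y", c(".between", ".within"), ".id",
                         focal = ".between", nboot = 2, seed = seed)$lrt
  diff_fit <- fit_lmm(d, ".y", c(".x", ".between"), ".id",
                      focal = ".between", nboot = nboot, seed = seed,
                      conf = conf)
  pick <- function(fit, term) {
    r <- fit$coefficients[fit$coefficients$term == term, ]
    if (nrow(r) != 1) {  # dropped for rank deficiency (e.g. constant xbar)
      return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    list(estimate = r$estimate, ci = c(r$ci_lo, r$ci_hi))
  }
  structure(list(
    between = pick(main, ".between"),
    within = pick(main, ".within"),
    difference = pick(diff_fit, ".between"),
    lrt_within = main$lrt, lrt_between = lrt_between,
    n = nrow(d), n_birds = nlevels(d$.id), nboot = nboot, seed = seed
  ), class = "centring_result")
}

#' @export
print.centring_result <- function(x, ...) {
  fmt <- function(s, v) cat(sprintf(
    "  %-22s %8.3f  [%.3f, %.3f]\n", s, v$estimate, v$ci[1], v$ci[2]))
  cat("Subject-centred mixed model:", x$n, "observations of",
      x$n_birds, "individuals\n")
  fmt("between-individual", x$between)
  fmt("within-individual", x$within)
  fmt("difference (b - w)", x$difference)
  cat(sprintf("  LRT within: chi^2_1 = %.2f, p = %.4g\n",
              x$lrt_within$chisq, x$lrt_within$p))
  invisible(x)
}

# Firth-penalised logistic regression (Jeffreys-prior score correction),
# used when ML separates. Plain IWLS with the hat-value adjustment.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XW <- X * W
    info <- crossprod(X, XW)
    H <- (X * sqrt(W)) %*% solve(info, t(X * sqrt(W)))
    h <- diag(H)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, U)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  list(coefficients = beta, se = se, iterations = i)
}

#' Binomial GLM for skipped breeding
#'
#' Logistic regression of skipping breeding on non-breeding (January)
#' foraging effort, by maximum likelihood with Wald z tests. Under complete
#' or quasi-complete separation the ML estimate diverges; the fit is then
#' flagged and Firth-penalised estimates are reported instead.
#'
#' @param foraging numeric January foraging proportions.
#' @param skipped logical (TRUE = skipped breeding); both classes required.
#' @return object of class `skip_glm`: `coefficients` (term, beta, se, z,
#'   p), `separation`, `method` ("ml" or "firth"), `n`.
#' @export
fit_skip_glm <- function(foraging, skipped) {
  skipped <- as.logical(skipped)
  if (length(unique(skipped)) < 2) {
    stop("both breeding outcomes must be present")
  }
  d <- data.frame(foraging = foraging, skipped = skipped)
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm(skipped ~ foraging, data = d, family = stats::binomial()),
    warning = function(cond) {
      w <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    })
  separation <- (!is.null(w) &&
                   grepl("fitted probabilities numerically 0 or 1", w)) ||
    any(abs(stats::coef(fit)) > 50)
  if (separation) {
    X <- cbind(1, foraging)
    fl <- .firth_logistic(X, as.numeric(skipped))
    beta <- fl$coefficients; se <- fl$se
    method <- "firth"
  } else {
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    method <- "ml"
  }
  z <- beta / se
  structure(list(
    coefficients = data.frame(term = c("(Intercept)", "foraging"),
                              beta = unname(beta), se = unname(se),
                              z = unname(z), p = 2 * stats::pnorm(-abs(z))),
    separation = separation, method = method, n = length(skipped)
  ), class = "skip_glm")
}

#' @export
print.skip_glm <- function(x, ...) {
  cat("Skipped-breeding logistic model (", x$method, "), n = ", x$n,
      if (x$separation) " -- separation detected, Firth penalty applied",
      "\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Validate colony visits against chick peak mass
#'
#' Linear mixed model `mass ~ visits + peak_date + (1 | burrow)`: colony
#' visitation should predict chick peak mass if GLS-derived visits index
#' provisioning, with the measurement date as a fixed covariate so late
#' weighing cannot masquerade as provisioning.
#'
#' @param records data.frame with `mass`, `visits`, `peak_date`, `burrow`.
#' @param nboot,seed,conf as in [fit_lmm()].
#' @return an `lmm_fit` with focal effect `visits`.
#' @export
validate_visits_vs_mass <- function(records, nboot = 1000, seed = 1,
                                    conf = 0.95) {
  if (length(unique(records$burrow)) < 2) stop("need >= 2 burrows")
  if (stats::var(records$visits) == 0) {
    stop("visit counts constant: slope inestimable")
  }
  fit_lmm(records, "mass", c("visits", "peak_date"), "burrow",
          focal = "visits", nboot = nboot, seed = seed, conf = conf)
}
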