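test_that("path specification rejects cyclic graphs", {
  expect_s3_class(path_model_spec(), "path_model_spec")
  cyc <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
  expect_error(path_model_spec(cyc), "acyclic")
})

test_that("recursive path estimates equal equation-wise least squares", {
  spec <- path_model_spec()
  beta <- c("soi_ond->january_latitude" = -0.33,
            "january_latitude->january_foraging" = -0.2,
            "august_foraging_prev->january_foraging" = 0.5,
            "january_foraging->august_foraging" = 0.25,
            "august_foraging->august_visits" = 0.4,
            "southbound_start->northbound_start" = 0.35,
            "northbound_start->northbound_end" = 0.7)
  d <- simulate_path_data(spec, beta, n = 250, seed = 4)
  pm <- fit_path_model(spec, d)
  ds <- as.data.frame(lapply(d, function(x) as.numeric(scale(x))))
  for (v in unique(spec$edges$to)) {
    parents <- spec$edges$from[spec$edges$to == v]
    ols <- coef(lm(reformulate(parents, v), data = ds))[parents]
    got <- pm$coefficients$beta[pm$coefficients$to == v]
    names(got) <- pm$coefficients$from[pm$coefficients$to == v]
    expect_equal(got[parents], ols, tolerance = 1e-8)
  }
  expect_true(all(pm$fit$df >= 0))
  expect_true(pm$fit$srmr >= 0 && pm$fit$rmsea >= 0)
})

test_that("fit indices hit their limits: saturated and near-independence models", {
  vars <- c("a", "b", "c", "d")
  ed <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  ed <- ed[match(ed$from, vars) < match(ed$to, vars), ]
  sat_spec <- path_model_spec(ed)
  d <- simulate_path_data(sat_spec, c("a->b" = 0.6, "b->c" = 0.5), n = 150,
                          seed = 6)
  sat <- fit_path_model(sat_spec, d)
  expect_equal(sat$fit$chisq, 0, tolerance = 1e-8)
  expect_equal(sat$fit$df, 0)
  expect_equal(sat$fit$cfi, 1)
  expect_equal(sat$fit$tli, 1)
  expect_lt(sat$fit$srmr, 1e-7)

  # a model blind to the only real dependence (x -> y) fits no better than
  # the independence baseline: CFI collapses toward 0
  set.seed(11)
  n <- 300
  x <- rnorm(n); zv <- rnorm(n); yv <- 0.9 * x + rnorm(n, 0, 0.3)
  dd <- data.frame(x = x, z = zv, y = yv)
  bad <- path_model_spec(data.frame(from = c("x", "z"), to = c("z", "y")))
  fb <- fit_path_model(bad, dd)
  expect_lt(fb$fit$cfi, 0.1)
  expect_gt(fb$fit$rmsea, 0.2)
})

test_that("path-model coverage: true edges inside 2 SE in >= 93% of replicates", {
  spec <- path_model_spec()
  beta <- c("soi_ond->january_latitude" = -0.33,
            "january_latitude->january_foraging" = -0.2,
            "august_foraging_prev->january_foraging" = 0.5,
            "january_foraging->august_foraging" = 0.25,
            "august_foraging->august_visits" = 0.4,
            "southbound_start->northbound_start" = 0.35,
            "northbound_start->northbound_end" = 0.7)
  hits <- 0; total <- 0
  for (r in 1:200) {
    d <- simulate_path_data(spec, beta, n = 200, resid_sd = 1, seed = 100 + r)
    pm <- fit_path_model(spec, d, standardize = FALSE)
    co <- pm$coefficients
    key <- paste0(co$from, "->", co$to)
    truth <- ifelse(key %in% names(beta), beta[key], 0)
    hits <- hits + sum(abs(co$beta - truth) <= 2 * co$se)
    total <- total + nrow(co)
  }
  expect_gte(hits / total, 0.93)
})

test_that("SEM Bonferroni alpha follows 0.05 / k^(1 - r)", {
  expect_equal(sem_bonferroni_alpha(1, 0.3), 0.05)
  expect_equal(sem_bonferroni_alpha(7, 1), 0.05)
  expect_equal(sem_bonferroni_alpha(10, 0.5), 0.05 / sqrt(10),
               tolerance = 1e-12)
  expect_equal(sem_bonferroni_alpha(10, 0), 0.005)
  expect_error(sem_bonferroni_alpha(10, 1.2), "mean_r")
  expect_error(sem_bonferroni_alpha(0, 0.5), "k must")
})

test_that("mixed model: boundary variance, seeded bootstrap reproducibility", {
  # zero true group variance: estimate on the boundary, flagged singular
  set.seed(30)
  d <- data.frame(g = factor(rep(1:20, each = 5)), x = rnorm(100))
  d$y <- 2 * d$x + rnorm(100)
  f <- fit_lmm(d, "y", "x", "g", nboot = 50, seed = 7)
  vc <- as.data.frame(lme4::VarCorr(f$model))
  expect_lt(vc$vcov[vc$grp == "g"], 0.05)  # boundary estimate

  f2 <- fit_lmm(d, "y", "x", "g", nboot = 50, seed = 7)
  expect_identical(f$coefficients, f2$coefficients)
  expect_error(fit_lmm(d[d$g == "1", ], "y", "x", "g"), "2 groups")
})

test_that("bootstrap CI covers a known slope at roughly nominal rate", {
  hits <- 0
  reps <- 150
  for (r in seq_len(reps)) {
    d <- local({
      set.seed(4000 + r)
      g <- factor(rep(1:50, each = 10))
      u <- rnorm(50, 0, 1)
      x <- rnorm(500)
      data.frame(g = g, x = x, y = 2 * x + u[g] + rnorm(500))
    })
    f <- fit_lmm(d, "y", "x", "g", nboot = 99, seed = r)
    ci <- f$coefficients[f$coefficients$term == "x", c("ci_lo", "ci_hi")]
    if (ci$ci_lo <= 2 && 2 <= ci$ci_hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.93)
})

test_that("LRT on a null fixed effect rejects at close to the nominal 5%", {
  rej <- 0
  nsim <- 500
  for (r in seq_len(nsim)) {
    d <- local({
      set.seed(9000 + r)
      g <- factor(rep(1:30, each = 5))
      u <- rnorm(30, 0, 1)
      x <- rnorm(150)
      data.frame(g = g, x = x, y = u[g] + rnorm(150))
    })
    fml <- y ~ x + (1 | g)
    full <- lme4::lmer(fml, data = d, REML = FALSE)
    null <- lme4::lmer(y ~ (1 | g), data = d, REML = FALSE)
    p <- pchisq(2 * (logLik(full) - logLik(null)), 1, lower.tail = FALSE)
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.08)
})

test_that("subject centring reconstructs x and rejects degenerate designs", {
  d <- simulate_centring_data(n_birds = 10, n_per = 4, seed = 2)
  xbar <- ave(d$x, d$bird)
  expect_equal(xbar + (d$x - xbar), d$x)   # centring identity

  cen <- subject_centring(d, nboot = 30, seed = 1)
  expect_true(cen$between$ci[1] <= cen$between$estimate &&
                cen$between$estimate <= cen$between$ci[2])
  expect_true(cen$within$ci[1] <= cen$within$estimate &&
                cen$within$estimate <= cen$within$ci[2])

  # identical x within each bird: within slope undefined
  d2 <- d; d2$x <- ave(d2$x, d2$bird)
  expect_error(subject_centring(d2), "inestimable")
})

test_that("skipped-breeding GLM: null effect, separation fallback, class check", {
  set.seed(5)
  n <- 200
  forag <- runif(n)
  skip <- runif(n) < 0.5                 # no relationship
  f <- fit_skip_glm(forag, skip)
  expect_equal(f$method, "ml")
  b <- f$coefficients[f$coefficients$term == "foraging", ]
  expect_lt(abs(b$beta), 2 * b$se + 1)

  # complete separation -> flagged, Firth estimates finite
  sep <- forag > 0.5
  fs <- fit_skip_glm(forag, sep)
  expect_true(fs$separation)
  expect_equal(fs$method, "firth")
  expect_true(all(is.finite(fs$coefficients$beta)))
  expect_true(all(is.finite(fs$coefficients$se)))

  expect_error(fit_skip_glm(forag, rep(TRUE, n)), "both breeding outcomes")
})

test_that("logistic slope recovered within 2 SE at simulated strength", {
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    set.seed(6000 + r)
    x <- runif(200)
    pr <- plogis(-6 + 12 * x)
    yv <- runif(200) < pr
    if (length(unique(yv)) < 2) next
    f <- fit_skip_glm(x, yv)
    b <- f$coefficients[f$coefficients$term == "foraging", ]
    if (abs(b$beta - 12) <= 2 * b$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
})

test_that("chick peak mass validates colony visits with date as covariate", {
  rec <- simulate_peak_mass(n_burrows = 25, years_per = 3, beta_visits = 2.13,
                            beta_date = 0, seed = 3)
  f <- validate_visits_vs_mass(rec, nboot = 200, seed = 2)
  cv <- f$coefficients[f$coefficients$term == "visits", ]
  expect_true(cv$ci_lo <= 2.13 && 2.13 <= cv$ci_hi)
  cd <- f$coefficients[f$coefficients$term == "peak_date", ]
  expect_true(cd$ci_lo <= 0 && 0 <= cd$ci_hi)   # null date effect covered

  rec2 <- rec; rec2$visits <- 8L
  expect_error(validate_visits_vs_mass(rec2), "constant")
})
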