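make_leroux_data <- function(rows = 10, cols = 10, seed = 1,
                             rho = 0.9, tau2 = 0.05, phi = NULL) {
  g <- generate_lattice(rows, cols)
  w <- build_weights(g, "binary")
  tab <- simulate_covariates(g, seed = seed)
  if (is.null(phi)) phi <- sample_leroux_field(w, rho, tau2, seed = seed + 1)
  tab <- simulate_counts(tab, synthetic_truth(beta_reference(), phi,
                                              rho, max(tau2, 1e-6),
                                              seed = seed + 2))
  list(graph = g, weights = w, table = derive_analysis_variables(tab))
}

test_that("draw retention follows the iteration arithmetic", {
  gp <- make_path_graph(3)
  wp <- build_weights(gp, "binary")
  tp <- data.frame(area_id = gp$ids, child_pop = 1000L, total_pop = 5000L,
                   asthma_count = c(55L, 60L, 70L), indigenous_pct = 1,
                   seifa_score = 1000, seifa_decile = 5L)
  tp <- derive_analysis_variables(tp)
  fit <- fit_car(asthma_count ~ 1 + offset(log(child_pop)), tp, wp,
                 prior = "leroux", n_iter = 30000, burn_in = 10000,
                 thin = 10, seed = 1)
  expect_equal(nrow(fit$chains$beta), 2000)
  expect_equal(length(fit$chains$tau2), 2000)
  expect_true(all(fit$chains$tau2 > 0))
  expect_true(all(fit$chains$rho > 0 & fit$chains$rho < 1))
  expect_error(fit_car(asthma_count ~ 1 + offset(log(child_pop)), tp, wp,
                       n_iter = 100, burn_in = 100), "burn_in")
  expect_error(fit_car(asthma_count ~ 1, tp, wp), "offset")
})

test_that("posterior means agree with the Poisson MLE when phi is zero", {
  d <- make_leroux_data(20, 20, seed = 5, phi = rep(0, 400))
  fit <- fit_car_leroux(d$table, d$weights, n_iter = 11000, burn_in = 1000,
                        thin = 5, seed = 2)
  mle <- stats::glm(asthma_count ~ seifa_category + indigenous_group +
                      offset(log(child_pop)),
                    family = stats::poisson(), data = d$table)
  cf <- coef(fit)[names(coef(mle))]
  sds <- apply(fit$chains$beta[, names(coef(mle))], 2, sd)
  expect_true(all(abs(cf - coef(mle)) < 2 * sds))
})

test_that("fixed seeds give bitwise-identical chains; fixed parameters hold", {
  d <- make_leroux_data(5, 5, seed = 9)
  f1 <- fit_car_leroux(d$table, d$weights, n_iter = 2000, burn_in = 500,
                       thin = 2, seed = 77)
  f2 <- fit_car_leroux(d$table, d$weights, n_iter = 2000, burn_in = 500,
                       thin = 2, seed = 77)
  expect_identical(f1$chains, f2$chains)
  f3 <- fit_car_leroux(d$table, d$weights, n_iter = 2000, burn_in = 500,
                       thin = 2, seed = 77, fix_rho = 0.3, fix_tau2 = 0.2)
  expect_true(all(f3$chains$rho == 0.3))
  expect_true(all(f3$chains$tau2 == 0.2))
})

test_that("with rho at zero the fit matches an iid random-intercept oracle", {
  d <- make_leroux_data(10, 10, seed = 31, phi = NULL, rho = 0, tau2 = 0.02)
  set.seed(32)
  d$table$asthma_count <- rpois(100, d$table$child_pop *
                                  exp(log(0.0627) + rnorm(100, 0, 0.15)))
  d$table <- derive_analysis_variables(d$table)
  fit <- fit_car_leroux(d$table, d$weights, fix_rho = 0, n_iter = 11000,
                        burn_in = 1000, thin = 5, seed = 34)
  gm <- lme4::glmer(asthma_count ~ seifa_category + indigenous_group +
                      (1 | area_id) + offset(log(child_pop)),
                    data = d$table, family = stats::poisson())
  fe <- lme4::fixef(gm)
  cf <- coef(fit)[names(fe)]
  sds <- apply(fit$chains$beta[, names(fe)], 2, sd)
  expect_true(all(abs(cf - fe) < 2 * sds))
})

test_that("localised chains respect ordering and max-cluster semantics", {
  d <- make_leroux_data(8, 8, seed = 41)
  fit <- fit_car_localised(d$table, d$weights, G = 5, n_iter = 5000,
                           burn_in = 1000, thin = 4, seed = 42)
  lam <- fit$chains$lambda
  expect_true(all(apply(lam, 1, function(v) all(diff(v) > 0))))
  expect_true(all(fit$chains$Z >= 1 & fit$chains$Z <= 5))
  occupied <- apply(fit$chains$Z, 1, function(z) length(unique(z)))
  expect_true(all(occupied <= 5))
  expect_true(all(fit$chains$delta > 1 & fit$chains$delta < 10))
  expect_true(all(fit$chains$sigma2 > 0))
  ## the design intercept is absorbed by the cluster intercepts
  expect_false("(Intercept)" %in% colnames(fit$chains$beta))
})

test_that("localised model recovers well-separated contiguous blocks", {
  g <- generate_lattice(10, 10)
  w <- build_weights(g, "binary")
  tb <- simulate_covariates(g, seed = 21)
  st <- sample_localised_structure(g, G = 2, seed = 22,
                                   lambda = c(-0.4, 0.4))
  tb <- derive_analysis_variables(simulate_counts(
    tb, synthetic_truth(beta_reference(), st$lambda[st$assignments],
                        seed = 23)))
  fit <- fit_car_localised(tb, w, G = 3, n_iter = 11000, burn_in = 1000,
                           thin = 5, seed = 24)
  modal <- apply(fit$chains$Z, 2,
                 function(z) as.integer(names(which.max(table(z)))))
  ## fraction of areas whose modal class is the majority class of their block
  agree <- sum(vapply(split(modal, st$assignments),
                      function(m) max(table(m)), numeric(1)))
  expect_gte(agree / 100, 0.9)
})

test_that("WAIC follows its definition and stays numerically stable", {
  ## identical draws: zero effective-parameter penalty
  ll <- matrix(rep(c(-1.3, -2.1, -0.7), each = 5), nrow = 5)
  wa <- compute_waic(ll)
  expect_equal(wa$p_waic, 0)
  expect_equal(wa$waic, -2 * wa$lppd)
  expect_equal(wa$lppd, sum(ll[1, ]))
  ## extreme log-likelihoods do not overflow
  ll2 <- matrix(c(-700, -702, -698, -700), 2)
  wa2 <- compute_waic(ll2)
  expect_true(is.finite(wa2$waic))
  expect_error(compute_waic(ll[1, , drop = FALSE]), "at least 2")
})

test_that("Geweke diagnostic behaves across chain regimes", {
  expect_error(geweke_diagnostic(rnorm(50)), "at least 100")
  expect_warning(z0 <- geweke_diagnostic(rep(1, 500)), "constant")
  expect_true(is.na(z0))
  ## a strong linear trend blows the score up
  set.seed(5)
  base <- abs(geweke_diagnostic(rnorm(2000)))
  trended <- abs(geweke_diagnostic(rnorm(2000) + seq(0, 5, length.out = 2000)))
  expect_gt(trended, 5)
  expect_gt(trended, base)
})

test_that("posterior summaries expose prevalence ratios with references", {
  ## PR arithmetic on a constant chain
  fake <- structure(list(
    chains = list(beta = matrix(0.0953, 200, 1,
                                dimnames = list(NULL, "exposure"))),
    xlevels = list()), class = "car_fit")
  expect_warning(ps <- posterior_summary(fake), "constant chain")
  expect_equal(round(ps$PR, 2), 1.10)
  ## quantiles match a sort-based oracle on a real fit
  d <- make_leroux_data(5, 5, seed = 51)
  fit <- fit_car_leroux(d$table, d$weights, n_iter = 3000, burn_in = 1000,
                        thin = 2, seed = 52)
  ps <- posterior_summary(fit)
  dr <- sort(fit$chains$beta[, "indigenous_grouphigh"])
  m <- length(dr)
  qo <- function(p) {           # type-7 interpolation, written out
    h <- (m - 1) * p + 1
    lo <- floor(h)
    dr[lo] + (h - lo) * (dr[min(lo + 1, m)] - dr[lo])
  }
  row <- ps[ps$variable == "indigenous_grouphigh", ]
  expect_equal(row$lower, qo(0.025))
  expect_equal(row$upper, qo(0.975))
  expect_equal(row$median, qo(0.5))
  ## reference categories are printed as PR exactly 1
  refs <- ps[ps$reference, ]
  expect_true(all(refs$PR == 1))
  expect_true(all(is.na(refs$PR_lower)))
  expect_setequal(refs$variable,
                  c("seifa_categorymost_advantaged", "indigenous_grouplow"))
})

test_that("fit methods produce coherent views of the model", {
  d <- make_leroux_data(5, 5, seed = 61)
  fit <- fit_car_leroux(d$table, d$weights, n_iter = 3000, burn_in = 1000,
                        thin = 2, seed = 62)
  expect_named(coef(fit), colnames(fit$chains$beta))
  mu <- fitted(fit)
  expect_length(mu, 25)
  expect_true(all(mu > 0))
  ## fitted values track the observed counts reasonably
  expect_gt(cor(mu, d$table$asthma_count), 0.9)
  r <- residuals(fit)
  expect_equal(r, (d$table$asthma_count - mu) / sqrt(mu))
  sims <- simulate(fit, nsim = 3, seed = 63)
  expect_equal(dim(sims), c(25, 3))
  s <- summary(fit)
  expect_s3_class(s, "summary.car_fit")
  expect_output(print(s), "Prevalence ratios")
})
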