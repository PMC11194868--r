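test_that("covariate generator matches the census-style marginals", {
  g <- generate_lattice(11, 211)                 # 2321 areas
  tab <- simulate_covariates(g, seed = 42)
  expect_equal(nrow(tab), 2321)
  expect_lt(abs(mean(tab$seifa_score) - 999), 5)
  expect_lt(abs(sd(tab$seifa_score) - 82.5), 5)
  expect_lt(abs(mean(tab$child_pop) - 1991), 120)
  expect_true(all(tab$child_pop >= 10 & tab$child_pop <= 7889))
  expect_true(all(tab$child_pop <= tab$total_pop))
  ## right-skewed Indigenous % with median near the census value
  expect_gt(median(tab$indigenous_pct), 1.5)
  expect_lt(median(tab$indigenous_pct), 2.8)
  expect_gt(mean(tab$indigenous_pct), median(tab$indigenous_pct))
  ## rank-derived deciles partition areas into near-equal tenths
  sizes <- table(tab$seifa_decile)
  expect_length(sizes, 10)
  expect_lte(diff(range(sizes)), 1)
  ## determinism
  expect_identical(tab, simulate_covariates(g, seed = 42))
  expect_error(simulate_covariates(g, marginals = list(seifa_sd = -1)),
               "positive")
  expect_error(simulate_covariates(g, marginals = list(child_min = 100,
                                                       child_max = 10)),
               "reversed")
})

test_that("Leroux field sampling is exact", {
  gp <- make_path_graph(3)
  wp <- build_weights(gp, "binary")
  ## rho = 0: iid N(0, tau2)
  X0 <- sample_leroux_field(wp, 0, 2.5, seed = 1, n = 20000)
  expect_lt(abs(cor(X0[1, ], X0[2, ])), 4 / sqrt(20000))
  expect_lt(abs(var(X0[1, ]) - 2.5), 0.1)
  ## rho = 0.9: empirical covariance matches the inverse precision
  rho <- 0.9; tau2 <- 1
  D <- diag(c(1, 2, 1)); W <- dense_W(wp)
  S <- solve((rho * (D - W) + (1 - rho) * diag(3)) / tau2)
  X <- sample_leroux_field(wp, rho, tau2, seed = 2, n = 50000)
  emp <- cov(t(X))
  se <- sqrt((outer(diag(S), diag(S)) + S^2) / 50000)
  expect_true(all(abs(emp - S) < 3 * se))
  ## per-area mean within 4 SE of zero
  se_mean <- sqrt(diag(S) / 50000)
  expect_true(all(abs(rowMeans(X)) < 4 * se_mean))
  ## contracts
  expect_length(sample_leroux_field(wp, 0.5, 1, seed = 3), 3)
  expect_error(sample_leroux_field(wp, 1, 1), "rho")
  expect_error(sample_leroux_field(wp, -0.1, 1), "rho")
  expect_error(sample_leroux_field(wp, 0.5, 0), "tau2")
})

test_that("count simulation reproduces the target prevalence scale", {
  g <- generate_lattice(40, 50)                  # 2000 areas
  tab <- simulate_covariates(g, seed = 7)
  ## intercept-only truth at baseline prevalence 6.27%
  tr <- synthetic_truth(beta = c(log(0.0627), 0, 0, 0, 0, 0),
                        phi = rep(0, 2000), seed = 8)
  tab2 <- simulate_counts(tab, tr)
  expect_lt(abs(mean(tab2$prevalence_pct) - 6.27), 0.3)
  ## Poisson mean contract: E = 1000, rate 5% -> mean count about 50
  flat <- data.frame(area_id = g$ids, child_pop = 1000L, total_pop = 5000L,
                     indigenous_pct = 1, seifa_score = 1000,
                     seifa_decile = 10L)
  flat <- derive_analysis_variables(flat, indigenous_threshold = 50,
                                    require_counts = FALSE)
  tr2 <- synthetic_truth(beta = c(log(0.05), 0, 0, 0, 0, 0),
                         phi = rep(0, 2000), seed = 9)
  flat2 <- simulate_counts(flat, tr2)
  expect_lt(abs(mean(flat2$asthma_count) - 50), 3 * sqrt(50 / 2000) * 2)
  ## determinism and shape errors
  expect_identical(simulate_counts(tab, tr), tab2)
  bad <- synthetic_truth(beta = c(1, 2), phi = rep(0, 2000), seed = 1)
  expect_error(simulate_counts(tab, bad), "beta")
})

test_that("localised structure is contiguous with ordered intercepts", {
  g <- generate_lattice(10, 10)
  expect_error(sample_localised_structure(g, G = 1), "between 2 and 10")
  expect_error(sample_localised_structure(g, G = 11), "between 2 and 10")
  expect_error(sample_localised_structure(make_path_graph(3), G = 5),
               "exceeds")
  st <- sample_localised_structure(g, G = 3, seed = 5)
  expect_setequal(unique(st$assignments), 1:3)
  expect_true(all(diff(st$lambda) > 0))
  ## each class induces a connected subgraph (BFS oracle via components)
  for (k in 1:3) {
    sub <- subset_graph(g, st$assignments == k)
    expect_equal(max(graph_components(sub)), 1L)
  }
  expect_identical(st, sample_localised_structure(g, G = 3, seed = 5))
})

test_that("fixtures round-trip through the readers", {
  g <- generate_lattice(4, 4)
  tab <- simulate_covariates(g, seed = 3)
  tr <- synthetic_truth(beta_reference(),
                        phi = rep(0, 16), seed = 4)
  tab <- simulate_counts(tab, tr)
  dir <- file.path(tempdir(), "fixture-rt")
  paths <- write_fixture(tab, g, dir, truth = tr)
  back <- read_area_table(paths[["table"]])
  for (cl in c("area_id", "child_pop", "total_pop", "asthma_count",
               "indigenous_pct", "seifa_score", "seifa_decile"))
    expect_equal(back[[cl]], tab[[cl]])
  g2 <- read_edges(paths[["edges"]], ids = g$ids)
  expect_equal(g2$nb, g$nb)
  truth_back <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth_back$beta, beta_reference())
})
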