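test_that("global Moran's I matches hand-computable cases", {
  c4 <- make_cycle_graph(4)
  w <- build_weights(c4, "row_standardised")
  expect_equal(global_moran(c(1, -1, 1, -1), w), -1)
  expect_error(global_moran(rep(2, 4), w), "zero variance")
  ## permutation invariance under consistent relabelling
  g <- generate_lattice(4, 4)
  set.seed(1); x <- rnorm(16)
  I1 <- global_moran(x, build_weights(g, "row_standardised"))
  perm <- sample(16)
  gperm <- area_graph(g$ids[perm],
                      lapply(g$nb[perm], function(v) order(perm)[v]))
  I2 <- global_moran(x[perm], build_weights(gperm, "row_standardised"))
  expect_equal(I1, I2)
  ## strong Leroux field on a lattice shows clear positive autocorrelation
  g30 <- generate_lattice(30, 30)
  wb <- build_weights(g30, "binary")
  f <- sample_leroux_field(wb, 0.98, 1, seed = 11)
  expect_gt(global_moran(f, build_weights(g30, "row_standardised")), 0.3)
  ## and so does the full simulated prevalence surface, despite Poisson noise
  syn <- simulate_asthma_dataset(g30, seed = 12)
  expect_gt(global_moran(syn$table$prevalence_pct,
                         build_weights(g30, "row_standardised")), 0.3)
  expect_lt(abs(sd(syn$table$prevalence_pct) - 1.95), 0.5)
})

test_that("Monte-Carlo Moran test follows the pseudo-p rules", {
  g <- generate_lattice(5, 5)
  w <- build_weights(g, "row_standardised")
  grad <- rep(1:5, each = 5) + seq(0, 0.4, length.out = 25)
  mt <- moran_mc(grad, w, n_perm = 999, seed = 1)
  expect_equal(mt$pseudo_p, 0.001)      # minimum achievable at 999
  expect_length(mt$perm_values, 999)
  expect_equal(mt$expected_I, -1 / 24)
  ## determinism
  mt2 <- moran_mc(grad, w, n_perm = 999, seed = 1)
  expect_identical(mt$pseudo_p, mt2$pseudo_p)
  expect_error(moran_mc(grad, w, n_perm = 0), "n_perm")
  ## pseudo-p bounds across random fields
  set.seed(2)
  for (k in 1:5) {
    p <- moran_mc(rnorm(25), w, n_perm = 99)$pseudo_p
    expect_gte(p, 1 / 100)
    expect_lte(p, 1)
  }
})

test_that("exact global enumeration matches a brute-force oracle", {
  g <- generate_lattice(2, 3)
  w <- build_weights(g, "row_standardised")
  set.seed(3); x <- rnorm(6)
  mt <- moran_mc(x, w, exact = TRUE)
  ## oracle: enumerate all 6! permutations independently
  P <- oracle_perms(6)
  Wd <- dense_W(w)
  I_obs <- oracle_moran(x, Wd)
  perm_I <- apply(P, 1, function(idx) oracle_moran(x[idx], Wd))
  expect_equal(mt$pseudo_p, oracle_pseudo_p(I_obs, perm_I, -1 / 5))
  expect_equal(mt$I_obs, I_obs)
})

test_that("local Moran statistics are consistent with the global statistic", {
  g <- generate_lattice(6, 6)
  w <- build_weights(g, "row_standardised")
  for (s in 1:3) {
    set.seed(s); x <- rnorm(36)
    li <- local_moran(x, w, n_perm = 49, seed = s)
    expect_equal(mean(li$local_I), global_moran(x, w))
    expect_true(all(li$pseudo_p >= 1 / 50 & li$pseudo_p <= 1))
  }
  ## an area above the mean with all neighbours above the mean has I_i > 0
  x <- rep(-1, 36); x[c(8, 7, 9, 2, 14, 1, 3, 13, 15)] <- 3
  li <- local_moran(x, w, n_perm = 49, seed = 1)
  expect_gt(li$local_I[8], 0)
})

test_that("conditional-permutation p matches exhaustive enumeration on a path", {
  g <- make_path_graph(6)
  w <- build_weights(g, "row_standardised")
  set.seed(4); x <- rnorm(6)
  li <- local_moran(x, w, exact = TRUE)
  ## oracle: for each area, enumerate all 5! arrangements of the other values
  zc <- x - mean(x)
  z <- zc / sqrt(sum(zc^2) / 6)
  Wd <- dense_W(w)
  for (i in 1:6) {
    nbr <- which(Wd[i, ] > 0)
    others <- z[-i]
    P <- oracle_perms(5)
    I_obs <- z[i] * sum(Wd[i, nbr] * z[nbr])
    Ip <- apply(P, 1, function(idx) {
      vals <- others[idx]
      z[i] * sum(Wd[i, nbr] * vals[seq_along(nbr)])
    })
    expect_equal(li$pseudo_p[i], oracle_pseudo_p(I_obs, Ip, mean(Ip)))
    expect_equal(li$local_I[i], I_obs)
  }
})

test_that("LISA classification assigns the five cluster types", {
  g <- generate_lattice(6, 6)
  w <- build_weights(g, "row_standardised")
  ## high block in one corner, low elsewhere: block interior is high-high
  x <- rep(1, 36); x[c(1, 2, 3, 7, 8, 9, 13, 14, 15)] <- 10
  li <- classify_lisa(local_moran(x, w, n_perm = 999, seed = 1), alpha = 0.05)
  expect_equal(li$label[8], "high_high")
  expect_equal(li$quadrant[8], "HH")
  ## labels partition the areas
  expect_true(all(li$label %in% c("high_high", "low_low", "high_low",
                                  "low_high", "non_significant")))
  expect_equal(sum(table(li$label)), 36)
  ## threshold behaviour
  li2 <- classify_lisa(local_moran(x, w, n_perm = 999, seed = 1),
                       alpha = 1 / 1000)
  expect_true(all(li2$label[li2$pseudo_p > 1 / 1000] == "non_significant"))
  expect_error(classify_lisa(li, alpha = 0), "alpha")
  expect_error(classify_lisa(li, alpha = 1.2), "alpha")
})
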