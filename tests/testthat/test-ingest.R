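test_that("table reader enforces the schema and invariants", {
  g <- generate_lattice(3, 3)
  tab <- simulate_counts(simulate_covariates(g, seed = 1),
                         synthetic_truth(beta_reference(),
                                         phi = rep(0, 9), seed = 2))
  p <- file.path(tempdir(), "ingest.csv")
  write.csv(tab[, c("area_id", "child_pop", "total_pop", "asthma_count",
                    "indigenous_pct", "seifa_score", "seifa_decile")],
            p, row.names = FALSE)
  back <- read_area_table(p)
  expect_equal(back$asthma_count, tab$asthma_count)

  ## missing required column is named in the error
  write.csv(tab[, c("area_id", "child_pop", "total_pop", "asthma_count",
                    "indigenous_pct", "seifa_decile")], p, row.names = FALSE)
  expect_error(read_area_table(p), "seifa_score")

  bad <- tab
  bad$asthma_count[1] <- -1L
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_area_table(p), "negative asthma_count")

  bad <- tab
  bad$asthma_count[2] <- bad$child_pop[2] + 1L
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_area_table(p), "exceeds child_pop")
})

test_that("exclusion rules drop the right areas with logged reasons", {
  g <- generate_lattice(3, 3)
  tab <- simulate_covariates(g, seed = 1)
  tab$child_pop <- pmax(tab$child_pop, 300L)
  tab$total_pop <- pmax(tab$total_pop, 1000L)

  ## all valid and connected: identity, empty log
  ex <- apply_exclusions(tab, g)
  expect_equal(nrow(ex$table), 9)
  expect_equal(nrow(ex$log), 0)

  ## one area under the child threshold
  tab2 <- tab
  tab2$child_pop[5] <- 4L
  ex <- apply_exclusions(tab2, g)
  expect_equal(ex$log$area_id, tab2$area_id[5])
  expect_equal(ex$log$reason, "children < 5")

  ## missing SEIFA and small population
  tab3 <- tab
  tab3$seifa_score[1] <- NA
  tab3$total_pop[2] <- 150L
  ex <- apply_exclusions(tab3, g)
  expect_setequal(ex$log$reason, c("missing SEIFA", "population < 200"))

  ## chain a-b-c: ends fail the population filter, middle then isolated
  gp <- make_path_graph(3)
  tp <- data.frame(area_id = gp$ids, child_pop = c(2L, 500L, 3L),
                   total_pop = c(5000L, 5000L, 5000L),
                   asthma_count = c(0L, 30L, 0L),
                   indigenous_pct = 1, seifa_score = 1000,
                   seifa_decile = 5L)
  expect_error(apply_exclusions(tp, gp), "all areas excluded")
  gp4 <- make_path_graph(4)
  tp4 <- data.frame(area_id = gp4$ids, child_pop = c(500L, 500L, 2L, 500L),
                    total_pop = 5000L, asthma_count = 10L,
                    indigenous_pct = 1, seifa_score = 1000, seifa_decile = 5L)
  ex <- apply_exclusions(tp4, gp4)
  expect_equal(ex$log$area_id, gp4$ids[3:4])
  expect_equal(ex$log$reason, c("children < 5", "isolated"))
  expect_equal(ex$table$area_id, gp4$ids[1:2])

  ## idempotence
  ex2 <- apply_exclusions(ex$table, ex$graph)
  expect_equal(ex2$table, ex$table)
  expect_equal(nrow(ex2$log), 0)
})

test_that("derived variables follow the categorisation rules", {
  g <- make_path_graph(5)
  tab <- data.frame(area_id = g$ids, child_pop = c(100L, 200L, 400L, 100L, 50L),
                    total_pop = 2000L,
                    asthma_count = c(0L, 10L, 30L, 5L, 2L),
                    indigenous_pct = c(1, 2.08, 3, 0.5, 9),
                    seifa_score = c(900, 950, 1000, 1050, 1100),
                    seifa_decile = c(2L, 4L, 6L, 8L, 10L))
  out <- derive_analysis_variables(tab)
  ## the area exactly at the median is in the high group (inclusive rule)
  expect_equal(attr(out, "indigenous_threshold"), 2.08)
  expect_equal(as.character(out$indigenous_group),
               c("low", "high", "high", "low", "high"))
  expect_equal(as.character(out$seifa_category),
               c("most_disadvantaged", "disadvantaged", "medium",
                 "advantaged", "most_advantaged"))
  expect_equal(out$prevalence_pct[1], 0)
  expect_equal(out$prevalence_pct[2], 5)
  ## partition: exactly one category and one group per retained row
  expect_false(anyNA(out$seifa_category))
  expect_false(anyNA(out$indigenous_group))
  expect_equal(sum(table(out$seifa_category)), nrow(out))
})
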