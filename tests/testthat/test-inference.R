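# Fabricate a minimal fit object from draw matrices (for testing the
# summary/diagnostic layer without running the sampler).
fake_fit <- function(chains) {
  structure(list(chains = chains, accept = NULL, graph = NULL,
                 spec = NULL, cfg = NULL, n_records = NA_integer_),
            class = "sharedcomp_fit")
}

test_that("posterior summaries match naive sort-based oracles", {
  m <- matrix(0.7, nrow = 50, ncol = 1, dimnames = list(NULL, "alpha.mcu"))
  sm <- summarize_chains(fake_fit(list(m, m)))
  expect_equal(sm$mean, 0.7)
  expect_equal(sm$sd, 0)
  expect_equal(sm$q2.5, 0.7)
  expect_equal(sm$q97.5, 0.7)

  m2 <- matrix(log(2), 40, 1, dimnames = list(NULL, "beta_mcu.x.b"))
  sm2 <- summarize_chains(fake_fit(list(m2)))
  expect_equal(sm2$or_mean, 2.0)

  set.seed(61)
  d <- matrix(rnorm(500), 250, 2,
              dimnames = list(NULL, c("beta_mcu.x.b", "tau_V")))
  sm3 <- summarize_chains(fake_fit(list(d[1:125, ], d[126:250, ])))
  for (k in 1:2) {
    v <- sort(d[, k])
    expect_equal(sm3$q2.5[k], unname(quantile(v, 0.025)), tolerance = 1e-12)
    expect_equal(sm3$q97.5[k], unname(quantile(v, 0.975)), tolerance = 1e-12)
    expect_equal(sm3$mean[k], mean(v), tolerance = 1e-12)
  }
  # OR quantiles are the exponentiated coefficient quantiles
  expect_equal(sm3$or_q2.5[1], exp(sm3$q2.5[1]), tolerance = 1e-12)
  expect_error(summarize_chains(fake_fit(list())), "empty")
})

test_that("odds-ratio table prints reference rows as 1 and formats CIs", {
  sch <- tiny_schema()
  sm <- data.frame(param = c("beta_mcu.x.b", "beta_shk.x.b"),
                   or_mean = c(1.23456, 0.5), or_q2.5 = c(1.001, 0.25),
                   or_q97.5 = c(1.5239, 0.98765),
                   stringsAsFactors = FALSE)
  tab <- odds_ratio_table(sm, sch)
  expect_equal(tab$mcu[tab$category == "a"], "1")
  expect_equal(tab$mcu[tab$category == "b"], "1.235 (1.001, 1.524)")
  expect_equal(tab$shk[tab$category == "b"], "0.500 (0.250, 0.988)")

  # near-null coefficient formats to 1.000
  sm0 <- data.frame(param = c("beta_mcu.x.b", "beta_shk.x.b"),
                    or_mean = 1 + 1e-7, or_q2.5 = 1 - 1e-7,
                    or_q97.5 = 1 + 2e-7, stringsAsFactors = FALSE)
  expect_equal(odds_ratio_table(sm0, sch)$mcu[2], "1.000 (1.000, 1.000)")
})

test_that("district surfaces exponentiate the spatial draws", {
  labs <- c("p1", "p2")
  nm <- c("V.p1", "V.p2", "S_mcu.p1", "S_mcu.p2", "S_shk.p1", "S_shk.p2",
          "delta")
  zero <- matrix(rep(c(0, 0, 0, 0, 0, 0, 1), each = 30), 30, 7,
                 dimnames = list(NULL, nm))
  surf <- district_effect_surface(fake_fit(list(zero)))
  expect_true(all(surf[, -(1:2)] == 1))

  # delta = 1 draws: shared surface identical for the two outcomes
  set.seed(67)
  d <- matrix(rnorm(30 * 6, sd = 0.5), 30, 6)
  d <- cbind(d, 1)
  colnames(d) <- nm
  surf1 <- district_effect_surface(fake_fit(list(d)))
  m <- surf1[surf1$outcome == "mcu", ]
  s <- surf1[surf1$outcome == "shk", ]
  expect_equal(m$shared_mean, s$shared_mean, tolerance = 1e-12)

  # naive per-draw exponentiation oracle
  d[, "delta"] <- exp(rnorm(30, 0, 0.3))
  surf2 <- district_effect_surface(fake_fit(list(d)))
  tot <- exp(d[, "delta"] * d[, "V.p2"] + d[, "S_mcu.p2"])
  row <- surf2[surf2$district == "p2" & surf2$outcome == "mcu", ]
  expect_equal(row$total_mean, mean(tot), tolerance = 1e-12)
  expect_equal(row$total_q2.5, unname(quantile(tot, 0.025)),
               tolerance = 1e-12)
  expect_true(all(surf2[, -(1:2)] > 0))
})

test_that("R-hat and ESS behave on designed chains", {
  set.seed(71)
  good <- lapply(1:2, function(i)
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "a")))
  dg <- diagnostics(fake_fit(good))
  expect_lt(abs(dg$rhat - 1), 0.01)
  expect_gt(dg$ess, 200)
  expect_false(dg$flagged)

  apart <- list(matrix(rnorm(500, -5), ncol = 1, dimnames = list(NULL, "a")),
                matrix(rnorm(500, +5), ncol = 1, dimnames = list(NULL, "a")))
  dg2 <- diagnostics(fake_fit(apart))
  expect_gt(dg2$rhat, 1.1)
  expect_true(dg2$flagged)

  flat <- lapply(1:2, function(i)
    matrix(1.5, 100, 1, dimnames = list(NULL, "a")))
  expect_warning(dg3 <- diagnostics(fake_fit(flat)), "constant")
  expect_true(is.na(dg3$rhat))
  expect_equal(dg3$ess, 0)

  expect_error(diagnostics(fake_fit(good[1])), "2 chains")
  uneq <- list(good[[1]], good[[2]][1:10, , drop = FALSE])
  expect_error(diagnostics(fake_fit(uneq)), "unequal")
})

test_that("quadrature oracle recovers the logistic MLE limit and symmetry", {
  g <- path_graph(2)
  spec <- empty_spec(fixed_effect_precision = 1e-6,
                     include_shared = FALSE, include_specific = FALSE)
  # large balanced data: posterior mean of alpha ~ logit of the observed
  # proportion
  n1 <- 300; n0 <- 200
  rec <- bare_records(rep("p1", n1 + n0), c(rep(1, n1), rep(0, n0)),
                      rep(0, n1 + n0))
  orc <- quadrature_oracle(rec, g, spec, bare_state(g),
                           free = list(alpha_mcu = seq(-1, 2, length = 401)))
  expect_equal(unname(orc$mean["alpha_mcu"]), qlogis(n1 / (n1 + n0)),
               tolerance = 0.01)

  # sign-symmetric data: posterior mean ~ 0
  rec2 <- bare_records(rep("p1", 100), rep(0:1, 50), rep(0, 100))
  orc2 <- quadrature_oracle(rec2, g, spec, bare_state(g),
                            free = list(alpha_mcu = seq(-3, 3, length = 301)))
  expect_lt(abs(orc2$mean["alpha_mcu"]), 0.01)

  # doubling grid resolution barely moves the moments
  orc3 <- quadrature_oracle(rec, g, spec, bare_state(g),
                            free = list(alpha_mcu = seq(-1, 2, length = 801)))
  expect_lt(abs(orc3$mean - orc$mean), 1e-3)
  expect_lt(abs(orc3$sd - orc$sd), 1e-3)

  # boundary-mass guard
  expect_error(
    quadrature_oracle(rec, g, spec, bare_state(g),
                      free = list(alpha_mcu = seq(0.5, 0.6, length = 51))),
    "widen the grid")
})

test_that("the sampler is bitwise reproducible and validates input", {
  set.seed(1)
  g <- path_graph(3)
  rec <- bare_records(sample(g$node_ids, 90, TRUE),
                      sample(0:1, 90, TRUE), sample(0:1, 90, TRUE))
  spec <- empty_spec()
  cfg <- chain_config(n_iter = 300, burn_in = 100, seed = 5, n_chains = 2)
  f1 <- fit_mcmc(rec, g, spec, cfg)
  f2 <- fit_mcmc(rec, g, spec, cfg)
  expect_identical(f1$chains, f2$chains)

  bad <- rec; bad$district[1] <- "x"
  expect_error(fit_mcmc(bad, g, spec, cfg), "not in graph")
  const <- rec; const$y_mcu <- 1
  expect_warning(fit_mcmc(const, g, spec,
                          chain_config(n_iter = 60, burn_in = 20,
                                       n_chains = 1)),
                 "zero variance")
})

test_that("fixed parameters stay fixed and excluded blocks are dropped", {
  set.seed(2)
  g <- path_graph(3)
  rec <- bare_records(sample(g$node_ids, 60, TRUE),
                      sample(0:1, 60, TRUE), sample(0:1, 60, TRUE))
  Vfix <- c(0.4, 0, -0.4)
  cfg <- chain_config(n_iter = 200, burn_in = 50, seed = 9, n_chains = 1,
                      fixed = list(V = Vfix, delta = 1.5,
                                   S_mcu = numeric(3), S_shk = numeric(3),
                                   tau_S_mcu = 1, tau_S_shk = 1))
  f <- fit_mcmc(rec, g, empty_spec(), cfg)
  dr <- f$chains[[1]]
  expect_true(all(dr[, "V.p1"] == 0.4))
  expect_true(all(dr[, "delta"] == 1.5))
  expect_gt(var(dr[, "alpha.mcu"]), 0)   # free parameters do move
  expect_gt(var(dr[, "tau_V"]), 0)

  f2 <- fit_mcmc(rec, g, empty_spec(include_shared = FALSE,
                                    include_specific = FALSE),
                 chain_config(n_iter = 100, burn_in = 40, n_chains = 1))
  expect_equal(colnames(f2$chains[[1]]), c("alpha.mcu", "alpha.shk"))
})

test_that("chains persist to CSV and reload identically", {
  set.seed(3)
  g <- path_graph(2)
  rec <- bare_records(sample(g$node_ids, 40, TRUE),
                      sample(0:1, 40, TRUE), sample(0:1, 40, TRUE))
  f <- fit_mcmc(rec, g, empty_spec(),
                chain_config(n_iter = 120, burn_in = 40, n_chains = 2))
  dir <- tempfile()
  write_chains(f, dir)
  f2 <- read_chains(dir)
  expect_equal(length(f2$chains), 2L)
  expect_equal(colnames(f2$chains[[1]]), colnames(f$chains[[1]]))
  expect_equal(f2$chains[[1]], f$chains[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
})
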