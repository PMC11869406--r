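test_that("knowledge dichotomization follows the configured cut", {
  expect_equal(dichotomize_knowledge("Good"), 1L)
  expect_equal(dichotomize_knowledge("Poor"), 0L)
  expect_equal(dichotomize_knowledge("Moderate"), 0L)
  expect_equal(dichotomize_knowledge("Moderate", cut = "moderate"), 1L)
  expect_equal(dichotomize_knowledge(c("Poor", "Good", "Moderate")),
               c(0L, 1L, 0L))
  expect_error(dichotomize_knowledge("Excellent"), "unknown")
})

test_that("design encoding drops references and matches a naive one-hot oracle", {
  sch <- list(education = list(categories = c("None", "Primary", "Secondary+"),
                               reference = "None"))
  expect_equal(unname(encode_design(list(education = "None"), sch)), c(0, 0))
  expect_equal(unname(encode_design(list(education = "Primary"), sch)),
               c(1, 0))
  expect_error(encode_design(list(education = "PhD"), sch), "unknown category")
  expect_error(encode_design(list(), sch), "missing covariate")

  # naive oracle: full one-hot, then drop reference columns
  sch2 <- default_schema()
  naive <- function(rec) {
    out <- c()
    for (nm in names(sch2)) {
      oh <- as.numeric(sch2[[nm]]$categories == rec[[nm]])
      names(oh) <- paste(nm, sch2[[nm]]$categories, sep = ".")
      out <- c(out, oh[names(oh) != paste(nm, sch2[[nm]]$reference,
                                          sep = ".")])
    }
    out
  }
  set.seed(21)
  for (rep in 1:10) {
    rec <- lapply(sch2, function(cv) sample(cv$categories, 1))
    expect_equal(encode_design(rec, sch2), naive(rec))
  }
})

test_that("linear predictor assembles the shared-component terms", {
  g <- path_graph(3)
  st <- bare_state(g, alpha = c(0, 0))
  expect_equal(linear_predictor(st, numeric(0), 1, 1), 0)

  st2 <- bare_state(g, alpha = c(0.5, 0.5), V = c(1, 0, -1), delta = 2)
  expect_equal(linear_predictor(st2, numeric(0), 1, 1), 2.5)
  expect_equal(linear_predictor(st2, numeric(0), 1, 2), 1.0)

  # term-by-term oracle with covariates
  sch <- tiny_schema()
  set.seed(31)
  for (rep in 1:10) {
    b <- list(rnorm(1), rnorm(1))
    st3 <- latent_state(alpha = rnorm(2), beta = b,
                        V = c(0.3, -0.1, -0.2),
                        S = list(c(0.1, 0, -0.1), c(-0.2, 0.2, 0)),
                        delta = runif(1, 0.5, 2))
    x <- sample(0:1, 1)
    j <- sample(1:3, 1)
    d <- sample(1:2, 1)
    sig <- if (d == 1) st3$delta else 1 / st3$delta
    manual <- st3$alpha[[d]] + x * b[[d]] + sig * st3$V[j] + st3$S[[d]][j]
    expect_equal(linear_predictor(st3, x, j, d), manual, tolerance = 1e-12)
  }
  expect_error(linear_predictor(st2, c(1, 2), 1, 1), "does not match")
})

test_that("Bernoulli log-likelihood is the stable exponential-family form", {
  expect_equal(bernoulli_loglik(1, 0), -log(2))
  # y = 0, eta = -50: tiny but nonzero, no overflow
  v <- bernoulli_loglik(0, -50)
  expect_lt(v, 0)
  expect_equal(v, -exp(-50), tolerance = 1e-6)
  expect_true(is.finite(bernoulli_loglik(1, 700)))
  expect_true(is.finite(bernoulli_loglik(0, -700)))

  # probability-form oracle: ln[P^y (1-P)^(1-y)] with P = plogis(eta)
  set.seed(13)
  y <- sample(0:1, 200, replace = TRUE)
  eta <- rnorm(200, sd = 3)
  p <- plogis(eta)
  expect_equal(bernoulli_loglik(y, eta),
               y * log(p) + (1 - y) * log(1 - p), tolerance = 1e-10)
})

test_that("total log-likelihood sums records and outcomes", {
  g <- path_graph(3)
  st <- bare_state(g)
  sch <- setNames(list(), character(0))
  expect_equal(loglik_total(st, bare_records(character(0), integer(0),
                                             integer(0), numeric(0)),
                            g, sch), 0)
  one <- bare_records("p1", 1, 0)
  expect_equal(loglik_total(st, one, g, sch), 2 * -log(2))

  # brute-force loop oracle on 50 random records with covariates
  sch2 <- tiny_schema()
  set.seed(17)
  rec <- data.frame(district = sample(g$node_ids, 50, replace = TRUE),
                    x = sample(c("a", "b"), 50, replace = TRUE),
                    y_mcu = sample(0:1, 50, replace = TRUE),
                    y_shk = sample(0:1, 50, replace = TRUE),
                    weight = 1, stringsAsFactors = FALSE)
  st2 <- latent_state(alpha = c(0.2, -0.4), beta = list(0.7, -0.3),
                      V = c(0.3, -0.1, -0.2),
                      S = list(c(0.1, 0, -0.1), c(-0.2, 0.2, 0)),
                      delta = 1.5)
  manual <- 0
  for (i in seq_len(50)) {
    x <- encode_design(rec[i, ], sch2)
    j <- match(rec$district[i], g$node_ids)
    for (d in 1:2) {
      eta <- linear_predictor(st2, x, j, d)
      y <- rec[[c("y_mcu", "y_shk")[d]]][i]
      manual <- manual + bernoulli_loglik(y, eta)
    }
  }
  expect_equal(loglik_total(st2, rec, g, sch2), manual, tolerance = 1e-9)
  bad <- rec; bad$district[1] <- "nowhere"
  expect_error(loglik_total(st2, bad, g, sch2), "nowhere")
})

test_that("loading prior is log-normal(0, precision 0.1)", {
  expect_equal(log_prior_delta(1), -0.5 * log(20 * pi), tolerance = 1e-12)
  expect_error(log_prior_delta(-1), "positive")
  set.seed(23)
  for (d in exp(rnorm(10))) {
    expect_equal(log_prior_delta(d) - log_prior_delta(1 / d), -2 * log(d),
                 tolerance = 1e-10)
    # naive density-then-log oracle
    dens <- exp(-0.05 * log(d)^2) / (d * sqrt(2 * pi * 10))
    expect_equal(log_prior_delta(d), log(dens), tolerance = 1e-10)
  }
})

test_that("fixed-effect prior is iid Gaussian with precision tau_beta", {
  k <- 4
  expect_equal(log_prior_beta(numeric(k), 0.5), k * 0.5 * log(0.5 / (2 * pi)))
  expect_equal(log_prior_beta(1, 1), -0.5 * log(2 * pi) - 0.5)
  expect_error(log_prior_beta(0, -2), "tau_beta")
  set.seed(29)
  b <- rnorm(6)
  expect_equal(log_prior_beta(b, 2.5),
               sum(log(sqrt(2.5 / (2 * pi)) * exp(-1.25 * b^2))),
               tolerance = 1e-10)
})

test_that("PC prior has the Type-2 Gumbel form and the defining tail mass", {
  lam <- -log(0.01)
  expect_equal(pc_prior_logpdf(1), log(lam / 2) - lam, tolerance = 1e-10)
  expect_equal(pc_prior_logpdf(1), -3.771138, tolerance = 1e-5)
  expect_error(pc_prior_logpdf(-1), "positive")
  expect_error(pc_prior_logpdf(1, alpha = 2), "alpha")

  total <- integrate(function(t) exp(pc_prior_logpdf(t)), 0, Inf,
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # P(tau < 1/U^2) = P(sd > U) = alpha
  tail <- integrate(function(t) exp(pc_prior_logpdf(t, U = 1, alpha = 0.01)),
                    0, 1, rel.tol = 1e-9)$value
  expect_equal(tail, 0.01, tolerance = 1e-6)
  # literal-rate override
  expect_equal(pc_prior_logpdf(2, lambda = 0.01),
               log(0.005) - 1.5 * log(2) - 0.01 / sqrt(2), tolerance = 1e-10)
})

test_that("joint log-posterior composes its parts", {
  g <- grid_graph(2, 2)
  spec <- empty_spec()
  sc <- scale_factor(g)
  empty <- bare_records(character(0), integer(0), integer(0), numeric(0))

  # zero state, empty data: sum of prior terms only
  st <- bare_state(g)
  parts <- icar_logdensity(st$V, sc, g) * 3 +   # three zero fields, tau = 1
    log_prior_delta(1) + 3 * pc_prior_logpdf(1) +
    2 * log_prior_beta(0, 0.001)
  expect_equal(joint_log_posterior(st, empty, g, spec), parts,
               tolerance = 1e-9)

  # random states: compositional oracle
  set.seed(37)
  rec <- bare_records(sample(g$node_ids, 40, replace = TRUE),
                      sample(0:1, 40, TRUE), sample(0:1, 40, TRUE))
  for (rep in 1:5) {
    st2 <- bare_state(g, alpha = rnorm(2),
                      V = rand_centered(g), S1 = rand_centered(g),
                      S2 = rand_centered(g), delta = exp(rnorm(1, 0, 0.4)),
                      tau_V = exp(rnorm(1)), tau_S = exp(rnorm(2)))
    manual <- loglik_total(st2, rec, g, spec$covariate_schema) +
      icar_logdensity(st2$V, st2$tau_V * sc, g) +
      icar_logdensity(st2$S[[1]], st2$tau_S[1] * sc, g) +
      icar_logdensity(st2$S[[2]], st2$tau_S[2] * sc, g) +
      log_prior_delta(st2$delta) +
      pc_prior_logpdf(st2$tau_V) + sum(pc_prior_logpdf(st2$tau_S)) +
      2 * log_prior_beta(0, 0.001) +
      log_prior_beta(st2$alpha[1], 0.001) + log_prior_beta(st2$alpha[2], 0.001)
    # note: alpha prior counted once per outcome, beta vectors are empty
    manual <- manual - 2 * log_prior_beta(0, 0.001)
    expect_equal(joint_log_posterior(st2, rec, g, spec), manual,
                 tolerance = 1e-9, ignore_attr = TRUE)

    # doubling the data doubles the likelihood part exactly
    lp1 <- joint_log_posterior(st2, rec, g, spec)
    lp2 <- joint_log_posterior(st2, rbind(rec, rec), g, spec)
    expect_equal(lp2 - lp1, loglik_total(st2, rec, g, spec$covariate_schema),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("joint posterior is invariant under district relabeling", {
  g <- grid_graph(2, 3)
  spec <- empty_spec()
  set.seed(41)
  rec <- bare_records(sample(g$node_ids, 60, replace = TRUE),
                      sample(0:1, 60, TRUE), sample(0:1, 60, TRUE))
  st <- bare_state(g, alpha = c(0.3, -0.2), V = rand_centered(g),
                   S1 = rand_centered(g), S2 = rand_centered(g),
                   delta = 1.4, tau_V = 2, tau_S = c(0.7, 1.3))
  lp <- joint_log_posterior(st, rec, g, spec)

  perm <- sample(g$n_nodes)
  g2 <- build_graph(g$node_ids[perm],
                    cbind(g$node_ids[g$edges[, 1]], g$node_ids[g$edges[, 2]]))
  idx <- match(g2$node_ids, g$node_ids)
  st2 <- st
  st2$V <- st$V[idx]
  st2$S[[1]] <- st$S[[1]][idx]
  st2$S[[2]] <- st$S[[2]][idx]
  expect_equal(joint_log_posterior(st2, rec, g2, spec), lp, tolerance = 1e-9)
})

test_that("swapping outcomes and inverting the loading leaves the posterior unchanged", {
  g <- grid_graph(2, 3)
  spec <- empty_spec()
  set.seed(43)
  rec <- bare_records(sample(g$node_ids, 60, replace = TRUE),
                      sample(0:1, 60, TRUE), sample(0:1, 60, TRUE))
  st <- bare_state(g, alpha = c(0.3, -0.2), V = rand_centered(g),
                   S1 = rand_centered(g), S2 = rand_centered(g),
                   delta = 1.7, tau_V = 2, tau_S = c(0.7, 1.3))
  lp <- joint_log_posterior(st, rec, g, spec)

  rec_sw <- rec
  rec_sw$y_mcu <- rec$y_shk
  rec_sw$y_shk <- rec$y_mcu
  st_sw <- bare_state(g, alpha = rev(st$alpha), V = st$V,
                      S1 = st$S[[2]], S2 = st$S[[1]],
                      delta = 1 / st$delta, tau_V = st$tau_V,
                      tau_S = rev(st$tau_S))
  lp_sw <- joint_log_posterior(st_sw, rec_sw, g, spec)
  # the loading prior is symmetric on the log scale only up to the
  # Jacobian: lp(delta) - lp(1/delta) = -2 log(delta)
  expect_equal(lp_sw - lp, 2 * log(st$delta), tolerance = 1e-9)
})

test_that("with both spatial components off the model is two logistic regressions", {
  g <- path_graph(2)
  spec <- empty_spec(include_shared = FALSE, include_specific = FALSE)
  set.seed(47)
  rec <- bare_records(sample(g$node_ids, 30, replace = TRUE),
                      sample(0:1, 30, TRUE), sample(0:1, 30, TRUE))
  st <- bare_state(g, alpha = c(0.5, -0.5))
  lp <- joint_log_posterior(st, rec, g, spec)
  manual <- sum(bernoulli_loglik(rec$y_mcu, 0.5)) +
    sum(bernoulli_loglik(rec$y_shk, -0.5)) +
    log_prior_beta(0.5, 0.001) + log_prior_beta(-0.5, 0.001)
  expect_equal(lp, manual, tolerance = 1e-10)
})
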