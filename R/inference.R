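#' MCMC chain configuration
#'
#' @param n_iter total iterations per chain (including burn-in).
#' @param burn_in iterations discarded (and during which proposal scales
#'   adapt; adaptation is frozen afterwards so the post-burn-in kernel is a
#'   valid MCMC).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain `k` uses `seed + 1000 * (k - 1)`.
#' @param n_chains number of chains (>= 2 for split-R-hat).
#' @param target_accept Robbins-Monro target acceptance rate for the
#'   scalar random-walk updates (default 0.44).
#' @param target_block target acceptance for the joint
#'   (intercept, coefficients) block updates, which use a Haario-style
#'   adaptive proposal covariance (default 0.35).
#' @param adapt_rate,init_scale adaptation step constant and initial
#'   proposal scale.
#' @param fixed named list of parameters to hold fixed at given values
#'   (not updated). Recognised names: `alpha_mcu`, `alpha_shk`,
#'   `beta_mcu`, `beta_shk` (full vectors), `V`, `S_mcu`, `S_shk`,
#'   `delta`, `tau_V`, `tau_S_mcu`, `tau_S_shk`.
#' @param init named list of initial values for chain 1 (same names);
#'   defaults: 0 for location parameters and fields, 1 for `delta` and
#'   precisions.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 4000, burn_in = 1500, thin = 1, seed = 1,
                         n_chains = 2, target_accept = 0.44,
                         target_block = 0.35,
                         adapt_rate = 1.5, init_scale = 0.3,
                         fixed = list(), init = list()) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed), n_chains = as.integer(n_chains),
                 target_accept = target_accept,
                 target_block = target_block, adapt_rate = adapt_rate,
                 init_scale = init_scale, fixed = fixed, init = init),
            class = "chain_config")
}

# Full parameter-vector naming for a given graph/spec, matching the column
# layout emitted by the C++ sampler.
param_layout <- function(graph, spec) {
  cols <- design_colnames(spec$covariate_schema)
  lab <- graph$node_ids
  nm <- c("alpha.mcu", "alpha.shk",
          if (length(cols)) paste0("beta_mcu.", cols),
          if (length(cols)) paste0("beta_shk.", cols),
          paste0("V.", lab), paste0("S_mcu.", lab), paste0("S_shk.", lab),
          if (spec$loading_mode == "reciprocal") "delta"
          else c("sigma_mcu", "sigma_shk"),
          "tau_V", "tau_S_mcu", "tau_S_shk")
  nm
}

# Columns actually part of the model given the include switches.
active_params <- function(nm, spec) {
  keep <- rep(TRUE, length(nm))
  if (!spec$include_shared) {
    keep[grepl("^(V\\.|delta$|sigma_|tau_V$)", nm)] <- FALSE
  }
  if (!spec$include_specific) {
    keep[grepl("^(S_mcu\\.|S_shk\\.|tau_S_)", nm)] <- FALSE
  }
  keep
}

#' Fit the shared-component model by adaptive Metropolis-within-Gibbs
#'
#' Runs `cfg$n_chains` MCMC chains targeting [joint_log_posterior()].
#' Update blocks: a joint random-walk over (intercept, coefficients) per
#' outcome with Haario-style adaptive proposal covariance; single-site
#' updates of the shared field `V` and the specific fields `S_d` followed
#' by per-component recentering (the identifiability projection of the
#' intrinsic CAR); and log-scale random walks for the loading and the
#' spatial precisions. Proposal scales adapt toward `cfg$target_block`
#' (blocks) and `cfg$target_accept` (scalars) during burn-in only, so the
#' post-burn-in kernel is a valid MCMC. Chain 1 starts at a neutral
#' state (zeros; `delta` and precisions at 1); later chains start
#' overdispersed via documented seed offsets.
#'
#' @param records data frame of individual records (see
#'   [read_records_csv()]); covariates must match the model's schema.
#' @param graph a [build_graph()] object covering all record districts.
#' @param spec a [model_spec()].
#' @param cfg a [chain_config()].
#' @return Object of class `sharedcomp_fit`: list with `chains` (one draw
#'   matrix per chain, columns named like `beta_mcu.education.Primary`,
#'   `V.<district>`), `accept` (per-chain block acceptance rates), plus
#'   the graph, spec and config used.
#' @export
fit_mcmc <- function(records, graph, spec, cfg = chain_config()) {
  stopifnot(inherits(graph, "district_graph"),
            inherits(spec, "sharedcomp_spec"),
            inherits(cfg, "chain_config"))
  if (NROW(records) == 0L) stop("no records to fit")
  j <- match(as.character(records$district), graph$node_ids)
  if (anyNA(j)) {
    stop("record district(s) not in graph: ",
         paste(unique(records$district[is.na(j)]), collapse = ", "))
  }
  y <- cbind(as.integer(records$y_mcu), as.integer(records$y_shk))
  if (!all(y %in% c(0L, 1L))) stop("outcomes must be binary 0/1")
  for (d in 1:2) {
    if (stats::var(y[, d]) == 0) {
      warning("outcome '", outcome_names[d], "' has zero variance; its ",
              "coefficients will be prior-dominated")
    }
  }
  X <- build_design(records, spec$covariate_schema)
  p <- ncol(X)
  n_nodes <- graph$n_nodes
  edges0 <- graph$edges - 1L
  if (!nrow(edges0)) edges0 <- matrix(integer(0), 0, 2)
  comp0 <- graph$components - 1L
  sc <- if (nrow(graph$edges)) scale_factor(graph) else 1
  lam <- pc_lambda(spec$pc_prior)
  reciprocal <- spec$loading_mode == "reciprocal"
  n_delta <- if (reciprocal) 1L else 2L

  fx <- cfg$fixed
  upd <- function(nm) !nm %in% names(fx)
  getv <- function(nm, default) if (!is.null(fx[[nm]])) fx[[nm]] else
    if (!is.null(cfg$init[[nm]])) cfg$init[[nm]] else default

  nm_all <- param_layout(graph, spec)
  chains <- vector("list", cfg$n_chains)
  accept <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + 1000L * (ch - 1L))
    # Overdispersed starts for chains > 1 (moderate scale so finite
    # chains still mix through the high-likelihood region).
    od <- function(x, sd) if (ch == 1L) x else x + stats::rnorm(length(x), 0, sd)
    alpha0 <- c(getv("alpha_mcu", 0), getv("alpha_shk", 0))
    if (upd("alpha_mcu")) alpha0[1] <- od(alpha0[1], 1)
    if (upd("alpha_shk")) alpha0[2] <- od(alpha0[2], 1)
    beta0 <- matrix(0, p, 2)
    if (!is.null(fx$beta_mcu)) beta0[, 1] <- fx$beta_mcu
    if (!is.null(fx$beta_shk)) beta0[, 2] <- fx$beta_shk
    if (p && upd("beta_mcu")) beta0[, 1] <- od(beta0[, 1], 1)
    if (p && upd("beta_shk")) beta0[, 2] <- od(beta0[, 2], 1)
    V0 <- getv("V", numeric(n_nodes))
    S0 <- cbind(getv("S_mcu", numeric(n_nodes)),
                getv("S_shk", numeric(n_nodes)))
    if (upd("V") && ch > 1L && nrow(graph$edges)) {
      V0 <- sample_icar(graph, tau = 1)
    }
    delta0 <- rep(getv("delta", 1), length.out = n_delta)
    if (upd("delta")) delta0 <- exp(od(log(delta0), 0.5))
    tau0 <- c(getv("tau_V", 1), getv("tau_S_mcu", 1), getv("tau_S_shk", 1))
    if (ch > 1L) {
      free_tau <- c(upd("tau_V"), upd("tau_S_mcu"), upd("tau_S_shk"))
      tau0[free_tau] <- exp(log(tau0[free_tau]) +
                              stats::rnorm(sum(free_tau), 0, 0.5))
    }
    res <- run_chain_cpp(
      y, X, as.integer(j - 1L), n_nodes,
      matrix(as.integer(edges0), ncol = 2), as.integer(comp0), sc,
      spec$fixed_effect_precision,
      spec$loading_prior$mean, spec$loading_prior$precision, lam,
      spec$include_shared, spec$include_specific, reciprocal,
      c(upd("alpha_mcu"), upd("alpha_shk")),
      c(upd("beta_mcu"), upd("beta_shk")),
      upd("V"), c(upd("S_mcu"), upd("S_shk")),
      upd("delta"), upd("tau_V"), c(upd("tau_S_mcu"), upd("tau_S_shk")),
      alpha0, beta0, V0, S0, delta0, tau0,
      cfg$n_iter, cfg$burn_in, cfg$thin,
      cfg$target_accept, cfg$target_block, cfg$adapt_rate, cfg$init_scale)
    dr <- res$draws
    colnames(dr) <- nm_all
    chains[[ch]] <- dr[, active_params(nm_all, spec), drop = FALSE]
    accept[[ch]] <- res$accept
  }
  structure(list(chains = chains, accept = accept, graph = graph,
                 spec = spec, cfg = cfg, n_records = nrow(records)),
            class = "sharedcomp_fit")
}

#' @export
print.sharedcomp_fit <- function(x, ...) {
  cat("sharedcomp_fit: ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]), " draws of ", ncol(x$chains[[1]]),
      " parameters (", x$n_records, " records, ",
      x$graph$n_nodes, " districts)\n", sep = "")
  invisible(x)
}

# ---- convergence diagnostics ------------------------------------------

# Split-R-hat (each chain halved) per Gelman et al.; NA for constant draws.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[seq.int(length(x) - n2 + 1L, length(x))])
  }), recursive = FALSE)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Batch-means effective sample size (consistent and robust to slowly
# decaying autocorrelation, cf. the mcmcse approach): the Monte-Carlo
# variance of the pooled mean is estimated from the spread of batch means,
# with batches long relative to the autocorrelation time. Between-chain
# mean differences inflate the estimate (smaller ESS), which is the
# conservative direction for unconverged chains. 0 for constant draws.
ess_multi <- function(draws_by_chain, n_batches = 25L) {
  n <- min(lengths(draws_by_chain))
  draws_by_chain <- lapply(draws_by_chain, function(x) x[seq_len(n)])
  pooled_var <- stats::var(unlist(draws_by_chain))
  if (!is.finite(pooled_var) || pooled_var == 0) return(0)
  k <- min(n_batches, max(2L, n %/% 2L))
  b <- n %/% k
  bm <- unlist(lapply(draws_by_chain, function(x) {
    colMeans(matrix(x[seq_len(b * k)], nrow = b))
  }))
  v_bm <- stats::var(bm)
  if (!is.finite(v_bm) || v_bm == 0) return(length(draws_by_chain) * n)
  mcse2 <- v_bm / length(bm)
  min(pooled_var / mcse2, length(draws_by_chain) * n)
}

#' Convergence diagnostics for a fitted model
#'
#' Split-R-hat (potential scale-reduction factor with halved chains) and
#' effective sample size per parameter, flagging parameters with
#' R-hat > 1.05. Parameters with constant draws (e.g. held fixed) get
#' `NA` R-hat and ESS 0, with a warning.
#'
#' @param fit a [fit_mcmc()] result (needs >= 2 chains).
#' @return Data frame with columns `param`, `rhat`, `ess`, `flagged`.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "sharedcomp_fit") || is.list(fit))
  chains <- fit$chains
  if (length(chains) < 2L) stop("need at least 2 chains for R-hat")
  if (length(unique(vapply(chains, nrow, 0L))) != 1L) {
    stop("chains have unequal lengths")
  }
  nm <- colnames(chains[[1]])
  rhat <- ess <- numeric(length(nm))
  for (k in seq_along(nm)) {
    dk <- lapply(chains, function(m) m[, k])
    rhat[k] <- split_rhat(dk)
    ess[k] <- ess_multi(dk)
  }
  if (anyNA(rhat)) {
    warning("constant draws for: ",
            paste(nm[is.na(rhat)], collapse = ", "),
            " (R-hat undefined, ESS 0)")
  }
  data.frame(param = nm, rhat = rhat, ess = ess,
             flagged = !is.na(rhat) & rhat > 1.05,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior summaries
#'
#' Pooled posterior mean, sd and equal-tailed 95% credible interval per
#' parameter, with split-R-hat and effective sample size, and — for
#' intercepts and coefficients — the odds-ratio view obtained by applying
#' the same summaries to the exponentiated draws (so OR quantiles are the
#' exponentiated coefficient quantiles).
#'
#' @param fit a [fit_mcmc()] result.
#' @return Data frame, one row per parameter, with columns `param`,
#'   `mean`, `sd`, `q2.5`, `q97.5`, `rhat`, `ess`, `or_mean`, `or_sd`,
#'   `or_q2.5`, `or_q97.5` (OR columns `NA` for non-coefficients).
#' @export
summarize_chains <- function(fit) {
  chains <- fit$chains
  if (!length(chains) || !nrow(chains[[1]])) stop("empty chains")
  nm <- colnames(chains[[1]])
  pooled <- do.call(rbind, chains)
  qs <- t(apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  out <- data.frame(
    param = nm,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = qs[, 1], q97.5 = qs[, 2],
    rhat = NA_real_, ess = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(chains) >= 2L) {
    dg <- suppressWarnings(diagnostics(fit))
    out$rhat <- dg$rhat
    out$ess <- dg$ess
  }
  is_coef <- grepl("^(alpha\\.|beta_)", nm)
  out$or_mean <- out$or_sd <- out$or_q2.5 <- out$or_q97.5 <- NA_real_
  if (any(is_coef)) {
    ex <- exp(pooled[, is_coef, drop = FALSE])
    out$or_mean[is_coef] <- colMeans(ex)
    out$or_sd[is_coef] <- apply(ex, 2, stats::sd)
    # quantiles commute with the monotone exp transform
    out$or_q2.5[is_coef] <- exp(out$q2.5[is_coef])
    out$or_q97.5[is_coef] <- exp(out$q97.5[is_coef])
  }
  out
}

fmt3 <- function(x) formatC(round(x, 3), format = "f", digits = 3)

#' Adjusted odds-ratio table
#'
#' One row per covariate category and outcome, in the reporting style of
#' adjusted-OR tables: reference categories print the literal `"1"`,
#' non-reference categories print `"OR (q2.5, q97.5)"` rounded to three
#' decimals (round-half-even).
#'
#' @param summary result of [summarize_chains()].
#' @param schema covariate schema used in the fit.
#' @return Data frame with columns `covariate`, `category`, `mcu`, `shk`.
#' @export
odds_ratio_table <- function(summary, schema) {
  schema <- validate_schema(schema)
  rows <- list()
  for (nm in names(schema)) {
    cv <- schema[[nm]]
    for (cat in cv$categories) {
      cell <- function(outc) {
        if (cat == cv$reference) return("1")
        par <- paste0("beta_", outc, ".", nm, ".", cat)
        r <- summary[summary$param == par, , drop = FALSE]
        if (!nrow(r)) stop("summary lacks coefficient ", par)
        paste0(fmt3(r$or_mean), " (", fmt3(r$or_q2.5), ", ",
               fmt3(r$or_q97.5), ")")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = nm, category = cat,
        mcu = cell("mcu"), shk = cell("shk"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Posterior district-effect surfaces
#'
#' Per-district posterior summaries of the exponentiated spatial effects:
#' the shared surface \eqn{\exp(\sigma_d V_j)}, the specific surface
#' \eqn{\exp(S_{jd})} and the total \eqn{\exp(\sigma_d V_j + S_{jd})},
#' for each outcome. All entries are strictly positive; 1 means "at the
#' average district odds".
#'
#' @param fit a [fit_mcmc()] result.
#' @return Data frame keyed by `district` and `outcome` with columns
#'   `<surface>_mean`, `<surface>_q2.5`, `<surface>_q97.5` for surfaces
#'   `shared`, `specific`, `total`.
#' @export
district_effect_surface <- function(fit) {
  pooled <- do.call(rbind, fit$chains)
  nm <- colnames(pooled)
  labels <- sub("^V\\.", "", grep("^V\\.", nm, value = TRUE))
  if (!length(labels)) {
    labels <- sub("^S_mcu\\.", "", grep("^S_mcu\\.", nm, value = TRUE))
  }
  n_draw <- nrow(pooled)
  col_or_zero <- function(cn) {
    if (cn %in% nm) pooled[, cn] else numeric(n_draw)
  }
  sigma_draws <- function(d) {
    if ("delta" %in% nm) {
      if (d == 1) pooled[, "delta"] else 1 / pooled[, "delta"]
    } else if ("sigma_mcu" %in% nm) {
      pooled[, if (d == 1) "sigma_mcu" else "sigma_shk"]
    } else {
      rep(1, n_draw)
    }
  }
  summ <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    c(mean = mean(x), q2.5 = q[1], q97.5 = q[2])
  }
  out <- list()
  for (d in 1:2) {
    sig <- sigma_draws(d)
    for (j in seq_along(labels)) {
      v <- col_or_zero(paste0("V.", labels[j]))
      s <- col_or_zero(paste0("S_", outcome_names[d], ".", labels[j]))
      sh <- summ(exp(sig * v)); sp <- summ(exp(s)); tt <- summ(exp(sig * v + s))
      out[[length(out) + 1L]] <- data.frame(
        district = labels[j], outcome = outcome_names[d],
        shared_mean = sh[1], shared_q2.5 = sh[2], shared_q97.5 = sh[3],
        specific_mean = sp[1], specific_q2.5 = sp[2], specific_q97.5 = sp[3],
        total_mean = tt[1], total_q2.5 = tt[2], total_q97.5 = tt[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# ---- quadrature oracle -------------------------------------------------

# Assign a named scalar parameter into a latent state.
set_state_param <- function(state, name, value) {
  if (name == "alpha_mcu") state$alpha[1] <- value
  else if (name == "alpha_shk") state$alpha[2] <- value
  else if (name == "delta") state$delta <- value
  else if (name == "tau_V") state$tau_V <- value
  else if (name == "tau_S_mcu") state$tau_S[1] <- value
  else if (name == "tau_S_shk") state$tau_S[2] <- value
  else if (startsWith(name, "beta_mcu.")) {
    state$beta[[1]][sub("^beta_mcu\\.", "", name)] <- value
  } else if (startsWith(name, "beta_shk.")) {
    state$beta[[2]][sub("^beta_shk\\.", "", name)] <- value
  } else stop("unknown free parameter: ", name)
  state
}

#' Brute-force quadrature posterior for small instances
#'
#' Dense-grid integration of [joint_log_posterior()] over up to three free
#' scalar parameters, all other parameters held fixed at the supplied
#' state. Normalization is by log-sum-exp; non-uniform grids (e.g.
#' log-spaced precision grids) are handled by midpoint-width weights. The
#' total normalized mass on the boundary slices of the grid must be below
#' `boundary_tol`, otherwise an error asks for a wider grid. Serves as the
#' independent oracle for the MCMC sampler on tiny instances.
#'
#' @param records,graph,spec as in [fit_mcmc()].
#' @param state a [latent_state()] providing every fixed parameter.
#' @param free named list (length 1-3) of grid vectors; names as in
#'   [chain_config()]`$fixed` (scalar parameters only, plus
#'   `beta_<outcome>.<column>`).
#' @param boundary_tol maximum tolerated boundary mass (default 1e-6).
#' @return List with named vectors `mean` and `sd`, and the achieved
#'   `boundary_mass`.
#' @export
quadrature_oracle <- function(records, graph, spec, state, free,
                              boundary_tol = 1e-6) {
  stopifnot(is.list(free), length(free) >= 1L, length(free) <= 3L,
            !is.null(names(free)))
  grids <- lapply(free, as.numeric)
  widths <- lapply(grids, function(g) {
    if (length(g) < 2L) return(1)
    mid <- diff(g)
    c(mid[1], (mid[-length(mid)] + mid[-1]) / 2, mid[length(mid)])
  })
  pts <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  logw <- rowSums(log(as.matrix(expand.grid(widths,
                                            KEEP.OUT.ATTRS = FALSE))))
  lp <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    st <- state
    for (k in seq_along(free)) {
      st <- set_state_param(st, names(free)[k], pts[i, k])
    }
    lp[i] <- joint_log_posterior(st, records, graph, spec)
  }
  lw <- lp + logw
  lw <- lw - max(lw)
  w <- exp(lw)
  w <- w / sum(w)
  on_boundary <- rep(FALSE, nrow(pts))
  for (k in seq_along(free)) {
    g <- grids[[k]]
    if (length(g) > 1L) {
      on_boundary <- on_boundary | pts[, k] == g[1] | pts[, k] == g[length(g)]
    }
  }
  bmass <- sum(w[on_boundary])
  if (bmass > boundary_tol) {
    stop("posterior mass ", signif(bmass, 3),
         " on the grid boundary; widen the grid")
  }
  mu <- colSums(w * pts)
  sdv <- sqrt(pmax(colSums(w * pts^2) - mu^2, 0))
  names(mu) <- names(sdv) <- names(free)
  list(mean = mu, sd = sdv, boundary_mass = bmass)
}
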