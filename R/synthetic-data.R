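#' Configuration for the DHS-like synthetic data generator
#'
#' The generator draws data from the model's own generative process:
#' districts on a lattice (default a 6 x 5 grid, 30 districts), shared and
#' specific fields from the scaled ICAR prior, independent categorical
#' covariates with configurable category probabilities, two Bernoulli
#' outcomes from the shared-component linear predictor, and positive
#' survey weights (constant 1 by default, optionally log-normal to
#' exercise the weighted descriptives).
#'
#' @param graph a [build_graph()] object (default `grid_graph(6, 5)`).
#' @param n_per_district records per district (scalar or per-district
#'   vector in graph node order).
#' @param schema covariate schema ([default_schema()]).
#' @param covariate_probs named list of per-covariate category probability
#'   vectors (defaults: uniform over each covariate's categories).
#' @param alpha length-2 true intercepts (mcu, shk).
#' @param beta list of two true coefficient vectors in design-column
#'   order (defaults: all zero).
#' @param delta true shared loading (reciprocal parameterization).
#' @param tau_V,tau_S true scaled-ICAR precisions (tau_S length 2).
#' @param weight_model `list(type = "constant")` or
#'   `list(type = "lognormal", sd = <sdlog>)` (meanlog 0).
#' @param seed integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(graph = grid_graph(6, 5),
                       n_per_district = 100,
                       schema = default_schema(),
                       covariate_probs = NULL,
                       alpha = c(0, 0),
                       beta = NULL,
                       delta = 1,
                       tau_V = 1, tau_S = c(1, 1),
                       weight_model = list(type = "constant"),
                       seed = 1) {
  stopifnot(inherits(graph, "district_graph"),
            all(n_per_district >= 1), length(alpha) == 2L,
            delta > 0, tau_V > 0, all(tau_S > 0))
  schema <- validate_schema(schema)
  if (is.null(covariate_probs)) {
    covariate_probs <- lapply(schema, function(cv) {
      stats::setNames(rep(1 / length(cv$categories), length(cv$categories)),
                      cv$categories)
    })
  }
  for (nm in names(schema)) {
    pr <- covariate_probs[[nm]]
    if (is.null(pr) || length(pr) != length(schema[[nm]]$categories)) {
      stop("covariate_probs for '", nm, "' must give one probability per ",
           "category")
    }
    if (abs(sum(pr) - 1) > 1e-8) {
      stop("probabilities for '", nm, "' must sum to 1")
    }
  }
  cols <- design_colnames(schema)
  if (is.null(beta)) {
    beta <- list(stats::setNames(numeric(length(cols)), cols),
                 stats::setNames(numeric(length(cols)), cols))
  }
  stopifnot(length(beta) == 2L,
            all(lengths(beta) == length(cols)))
  weight_model$type <- match.arg(weight_model$type,
                                 c("constant", "lognormal"))
  structure(list(graph = graph,
                 n_per_district = rep(n_per_district,
                                      length.out = graph$n_nodes),
                 schema = schema, covariate_probs = covariate_probs,
                 alpha = alpha, beta = beta, delta = delta,
                 tau_V = tau_V, tau_S = tau_S,
                 weight_model = weight_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Named generator presets calibrated to published prevalence extremes
#'
#' `"uganda-like"` sets both intercepts to `qlogis(0.27)` (the highest
#' observed country prevalence of modern contraceptive use, 27%);
#' `"chad-like"` sets them to `qlogis(0.01)` (the 1% low end). These are
#' generator calibrations for testing, not reproductions of any survey
#' estimate.
#'
#' @param name `"uganda-like"` or `"chad-like"`.
#' @param ... further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
preset_sim_config <- function(name = c("uganda-like", "chad-like"), ...) {
  name <- match.arg(name)
  prev <- switch(name, "uganda-like" = 0.27, "chad-like" = 0.01)
  sim_config(alpha = rep(stats::qlogis(prev), 2), ...)
}

#' Draw the latent ground truth of a simulation
#'
#' Samples the shared field `V` and the specific fields `S_d` from the
#' scaled ICAR prior at the configured precisions and assembles them with
#' the configured fixed effects into a [latent_state()]. Deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return Object of class `sim_truth`: the generating `state`, the
#'   `graph`, and (after [simulate_records()]) realized per-district
#'   prevalences.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$graph
  has_edges <- nrow(g$edges) > 0
  V <- if (has_edges) sample_icar(g, config$tau_V) else numeric(g$n_nodes)
  S <- list(
    if (has_edges) sample_icar(g, config$tau_S[1]) else numeric(g$n_nodes),
    if (has_edges) sample_icar(g, config$tau_S[2]) else numeric(g$n_nodes))
  state <- latent_state(alpha = config$alpha, beta = config$beta,
                        V = V, S = S, delta = config$delta,
                        tau_V = config$tau_V, tau_S = config$tau_S)
  structure(list(state = state, graph = g, realized_prevalence = NULL),
            class = "sim_truth")
}

#' Simulate individual records from a ground truth
#'
#' Covariate categories are drawn independently from the configured
#' probabilities, each outcome from
#' `Bernoulli(plogis(eta))` with `eta` the shared-component linear
#' predictor at the true state, and weights from the configured weight
#' model. Deterministic given `config$seed` (a fixed offset separates the
#' record stream from the truth stream).
#'
#' @param truth a [simulate_truth()] result.
#' @param config the same [sim_config()].
#' @return Data frame of records: `district`, covariate columns, `y_mcu`,
#'   `y_shk`, `weight`.
#' @export
simulate_records <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 500000L)
  g <- config$graph
  n_j <- config$n_per_district
  district <- rep(g$node_ids, times = n_j)
  j <- rep(seq_len(g$n_nodes), times = n_j)
  n <- length(district)
  rec <- data.frame(district = district, stringsAsFactors = FALSE)
  for (nm in names(config$schema)) {
    pr <- config$covariate_probs[[nm]]
    rec[[nm]] <- sample(config$schema[[nm]]$categories, n,
                        replace = TRUE, prob = pr)
  }
  X <- build_design(rec, config$schema)
  st <- truth$state
  sig <- loadings(st, "reciprocal")
  y <- matrix(0L, n, 2)
  for (d in 1:2) {
    eta <- st$alpha[[d]] + as.vector(X %*% st$beta[[d]]) +
      sig[d] * st$V[j] + st$S[[d]][j]
    y[, d] <- stats::rbinom(n, 1, stats::plogis(eta))
  }
  rec$y_mcu <- y[, 1]
  rec$y_shk <- y[, 2]
  rec$weight <- if (config$weight_model$type == "constant") {
    rep(1, n)
  } else {
    stats::rlnorm(n, 0, config$weight_model$sd %||% 0.5)
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full dataset (records, graph, ground truth)
#'
#' Composes [simulate_truth()] and [simulate_records()] and records the
#' realized per-district prevalence of both outcomes in the truth object.
#' Optionally writes the records CSV, the adjacency edge list and the
#' truth (full latent state) as JSON into `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return List with `records`, `graph`, `truth`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  truth <- simulate_truth(config)
  records <- simulate_records(truth, config)
  agg <- function(y) {
    vapply(split(y, factor(records$district, levels = config$graph$node_ids)),
           mean, 0)
  }
  truth$realized_prevalence <- data.frame(
    district = config$graph$node_ids,
    mcu = agg(records$y_mcu), shk = agg(records$y_shk),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records_csv(records, file.path(out_dir, "records.csv"))
    write_edge_list(config$graph, file.path(out_dir, "edges.csv"))
    st <- truth$state
    jsonlite::write_json(
      list(alpha = st$alpha, beta = st$beta, V = st$V, S = st$S,
           delta = st$delta, tau_V = st$tau_V, tau_S = st$tau_S,
           realized_prevalence = truth$realized_prevalence),
      file.path(out_dir, "truth.json"), digits = NA)
  }
  list(records = records, graph = config$graph, truth = truth)
}
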