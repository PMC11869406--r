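#' Default covariate schema
#'
#' The DHS-style individual covariates used throughout the package: age
#' group, education, marital status, mass-media exposure, residence,
#' community literacy and community socio-economic level. Each covariate is
#' a named entry with its ordered category labels and reference category
#' (first label). Dummy coding always omits the reference, matching the
#' "reference row prints 1" convention of adjusted odds-ratio tables.
#'
#' @return Named list; each element has `categories` and `reference`.
#' @export
default_schema <- function() {
  sc <- list(
    age       = c("15-24", "25-34", "35+"),
    education = c("None", "Primary", "Secondary+"),
    marital   = c("NeverMarried", "CurrentlyMarried", "PreviouslyMarried"),
    media     = c("NoExposure", "Exposure"),
    residence = c("Urban", "Rural"),
    literacy  = c("Low", "Medium", "High"),
    ses       = c("Low", "Medium", "High"))
  lapply(sc, function(v) list(categories = v, reference = v[[1L]]))
}

validate_schema <- function(schema) {
  stopifnot(is.list(schema), length(names(schema)) == length(schema))
  for (nm in names(schema)) {
    cv <- schema[[nm]]
    if (!all(c("categories", "reference") %in% names(cv))) {
      stop("schema entry '", nm, "' needs 'categories' and 'reference'")
    }
    if (!cv$reference %in% cv$categories) {
      stop("reference category '", cv$reference,
           "' not among the categories of '", nm, "'")
    }
    if (anyDuplicated(cv$categories)) {
      stop("duplicate categories in '", nm, "'")
    }
  }
  schema
}

#' Model specification for the shared-component model
#'
#' Collects the covariate schema, all prior hyperparameters and the
#' parameterization switches in one object.
#'
#' @param covariate_schema see [default_schema()].
#' @param fixed_effect_precision Gaussian prior precision \eqn{\tau_\beta}
#'   for fixed effects and intercepts (default 0.001, i.e. sd ~ 31.6 on the
#'   log-odds scale: weakly informative).
#' @param loading_prior log-normal prior on the shared loading: `mean` and
#'   `precision` of \eqn{\log\delta} (defaults 0 and 0.1).
#' @param pc_prior penalised-complexity prior on each spatial precision,
#'   defined by the tail condition \eqn{P(1/\sqrt\tau > U) = \alpha};
#'   defaults `U = 1`, `alpha = 0.01`. Supply `lambda` to set the rate
#'   directly instead of deriving it as \eqn{-\log(\alpha)/U}.
#' @param loading_mode `"reciprocal"` (default; \eqn{\sigma_1 = \delta},
#'   \eqn{\sigma_2 = 1/\delta}, identifiable) or `"free"` (two independent
#'   log-normal loadings; weakly identified, use with care).
#' @param include_shared,include_specific include the shared field
#'   \eqn{V} and/or the outcome-specific fields \eqn{S_d}. With both off
#'   the model reduces to two independent Bayesian logistic regressions.
#' @param knowledge_cut where to dichotomize the three-level knowledge
#'   variable: `"good"` (default; Good vs Poor/Moderate) or `"moderate"`
#'   (Moderate/Good vs Poor).
#' @return Object of class `sharedcomp_spec`.
#' @export
model_spec <- function(covariate_schema = default_schema(),
                       fixed_effect_precision = 0.001,
                       loading_prior = list(mean = 0, precision = 0.1),
                       pc_prior = list(U = 1, alpha = 0.01, lambda = NULL),
                       loading_mode = c("reciprocal", "free"),
                       include_shared = TRUE,
                       include_specific = TRUE,
                       knowledge_cut = c("good", "moderate")) {
  loading_mode <- match.arg(loading_mode)
  knowledge_cut <- match.arg(knowledge_cut)
  stopifnot(fixed_effect_precision > 0, loading_prior$precision > 0)
  if (is.null(pc_prior$lambda)) {
    stopifnot(pc_prior$U > 0, pc_prior$alpha > 0, pc_prior$alpha < 1)
  } else {
    stopifnot(pc_prior$lambda > 0)
  }
  structure(
    list(covariate_schema = validate_schema(covariate_schema),
         fixed_effect_precision = fixed_effect_precision,
         loading_prior = loading_prior,
         pc_prior = pc_prior,
         loading_mode = loading_mode,
         include_shared = isTRUE(include_shared),
         include_specific = isTRUE(include_specific),
         knowledge_cut = knowledge_cut),
    class = "sharedcomp_spec")
}

# PC-prior rate: lambda = -log(alpha)/U unless fixed directly.
pc_lambda <- function(pc) {
  if (!is.null(pc$lambda)) pc$lambda else -log(pc$alpha) / pc$U
}

outcome_names <- c("mcu", "shk")

#' Dichotomize the three-level sexual health knowledge variable
#'
#' Knowledge is graded Poor / Moderate / Good; the Bernoulli model needs a
#' binary outcome. The default codes Good as 1 (comprehensive knowledge);
#' `cut = "moderate"` codes Moderate and Good as 1.
#'
#' @param level character vector of levels among Poor, Moderate, Good.
#' @param cut `"good"` (default) or `"moderate"`.
#' @return Integer vector of 0/1.
#' @export
dichotomize_knowledge <- function(level, cut = c("good", "moderate")) {
  cut <- match.arg(cut)
  ok <- c("Poor", "Moderate", "Good")
  bad <- setdiff(unique(as.character(level)), ok)
  if (length(bad)) {
    stop("unknown knowledge level(s): ", paste(bad, collapse = ", "))
  }
  thr <- if (cut == "good") "Good" else c("Moderate", "Good")
  as.integer(as.character(level) %in% thr)
}

# Names of the dummy columns in fixed, documented order:
# <covariate>.<category> for every non-reference category, covariates in
# schema order, categories in declared order.
design_colnames <- function(schema) {
  unlist(lapply(names(schema), function(nm) {
    cv <- schema[[nm]]
    keep <- setdiff(cv$categories, cv$reference)
    keep <- cv$categories[cv$categories %in% keep]   # declared order
    paste(nm, keep, sep = ".")
  }), use.names = FALSE)
}

#' Dummy-encode one individual record
#'
#' Reference-category dummy coding: one indicator per non-reference
#' category, covariates in schema order, reference omitted, so a record at
#' the reference level of every covariate maps to the zero vector.
#'
#' @param record named list or one-row data frame with one entry per
#'   schema covariate.
#' @param schema covariate schema ([default_schema()]).
#' @return Named numeric vector of indicators.
#' @export
encode_design <- function(record, schema) {
  schema <- validate_schema(schema)
  rec <- as.list(record)
  out <- numeric(0)
  for (nm in names(schema)) {
    cv <- schema[[nm]]
    if (is.null(rec[[nm]]) || is.na(rec[[nm]])) {
      stop("record is missing covariate '", nm, "'")
    }
    val <- as.character(rec[[nm]])
    if (!val %in% cv$categories) {
      stop("unknown category '", val, "' for covariate '", nm, "' (record: ",
           paste(utils::head(unlist(rec), 8), collapse = ","), ")")
    }
    keep <- cv$categories[cv$categories != cv$reference]
    out <- c(out, as.numeric(keep == val))
  }
  names(out) <- design_colnames(schema)
  out
}

# Vectorized design matrix for a records data frame (rows x dummies).
build_design <- function(records, schema) {
  schema <- validate_schema(schema)
  cols <- design_colnames(schema)
  X <- matrix(0, nrow(records), length(cols), dimnames = list(NULL, cols))
  j <- 0L
  for (nm in names(schema)) {
    cv <- schema[[nm]]
    if (!nm %in% names(records)) stop("records lack covariate column '", nm, "'")
    val <- as.character(records[[nm]])
    bad <- setdiff(unique(val), cv$categories)
    if (length(bad)) {
      stop("unknown category '", bad[[1L]], "' for covariate '", nm, "'")
    }
    for (cat in cv$categories[cv$categories != cv$reference]) {
      j <- j + 1L
      X[, j] <- as.numeric(val == cat)
    }
  }
  X
}

#' Latent state of the shared-component model
#'
#' Bundles every model unknown: per-outcome intercepts and coefficient
#' vectors, the shared field `V`, the specific fields `S`, the shared
#' loading `delta` and the three spatial precisions.
#'
#' @param alpha numeric length-2 intercepts (mcu, shk).
#' @param beta list of two coefficient vectors named as the design columns.
#' @param V shared spatial field over districts (sum-to-zero per component).
#' @param S list of two specific fields (same constraint).
#' @param delta positive loading; scalar in reciprocal mode
#'   (\eqn{\sigma_1 = \delta, \sigma_2 = 1/\delta}), length-2
#'   \eqn{(\sigma_1, \sigma_2)} in free mode.
#' @param tau_V,tau_S positive precisions (`tau_S` length 2).
#' @return Object of class `sharedcomp_state`.
#' @export
latent_state <- function(alpha, beta, V, S, delta = 1,
                         tau_V = 1, tau_S = c(1, 1)) {
  stopifnot(length(alpha) == 2L, is.list(beta), length(beta) == 2L,
            is.list(S), length(S) == 2L,
            all(delta > 0), tau_V > 0, all(tau_S > 0), length(tau_S) == 2L)
  names(alpha) <- outcome_names
  names(beta) <- outcome_names
  names(S) <- outcome_names
  names(tau_S) <- outcome_names
  structure(list(alpha = alpha, beta = beta, V = V, S = S, delta = delta,
                 tau_V = tau_V, tau_S = tau_S),
            class = "sharedcomp_state")
}

# Loadings (sigma_1, sigma_2) under the configured parameterization.
loadings <- function(state, loading_mode = "reciprocal") {
  if (loading_mode == "reciprocal") {
    c(state$delta[[1L]], 1 / state$delta[[1L]])
  } else {
    if (length(state$delta) != 2L) stop("free mode needs two loadings")
    as.numeric(state$delta)
  }
}

#' Linear predictor of the shared-component model
#'
#' \deqn{\eta_{ijd} = \alpha_d + x_i^T \beta_d + \sigma_d V_j + S_{jd}}
#' with \eqn{\sigma_1 = \delta} and \eqn{\sigma_2 = 1/\delta} in the
#' reciprocal loading mode.
#'
#' @param state a [latent_state()].
#' @param x design vector from [encode_design()].
#' @param district_index 1-based district index into `V`/`S`.
#' @param outcome_d 1 (contraceptive use) or 2 (health knowledge).
#' @param loading_mode `"reciprocal"` or `"free"`.
#' @return Scalar log-odds.
#' @export
linear_predictor <- function(state, x, district_index, outcome_d,
                             loading_mode = "reciprocal") {
  stopifnot(outcome_d %in% c(1L, 2L))
  beta <- state$beta[[outcome_d]]
  if (length(beta) != length(x)) {
    stop("design vector length ", length(x), " does not match ",
         length(beta), " coefficients")
  }
  if (district_index < 1L || district_index > length(state$V)) {
    stop("district_index out of range")
  }
  sig <- loadings(state, loading_mode)[outcome_d]
  state$alpha[[outcome_d]] + sum(x * beta) +
    sig * state$V[[district_index]] + state$S[[outcome_d]][[district_index]]
}

#' Bernoulli log-likelihood on the logit scale
#'
#' Exponential-family form \eqn{y\eta - \log(1 + e^\eta)}, evaluated
#' stably for large \eqn{|\eta|} (no overflow up to |eta| ~ 700 and
#' beyond).
#'
#' @param y 0/1 outcome (vectorized).
#' @param eta log-odds (vectorized).
#' @return Log-likelihood value(s).
#' @export
bernoulli_loglik <- function(y, eta) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  # log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
  y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
}

#' Total Bernoulli log-likelihood over all records and both outcomes
#'
#' @param state a [latent_state()].
#' @param records data frame with `district`, covariate columns, `y_mcu`,
#'   `y_shk` (see [read_records_csv()]).
#' @param graph a [build_graph()] object covering all record districts.
#' @param schema covariate schema.
#' @param loading_mode `"reciprocal"` or `"free"`.
#' @return Scalar log-likelihood; 0 for an empty record set.
#' @export
loglik_total <- function(state, records, graph, schema,
                         loading_mode = "reciprocal") {
  if (NROW(records) == 0L) return(0)
  j <- match(as.character(records$district), graph$node_ids)
  if (anyNA(j)) {
    stop("record district(s) not in graph: ",
         paste(unique(records$district[is.na(j)]), collapse = ", "))
  }
  X <- build_design(records, schema)
  sig <- loadings(state, loading_mode)
  total <- 0
  y <- cbind(records$y_mcu, records$y_shk)
  for (d in 1:2) {
    eta <- state$alpha[[d]] + as.vector(X %*% state$beta[[d]]) +
      sig[d] * state$V[j] + state$S[[d]][j]
    total <- total + sum(bernoulli_loglik(y[, d], eta))
  }
  total
}

#' Log-normal prior for the shared loading
#'
#' \eqn{\log\delta \sim N(\mu, 1/\kappa)} so the density of \eqn{\delta}
#' itself picks up the Jacobian \eqn{1/\delta}. Defaults mean 0 and
#' precision 0.1.
#'
#' @param delta positive loading value(s).
#' @param mean,precision hyperparameters of the normal on the log scale.
#' @return Log-density.
#' @export
log_prior_delta <- function(delta, mean = 0, precision = 0.1) {
  if (any(delta <= 0)) stop("delta must be positive")
  stats::dlnorm(delta, meanlog = mean, sdlog = 1 / sqrt(precision),
                log = TRUE)
}

#' Gaussian prior for fixed effects
#'
#' Independent \eqn{N(0, 1/\tau_\beta)} on each coefficient (and on each
#' intercept, treated as a length-1 coefficient vector).
#'
#' @param beta coefficient vector.
#' @param tau_beta positive prior precision.
#' @return Scalar log-density (sum over elements); 0 for an empty vector.
#' @export
log_prior_beta <- function(beta, tau_beta) {
  if (!is.numeric(tau_beta) || tau_beta <= 0) stop("tau_beta must be > 0")
  if (!length(beta)) return(0)
  sum(stats::dnorm(beta, sd = 1 / sqrt(tau_beta), log = TRUE))
}

#' Penalised-complexity prior on a precision
#'
#' The PC prior for the precision of a Gaussian random effect, a Type-2
#' Gumbel density
#' \deqn{\pi(\tau) = \frac{\lambda}{2}\, \tau^{-3/2}
#'   e^{-\lambda \tau^{-1/2}},}
#' with rate \eqn{\lambda = -\log(\alpha)/U} chosen so that
#' \eqn{P(1/\sqrt{\tau} > U) = \alpha}: the prior standard deviation of the
#' effect exceeds `U` with small probability `alpha`.
#'
#' @param tau positive precision value(s).
#' @param U,alpha tail definition (defaults 1 and 0.01).
#' @param lambda optional direct rate, overriding `U`/`alpha`.
#' @return Log-density.
#' @export
pc_prior_logpdf <- function(tau, U = 1, alpha = 0.01, lambda = NULL) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (is.null(lambda)) {
    if (alpha <= 0 || alpha >= 1 || U <= 0) {
      stop("need U > 0 and alpha in (0,1)")
    }
    lambda <- -log(alpha) / U
  }
  log(lambda / 2) - 1.5 * log(tau) - lambda / sqrt(tau)
}

#' Joint log-posterior of the shared-component model
#'
#' Assembles likelihood and all prior terms: the Bernoulli likelihood over
#' both outcomes, scaled-ICAR densities for the shared and specific fields
#' (precision `scale_factor(graph) * tau`), the log-normal loading prior,
#' Gaussian priors on intercepts and coefficients, and PC priors on each
#' active spatial precision. Normalising constants that do not involve any
#' unknown are dropped. This pure-R evaluation is the reference density the
#' MCMC sampler targets and the quadrature oracle integrates.
#'
#' @param state a [latent_state()].
#' @param records records data frame (may be empty).
#' @param graph a [build_graph()] object.
#' @param spec a [model_spec()].
#' @return Finite scalar log-posterior (up to a constant).
#' @export
joint_log_posterior <- function(state, records, graph, spec) {
  stopifnot(inherits(spec, "sharedcomp_spec"))
  lp <- loglik_total(state, records, graph, spec$covariate_schema,
                     spec$loading_mode)
  sc <- if (nrow(graph$edges)) scale_factor(graph) else 1
  if (spec$include_shared) {
    lp <- lp + icar_logdensity(state$V, state$tau_V * sc, graph) +
      sum(log_prior_delta(state$delta,
                          mean = spec$loading_prior$mean,
                          precision = spec$loading_prior$precision)) +
      pc_prior_logpdf(state$tau_V, spec$pc_prior$U, spec$pc_prior$alpha,
                      spec$pc_prior$lambda)
  }
  if (spec$include_specific) {
    for (d in 1:2) {
      lp <- lp + icar_logdensity(state$S[[d]], state$tau_S[[d]] * sc, graph) +
        pc_prior_logpdf(state$tau_S[[d]], spec$pc_prior$U,
                        spec$pc_prior$alpha, spec$pc_prior$lambda)
    }
  }
  for (d in 1:2) {
    lp <- lp + log_prior_beta(state$beta[[d]], spec$fixed_effect_precision) +
      log_prior_beta(state$alpha[[d]], spec$fixed_effect_precision)
  }
  lp
}
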