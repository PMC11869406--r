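# Shared fixtures and independent oracles for the test suite.

path_graph <- function(n) {
  ids <- paste0("p", seq_len(n))
  if (n == 1L) return(build_graph(ids, NULL))
  build_graph(ids, cbind(ids[-n], ids[-1]))
}

# Independent dense Laplacian: built from scratch via pairwise adjacency
# lookup, not via the package's edge bookkeeping.
oracle_laplacian <- function(graph) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    A[i, j] <- A[j, i] <- 1
  }
  diag(rowSums(A)) - A
}

# Centered random field (per-component sum-to-zero).
rand_centered <- function(graph) {
  s <- rnorm(graph$n_nodes)
  m <- tapply(s, graph$components, mean)
  s - m[graph$components]
}

# Minimal single-covariate schema for small fitting problems.
tiny_schema <- function() {
  list(x = list(categories = c("a", "b"), reference = "a"))
}

# Records with no covariates at all (empty schema).
bare_records <- function(district, y_mcu, y_shk, weight = 1) {
  data.frame(district = district, y_mcu = y_mcu, y_shk = y_shk,
             weight = weight, stringsAsFactors = FALSE)
}

empty_spec <- function(...) {
  model_spec(covariate_schema = setNames(list(), character(0)), ...)
}

# Latent state with empty coefficient vectors over a given graph.
bare_state <- function(graph, alpha = c(0, 0), V = NULL, S1 = NULL,
                       S2 = NULL, delta = 1, tau_V = 1, tau_S = c(1, 1)) {
  z <- numeric(graph$n_nodes)
  latent_state(alpha = alpha,
               beta = list(numeric(0), numeric(0)),
               V = if (is.null(V)) z else V,
               S = list(if (is.null(S1)) z else S1,
                        if (is.null(S2)) z else S2),
               delta = delta, tau_V = tau_V, tau_S = tau_S)
}

# Monte-Carlo standard error of a posterior mean from a fit summary row.
mcse_mean <- function(row) row$sd / sqrt(max(row$ess, 1))
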