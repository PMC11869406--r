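#' District adjacency graphs
#'
#' A `district_graph` is the lattice on which every intrinsic CAR (Besag)
#' prior in the package lives: an ordered set of district labels plus a
#' symmetric, deduplicated edge set. Connected components are computed at
#' construction time because the ICAR prior is rank-deficient by one per
#' component and every sum-to-zero constraint is applied per component.
#'
#' @param node_ids character vector of unique district labels. Vector order
#'   fixes the index order of every field defined on the graph.
#' @param edge_pairs two-column matrix or data frame of district labels, one
#'   adjacency per row (orientation and duplicates are ignored).
#' @return An object of class `district_graph` with elements `node_ids`,
#'   `edges` (two-column integer matrix, `from < to`), `n_nodes`, and
#'   `components` (integer component membership, 1-based).
#' @examples
#' g <- build_graph(c("A", "B", "C"), rbind(c("A", "B"), c("B", "A")))
#' g$n_nodes
#' @export
build_graph <- function(node_ids, edge_pairs) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) {
    stop("duplicate district labels: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  }
  if (length(node_ids) == 0L) stop("at least one district is required")
  if (is.null(edge_pairs) || NROW(edge_pairs) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    ep <- as.matrix(edge_pairs)
    if (ncol(ep) != 2L) stop("edge_pairs must have two columns")
    a <- match(as.character(ep[, 1L]), node_ids)
    b <- match(as.character(ep[, 2L]), node_ids)
    bad <- c(as.character(ep[, 1L])[is.na(a)], as.character(ep[, 2L])[is.na(b)])
    if (length(bad)) {
      stop("edge endpoint(s) not among node_ids: ",
           paste(unique(bad), collapse = ", "))
    }
    if (any(a == b)) {
      stop("self-loop on district ", node_ids[a[which(a == b)[1L]]])
    }
    edges <- cbind(pmin(a, b), pmax(a, b))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  g <- structure(
    list(node_ids = node_ids,
         edges = edges,
         n_nodes = length(node_ids),
         components = integer(length(node_ids))),
    class = "district_graph")
  g$components <- graph_components(g)
  g
}

# Union-find over the edge list; labels components 1..k in order of first
# appearance so the partition is stable under node order.
graph_components <- function(graph) {
  n <- graph$n_nodes
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      ri <- find(graph$edges[k, 1L]); rj <- find(graph$edges[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' @export
print.district_graph <- function(x, ...) {
  cat("district_graph: ", x$n_nodes, " districts, ", nrow(x$edges),
      " adjacencies, ", max(x$components), " component(s)\n", sep = "")
  invisible(x)
}

#' Rectangular grid of districts with rook adjacency
#'
#' Convenience generator of synthetic district lattices: districts are the
#' cells of an `nrows` by `ncols` grid, adjacent when they share a side
#' (rook contiguity, no diagonals). Labels are `d<row>_<col>`.
#'
#' @param nrows,ncols positive integers.
#' @return A [build_graph()] object with `nrows * ncols` districts.
#' @examples
#' grid_graph(2, 2)
#' @export
grid_graph <- function(nrows, ncols) {
  if (length(nrows) != 1L || length(ncols) != 1L ||
      is.na(nrows) || is.na(ncols) || nrows < 1 || ncols < 1 ||
      nrows != floor(nrows) || ncols != floor(ncols)) {
    stop("nrows and ncols must be positive integers")
  }
  ids <- outer(seq_len(nrows), seq_len(ncols),
               function(r, c) sprintf("d%d_%d", r, c))
  ids <- as.vector(ids)          # column-major, matching R matrix layout
  idx <- matrix(seq_len(nrows * ncols), nrows, ncols)
  edges <- NULL
  if (nrows > 1) {
    edges <- rbind(edges, cbind(as.vector(idx[-nrows, , drop = FALSE]),
                                as.vector(idx[-1, , drop = FALSE])))
  }
  if (ncols > 1) {
    edges <- rbind(edges, cbind(as.vector(idx[, -ncols, drop = FALSE]),
                                as.vector(idx[, -1, drop = FALSE])))
  }
  if (is.null(edges)) {
    build_graph(ids, NULL)
  } else {
    build_graph(ids, cbind(ids[edges[, 1L]], ids[edges[, 2L]]))
  }
}

#' ICAR pairwise-difference quadratic form
#'
#' Computes \eqn{Q(s) = \sum_{i \sim j} (s_i - s_j)^2} over unordered
#' adjacent district pairs, the kernel of the intrinsic CAR prior. Equals
#' \eqn{s^T (D - A) s} for the graph Laplacian (degree diagonal `D`,
#' adjacency indicator `A`).
#'
#' @param s numeric vector, one value per district in graph order.
#' @param graph a [build_graph()] object.
#' @return Non-negative scalar.
#' @export
icar_quadratic_form <- function(s, graph) {
  stopifnot(inherits(graph, "district_graph"))
  if (length(s) != graph$n_nodes) {
    stop("length(s) = ", length(s), " but graph has ", graph$n_nodes,
         " districts")
  }
  if (!nrow(graph$edges)) return(0)
  d <- s[graph$edges[, 1L]] - s[graph$edges[, 2L]]
  sum(d * d)
}

# Dense graph Laplacian D - A; used by the scale factor, the eigen-based
# sampler and as the oracle target in tests.
graph_laplacian <- function(graph) {
  n <- graph$n_nodes
  L <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1L]; j <- graph$edges[k, 2L]
      L[i, j] <- L[i, j] - 1
      L[j, i] <- L[j, i] - 1
      L[i, i] <- L[i, i] + 1
      L[j, j] <- L[j, j] + 1
    }
  }
  L
}

#' Intrinsic CAR log-density
#'
#' Rank-aware log-density of the Besag ICAR prior,
#' \deqn{\log \pi(s \mid \tau) = \frac{n - c}{2} \log \tau
#'       - \frac{\tau}{2} \sum_{i \sim j} (s_i - s_j)^2,}
#' where `c` is the number of connected components (the rank deficiency of
#' the Laplacian). The \eqn{\tau}-independent normalising constant (the
#' log pseudo-determinant of the Laplacian and the \eqn{2\pi} term) is
#' dropped by convention; the \eqn{\tau}-dependent term is kept so that
#' precision hyperparameters have correct posteriors. `s` must satisfy the
#' per-component sum-to-zero constraint.
#'
#' @param s numeric vector over districts, centered within each component.
#' @param tau positive precision.
#' @param graph a [build_graph()] object.
#' @param tol tolerance for the sum-to-zero check.
#' @return Scalar log-density (up to a constant not involving `tau`).
#' @export
icar_logdensity <- function(s, tau, graph, tol = 1e-8) {
  stopifnot(inherits(graph, "district_graph"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  if (length(s) != graph$n_nodes) stop("length(s) must equal n_nodes")
  comp_sums <- tapply(s, graph$components, sum)
  if (any(abs(comp_sums) > tol * max(1, max(abs(s))))) {
    stop("s violates the per-component sum-to-zero constraint")
  }
  n <- graph$n_nodes
  c_n <- max(graph$components)
  (n - c_n) / 2 * log(tau) - tau / 2 * icar_quadratic_form(s, graph)
}

# Constrained generalized inverse of the Laplacian: eigendecompose, invert
# the non-null eigenvalues. The null space is spanned by per-component
# indicators, so this is the covariance of the sum-to-zero constrained ICAR
# at tau = 1.
laplacian_pseudoinverse <- function(graph, eigen_tol = 1e-9) {
  L <- graph_laplacian(graph)
  e <- eigen(L, symmetric = TRUE)
  keep <- e$values > eigen_tol * max(e$values, 1)
  if (!any(keep)) return(matrix(0, graph$n_nodes, graph$n_nodes))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

#' Variance scaling factor of the ICAR prior
#'
#' The marginal variances of the constrained ICAR depend on the graph, so a
#' precision hyperprior calibrated on one graph means something different on
#' another. Scaling fixes this: with `c = scale_factor(graph)` the scaled
#' prior uses precision `c * tau * (D - A)`, which makes the geometric mean
#' of the marginal variances equal `1/tau` on every graph. `c` is the
#' geometric mean of the diagonal of the constrained generalized inverse of
#' the Laplacian; isolated districts carry no spatial structure and are
#' excluded from the mean.
#'
#' @param graph a [build_graph()] object with at least one adjacency.
#' @return Positive scalar.
#' @export
scale_factor <- function(graph) {
  stopifnot(inherits(graph, "district_graph"))
  if (!nrow(graph$edges)) {
    stop("graph has no adjacencies: no spatial structure to scale")
  }
  d <- diag(laplacian_pseudoinverse(graph))
  deg <- tabulate(c(graph$edges), nbins = graph$n_nodes)
  d <- d[deg > 0]                       # isolated districts excluded
  exp(mean(log(d)))
}

#' Draw from the (scaled) intrinsic CAR prior
#'
#' Samples the constrained ICAR distribution by drawing independent normals
#' along the non-null eigenvectors of the Laplacian with variances
#' \eqn{1/(\tau \lambda_k)} (or \eqn{1/(c \tau \lambda_k)} when `scaled`),
#' then centering each connected component. Isolated districts are set to 0.
#' Uses R's RNG stream, so `set.seed()` (or the `seed` argument) makes
#' draws reproducible.
#'
#' @param graph a [build_graph()] object.
#' @param tau positive precision.
#' @param scaled if `TRUE` (default) use the scaled-ICAR convention so the
#'   geometric-mean marginal variance is `1/tau`.
#' @param seed optional integer seed applied before the draw.
#' @return Numeric vector over districts, each component summing to zero.
#' @export
sample_icar <- function(graph, tau, scaled = TRUE, seed = NULL) {
  stopifnot(inherits(graph, "district_graph"))
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n_nodes
  if (!nrow(graph$edges)) return(numeric(n))
  prec <- tau * if (scaled) scale_factor(graph) else 1
  e <- eigen(graph_laplacian(graph), symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values, 1)
  z <- stats::rnorm(sum(keep), sd = 1 / sqrt(prec * e$values[keep]))
  s <- as.vector(e$vectors[, keep, drop = FALSE] %*% z)
  center_components(s, graph)
}

# Enforce the per-component sum-to-zero constraint by centering.
center_components <- function(s, graph) {
  means <- tapply(s, graph$components, mean)
  s - means[graph$components]
}

#' Read a district adjacency edge list
#'
#' Plain-text/CSV file with header `district_a,district_b`, one adjacency
#' per line; lines starting with `#` are ignored. Labels must match the
#' records file used alongside the graph.
#'
#' @param path file path.
#' @param node_ids optional full label set (so districts with no neighbours
#'   are retained); defaults to the labels present in the file.
#' @return A [build_graph()] object.
#' @export
read_edge_list <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "character", strip.white = TRUE)
  if (!all(c("district_a", "district_b") %in% names(df))) {
    stop("edge list must have header 'district_a,district_b'; got: ",
         paste(names(df), collapse = ","))
  }
  if (is.null(node_ids)) {
    node_ids <- unique(c(df$district_a, df$district_b))
  }
  build_graph(node_ids, cbind(df$district_a, df$district_b))
}

#' Write a district adjacency edge list
#'
#' @param graph a [build_graph()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "district_graph"))
  df <- data.frame(district_a = graph$node_ids[graph$edges[, 1L]],
                   district_b = graph$node_ids[graph$edges[, 2L]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
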