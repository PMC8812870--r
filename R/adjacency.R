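#' Adjacency graphs for spatial priors
#'
#' An `adjacency_graph` records the neighbour relation used by the intrinsic
#' autoregressive (IAR) prior on the logit prior inclusion probabilities:
#' `n_nodes` predictors/locations and an undirected edge set with each
#' unordered pair stored once. Node indices are 1-based.
#'
#' @param n_nodes Positive integer, number of predictors/locations.
#' @param edges Two-column integer matrix of node index pairs (1-based),
#'   one row per undirected edge. Zero rows give an edgeless graph.
#'
#' @return An object of class `adjacency_graph` with elements `n_nodes`
#'   and `edges` (a two-column integer matrix with `edges[, 1] < edges[, 2]`).
#' @export
#' @examples
#' g <- adjacency_graph(3, rbind(c(1, 2), c(2, 3)))
#' g$n_nodes
adjacency_graph <- function(n_nodes, edges) {
  if (length(n_nodes) != 1L || !is.finite(n_nodes) || n_nodes < 1 ||
      n_nodes != round(n_nodes)) {
    rlang::abort("`n_nodes` must be a single positive integer.")
  }
  n_nodes <- as.integer(n_nodes)
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2L)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) {
    rlang::abort("`edges` must have two columns (node index pairs).")
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0L) {
    if (anyNA(edges) || any(edges < 1L) || any(edges > n_nodes)) {
      rlang::abort("Edge indices must lie in [1, n_nodes].")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      rlang::abort("Self-loops are not allowed.")
    }
    # store each unordered pair once, smaller index first
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(edges)) {
      rlang::abort("Duplicate edges are not allowed.")
    }
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  colnames(edges) <- c("i", "j")
  structure(list(n_nodes = n_nodes, edges = edges),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> ", x$n_nodes, " nodes, ",
      nrow(x$edges), " undirected edges\n", sep = "")
  dims <- attr(x, "lattice_dim")
  if (!is.null(dims)) {
    cat("  lattice ", dims[1L], " x ", dims[2L], " (",
        attr(x, "scheme"), ")\n", sep = "")
  }
  invisible(x)
}

#' Regular 2-D lattice adjacency
#'
#' Builds the neighbour graph of an `n_rows` by `n_cols` lattice with nodes
#' indexed in row-major order (node of row r, column c is
#' `(r - 1) * n_cols + c`). The `rook` scheme connects horizontal and
#' vertical neighbours; `queen` additionally connects diagonal neighbours.
#' This is the graph used for simulated predictor images, matching their
#' row-major vectorisation.
#'
#' @param n_rows,n_cols Positive integers, the lattice dimensions.
#' @param scheme `"rook"` (4-neighbour, the default) or `"queen"`
#'   (8-neighbour).
#' @return An [adjacency_graph] carrying `lattice_dim` and `scheme`
#'   attributes.
#' @export
#' @examples
#' lattice_adjacency(2, 2)          # 4 edges
#' lattice_adjacency(3, 3, "queen") # 12 rook edges + 8 diagonals
lattice_adjacency <- function(n_rows, n_cols, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      !is.finite(n_rows) || !is.finite(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    rlang::abort("`n_rows` and `n_cols` must be single positive integers.")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  idx <- function(r, c) (r - 1L) * n_cols + c
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  e <- list()
  right <- cols < n_cols
  e$h <- cbind(idx(rows[right], cols[right]), idx(rows[right], cols[right] + 1L))
  down <- rows < n_rows
  e$v <- cbind(idx(rows[down], cols[down]), idx(rows[down] + 1L, cols[down]))
  if (scheme == "queen") {
    dr <- rows < n_rows & cols < n_cols
    e$d1 <- cbind(idx(rows[dr], cols[dr]), idx(rows[dr] + 1L, cols[dr] + 1L))
    dl <- rows < n_rows & cols > 1L
    e$d2 <- cbind(idx(rows[dl], cols[dl]), idx(rows[dl] + 1L, cols[dl] - 1L))
  }
  g <- adjacency_graph(n_rows * n_cols, do.call(rbind, e))
  attr(g, "lattice_dim") <- c(n_rows, n_cols)
  attr(g, "scheme") <- scheme
  g
}

#' Read an edge list from a delimited text file
#'
#' Reads a two-column whitespace- or comma-delimited file of node index
#' pairs, one edge per line. Lines whose first field is non-numeric (a
#' header) are skipped.
#'
#' @param path Path to the edge-list file.
#' @param n_nodes Number of nodes; if `NULL`, taken as the largest index
#'   seen (after `index_base` adjustment).
#' @param index_base Base of the indices in the file: `0` (the default,
#'   common for exported edge lists) or `1`.
#' @return An [adjacency_graph].
#' @export
read_edge_list <- function(path, n_nodes = NULL, index_base = 0) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[,[:space:]]+")
  keep <- vapply(fields, function(f) {
    length(f) >= 2L && !is.na(suppressWarnings(as.numeric(f[1L])))
  }, logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) rlang::abort("No edges found in file.")
  m <- t(vapply(fields, function(f) as.integer(f[1:2]), integer(2)))
  m <- m + (1L - as.integer(index_base))
  if (is.null(n_nodes)) n_nodes <- max(m)
  adjacency_graph(n_nodes, m)
}

#' Graph Laplacian of an adjacency graph
#'
#' Returns the combinatorial Laplacian `L = D - A` as a sparse symmetric
#' matrix. Rows sum to zero, so the quadratic form `psi' L psi` equals the
#' sum over edges of squared differences, each unordered edge counted once.
#'
#' @param graph An [adjacency_graph].
#' @return A sparse symmetric `Matrix` of dimension `n_nodes`.
#' @export
graph_laplacian <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n_nodes
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), symmetric = TRUE))
  }
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = n)
  A <- Matrix::sparseMatrix(i = e[, 1L], j = e[, 2L], x = -1,
                            dims = c(n, n), symmetric = TRUE)
  A + Matrix::Diagonal(n, deg)
}

# numerically safe log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' IAR smoothing update of inclusion probabilities
#'
#' Given posterior inclusion probabilities `p`, computes the maximizer over
#' the logit field `psi` of
#' \deqn{Q(\psi) = \sum_j [p_j \psi_j - \log(1 + e^{\psi_j})] -
#'   \frac{\tau^2}{2} \sum_{(i,j) \in E} (\psi_j - \psi_i)^2,}
#' the M-step for the prior-inclusion block when an intrinsic autoregressive
#' prior is placed on \eqn{\psi_j = \mathrm{logit}(\theta_j)}. The objective
#' is concave and is solved by damped Newton iterations using the graph
#' Laplacian; with an empty edge set the update reduces to
#' \eqn{\theta_j = p_j}.
#'
#' `p` is clipped into `plogis(c(-psi_bound, psi_bound))` before solving and
#' the returned `psi` is clipped to `[-psi_bound, psi_bound]`, so `theta`
#' never reaches 0 or 1 exactly.
#'
#' @param p Numeric vector of posterior inclusion probabilities in `[0, 1]`,
#'   length `graph$n_nodes`.
#' @param graph An [adjacency_graph].
#' @param tau Positive IAR precision scale (conventionally fixed at 1).
#' @param psi_init Optional starting value for `psi`; defaults to the
#'   clipped logit of `p`.
#' @param psi_bound Clipping bound on `|psi|` (default 8).
#' @param tol Convergence tolerance on the gradient max-norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param laplacian Optional precomputed [graph_laplacian()] of `graph`,
#'   avoiding its reconstruction in repeated calls.
#' @return An object of class `inclusion_field`: a list with `theta`, `psi`,
#'   `tau`, `n_iter`, `converged`, and the final objective value `objective`.
#' @export
#' @examples
#' g <- lattice_adjacency(2, 2)
#' iar_update(rep(0.4, 4), g, tau = 1)$theta # constant field is fixed point
iar_update <- function(p, graph, tau = 1, psi_init = NULL, psi_bound = 8,
                       tol = 1e-8, max_iter = 100, laplacian = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(p) != graph$n_nodes) {
    rlang::abort("`p` must have one entry per graph node.")
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    rlang::abort("`tau` must be a single positive number.")
  }
  lo <- stats::plogis(-psi_bound)
  p <- pmin(pmax(p, lo), 1 - lo)
  n <- graph$n_nodes

  if (nrow(graph$edges) == 0L) {
    psi <- pmin(pmax(stats::qlogis(p), -psi_bound), psi_bound)
    theta <- stats::plogis(psi)
    obj <- sum(p * psi - log1pexp(psi))
    return(structure(list(theta = theta, psi = psi, tau = tau,
                          n_iter = 0L, converged = TRUE, objective = obj),
                     class = "inclusion_field"))
  }

  L <- laplacian %||% graph_laplacian(graph)
  t2 <- tau^2
  qfun <- function(psi) {
    sum(p * psi - log1pexp(psi)) -
      0.5 * t2 * as.numeric(Matrix::crossprod(psi, L %*% psi))
  }
  psi <- if (is.null(psi_init)) {
    pmin(pmax(stats::qlogis(p), -psi_bound), psi_bound)
  } else {
    as.numeric(psi_init)
  }
  if (length(psi) != n) rlang::abort("`psi_init` has the wrong length.")

  q_cur <- qfun(psi)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    theta <- stats::plogis(psi)
    grad <- p - theta - t2 * as.numeric(L %*% psi)
    if (max(abs(grad)) < tol) { converged <- TRUE; iter <- iter - 1L; break }
    w <- pmax(theta * (1 - theta), 1e-10)
    H <- Matrix::Diagonal(n, w) + t2 * L
    step <- as.numeric(Matrix::solve(H, grad))
    # damped step: halve until the concave objective does not decrease
    alpha <- 1
    repeat {
      psi_new <- psi + alpha * step
      q_new <- qfun(psi_new)
      if (q_new >= q_cur - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    psi <- psi_new
    q_cur <- q_new
  }
  if (!converged) {
    grad <- p - stats::plogis(psi) - t2 * as.numeric(L %*% psi)
    if (max(abs(grad)) < tol) converged <- TRUE
  }
  if (!converged) {
    rlang::abort(
      "IAR Newton update did not converge within `max_iter` iterations.",
      class = "ssenet_iar_nonconvergence",
      psi = psi, gradient_max = max(abs(p - stats::plogis(psi) -
                                          t2 * as.numeric(L %*% psi)))
    )
  }
  psi <- pmin(pmax(psi, -psi_bound), psi_bound)
  structure(list(theta = stats::plogis(psi), psi = psi, tau = tau,
                 n_iter = iter, converged = TRUE, objective = qfun(psi)),
            class = "inclusion_field")
}
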