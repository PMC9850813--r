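# Contiguity graphs, CAR/ICAR precision matrices, neighbourhood smoothers and
# GMRF simulation. All downstream models share the area ordering fixed here.

#' Build a contiguity graph from an undirected edge list
#'
#' Constructs the areal adjacency structure used by every spatial model in the
#' package: a symmetric 0/1 contiguity matrix over a fixed ordering of area
#' identifiers, with node degrees and connected components precomputed.
#' Duplicate edges (including reversed duplicates) are collapsed; isolated
#' areas (degree 0) are permitted and flagged.
#'
#' @param edge_list A two-column matrix or data frame of area-identifier pairs,
#'   one undirected edge per row. May be empty (a graph with no edges).
#' @param area_ids Character vector of unique area identifiers; its order fixes
#'   the row/column ordering of all derived matrices.
#' @return An object of class `area_graph`: a list with elements `n_areas`,
#'   `ids`, `edges` (two-column integer matrix, `i < j`), `W` (sparse symmetric
#'   0/1 adjacency), `degree`, `component` (integer component labels) and
#'   `isolated` (logical).
#' @examples
#' g <- build_graph(rbind(c("a", "b")), c("a", "b", "c"))
#' g$degree            # 1 1 0; area "c" is an island
#' which(g$isolated)
#' @export
build_graph <- function(edge_list, area_ids) {
  ids <- as.character(area_ids)
  if (anyDuplicated(ids)) stop("duplicated area identifiers in `area_ids`")
  n <- length(ids)
  el <- edge_list
  if (is.data.frame(el)) el <- as.matrix(el)
  if (is.null(el) || length(el) == 0L) {
    el <- matrix(character(0), ncol = 2)
  }
  if (ncol(el) != 2L) stop("`edge_list` must have exactly two columns")
  from <- as.character(el[, 1])
  to <- as.character(el[, 2])
  a <- match(from, ids)
  b <- match(to, ids)
  bad <- c(from[is.na(a)], to[is.na(b)])
  if (length(bad)) {
    stop("unknown area identifier(s) in edge list: ",
         paste(unique(bad), collapse = ", "))
  }
  loops <- a == b
  if (any(loops)) {
    stop("self-loop(s) in edge list for area(s): ",
         paste(unique(from[loops]), collapse = ", "))
  }
  i <- pmin(a, b)
  j <- pmax(a, b)
  keep <- !duplicated(cbind(i, j))
  i <- i[keep]
  j <- j[keep]
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), dimnames = list(ids, ids))
  degree <- as.integer(Matrix::rowSums(W))
  structure(
    list(n_areas = n, ids = ids,
         edges = cbind(i = i, j = j),
         W = W, degree = degree,
         component = graph_components(n, i, j),
         isolated = degree == 0L),
    class = "area_graph")
}

# Connected component labels via breadth-first search on the edge set.
graph_components <- function(n, i, j) {
  adj <- vector("list", n)
  for (k in seq_along(i)) {
    adj[[i[k]]] <- c(adj[[i[k]]], j[k])
    adj[[j[k]]] <- c(adj[[j[k]]], i[k])
  }
  comp <- integer(n)
  label <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- label
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' @export
print.area_graph <- function(x, ...) {
  cat("Contiguity graph:", x$n_areas, "areas,", nrow(x$edges), "edges,",
      max(x$component), "component(s),", sum(x$isolated), "isolated\n")
  invisible(x)
}

#' Read an undirected edge list from a text file
#'
#' Accepts two-column whitespace- or comma-separated text; lines starting with
#' `#` are comments. Area identifiers are opaque strings.
#'
#' @param path Path to the edge-list file.
#' @return A two-column character matrix of area-id pairs.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(matrix(character(0), ncol = 2))
  parts <- strsplit(lines, "[,[:space:]]+")
  if (any(lengths(parts) != 2L)) {
    stop("each edge-list line must contain exactly two area identifiers")
  }
  matrix(unlist(parts), ncol = 2, byrow = TRUE)
}

#' Write an edge list to a text file
#'
#' @param graph An `area_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  df <- data.frame(from = graph$ids[graph$edges[, 1]],
                   to = graph$ids[graph$edges[, 2]])
  writeLines(c("# undirected contiguity edges",
               paste(df$from, df$to)), path)
  invisible(path)
}

#' Intrinsic CAR (ICAR) precision matrix
#'
#' Builds the improper intrinsic autoregressive precision
#' \eqn{Q = \tau (D - W)} with \eqn{D = \mathrm{diag}(d_i)} the degree matrix.
#' Each row of \eqn{Q/\tau} sums to zero exactly; the rank deficiency equals
#' the number of connected components, which is why ICAR fields are used only
#' under a per-component sum-to-zero constraint.
#'
#' @param graph An `area_graph`.
#' @param tau Positive precision scale \eqn{\tau}.
#' @return An object of class `car_structure` with elements `Q` (sparse),
#'   `M` (the unscaled \eqn{D - W}), `variant = "icar"`, `tau`, `alpha = NA`,
#'   and the graph's `component`/`degree` bookkeeping.
#' @examples
#' g <- build_graph(rbind(c("a", "b")), c("a", "b"))
#' as.matrix(icar_precision(g, 1)$Q)   # [[1,-1],[-1,1]]
#' @export
icar_precision <- function(graph, tau) {
  stopifnot(inherits(graph, "area_graph"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number")
  }
  M <- Matrix::Diagonal(graph$n_areas, graph$degree) - graph$W
  new_car_structure(Q = tau * M, M = M, variant = "icar", tau = tau,
                    alpha = NA_real_, graph = graph)
}

#' Proper CAR precision matrix
#'
#' Builds the proper conditional autoregressive precision
#' \eqn{Q = \tau (D - \alpha W)} with propriety parameter
#' \eqn{\alpha \in [0, 1)}. For any such \eqn{\alpha} the matrix is positive
#' definite (strictly diagonally dominant for non-isolated nodes), so it
#' defines a proper Gaussian prior — the form used for the latent confounder
#' in the neighbourhood-adjustment model, where the prior must be proper.
#'
#' @param graph An `area_graph`.
#' @param tau Positive precision scale.
#' @param alpha Propriety/range parameter in `[0, 1)`; larger values give
#'   longer-range spatial correlation.
#' @return A `car_structure` with `variant = "proper"`.
#' @examples
#' g <- build_graph(rbind(c("a", "b")), c("a", "b"))
#' eigen(as.matrix(proper_car_precision(g, 1, 0.5)$Q))$values  # 1.5, 0.5
#' @export
proper_car_precision <- function(graph, tau, alpha) {
  stopifnot(inherits(graph, "area_graph"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha >= 1) {
    stop("`alpha` must lie in [0, 1)")
  }
  # Isolated nodes have degree 0; give them unit conditional precision so the
  # joint remains positive definite (they carry an independent N(0, 1/tau)).
  d <- graph$degree
  d[d == 0L] <- 1L
  M <- Matrix::Diagonal(graph$n_areas, d) - alpha * graph$W
  new_car_structure(Q = tau * M, M = M, variant = "proper", tau = tau,
                    alpha = alpha, graph = graph)
}

new_car_structure <- function(Q, M, variant, tau, alpha, graph) {
  structure(
    list(Q = methods::as(methods::as(Q, "generalMatrix"), "CsparseMatrix"),
         M = methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix"),
         variant = variant, tau = tau, alpha = alpha,
         n = graph$n_areas, degree = graph$degree,
         component = graph$component, isolated = graph$isolated),
    class = "car_structure")
}

#' Row-stochastic neighbourhood smoother
#'
#' The spatial smoothing operator of the neighbourhood-adjustment method:
#' row-normalized adjacency \eqn{S = D^{-1} W}, optionally iterated
#' (`S^order`). Isolated areas map to themselves (identity rows), so every row
#' sums to one and constant fields are preserved exactly.
#'
#' @param graph An `area_graph`.
#' @param order Positive integer number of smoothing passes (default 1).
#' @return A sparse row-stochastic matrix of dimension `n_areas`.
#' @examples
#' g <- build_graph(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
#' as.numeric(neighbourhood_smoother(g) %*% c(0, 3, 0))  # 3 0 3
#' @export
neighbourhood_smoother <- function(graph, order = 1L) {
  stopifnot(inherits(graph, "area_graph"))
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L) {
    stop("`order` must be a positive integer")
  }
  d <- graph$degree
  inv <- ifelse(d > 0L, 1 / pmax(d, 1L), 0)
  S <- Matrix::Diagonal(graph$n_areas, inv) %*% graph$W
  if (any(graph$isolated)) {
    S <- S + Matrix::Diagonal(graph$n_areas, as.numeric(graph$isolated))
  }
  out <- S
  if (order > 1L) for (k in seq_len(order - 1L)) out <- out %*% S
  methods::as(methods::as(out, "generalMatrix"), "CsparseMatrix")
}

#' Sample a Gaussian Markov random field
#'
#' Draws zero-mean fields from the Gaussian law defined by a CAR precision.
#' For the proper variant the draw is \eqn{N(0, Q^{-1})} via sparse Cholesky
#' factorization. For the intrinsic variant the density is improper; the draw
#' is taken in the span of the positive eigenvalues and then centred within
#' each connected component (the standard sum-to-zero constrained ICAR field),
#' so `sum_to_zero = TRUE` is required.
#'
#' @param structure A `car_structure`.
#' @param seed Optional integer seed; when supplied the draw is a pure
#'   function of `(structure, seed)`. When `NULL` the current RNG stream is
#'   used.
#' @param sum_to_zero Logical; must be `TRUE` for the intrinsic variant.
#' @param n_draws Number of independent fields to draw.
#' @return A numeric vector of length `n` (or an `n x n_draws` matrix when
#'   `n_draws > 1`).
#' @export
sample_gmrf <- function(structure, seed = NULL,
                        sum_to_zero = identical(structure$variant, "icar"),
                        n_draws = 1L) {
  stopifnot(inherits(structure, "car_structure"))
  n_draws <- as.integer(n_draws)
  stopifnot(n_draws >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- structure$n
  if (identical(structure$variant, "icar")) {
    if (!isTRUE(sum_to_zero)) {
      stop("intrinsic CAR fields are improper; `sum_to_zero` must be TRUE")
    }
    e <- eigen(as.matrix(structure$Q), symmetric = TRUE)
    tol <- max(e$values) * 1e-9
    pos <- e$values > tol
    z <- matrix(rnorm(sum(pos) * n_draws), nrow = sum(pos))
    x <- e$vectors[, pos, drop = FALSE] %*% (z / sqrt(e$values[pos]))
    # Explicit per-component centring (numerically exact sum-to-zero).
    for (cc in unique(structure$component)) {
      idx <- structure$component == cc
      x[idx, ] <- sweep(x[idx, , drop = FALSE], 2,
                        colMeans(x[idx, , drop = FALSE]))
    }
  } else {
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(structure$Q),
                                       "CsparseMatrix"),
                           LDL = FALSE, perm = TRUE)
    z <- matrix(rnorm(n * n_draws), nrow = n)
    y <- Matrix::solve(ch, z, system = "Lt")
    x <- as.matrix(Matrix::solve(ch, y, system = "Pt"))
  }
  if (n_draws == 1L) as.numeric(x) else x
}

#' Moran's I spatial autocorrelation statistic
#'
#' Global Moran's I under binary contiguity weights; used to check the
#' identification assumption that the exposure field varies on a spatial scale
#' at least as large as the confounder's.
#'
#' @param x Numeric field over the graph's areas.
#' @param graph An `area_graph`.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(x, graph) {
  stopifnot(inherits(graph, "area_graph"), length(x) == graph$n_areas)
  z <- x - mean(x)
  s0 <- sum(graph$W)
  if (s0 == 0) stop("graph has no edges; Moran's I undefined")
  as.numeric(graph$n_areas / s0 * (t(z) %*% (graph$W %*% z)) / sum(z^2))
}
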