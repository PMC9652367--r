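# Zone adjacency graphs: the spatial index set of the model.  A graph is a
# roster of zone labels plus an undirected edge set; the ICAR precision is
# its graph Laplacian.

#' Construct a zone adjacency graph
#'
#' @param zones character vector of zone labels (order is kept and defines
#'   the row/column order of all derived matrices).
#' @param edges two-column character matrix (or data.frame) of zone pairs;
#'   direction is ignored and duplicates are collapsed.
#' @return an object of class `zone_graph` with elements `zones` and `edges`
#'   (canonicalised two-column character matrix).
#' @export
zone_graph <- function(zones, edges = NULL) {
  zones <- as.character(zones)
  if (anyDuplicated(zones)) stop("duplicate zone labels in roster")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have two columns")
  }
  if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list")
  bad <- !(c(edges) %in% zones)
  if (any(bad)) stop("edge references unrostered zone: ", c(edges)[bad][1])
  # canonical order: endpoint with smaller roster index first, then dedupe
  if (nrow(edges) > 0L) {
    i <- match(edges[, 1], zones)
    j <- match(edges[, 2], zones)
    swap <- i > j
    edges[swap, ] <- edges[swap, 2:1, drop = FALSE]
    edges <- unique(edges)
    o <- order(match(edges[, 1], zones), match(edges[, 2], zones))
    edges <- edges[o, , drop = FALSE]
  }
  structure(list(zones = zones, edges = edges), class = "zone_graph")
}

#' @export
print.zone_graph <- function(x, ...) {
  cat("zone_graph:", length(x$zones), "zones,", nrow(x$edges), "edges,",
      max(graph_components(x)), "connected component(s)\n")
  invisible(x)
}

#' Rook-contiguity lattice of zones
#'
#' Builds a `rows` x `cols` grid of zones with edges between horizontal and
#' vertical neighbours — a stand-in for an administrative-zone contiguity
#' graph (an 8 x 9 lattice mimics the 72-zone setting of the Ethiopia
#' Socioeconomic Survey analysis).
#'
#' @param rows,cols positive integers.
#' @return a [zone_graph()] with `rows * cols` zones labelled `Z01`, `Z02`, ...
#' @export
#' @examples
#' g <- make_zone_lattice(8, 9)
#' length(g$zones) # 72
#' nrow(g$edges)   # 8*8 + 9*7 = 127
make_zone_lattice <- function(rows, cols) {
  if (length(rows) != 1L || length(cols) != 1L ||
      !is.finite(rows) || !is.finite(cols) || rows < 1 || cols < 1 ||
      rows != floor(rows) || cols != floor(cols))
    stop("rows and cols must be positive integers")
  n <- rows * cols
  lab <- sprintf(paste0("Z%0", max(2, nchar(n)), "d"), seq_len(n))
  id <- function(r, c) (r - 1) * cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    if (cc < cols) { from <- c(from, id(r, cc)); to <- c(to, id(r, cc + 1)) }
    if (r < rows)  { from <- c(from, id(r, cc)); to <- c(to, id(r + 1, cc)) }
  }
  zone_graph(lab, cbind(lab[from], lab[to]))
}

#' Zone degrees (neighbour counts)
#' @param graph a [zone_graph()].
#' @return named integer vector over zones.
#' @export
zone_degree <- function(graph) {
  d <- integer(length(graph$zones))
  names(d) <- graph$zones
  if (nrow(graph$edges) > 0) {
    t1 <- table(factor(graph$edges[, 1], levels = graph$zones))
    t2 <- table(factor(graph$edges[, 2], levels = graph$zones))
    d <- as.integer(t1 + t2)
    names(d) <- graph$zones
  }
  d
}

#' Connected components of a zone graph
#' @param graph a [zone_graph()].
#' @return integer vector of component labels (1-based) per zone, in roster
#'   order; isolated zones form singleton components.
#' @export
graph_components <- function(graph) {
  n <- length(graph$zones)
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges[, 1], graph$zones)
    j <- match(graph$edges[, 2], graph$zones)
    for (k in seq_along(i)) {
      adj[[i[k]]] <- c(adj[[i[k]]], j[k])
      adj[[j[k]]] <- c(adj[[j[k]]], i[k])
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  names(comp) <- graph$zones
  comp
}

#' Intrinsic CAR (ICAR) precision matrix of a zone graph
#'
#' The graph Laplacian: `Q[i,i] = degree(i)`, `Q[i,j] = -1` for neighbours,
#' 0 otherwise.  `Q` is symmetric with zero row sums and rank
#' `n_zones - n_components`; the quadratic form `v'Qv` equals the sum of
#' squared differences over edges.
#'
#' @param graph a [zone_graph()].
#' @return a dense symmetric matrix with zone labels as dimnames.
#' @export
icar_precision <- function(graph) {
  n <- length(graph$zones)
  if (n == 0L) stop("empty graph")
  Q <- matrix(0, n, n, dimnames = list(graph$zones, graph$zones))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges[, 1], graph$zones)
    j <- match(graph$edges[, 2], graph$zones)
    for (k in seq_along(i)) {
      Q[i[k], j[k]] <- Q[i[k], j[k]] - 1
      Q[j[k], i[k]] <- Q[j[k], i[k]] - 1
    }
  }
  diag(Q) <- zone_degree(graph)
  Q
}

#' Centre a zone vector to zero sum within each connected component
#'
#' Identifiability device: the intrinsic CAR prior is invariant to adding a
#' constant per component, which would otherwise be confounded with the
#' intercept.
#'
#' @param v numeric vector over zones.
#' @param components integer component labels as from [graph_components()].
#' @return `v` minus its per-component means.
#' @export
center_per_component <- function(v, components) {
  stopifnot(length(v) == length(components))
  means <- tapply(v, components, mean)
  v - as.numeric(means[as.character(components)])
}

#' Sample a zone field from the intrinsic CAR prior
#'
#' The ICAR prior is improper (flat on per-component constants), so a draw is
#' taken on the proper subspace orthogonal to them: eigendecompose the
#' Laplacian `Q`, draw independent `N(0, tau2 / lambda_k)` coordinates on the
#' positive-eigenvalue eigenvectors, and map back.  The result sums to zero
#' within each connected component.
#'
#' @param graph a [zone_graph()].
#' @param tau2 positive variance of the ICAR increments.
#' @param seed integer seed (all randomness flows through it).
#' @return named numeric vector over zones, component sums zero (1e-10).
#' @export
sample_icar_field <- function(graph, tau2, seed) {
  if (!is.numeric(tau2) || length(tau2) != 1L || !is.finite(tau2) || tau2 <= 0)
    stop("tau2 must be a positive variance")
  Q <- icar_precision(graph)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values, 1) * 1e-9
  x <- with_stream(seed, "icar_field",
                   rnorm(sum(pos), 0, sqrt(tau2 / e$values[pos])))
  f <- as.numeric(e$vectors[, pos, drop = FALSE] %*% x)
  # exact re-centring guards against eigenvector rounding
  f <- center_per_component(f, graph_components(graph))
  names(f) <- graph$zones
  f
}

#' Write / read a zone graph as plain text
#'
#' The edge list is a two-column tab-separated file (one edge per line); the
#' roster is a one-zone-per-line file so that isolated zones survive a
#' round-trip.
#'
#' @param graph a [zone_graph()].
#' @param edge_path,roster_path file paths.
#' @return `write_zone_graph` returns the graph invisibly;
#'   `read_zone_graph` returns a [zone_graph()].
#' @export
write_zone_graph <- function(graph, edge_path, roster_path) {
  writeLines(graph$zones, roster_path)
  if (nrow(graph$edges) > 0) {
    writeLines(paste(graph$edges[, 1], graph$edges[, 2], sep = "\t"), edge_path)
  } else {
    writeLines(character(0), edge_path)
  }
  invisible(graph)
}

#' @rdname write_zone_graph
#' @export
read_zone_graph <- function(edge_path, roster_path) {
  zones <- readLines(roster_path)
  zones <- zones[nzchar(zones)]
  lines <- readLines(edge_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(zone_graph(zones))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed edge at line ", bad[1])
  e <- do.call(rbind, parts)
  for (k in seq_len(nrow(e))) {
    if (e[k, 1] == e[k, 2])
      stop("self-loop at line ", k, ": ", e[k, 1])
    if (!all(e[k, ] %in% zones))
      stop("edge at line ", k, " references unrostered zone: ",
           e[k, ][!(e[k, ] %in% zones)][1])
  }
  zone_graph(zones, e)
}
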