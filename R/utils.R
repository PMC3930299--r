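# Internal helpers: condition constructors, small numerics.

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("aneumorph_io_error", "error")))
}

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("aneumorph_validation_error", "error")))
}

abort_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("aneumorph_infeasible_error", "error")))
}

# row-wise euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x)) {
    abort_validation("%s must be a numeric 3-vector", what)
  }
  x
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# ray-casting point-in-polygon; poly is an open ring (first row != last row ok)
point_in_polygon <- function(pt, poly) {
  x <- pt[1L]; y <- pt[2L]
  px <- poly[, 1L]; py <- poly[, 2L]
  nx <- c(px[-1L], px[1L]); ny <- c(py[-1L], py[1L])
  crosses <- ((py > y) != (ny > y)) &
    (x < (nx - px) * (y - py) / (ny - py) + px)
  sum(crosses) %% 2L == 1L
}

# connected components of an undirected graph given as parallel index vectors;
# breadth-first over adjacency lists, component id per node (1-based, dense)
connected_components <- function(n, a, b) {
  comp <- integer(n)
  if (n == 0L) return(comp)
  adj_from <- c(a, b)
  adj_to <- c(b, a)
  ord <- order(adj_from)
  adj_from <- adj_from[ord]
  adj_to <- adj_to[ord]
  # adjacency offsets: neighbours of v are adj_to[ptr[v]:(ptr[v+1]-1)]
  cnt <- tabulate(adj_from, nbins = n)
  ptr <- c(1L, 1L + cumsum(cnt))
  cid <- 0L
  stack <- integer(n)
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    comp[v] <- cid
    top <- 1L
    stack[1L] <- v
    while (top > 0L) {
      u <- stack[top]
      top <- top - 1L
      if (ptr[u] <= ptr[u + 1L] - 1L) {
        nb <- adj_to[ptr[u]:(ptr[u + 1L] - 1L)]
        nb <- nb[comp[nb] == 0L]
        if (length(nb) > 0L) {
          comp[nb] <- cid
          stack[(top + 1L):(top + length(nb))] <- nb
          top <- top + length(nb)
        }
      }
    }
  }
  comp
}
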