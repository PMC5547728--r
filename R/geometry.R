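# Internal geometry helpers shared across modules. All distances in Angstrom.

# n x m Euclidean distance matrix between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Coordinate matrix from an atom tibble.
coords_mat <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# Minimum distance from each row of `pts` to any row of `ref`. Chunked so the
# full pts x ref matrix is never held for large grids.
min_dist_to_set <- function(pts, ref, chunk = 4000L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j] <- apply(cross_dist(pts[i:j, , drop = FALSE], ref), 1L, min)
    i <- j + 1L
  }
  out
}

# Connected components of an undirected adjacency matrix (logical, symmetric).
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      queue <- v
      comp[v] <- cur
      while (length(queue) > 0L) {
        u <- queue[[1L]]
        queue <- queue[-1L]
        nb <- which(adj[u, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# Uniform random rotation matrix (det +1) via QR of a Gaussian matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L, 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Apply a rigid transform y = R x + t to an atom tibble or coordinate matrix.
apply_transform <- function(x, rotation, translation) {
  if (is.data.frame(x)) {
    m <- coords_mat(x) %*% t(rotation)
    x$x <- m[, 1L] + translation[[1L]]
    x$y <- m[, 2L] + translation[[2L]]
    x$z <- m[, 3L] + translation[[3L]]
    x
  } else {
    sweep(as.matrix(x) %*% t(rotation), 2L, as.numeric(translation), `+`)
  }
}

# Lexicographic order of 3D points (x, then y, then z).
lex_order <- function(m) {
  order(m[, 1L], m[, 2L], m[, 3L])
}
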