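# Maximal common substructure between a template site and a surface patch,
# found as a maximum clique of the distance-compatibility correspondence
# graph, followed by least-squares rigid superposition (Kabsch) and ligand
# placement.

#' Build the correspondence graph between template site and patch
#'
#' Vertices are pairs (template atom i, patch atom j) with equal
#' (atom name, residue type) keys. Two vertices (i, s -> j, t) are adjacent
#' iff the intra-set distances agree, `|D(a_i, a_s) - D(b_j, b_t)| <= tol`,
#' and `i != s`, `j != t`. Cliques of this graph are distance-consistent
#' common substructures.
#'
#' @param template_site Tibble of template site atoms.
#' @param patch Tibble of patch atoms.
#' @param tol Distance-compatibility tolerance in Angstrom; default 2.
#' @return List with `vertices` (tibble `i`, `j`) and `adj` (logical matrix).
#' @export
build_correspondence_graph <- function(template_site, patch, tol = 2) {
  stopifnot(tol > 0)
  ka <- atom_key(template_site)
  kb <- atom_key(patch)
  verts <- which(outer(ka, kb, `==`), arr.ind = TRUE)
  vertices <- tibble(i = as.integer(verts[, 1L]), j = as.integer(verts[, 2L]))
  nv <- nrow(vertices)
  if (nv == 0L) {
    return(list(vertices = vertices,
                adj = matrix(FALSE, 0L, 0L)))
  }
  da <- cross_dist(coords_mat(template_site), coords_mat(template_site))
  db <- cross_dist(coords_mat(patch), coords_mat(patch))
  i <- vertices$i
  j <- vertices$j
  adj <- abs(da[i, i, drop = FALSE] - db[j, j, drop = FALSE]) <= tol &
    outer(i, i, `!=`) & outer(j, j, `!=`)
  list(vertices = vertices, adj = adj)
}

#' Maximum clique by backtracking with pruning
#'
#' Exhaustive branch-and-bound over vertices ordered by degree descending,
#' pruning branches that cannot beat the incumbent. All cliques of the
#' maximum size found (up to `keep_max`) are returned so the caller can break
#' ties, e.g. by fitted RMSD. The search is exact when the node-expansion
#' budget is not exhausted and flagged best-effort otherwise.
#'
#' @param graph Correspondence graph from [build_correspondence_graph()].
#' @param min_size Minimum acceptable clique size; default 3.
#' @param budget Node-expansion limit; default 1e6.
#' @param keep_max Maximum number of ties retained; default 32.
#' @return List with `size`, `cliques` (list of vertex index vectors; empty
#'   if no clique reaches `min_size`) and `exact` (logical).
#' @export
max_clique_backtracking <- function(graph, min_size = 3L, budget = 1e6,
                                    keep_max = 32L) {
  stopifnot(min_size >= 3L)
  adj <- graph$adj
  nv <- nrow(adj)
  if (nv == 0L) return(list(size = 0L, cliques = list(), exact = TRUE))

  ord <- order(-colSums(adj), seq_len(nv))
  adj <- adj[ord, ord, drop = FALSE]

  env <- new.env(parent = emptyenv())
  env$best <- min_size - 1L
  env$cliques <- list()
  env$expansions <- 0L
  env$exhausted <- FALSE

  expand <- function(current, candidates) {
    if (env$exhausted) return(invisible())
    env$expansions <- env$expansions + 1L
    if (env$expansions > budget) {
      env$exhausted <- TRUE
      return(invisible())
    }
    if (length(candidates) == 0L) {
      sz <- length(current)
      if (sz > env$best) {
        env$best <- sz
        env$cliques <- list(current)
      } else if (sz == env$best && sz >= min_size &&
                 length(env$cliques) < keep_max) {
        env$cliques <- c(env$cliques, list(current))
      }
      return(invisible())
    }
    for (k in seq_along(candidates)) {
      # bound: remaining candidates cannot beat the incumbent
      if (length(current) + (length(candidates) - k + 1L) < env$best) break
      if (length(current) + (length(candidates) - k + 1L) == env$best &&
          length(env$cliques) >= keep_max) break
      v <- candidates[k]
      nxt <- candidates[-seq_len(k)]
      nxt <- nxt[adj[v, nxt]]
      expand(c(current, v), nxt)
      if (env$exhausted) return(invisible())
    }
    invisible()
  }
  expand(integer(0L), seq_len(nv))

  cliques <- lapply(env$cliques, function(cl) sort(ord[cl]))
  size <- if (length(cliques) > 0L) length(cliques[[1L]]) else 0L
  if (size < min_size) {
    cliques <- list()
    size <- 0L
  }
  list(size = size, cliques = cliques, exact = !env$exhausted)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets, moving `source_coords` onto `target_coords`
#' (centroid translation plus SVD rotation with determinant correction).
#'
#' @param source_coords,target_coords n x 3 matrices of paired points, n >= 3.
#' @return A `nucsite_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (3-vector), `rmsd`, `n`.
#' @export
fit_transform <- function(source_coords, target_coords) {
  x <- as.matrix(source_coords)
  y <- as.matrix(target_coords)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3L, ncol(x) == 3L, ncol(y) == 3L)
  if (is_collinear(x, tol = 1e-4) || is_collinear(y, tol = 1e-4)) {
    abort("point set is (nearly) collinear; rigid fit is degenerate",
          class = "nucsite_degenerate_fit")
  }
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2L, cx)
  y0 <- sweep(y, 2L, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- x0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - y0)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cy - rot %*% cx),
         rmsd = rmsd, n = nrow(x)),
    class = "nucsite_transform"
  )
}

#' Place the template ligand into the target frame
#'
#' Fits the rigid transform on the clique's matched atom pairs (template site
#' atoms onto patch atoms) and maps the template's ligand atoms through it.
#' The ligand conformation is copied unchanged from the template. When
#' several maximum cliques exist, the one with the lowest fitted RMSD is
#' kept (ties: first in deterministic search order).
#'
#' @param template A `nucsite_template`.
#' @param clique_result Result of [max_clique_backtracking()].
#' @param graph The correspondence graph the cliques refer to.
#' @param patch Tibble of patch atoms (the graph's second atom set).
#' @param seed Numeric 3-vector: the seed grid point (bookkeeping only).
#' @return A ligand pose: list with `template_id`, `ligand_name`, `atoms`,
#'   `center`, `transform`, `seed`, `clique_size`, `energy` (NA until
#'   scored); or `NULL` if every clique is geometrically degenerate.
#' @export
pose_ligand <- function(template, clique_result, graph, patch, seed = c(NA, NA, NA)) {
  if (clique_result$size == 0L) return(NULL)
  site_m <- coords_mat(template$site_atoms)
  patch_m <- coords_mat(patch)
  best <- NULL
  for (cl in clique_result$cliques) {
    i <- graph$vertices$i[cl]
    j <- graph$vertices$j[cl]
    tr <- tryCatch(
      fit_transform(site_m[i, , drop = FALSE], patch_m[j, , drop = FALSE]),
      nucsite_degenerate_fit = function(e) NULL
    )
    if (!is.null(tr) && (is.null(best) || tr$rmsd < best$rmsd)) best <- tr
  }
  if (is.null(best)) return(NULL)
  posed <- apply_transform(template$ligand_atoms, best$rotation, best$translation)
  list(
    template_id = template$template_id,
    ligand_name = template$ligand_name,
    atoms = posed,
    center = colMeans(coords_mat(posed)),
    transform = best,
    seed = as.numeric(seed),
    clique_size = clique_result$size,
    energy = NA_real_
  )
}
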