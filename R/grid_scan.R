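# Grid-space construction and template-driven grid scanning.
#
# A regular lattice of candidate ligand-center points is laid over the target
# (step 2 A by default), trimmed to the solvent shell (more than 1.6 A from
# every protein atom, within 10 A of some atom). Each solvent point is tested
# against a template by (i) the surface-distance criterion |r - r1| <= 2 A
# and (ii) triangle matching between the template site and the point's
# surface patch, then survivors are single-linkage clustered and each top
# cluster emits up to two seed points.

#' Build the solvent grid space around a protein
#'
#' The lattice is anchored at the floor of the protein bounding-box minimum
#' on each axis (deterministic across runs) and spans the box padded by
#' `outer`. A point is retained iff its distance to the nearest protein atom
#' is in `(inner, outer]`.
#'
#' @param protein Tibble of protein atoms.
#' @param step Lattice spacing in Angstrom; default 2.
#' @param outer Outer shell radius; default 10.
#' @param inner Exclusion radius around protein atoms; default 1.6.
#' @return A `nucsite_grid`: list with `points` (n x 3 matrix), `min_dist`
#'   (distance from each point to the nearest protein atom), `step`.
#' @export
build_grid <- function(protein, step = 2, outer = 10, inner = 1.6) {
  stopifnot(step > 0, outer > 0, inner >= 0, inner < outer)
  m <- coords_mat(protein)
  lo <- floor(apply(m, 2L, min))
  hi <- apply(m, 2L, max)
  axes <- lapply(1:3, function(k) {
    seq(lo[k] - step * ceiling(outer / step), hi[k] + outer, by = step)
  })
  pts <- as.matrix(expand.grid(x = axes[[1L]], y = axes[[2L]], z = axes[[3L]]))
  dimnames(pts) <- NULL
  dmin <- min_dist_to_set(pts, m)
  keep <- dmin > inner & dmin <= outer
  structure(
    list(points = pts[keep, , drop = FALSE], min_dist = dmin[keep], step = step),
    class = "nucsite_grid"
  )
}

#' @export
print.nucsite_grid <- function(x, ...) {
  cat(sprintf("<nucsite_grid> %d solvent points, step %.1f A\n",
              nrow(x$points), x$step))
  invisible(x)
}

#' Triangle set of a template binding site
#'
#' One triangle per unordered pair of site atoms, with the ligand center as
#' the invariant apex: n site atoms give n(n-1)/2 triangles. Each entry keeps
#' the two (atom name, residue type) keys and the three edge lengths
#' (apex-a, apex-b, a-b).
#'
#' @param template A `nucsite_template`.
#' @return Tibble with columns `ia`, `ib`, `key_a`, `key_b`, `e_a`, `e_b`,
#'   `e_ab`.
#' @export
template_triangles <- function(template) {
  site <- template$site_atoms
  n <- nrow(site)
  if (n < 2L) {
    abort("template has fewer than 2 site atoms; no triangles",
          class = "nucsite_degenerate_template")
  }
  keys <- atom_key(site)
  m <- coords_mat(site)
  apex_d <- cross_dist(rbind(template$ligand_center), m)[1L, ]
  pr <- combn(n, 2L)
  d <- cross_dist(m, m)
  tibble(
    ia = pr[1L, ], ib = pr[2L, ],
    key_a = keys[pr[1L, ]], key_b = keys[pr[2L, ]],
    e_a = apex_d[pr[1L, ]], e_b = apex_d[pr[2L, ]],
    e_ab = d[cbind(pr[1L, ], pr[2L, ])]
  )
}

# Count template triangles matched by the patch around one grid point.
#
# patch_keys/patch_m: (atom_name, residue_type) keys and coordinates of the
# patch atoms; d_apex: their distances to the grid point. A template triangle
# matches if some ordered patch pair (p, q), p != q, has key(p) = key_a,
# key(q) = key_b, |d(g,p) - e_a| <= tol, |d(g,q) - e_b| <= tol and
# |d(p,q) - e_ab| <= tol (ordered enumeration covers both assignments of the
# unordered pair). Early exit once `needed` cannot be reached or is secured
# and `full_count` is FALSE.
count_matched_triangles <- function(tri, patch_keys, patch_m, d_apex, tol,
                                    needed = 0L, full_count = TRUE) {
  nt <- nrow(tri)
  tol <- tol + 1e-9  # guard so exact-boundary edge differences still match
  if (length(patch_keys) < 2L) return(0L)
  d_patch <- cross_dist(patch_m, patch_m)
  by_key <- split(seq_along(patch_keys), patch_keys)
  matched <- 0L
  for (t in seq_len(nt)) {
    if (!full_count) {
      if (matched >= needed) break
      if (matched + (nt - t + 1L) < needed) break
    }
    ca <- by_key[[tri$key_a[t]]]
    if (is.null(ca)) next
    cb <- by_key[[tri$key_b[t]]]
    if (is.null(cb)) next
    ia <- ca[abs(d_apex[ca] - tri$e_a[t]) <= tol]
    if (length(ia) == 0L) next
    ib <- cb[abs(d_apex[cb] - tri$e_b[t]) <= tol]
    if (length(ib) == 0L) next
    ok <- abs(d_patch[ia, ib, drop = FALSE] - tri$e_ab[t]) <= tol &
      outer(ia, ib, `!=`)
    if (any(ok)) matched <- matched + 1L
  }
  matched
}

# Pass threshold for the triangle criterion: at least 25% of template
# triangles and at least min(50, T) of them must match (the 50-triangle floor
# is capped at T so sites with fewer than 11 atoms remain usable).
triangle_threshold <- function(n_triangles, frac = 0.25, min_triangles = 50L) {
  max(ceiling(frac * n_triangles), min(min_triangles, n_triangles))
}

#' Test one grid point against a template
#'
#' Applies the surface-distance criterion (fail fast if `|r - r1| > 2` where
#' `r1` is the distance from the point to the nearest protein atom) and then
#' counts template triangles matched by the patch of protein atoms within
#' `R + 2` of the point.
#'
#' @param grid_point Numeric 3-vector.
#' @param protein Tibble of protein atoms.
#' @param template A `nucsite_template`.
#' @param tri Triangle set from [template_triangles()] (recomputed if NULL).
#' @param edge_tol,center_tol Tolerances in Angstrom (defaults 2 and 2).
#' @param frac,min_triangles Match-count threshold parameters (0.25 and 50).
#' @return List with `passes` (logical), `match_count`, `r1`.
#' @export
match_grid_point <- function(grid_point, protein, template, tri = NULL,
                             edge_tol = 2, center_tol = 2,
                             frac = 0.25, min_triangles = 50L) {
  if (is.null(tri)) tri <- template_triangles(template)
  m <- coords_mat(protein)
  d <- cross_dist(rbind(as.numeric(grid_point)), m)[1L, ]
  r1 <- min(d)
  if (abs(template$r - r1) > center_tol + 1e-9) {
    return(list(passes = FALSE, match_count = 0L, r1 = r1))
  }
  keys <- atom_key(protein)
  in_patch <- d <= template$R + 2 & keys %in% unique(c(tri$key_a, tri$key_b))
  cnt <- count_matched_triangles(tri, keys[in_patch],
                                 m[in_patch, , drop = FALSE], d[in_patch],
                                 edge_tol)
  thr <- triangle_threshold(nrow(tri), frac, min_triangles)
  list(passes = cnt >= thr, match_count = cnt, r1 = r1)
}

#' Scan the whole grid against one template
#'
#' Vectorized front end over [match_grid_point()]: the `|r - r1| <= 2`
#' criterion prunes the grid first, then triangle matching (with early
#' abandonment of hopeless points) is run on the survivors and the full match
#' count is computed for retained points.
#'
#' @param grid A `nucsite_grid`.
#' @param protein Tibble of protein atoms.
#' @param template A `nucsite_template`.
#' @param tri Optional precomputed triangle set.
#' @inheritParams match_grid_point
#' @return Tibble of retained points: `x`, `y`, `z`, `match_count`, `r1`.
#' @export
scan_grid <- function(grid, protein, template, tri = NULL,
                      edge_tol = 2, center_tol = 2,
                      frac = 0.25, min_triangles = 50L) {
  if (is.null(tri)) tri <- template_triangles(template)
  thr <- triangle_threshold(nrow(tri), frac, min_triangles)
  cand <- which(abs(grid$min_dist - template$r) <= center_tol + 1e-9)
  if (length(cand) == 0L) {
    return(tibble(x = numeric(), y = numeric(), z = numeric(),
                  match_count = integer(), r1 = numeric()))
  }
  keys <- atom_key(protein)
  tri_keys <- unique(c(tri$key_a, tri$key_b))
  key_ok <- keys %in% tri_keys
  m <- coords_mat(protein)
  m_ok <- m[key_ok, , drop = FALSE]
  keys_ok <- keys[key_ok]

  res <- lapply(cand, function(i) {
    g <- grid$points[i, ]
    d <- cross_dist(rbind(g), m_ok)[1L, ]
    in_patch <- d <= template$R + 2
    cnt <- count_matched_triangles(tri, keys_ok[in_patch],
                                   m_ok[in_patch, , drop = FALSE],
                                   d[in_patch], edge_tol,
                                   needed = thr, full_count = FALSE)
    if (cnt < thr) return(NULL)
    cnt_full <- count_matched_triangles(tri, keys_ok[in_patch],
                                        m_ok[in_patch, , drop = FALSE],
                                        d[in_patch], edge_tol)
    c(g, cnt_full, grid$min_dist[i])
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) {
    return(tibble(x = numeric(), y = numeric(), z = numeric(),
                  match_count = integer(), r1 = numeric()))
  }
  mat <- do.call(rbind, res)
  tibble(x = mat[, 1L], y = mat[, 2L], z = mat[, 3L],
         match_count = as.integer(mat[, 4L]), r1 = mat[, 5L])
}

#' Cluster retained grid points and emit seeds
#'
#' Single-linkage clustering with adjacency = neighboring lattice points
#' (distance <= step plus a small tolerance). Clusters are sorted by size
#' descending (ties: smaller centroid-to-protein-surface distance, then
#' lexicographic point order) and the top `top_k` kept. Each cluster yields
#' up to two seeds: the member nearest the cluster centroid
#' (`cluster_center`) and the member with maximal match count (`best_match`);
#' if these coincide a single seed is emitted.
#'
#' @param retained Tibble from [scan_grid()] (`x`, `y`, `z`, `match_count`).
#' @param step Lattice spacing used to build the grid.
#' @param top_k Number of clusters to keep; default 3.
#' @param protein Optional protein atom tibble for the exact
#'   centroid-to-surface tie-break; without it the mean `r1` of members is
#'   used.
#' @return Tibble of seeds: `x`, `y`, `z`, `cluster_id`, `kind`,
#'   `match_count`, `cluster_size`.
#' @export
cluster_and_seed <- function(retained, step = 2, top_k = 3L, protein = NULL) {
  empty <- tibble(x = numeric(), y = numeric(), z = numeric(),
                  cluster_id = integer(), kind = character(),
                  match_count = integer(), cluster_size = integer())
  if (nrow(retained) == 0L) return(empty)
  pts <- cbind(retained$x, retained$y, retained$z)
  adj <- cross_dist(pts, pts) <= step + 1e-6
  comp <- adjacency_components(adj)

  info <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    ctr <- colMeans(pts[idx, , drop = FALSE])
    surf <- if (!is.null(protein)) {
      min(cross_dist(rbind(ctr), coords_mat(protein)))
    } else if ("r1" %in% names(retained)) {
      mean(retained$r1[idx])
    } else {
      0
    }
    lex <- pts[idx[lex_order(pts[idx, , drop = FALSE])[1L]], ]
    list(idx = idx, size = length(idx), ctr = ctr, surf = surf, lex = lex)
  })
  ord <- order(
    -vapply(info, `[[`, 0L, "size"),
    vapply(info, `[[`, 0, "surf"),
    vapply(info, function(z) z$lex[1L], 0),
    vapply(info, function(z) z$lex[2L], 0),
    vapply(info, function(z) z$lex[3L], 0)
  )
  info <- info[ord][seq_len(min(top_k, length(info)))]

  seeds <- lapply(seq_along(info), function(k) {
    cl <- info[[k]]
    sub <- pts[cl$idx, , drop = FALSE]
    mc <- retained$match_count[cl$idx]
    d_ctr <- cross_dist(rbind(cl$ctr), sub)[1L, ]
    i_ctr <- order(d_ctr, sub[, 1L], sub[, 2L], sub[, 3L])[1L]
    i_best <- order(-mc, sub[, 1L], sub[, 2L], sub[, 3L])[1L]
    rows <- tibble(
      x = sub[i_ctr, 1L], y = sub[i_ctr, 2L], z = sub[i_ctr, 3L],
      cluster_id = k, kind = "cluster_center",
      match_count = mc[i_ctr], cluster_size = cl$size
    )
    if (i_best != i_ctr) {
      rows <- dplyr::bind_rows(rows, tibble(
        x = sub[i_best, 1L], y = sub[i_best, 2L], z = sub[i_best, 3L],
        cluster_id = k, kind = "best_match",
        match_count = mc[i_best], cluster_size = cl$size
      ))
    }
    rows
  })
  dplyr::bind_rows(seeds)
}
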