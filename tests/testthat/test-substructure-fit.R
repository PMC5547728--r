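test_that("correspondence graph encodes key equality and distance consistency", {
  site <- mk_atoms(rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0)),
                   atom_name = c("NZ", "OG", "CB"),
                   res_name = c("LYS", "SER", "ALA"))
  # identical patch: identity matching forms a clique of size 3
  g <- build_correspondence_graph(site, site)
  expect_equal(nrow(g$vertices), 3L)                 # unique keys: 3 pairs
  ident <- which(g$vertices$i == g$vertices$j)
  expect_true(all(g$adj[ident, ident] | diag(3)))

  # rigidly moved copy preserves all distances: identity clique remains
  withr::local_seed(11)
  moved <- rigid_move(site, rand_rot(), c(7, -2, 3))
  g2 <- build_correspondence_graph(site, moved)
  ident2 <- which(g2$vertices$i == g2$vertices$j)
  expect_length(ident2, 3L)
  expect_true(all(g2$adj[ident2, ident2] | diag(3)))

  # disjoint keys give an empty graph
  other <- mk_atoms(rbind(c(0, 0, 0)), atom_name = "SD", res_name = "MET")
  expect_equal(nrow(build_correspondence_graph(site, other)$vertices), 0L)
})

test_that("backtracking clique search is exact against subset enumeration", {
  # complete graph K8
  k8 <- rand_graph(8, 1.1)
  res <- max_clique_backtracking(k8, min_size = 3)
  expect_equal(res$size, 8L)
  expect_true(res$exact)

  # 5-cycle is triangle-free: max clique 2 < min_size -> empty result
  c5 <- matrix(FALSE, 5, 5)
  for (k in 1:5) {
    c5[k, k %% 5 + 1] <- TRUE
    c5[k %% 5 + 1, k] <- TRUE
  }
  res5 <- max_clique_backtracking(list(vertices = NULL, adj = c5), min_size = 3)
  expect_equal(res5$size, 0L)
  expect_length(res5$cliques, 0L)

  # random 12-vertex graphs against the brute-force oracle
  withr::local_seed(77)
  for (k in 1:25) {
    g <- rand_graph(12, runif(1, 0.3, 0.8))
    oracle <- brute_force_max_clique(g$adj)
    mine <- max_clique_backtracking(g, min_size = 3)
    if (oracle >= 3L) {
      expect_equal(mine$size, oracle)
      # every returned clique really is a clique of that size
      for (cl in mine$cliques) {
        expect_length(cl, oracle)
        expect_true(all(g$adj[cl, cl] | diag(length(cl))))
      }
    } else {
      expect_equal(mine$size, 0L)
    }
  }
})

test_that("an exhausted budget is flagged best-effort", {
  withr::local_seed(5)
  g <- rand_graph(20, 0.9)
  res <- max_clique_backtracking(g, min_size = 3, budget = 50)
  expect_false(res$exact)
})

test_that("fit_transform recovers constructed rigid motions exactly", {
  withr::local_seed(19)
  x <- matrix(rnorm(15), ncol = 3)
  # identity
  id <- fit_transform(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)

  # 90 degrees about z plus translation (1, 2, 3)
  rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  y <- x %*% t(rz) + matrix(c(1, 2, 3), nrow(x), 3, byrow = TRUE)
  tr <- fit_transform(x, y)
  expect_equal(tr$rotation, rz, tolerance = 1e-6)
  expect_equal(tr$translation, c(1, 2, 3), tolerance = 1e-6)
  expect_lte(tr$rmsd, 1e-9)
  # orthonormality and proper rotation
  expect_equal(t(tr$rotation) %*% tr$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-8)

  # least-squares RMSD is symmetric in which set moves
  y2 <- y + matrix(rnorm(15, sd = 0.3), ncol = 3)
  expect_equal(fit_transform(x, y2)$rmsd, fit_transform(y2, x)$rmsd,
               tolerance = 1e-9)

  # collinear sets are degenerate
  line <- cbind(1:4, 0, 0)
  expect_error(fit_transform(line, line + 1), class = "nucsite_degenerate_fit")
})

test_that("planar three-point fits agree with a rotation-angle grid oracle", {
  withr::local_seed(23)
  for (k in 1:5) {
    x <- cbind(matrix(rnorm(6), ncol = 2), 0)
    ang <- runif(1, 0, 2 * pi)
    rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    y <- x %*% t(rz) + matrix(c(2, -1, 0), 3, 3, byrow = TRUE)
    y <- y + cbind(matrix(rnorm(6, sd = 0.15), ncol = 2), 0)  # planar noise
    fitted <- fit_transform(x, y)
    # oracle: direct minimization over in-plane rotation angles
    xc <- sweep(x, 2, colMeans(x))
    yc <- sweep(y, 2, colMeans(y))
    # a proper 3D rotation can also flip the plane (Rz(a) after a half-turn
    # about x), which acts as a 2D mirror: the oracle covers both families
    flip <- diag(c(1, -1, -1))
    angles <- seq(0, 2 * pi, length.out = 20000)
    rmsd_at <- vapply(angles, function(a) {
      rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
      min(sqrt(mean(rowSums((xc %*% t(rz) - yc)^2))),
          sqrt(mean(rowSums((xc %*% t(rz %*% flip) - yc)^2))))
    }, numeric(1))
    expect_equal(fitted$rmsd, min(rmsd_at), tolerance = 1e-3)
  }
})

test_that("pose_ligand reproduces the source geometry and preserves rigidity", {
  cx <- make_complex(seed = 61, n_shell_atoms = 10, decoy_size = 20)
  tpl <- extract_template(cx$protein, cx$ligand, template_id = "self")

  # fit the template to its own site: identity recovery
  g <- build_correspondence_graph(tpl$site_atoms, tpl$site_atoms)
  cl <- max_clique_backtracking(g, min_size = 4)
  expect_gte(cl$size, nrow(tpl$site_atoms))
  pose <- pose_ligand(tpl, cl, g, tpl$site_atoms, seed = tpl$ligand_center)
  expect_equal(pose$center, tpl$ligand_center, tolerance = 1e-6)
  expect_lte(pose$transform$rmsd, 1e-9)

  # rigid copy of the whole complex: the pose overlays the true ligand
  withr::local_seed(3)
  rot <- rand_rot()
  shift <- c(6, 6, -6)
  moved_site <- rigid_move(tpl$site_atoms, rot, shift)
  true_lig <- rigid_move(tpl$ligand_atoms, rot, shift)
  g2 <- build_correspondence_graph(tpl$site_atoms, moved_site)
  cl2 <- max_clique_backtracking(g2, min_size = 4)
  pose2 <- pose_ligand(tpl, cl2, g2, moved_site)
  dev <- sqrt((pose2$atoms$x - true_lig$x)^2 + (pose2$atoms$y - true_lig$y)^2 +
                (pose2$atoms$z - true_lig$z)^2)
  expect_lt(max(dev), 1e-6)

  # intra-ligand distances are untouched (conformation copied rigidly)
  d_before <- dist(cbind(tpl$ligand_atoms$x, tpl$ligand_atoms$y, tpl$ligand_atoms$z))
  d_after <- dist(cbind(pose2$atoms$x, pose2$atoms$y, pose2$atoms$z))
  expect_equal(as.numeric(d_after), as.numeric(d_before), tolerance = 1e-6)
})

test_that("degenerate (collinear) cliques are discarded, not fitted", {
  line_site <- mk_atoms(cbind(c(0, 4, 8), 0, 0), atom_name = "NZ",
                        res_name = "LYS")
  lig <- mk_atoms(rbind(c(0, 3.5, 0), c(4, 3.5, 0), c(8, 3.5, 0), c(4, 3.5, 2)),
                  is_hetero = TRUE, res_name = "ATP",
                  atom_name = c("PA", "PB", "PG", "O1A"))
  tpl <- extract_template(line_site, lig, template_id = "line")
  g <- build_correspondence_graph(tpl$site_atoms, tpl$site_atoms)
  cl <- max_clique_backtracking(g, min_size = 3)
  expect_gte(cl$size, 3L)
  expect_null(pose_ligand(tpl, cl, g, tpl$site_atoms))
})
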