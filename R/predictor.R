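# Orchestration: loop templates x seeds over the target, pool energy-filtered
# poses, cluster pose centers into ranked predicted sites, and score binding
# residues by the number of surviving poses they contact.

#' Prediction configuration
#'
#' All tunable thresholds of the pipeline with their defaults: grid step 2 A,
#' solvent shell (1.6, 10] A; matching tolerances 2 A (surface distance and
#' triangle edges), triangle fraction 0.25 with a 50-triangle floor; top 3
#' grid clusters; clique minimum size 4 with a 1e6-expansion budget; energy
#' threshold 0 kcal/mol; pose-center linkage < 4 A with top 5 sites; contact
#' cutoff 3.9 A.
#'
#' @param ... Name = value overrides of nested keys, e.g. `grid.step = 1`,
#'   `match.edge_tol = 1.5`, `sites.top_n = 3`.
#' @return Nested configuration list.
#' @export
nucsite_config <- function(...) {
  cfg <- list(
    grid = list(step = 2, inner = 1.6, outer = 10),
    match = list(edge_tol = 2, center_tol = 2, frac = 0.25, min_triangles = 50L),
    seeds = list(top_clusters = 3L),
    clique = list(min_size = 4L, budget = 1e6),
    energy = list(dielectric = "distance", coefficient = 4, cutoff = 12,
                  threshold = 0),
    sites = list(link_dist = 4, top_n = 5L),
    contact = list(cutoff = 3.9)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || is.null(cfg[[parts[1L]]]) ||
        !parts[2L] %in% names(cfg[[parts[1L]]])) {
      abort(paste0("unknown config key: ", nm), class = "nucsite_config_error")
    }
    cfg[[parts[1L]]][[parts[2L]]] <- dots[[nm]]
  }
  cfg
}

#' Predict nucleotide binding sites on a protein structure
#'
#' Runs the full template-matching pipeline: for each library template the
#' solvent grid is scanned with the surface-distance and triangle criteria,
#' surviving grid points are clustered into up to three seed regions, the
#' maximal common substructure between the template site and each
#' seed-associated surface patch is found by backtracking clique search, and
#' the template ligand is placed by least-squares superposition. Pooled poses
#' are filtered by nonbonded interaction energy, clustered into ranked
#' predicted sites, and per-residue binding scores are derived. The run is
#' deterministic given identical inputs and configuration.
#'
#' @param protein Tibble of protein atoms (or the list from
#'   [read_structure()], whose `$protein` is used).
#' @param library A `nucsite_library`.
#' @param config Configuration from [nucsite_config()].
#' @param params Nonbonded parameters; defaults follow the energy config keys.
#' @param target_labels,filter_level Optional homology filtering of the
#'   library before prediction (see [filter_library()]).
#' @return A `nucsite_prediction`: list with `sites` (ranked tibble),
#'   `residues` (scored tibble), `poses` (list), `n_templates`, `config`.
#' @export
predict_sites <- function(protein, library, config = nucsite_config(),
                          params = NULL, target_labels = NULL,
                          filter_level = NULL) {
  if (is.list(protein) && !is.data.frame(protein)) protein <- protein$protein
  if (!is.null(filter_level)) {
    library <- filter_library(library, target_labels, filter_level)
  }
  if (length(library) == 0L) {
    abort("template library is empty (after filtering)",
          class = "nucsite_config_error")
  }
  params <- params %||% nonbonded_params(
    dielectric = config$energy$dielectric,
    coefficient = config$energy$coefficient,
    cutoff = config$energy$cutoff
  )

  grid <- build_grid(protein, step = config$grid$step,
                     outer = config$grid$outer, inner = config$grid$inner)
  keys <- atom_key(protein)
  m <- coords_mat(protein)

  poses <- list()
  for (tpl in library) {
    tri <- template_triangles(tpl)
    retained <- scan_grid(grid, protein, tpl, tri,
                          edge_tol = config$match$edge_tol,
                          center_tol = config$match$center_tol,
                          frac = config$match$frac,
                          min_triangles = config$match$min_triangles)
    if (nrow(retained) == 0L) next
    seeds <- cluster_and_seed(retained, step = config$grid$step,
                              top_k = config$seeds$top_clusters,
                              protein = protein)
    for (s in seq_len(nrow(seeds))) {
      seed_pt <- c(seeds$x[s], seeds$y[s], seeds$z[s])
      d <- cross_dist(rbind(seed_pt), m)[1L, ]
      patch <- protein[d <= tpl$R + 2, ]
      graph <- build_correspondence_graph(tpl$site_atoms, patch,
                                          tol = config$match$edge_tol)
      cl <- max_clique_backtracking(graph,
                                    min_size = config$clique$min_size,
                                    budget = config$clique$budget)
      if (cl$size == 0L) next
      pose <- pose_ligand(tpl, cl, graph, patch, seed = seed_pt)
      if (!is.null(pose)) poses[[length(poses) + 1L]] <- pose
    }
  }

  if (length(poses) == 0L) {
    warn("no pose survived matching; returning empty predictions")
  } else {
    poses <- filter_poses(poses, protein, params,
                          threshold = config$energy$threshold)
    if (length(poses) == 0L) {
      warn("no pose survived the energy filter; returning empty predictions")
    }
  }

  sites <- cluster_sites(poses, link_dist = config$sites$link_dist,
                         top_n = config$sites$top_n)
  residues <- score_residues(protein, poses,
                             contact_cutoff = config$contact$cutoff)
  structure(
    list(sites = sites, residues = residues, poses = poses,
         n_templates = length(library), config = config),
    class = "nucsite_prediction"
  )
}

#' Cluster pose centers into ranked predicted sites
#'
#' Single-linkage clustering of pose geometric centers with strict
#' `< link_dist` adjacency (centers exactly `link_dist` apart stay separate).
#' Clusters are ranked by member count descending (ties: better best energy,
#' then lexicographic center) and the top `top_n` are kept; the
#' representative center is the mean of member centers.
#'
#' @param poses List of ligand poses (with `energy` filled).
#' @param link_dist Linkage distance in Angstrom; default 4.
#' @param top_n Number of sites to report; default 5.
#' @return Tibble: `rank`, `x`, `y`, `z`, `n_members`, `best_energy`,
#'   `member_templates` (list-column).
#' @export
cluster_sites <- function(poses, link_dist = 4, top_n = 5L) {
  stopifnot(link_dist > 0, top_n >= 1L)
  empty <- tibble(rank = integer(), x = numeric(), y = numeric(),
                  z = numeric(), n_members = integer(),
                  best_energy = numeric(), member_templates = list())
  if (length(poses) == 0L) return(empty)
  ctr <- do.call(rbind, lapply(poses, `[[`, "center"))
  adj <- cross_dist(ctr, ctr) < link_dist
  comp <- adjacency_components(adj)
  info <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    cc <- colMeans(ctr[idx, , drop = FALSE])
    list(
      idx = idx, n = length(idx), center = cc,
      best_energy = min(vapply(poses[idx], `[[`, 0, "energy")),
      templates = vapply(poses[idx], `[[`, "", "template_id")
    )
  })
  ord <- order(
    -vapply(info, `[[`, 0L, "n"),
    vapply(info, `[[`, 0, "best_energy"),
    vapply(info, function(z) z$center[1L], 0),
    vapply(info, function(z) z$center[2L], 0),
    vapply(info, function(z) z$center[3L], 0)
  )
  info <- info[ord][seq_len(min(top_n, length(info)))]
  tibble(
    rank = seq_along(info),
    x = vapply(info, function(z) z$center[1L], 0),
    y = vapply(info, function(z) z$center[2L], 0),
    z = vapply(info, function(z) z$center[3L], 0),
    n_members = vapply(info, `[[`, 0L, "n"),
    best_energy = vapply(info, `[[`, 0, "best_energy"),
    member_templates = lapply(info, `[[`, "templates")
  )
}

#' Score residues by the number of poses they contact
#'
#' For each residue of the target, counts the surviving poses with at least
#' one atom pair within `contact_cutoff` (a pose contributes 1 no matter how
#' many atom contacts it makes). Residues are sorted by score descending,
#' ties by protein residue order.
#'
#' @param protein Tibble of protein atoms.
#' @param poses List of ligand poses.
#' @param contact_cutoff Contact cutoff in Angstrom; default 3.9.
#' @return Tibble: `chain`, `res_num`, `ins_code`, `res_name`, `score`.
#' @export
score_residues <- function(protein, poses, contact_cutoff = 3.9) {
  stopifnot(contact_cutoff > 0)
  res <- dplyr::distinct(protein, .data$chain, .data$res_num, .data$ins_code,
                         .data$res_name)
  res$score <- 0L
  rkey <- residue_key(res)
  akey <- residue_key(protein)
  pm <- coords_mat(protein)
  for (p in poses) {
    d <- cross_dist(pm, coords_mat(p$atoms))
    hit <- unique(akey[apply(d <= contact_cutoff + 1e-9, 1L, any)])
    res$score <- res$score + as.integer(rkey %in% hit)
  }
  res$.ord <- seq_len(nrow(res))
  res <- dplyr::arrange(res, dplyr::desc(.data$score), .data$.ord)
  dplyr::select(res, -".ord")
}

#' Binary binding calls at a score threshold
#'
#' A residue is called binding iff its score is strictly greater than the
#' threshold, so raising the threshold can only shrink the predicted set.
#'
#' @param scores Residue score tibble from [score_residues()].
#' @param threshold Non-negative integer threshold.
#' @return `scores` with a logical `call` column added.
#' @export
calls_at_threshold <- function(scores, threshold) {
  stopifnot(threshold >= 0)
  scores$call <- scores$score > threshold
  scores
}

#' Write prediction outputs to a directory
#'
#' Emits `sites.tsv` (rank, x, y, z, n_members, best_energy),
#' `residues.tsv` (chain, res_num, ins_code, res_name, score) and `poses.pdb`
#' (multi-MODEL HETATM records), with fixed numeric formatting so identical
#' predictions give byte-identical files.
#'
#' @param prediction A `nucsite_prediction`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_predictions <- function(prediction, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- prediction$sites
  sites_chr <- data.frame(
    rank = s$rank,
    x = sprintf("%.4f", s$x), y = sprintf("%.4f", s$y),
    z = sprintf("%.4f", s$z),
    n_members = s$n_members,
    best_energy = sprintf("%.4f", s$best_energy)
  )
  utils::write.table(sites_chr, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(prediction$residues),
                     file.path(dir, "residues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_poses_pdb(prediction$poses, file.path(dir, "poses.pdb"))
  invisible(dir)
}

#' @export
print.nucsite_prediction <- function(x, ...) {
  cat(sprintf(
    "<nucsite_prediction> %d templates, %d surviving poses, %d predicted sites\n",
    x$n_templates, length(x$poses), nrow(x$sites)
  ))
  if (nrow(x$sites) > 0L) print(dplyr::select(x$sites, -"member_templates"))
  invisible(x)
}

#' @describeIn predict_sites Ranked predicted sites as a tibble.
#' @param x A `nucsite_prediction`.
#' @method tidy nucsite_prediction
#' @export
tidy.nucsite_prediction <- function(x, ...) {
  dplyr::select(x$sites, -"member_templates")
}

#' @describeIn predict_sites One-row run summary.
#' @method glance nucsite_prediction
#' @export
glance.nucsite_prediction <- function(x, ...) {
  tibble(
    n_templates = x$n_templates,
    n_poses = length(x$poses),
    n_sites = nrow(x$sites),
    best_energy = if (length(x$poses) > 0L) {
      min(vapply(x$poses, `[[`, 0, "energy"))
    } else NA_real_,
    n_binding_residues = sum(x$residues$score > 0L)
  )
}
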