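# Deterministic synthetic protein-nucleotide complexes and apo decoy targets.
#
# These toy structures let every pipeline stage run end to end without any
# downloaded data: a rigid toy nucleotide is surrounded by a planted contact
# shell (each shell atom 3.3-3.9 A from the ligand, so it is an interacting
# atom by construction) embedded in a decoy atom cloud that stays clear of
# the pocket. All randomness flows through one explicit seed.

# Pools of plausible (residue, atom) identities for shell and decoy atoms.
# Real nucleotide sites are charge-complementary: phosphates are coordinated
# by donors and cations (P-loop Lys/Thr/backbone NH), the nucleoside by
# polar/apolar atoms. Shell atoms anchored to a phosphate group draw from
# the donor pool; everything else (and all decoys) from the neutral pool.
POOL_DONOR <- tibble::tibble(
  res_name = c("LYS", "ARG", "ARG", "SER", "THR", "TYR", "HIS", "ASN",
               "GLN", "GLY"),
  atom_name = c("NZ", "NH1", "NH2", "OG", "OG1", "OH", "NE2", "ND2",
                "NE2", "N")
)
POOL_NEUTRAL <- tibble::tibble(
  res_name = c("ALA", "VAL", "LEU", "ILE", "PHE", "TRP", "MET", "CYS",
               "GLY", "THR", "SER", "HIS", "ASN", "PRO"),
  atom_name = c("CB", "CG1", "CD1", "CD1", "CZ", "NE1", "SD", "SG",
                "CA", "CB", "OG", "CD2", "OD1", "CB")
)

random_unit_vector <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

protein_atom_row <- function(pool_row, res_num, p) {
  tibble(
    atom_name = pool_row$atom_name,
    element = substr(pool_row$atom_name, 1L, 1L),
    res_name = pool_row$res_name,
    chain = "A",
    res_num = as.integer(res_num),
    ins_code = "",
    x = p[[1L]], y = p[[2L]], z = p[[3L]],
    is_hetero = FALSE,
    occupancy = 1
  )
}

# Place one decoy atom: 6-16 A from the ligand center, clear of the pocket
# (>= 4.5 A from every ligand atom), packed (>= 2.5 A from placed atoms), and
# never net-repulsive to the ligand. Bounded retries.
place_decoy <- function(lig, lig_m, lig_ctr, placed, res_num, params,
                        max_tries = 500L) {
  for (k in seq_len(max_tries)) {
    p <- lig_ctr + stats::runif(1L, 6, 16) * random_unit_vector()
    if (min(cross_dist(rbind(p), lig_m)) < 4.5) next
    if (nrow(placed) > 0L && min(cross_dist(rbind(p), placed)) < 2.5) next
    row <- protein_atom_row(POOL_NEUTRAL[sample.int(nrow(POOL_NEUTRAL), 1L), ],
                            res_num, p)
    if (interaction_energy(row, lig, params) > 0) next
    return(row)
  }
  abort("fixture packing failed after bounded retries",
        class = "nucsite_generation_error")
}

#' Generate a synthetic protein-nucleotide complex
#'
#' Places a rigid toy nucleotide at a random orientation, surrounds it with
#' `n_shell_atoms` protein atoms at 3.3-3.9 A from the ligand (guaranteed
#' interacting atoms, kept near the heavy-atom van der Waals minimum so the
#' native arrangement is net-attractive), and embeds the shell in a decoy
#' cloud in which no atom is closer than 2.5 A to any other and no decoy is
#' within 4.5 A of the ligand. Identical seeds give identical output.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_shell_atoms Number of contact-shell atoms (>= 4); default 12.
#' @param ligand_name `"ATP"`, `"ADP"` or `"AMP"`.
#' @param decoy_size Number of decoy atoms; default 60. `0` gives a shell-only
#'   protein.
#' @param noise_sigma Gaussian jitter (A) applied to shell atom placements
#'   before the contact-window check; default 0.
#' @param path Optional output path; if given, the complex is written as PDB.
#' @return List with `protein` (tibble), `ligand` (ligand instance list),
#'   `atoms` (all atoms), and `path` (or `NULL`).
#' @export
make_complex <- function(seed, n_shell_atoms = 12L, ligand_name = "ATP",
                         decoy_size = 60L, noise_sigma = 0, path = NULL) {
  stopifnot(n_shell_atoms >= 4L, decoy_size >= 0L, noise_sigma >= 0)
  withr::with_seed(seed, {
    lig <- toy_ligand(ligand_name)
    rot <- random_rotation()
    shift <- stats::runif(3L, -2, 2)
    lig <- apply_transform(lig, rot, shift)
    lig_m <- coords_mat(lig)
    lig_ctr <- colMeans(lig_m)

    group_map <- default_group_map(ligand_name)
    params <- nonbonded_params()
    placed <- matrix(numeric(0L), ncol = 3L)
    rows <- list()
    for (k in seq_len(n_shell_atoms)) {
      row <- NULL
      for (try in seq_len(500L)) {
        anchor <- sample.int(nrow(lig_m), 1L)
        p0 <- lig_m[anchor, ] + stats::runif(1L, 3.4, 3.9) * random_unit_vector()
        if (noise_sigma > 0) p0 <- p0 + stats::rnorm(3L, 0, noise_sigma)
        # contacts sit near the heavy-atom LJ minimum: within the 3.9 A
        # interacting window but not inside the repulsive wall
        dl <- min(cross_dist(rbind(p0), lig_m))
        if (dl < 3.3 || dl > 3.9) next
        if (nrow(placed) > 0L && min(cross_dist(rbind(p0), placed)) < 2.5) next
        pool <- if (grepl("phosphate", group_map[[lig$atom_name[anchor]]])) {
          POOL_DONOR
        } else {
          POOL_NEUTRAL
        }
        cand <- protein_atom_row(pool[sample.int(nrow(pool), 1L), ], k, p0)
        # real contacts are individually favorable: keep only identities whose
        # own nonbonded energy with the ligand is attractive
        if (interaction_energy(cand, lig, params) >= 0) next
        row <- cand
        break
      }
      if (is.null(row)) {
        abort("fixture packing failed after bounded retries",
              class = "nucsite_generation_error")
      }
      placed <- rbind(placed, c(row$x, row$y, row$z))
      rows[[k]] <- row
    }

    if (decoy_size > 0L) {
      for (k in seq_len(decoy_size)) {
        row <- place_decoy(lig, lig_m, lig_ctr, placed, n_shell_atoms + k,
                           params)
        placed <- rbind(placed, c(row$x, row$y, row$z))
        rows[[n_shell_atoms + k]] <- row
      }
    }

    protein <- dplyr::bind_rows(rows)
    atoms <- dplyr::bind_rows(protein, lig)
    if (!is.null(path)) write_pdb(atoms, path)
    list(
      protein = protein,
      ligand = list(ligand_name = ligand_name, atoms = lig,
                    source = paste0("synthetic-", seed, ":A")),
      atoms = atoms,
      path = path
    )
  })
}

#' Plant a template's site geometry into a fresh apo decoy target
#'
#' Copies the template's interacting atoms (optionally jittered) into a new
#' decoy protein at a random rigid placement. The ligand itself is not
#' written: the target is apo, and the transformed true ligand center plus
#' the contact residues are recorded as ground truth for planted-site
#' recovery tests.
#'
#' @param template A binding-site template (see [extract_template()]).
#' @param seed Integer seed.
#' @param decoy_size Number of decoy atoms; default 40.
#' @param noise_sigma Gaussian jitter (A) on planted site atoms; default 0.
#' @param path Optional output path for the apo PDB.
#' @return List with `protein`, `truth` (list: `center`, `residues`,
#'   `ligand_atoms`), and `path`.
#' @export
make_planted_target <- function(template, seed, decoy_size = 40L,
                                noise_sigma = 0, path = NULL) {
  withr::with_seed(seed, {
    rot <- random_rotation()
    shift <- stats::runif(3L, -5, 5)
    site <- apply_transform(template$site_atoms, rot, shift)
    lig <- apply_transform(template$ligand_atoms, rot, shift)
    lig_m <- coords_mat(lig)
    lig_ctr <- colMeans(lig_m)
    if (noise_sigma > 0) {
      # truncated jitter: structural variation never creates heavy-atom
      # overlaps, so redraw any displacement that lands inside 3.1 A of the
      # (unwritten) ligand
      sm <- coords_mat(site)
      for (i in seq_len(nrow(sm))) {
        for (try in seq_len(200L)) {
          cand <- sm[i, ] + stats::rnorm(3L, 0, noise_sigma)
          if (min(cross_dist(rbind(cand), lig_m)) >= 3.1) {
            sm[i, ] <- cand
            break
          }
        }
      }
      site$x <- sm[, 1L]
      site$y <- sm[, 2L]
      site$z <- sm[, 3L]
    }

    placed <- coords_mat(site)
    rows <- list()
    if (decoy_size > 0L) {
      params <- nonbonded_params()
      for (k in seq_len(decoy_size)) {
        row <- place_decoy(lig, lig_m, lig_ctr, placed, 500L + k, params)
        placed <- rbind(placed, c(row$x, row$y, row$z))
        rows[[k]] <- row
      }
    }
    protein <- dplyr::bind_rows(c(list(site), rows))
    protein$is_hetero <- FALSE
    if (!is.null(path)) write_pdb(protein, path)
    list(
      protein = protein,
      truth = list(
        center = lig_ctr,
        residues = unique(residue_key(site)),
        ligand_atoms = lig
      ),
      path = path
    )
  })
}
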