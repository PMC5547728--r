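# AMBER-style nonbonded (van der Waals + electrostatic) scoring of ligand
# poses against the protein, used as a keep/discard filter: because protein
# and ligand are not covalently linked, only intermolecular pair terms enter.
#
#   E = sum over protein-ligand pairs within the cutoff of
#       eps_ij [ (Rmin_ij / r)^12 - 2 (Rmin_ij / r)^6 ]  +  k q_i q_j / (eps_r(r) r)
#
# with Lorentz-Berthelot-style combination (eps_ij = sqrt(eps_i eps_j),
# Rmin_ij = Rmin/2_i + Rmin/2_j) and k = 332.0637 kcal A / (mol e^2). The
# dielectric is distance-dependent by default (eps_r = 4 r, the common choice
# for rigid hydrogen-free scoring) and can be set constant.

COULOMB_CONSTANT <- 332.0637

#' Nonbonded parameter set
#'
#' Loads the bundled minimal AMBER-ff99-style table (Lennard-Jones epsilon
#' and Rmin/2 per atom class, class-level partial charges) keyed by
#' (residue name, atom name), together with the dielectric model, cutoff and
#' element-level fallback settings.
#'
#' @param path Parameter TSV (columns `res_name`, `atom_name`, `epsilon`,
#'   `rmin_half`, `charge`); defaults to the bundled table.
#' @param dielectric `"distance"` for eps_r = coefficient * r (default) or
#'   `"constant"` for eps_r = coefficient.
#' @param coefficient Dielectric coefficient; default 4 for the
#'   distance-dependent model.
#' @param cutoff Nonbonded cutoff in Angstrom; default 12.
#' @param fallback Allow unparameterized atoms to fall back to element-level
#'   defaults (epsilon 0.1, Rmin/2 1.7, charge 0) with a warning; default TRUE.
#' @return A `nucsite_params` list.
#' @export
nonbonded_params <- function(path = NULL,
                             dielectric = c("distance", "constant"),
                             coefficient = NULL, cutoff = 12,
                             fallback = TRUE) {
  dielectric <- match.arg(dielectric)
  coefficient <- coefficient %||% if (dielectric == "distance") 4 else 1
  path <- path %||% system.file("extdata", "nonbonded_params.tsv",
                                package = "nucsite", mustWork = TRUE)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("res_name", "atom_name", "epsilon", "rmin_half", "charge")
                %in% names(tab)),
            all(tab$epsilon >= 0), all(tab$rmin_half > 0))
  structure(
    list(
      table = tab,
      index = setNames(seq_len(nrow(tab)),
                       paste(tab$res_name, tab$atom_name, sep = "/")),
      dielectric = dielectric,
      coefficient = coefficient,
      cutoff = cutoff,
      fallback = fallback
    ),
    class = "nucsite_params"
  )
}

# Per-atom (epsilon, rmin_half, charge) lookup with element-level fallback.
lookup_params <- function(atoms, params) {
  key <- paste(atoms$res_name, atoms$atom_name, sep = "/")
  idx <- params$index[key]
  miss <- is.na(idx)
  if (any(miss)) {
    if (!params$fallback) {
      abort(paste0("no nonbonded parameters for: ",
                   paste(unique(key[miss]), collapse = ", ")),
            class = "nucsite_parameter_error")
    }
    warn(paste0("element-level fallback parameters used for: ",
                paste(unique(key[miss]), collapse = ", ")))
  }
  tab <- params$table
  list(
    epsilon = ifelse(miss, 0.1, tab$epsilon[idx]),
    rmin_half = ifelse(miss, 1.7, tab$rmin_half[idx]),
    charge = ifelse(miss, 0, tab$charge[idx])
  )
}

#' Protein-ligand nonbonded interaction energy
#'
#' Sums Lennard-Jones and Coulomb terms over all protein-ligand atom pairs
#' within the cutoff. No intramolecular terms are computed. The energy is
#' invariant under joint rigid transformation of protein and pose and
#' symmetric in the roles of the two atoms of each pair.
#'
#' @param protein Tibble of protein atoms.
#' @param pose A ligand pose (list with `atoms`) or an atom tibble.
#' @param params A `nucsite_params` set from [nonbonded_params()].
#' @return Energy in kcal/mol (0 if no pair is within the cutoff).
#' @export
interaction_energy <- function(protein, pose, params = nonbonded_params()) {
  lig <- if (is.data.frame(pose)) pose else pose$atoms
  d <- cross_dist(coords_mat(protein), coords_mat(lig))
  within <- which(d <= params$cutoff, arr.ind = TRUE)
  if (nrow(within) == 0L) return(0)
  pp <- lookup_params(protein, params)
  pl <- lookup_params(lig, params)
  i <- within[, 1L]
  j <- within[, 2L]
  r <- d[within]
  eps <- sqrt(pp$epsilon[i] * pl$epsilon[j])
  rmin <- pp$rmin_half[i] + pl$rmin_half[j]
  q <- (rmin / r)^6
  vdw <- eps * (q^2 - 2 * q)
  er <- if (params$dielectric == "distance") params$coefficient * r else params$coefficient
  elec <- COULOMB_CONSTANT * pp$charge[i] * pl$charge[j] / (er * r)
  sum(vdw + elec)
}

#' Annotate poses with interaction energy and discard weak binders
#'
#' Each pose's `energy` field is filled; poses with energy at or above
#' `threshold` (default 0 kcal/mol, i.e. anything not net-attractive,
#' including steric clashes) are removed. Input order is preserved.
#'
#' @param poses List of ligand poses.
#' @param protein Tibble of protein atoms.
#' @param params A `nucsite_params` set.
#' @param threshold Discard threshold in kcal/mol; default 0.
#' @return Filtered list of poses with `energy` filled.
#' @export
filter_poses <- function(poses, protein, params = nonbonded_params(),
                         threshold = 0) {
  scored <- lapply(poses, function(p) {
    p$energy <- interaction_energy(protein, p, params)
    p
  })
  keep <- vapply(scored, function(p) p$energy < threshold, logical(1L))
  scored[keep]
}
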