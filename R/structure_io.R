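# PDB-format structure input/output and the contact primitive.
#
# Atoms are carried as tibbles with one row per non-hydrogen atom and columns
#   atom_name, element, res_name, chain, res_num, ins_code,
#   x, y, z, is_hetero, occupancy
# which is the universal currency of every downstream module.

WATER_NAMES <- c("HOH", "WAT", "DOD")
ION_NAMES <- c(
  "NA", "K", "MG", "CA", "ZN", "CL", "MN", "FE", "CU", "CO", "NI", "CD",
  "BR", "IOD", "SO4", "PO4"
)

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records from a PDB file into a protein atom table and a
#' list of ligand instances. Hydrogens (and deuterium), waters and common
#' monoatomic ions are dropped at parse time. For multi-model (NMR) files only
#' the first model is used; for alternate locations the highest-occupancy
#' conformer is kept, ties broken by altloc letter.
#'
#' @param path Path to a PDB-format file.
#' @param ligand_names Character vector of 3-letter HETATM residue codes to
#'   extract as ligand instances (e.g. `c("ATP", "ADP", "AMP")`).
#' @param id Structure identifier; defaults to the file name without extension.
#'
#' @return A list with elements
#'   \describe{
#'     \item{protein}{tibble of polymer (ATOM) atoms, `is_hetero = FALSE`.}
#'     \item{ligands}{list of ligand instances, each a list with `ligand_name`,
#'       `atoms` (tibble) and `source` (structure id plus chain).}
#'     \item{id}{the structure identifier.}
#'   }
#' @export
read_structure <- function(path, ligand_names = character(), id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "nucsite_format_error")
  }
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  # first model only
  first_model <- match(TRUE, startsWith(lines, "MODEL"), nomatch = NA_integer_)
  if (!is.na(first_model)) {
    end_model <- match(TRUE, startsWith(lines, "ENDMDL"), nomatch = length(lines) + 1L)
    lines <- lines[seq.int(first_model, min(end_model, length(lines)))]
  }

  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L) {
    abort("no ATOM/HETATM records found", class = "nucsite_format_error")
  }

  fld <- function(a, b) trimws(substr(lines, a, b))
  atoms <- tibble(
    record = fld(1L, 6L),
    atom_name = fld(13L, 16L),
    alt_loc = fld(17L, 17L),
    res_name = fld(18L, 20L),
    chain = fld(22L, 22L),
    res_num = suppressWarnings(as.integer(fld(23L, 26L))),
    ins_code = fld(27L, 27L),
    x = suppressWarnings(as.numeric(fld(31L, 38L))),
    y = suppressWarnings(as.numeric(fld(39L, 46L))),
    z = suppressWarnings(as.numeric(fld(47L, 54L))),
    occupancy = suppressWarnings(as.numeric(fld(55L, 60L))),
    element = toupper(fld(77L, 78L))
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    abort("malformed coordinate fields in PDB file", class = "nucsite_format_error")
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1

  # element fallback: strip leading digits/primes from the atom name
  guess <- sub("^[0-9']+", "", atoms$atom_name)
  atoms$element <- ifelse(atoms$element == "", substr(guess, 1L, 1L), atoms$element)

  atoms <- dplyr::filter(
    atoms,
    !(.data$element %in% c("H", "D")),
    !(.data$res_name %in% WATER_NAMES)
  )
  atoms <- dplyr::filter(
    atoms,
    !(.data$record == "HETATM" & .data$res_name %in% ION_NAMES)
  )

  # altloc resolution: highest occupancy, ties by altloc letter order;
  # file order restored afterwards via the serial column
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms |>
    dplyr::group_by(
      .data$record, .data$chain, .data$res_num, .data$ins_code,
      .data$res_name, .data$atom_name
    ) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt_loc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")

  atoms$is_hetero <- atoms$record == "HETATM"
  atoms <- dplyr::select(atoms, -"record", -"alt_loc")

  protein <- dplyr::filter(atoms, !.data$is_hetero)
  if (nrow(protein) == 0L) {
    abort("structure contains no polymer (ATOM) atoms after filtering",
          class = "nucsite_empty_structure")
  }

  het <- dplyr::filter(atoms, .data$is_hetero, .data$res_name %in% ligand_names)
  ligands <- list()
  if (nrow(het) > 0L) {
    grp <- split(het, paste(het$res_name, het$chain, het$res_num, het$ins_code))
    grp <- grp[order(match(names(grp), unique(paste(het$res_name, het$chain,
                                                    het$res_num, het$ins_code))))]
    for (g in grp) {
      if (nrow(g) < 3L || is_collinear(coords_mat(g))) {
        warn(paste0("skipping ligand ", g$res_name[[1L]], " ", g$chain[[1L]],
                    g$res_num[[1L]], ": fewer than 3 non-collinear atoms"))
        next
      }
      ligands[[length(ligands) + 1L]] <- list(
        ligand_name = g$res_name[[1L]],
        atoms = g,
        source = paste0(id, ":", g$chain[[1L]])
      )
    }
  }
  list(protein = protein, ligands = ligands, id = id)
}

# TRUE if a point set is (nearly) collinear.
is_collinear <- function(m, tol = 1e-6) {
  if (nrow(m) < 3L) return(TRUE)
  c0 <- sweep(m, 2L, colMeans(m))
  sv <- svd(c0, nu = 0L, nv = 0L)$d
  sv[2L] < tol
}

#' Protein atoms in contact with a ligand
#'
#' Returns exactly the protein atoms having at least one ligand atom within
#' `cutoff` (Euclidean, inclusive). Order follows the protein atom order.
#'
#' @param protein Tibble of protein atoms.
#' @param ligand_atoms Tibble of ligand atoms (or a ligand instance list).
#' @param cutoff Contact distance in Angstrom; default 3.9.
#' @return Tibble of contacting protein atoms.
#' @export
interacting_atoms <- function(protein, ligand_atoms, cutoff = 3.9) {
  stopifnot(cutoff > 0)
  ligand_atoms <- ligand_atom_table(ligand_atoms)
  if (nrow(protein) == 0L || nrow(ligand_atoms) == 0L) {
    return(protein[0L, ])
  }
  d <- cross_dist(coords_mat(protein), coords_mat(ligand_atoms))
  # 1e-9 guard keeps "within" inclusive at exact decimal boundaries
  protein[apply(d <= cutoff + 1e-9, 1L, any), ]
}

ligand_atom_table <- function(x) {
  if (is.data.frame(x)) x else x$atoms
}

#' Residues in contact with a ligand
#'
#' A residue is a binding residue iff any of its non-hydrogen atoms is within
#' `cutoff` of any ligand atom. Residue identity is
#' (chain, res_num, ins_code, res_name).
#'
#' @inheritParams interacting_atoms
#' @return Tibble with one row per binding residue, in protein order.
#' @export
binding_residues <- function(protein, ligand_atoms, cutoff = 3.9) {
  hits <- interacting_atoms(protein, ligand_atoms, cutoff)
  dplyr::distinct(hits, .data$chain, .data$res_num, .data$ins_code, .data$res_name)
}

# Compact residue identifier strings, e.g. "A:17::LYS".
residue_key <- function(atoms) {
  paste(atoms$chain, atoms$res_num, atoms$ins_code, atoms$res_name, sep = ":")
}

# Matching key used for atom-type comparison: PDB atom name + residue type.
atom_key <- function(atoms) {
  paste(atoms$atom_name, atoms$res_name, sep = "/")
}

#' Write an atom table as PDB ATOM/HETATM records
#'
#' @param atoms Tibble of atoms.
#' @param path Output file path.
#' @param append Append to an existing file (used for multi-MODEL output).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path, append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(format_pdb_lines(atoms), con)
  writeLines("END", con)
  invisible(path)
}

format_pdb_lines <- function(atoms) {
  rec <- ifelse(atoms$is_hetero, "HETATM", "ATOM  ")
  name <- ifelse(nchar(atoms$atom_name) < 4L,
                 sprintf(" %-3s", atoms$atom_name),
                 sprintf("%-4s", atoms$atom_name))
  pad1 <- function(s) ifelse(s == "", " ", substr(s, 1L, 1L))
  occ <- atoms$occupancy %||% rep(1, nrow(atoms))
  sprintf(
    "%s%5d %s %-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(atoms)), name, atoms$res_name, pad1(atoms$chain),
    atoms$res_num, pad1(atoms$ins_code), atoms$x, atoms$y, atoms$z,
    occ, 0, atoms$element
  )
}

#' Write ligand poses as a multi-MODEL PDB file
#'
#' Each pose becomes one MODEL of HETATM records, for visual inspection of
#' predicted placements.
#'
#' @param poses List of ligand poses (as produced by [pose_ligand()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_poses_pdb <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(poses)) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(format_pdb_lines(poses[[k]]$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
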