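# Shared builders for tiny in-code fixtures.

# One-row atom tibble with sensible defaults.
mk_atom <- function(x, y, z, atom_name = "CA", res_name = "GLY", chain = "A",
                    res_num = 1L, is_hetero = FALSE) {
  tibble::tibble(
    atom_name = atom_name,
    element = substr(sub("^[0-9']+", "", atom_name), 1L, 1L),
    res_name = res_name,
    chain = chain,
    res_num = as.integer(res_num),
    ins_code = "",
    x = x, y = y, z = z,
    is_hetero = is_hetero,
    occupancy = 1
  )
}

# Stack several atoms; coords is an n x 3 matrix, other args recycled.
mk_atoms <- function(coords, atom_name = "CA", res_name = "GLY", chain = "A",
                     res_num = NULL, is_hetero = FALSE) {
  coords <- rbind(coords)
  n <- nrow(coords)
  res_num <- res_num %||% seq_len(n)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    mk_atom(coords[i, 1], coords[i, 2], coords[i, 3],
            atom_name = rep_len(atom_name, n)[i],
            res_name = rep_len(res_name, n)[i],
            chain = rep_len(chain, n)[i],
            res_num = rep_len(res_num, n)[i],
            is_hetero = rep_len(is_hetero, n)[i])
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed-column PDB record line for raw-parsing tests.
pdb_line <- function(record = "ATOM", serial = 1L, name = "CA", alt = " ",
                     res = "GLY", chain = "A", resnum = 1L, icode = " ",
                     x = 0, y = 0, z = 0, occ = 1, elem = "C") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, res, chain, resnum, icode,
          x, y, z, occ, 0, elem)
}

write_pdb_lines <- function(lines, path = withr::local_tempfile(fileext = ".pdb",
                                                                .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# Random proper rotation for invariance tests.
rand_rot <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_move <- function(atoms, rot, shift) {
  m <- cbind(atoms$x, atoms$y, atoms$z) %*% t(rot)
  atoms$x <- m[, 1] + shift[1]
  atoms$y <- m[, 2] + shift[2]
  atoms$z <- m[, 3] + shift[3]
  atoms
}

# Library wrapper around templates.
as_library <- function(...) structure(list(...), class = "nucsite_library")

# Residue key strings matching the package convention.
res_keys <- function(atoms) {
  paste(atoms$chain, atoms$res_num, atoms$ins_code, atoms$res_name, sep = ":")
}

# Minimal synthetic template with homology labels, for filter tests.
stub_template <- function(id, structure_id = id, cluster40 = NA,
                          family = NA, superfamily = NA, fold = NA) {
  structure(
    list(template_id = id, ligand_name = "ATP",
         site_atoms = mk_atoms(diag(3) * 4), ligand_atoms = mk_atoms(diag(3)),
         ligand_center = c(0, 0, 0), R = 4, r = 4,
         labels = list(cluster40 = cluster40, family = family,
                       superfamily = superfamily, fold = fold),
         structure_id = structure_id, chain = "A"),
    class = "nucsite_template"
  )
}

# Bitmask brute-force maximum clique over all vertex subsets (n <= 14):
# the independent oracle for the backtracking search.
brute_force_max_clique <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  subsets <- 0:(2^n - 1)
  ok <- rep(TRUE, length(subsets))
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    # mask of vertices incompatible with i (non-neighbours other than i)
    bad <- 0L
    for (v in which(!adj[i, ] & seq_len(n) != i)) {
      bad <- bitwOr(bad, bitwShiftL(1L, v - 1L))
    }
    in_s <- bitwAnd(subsets, bit) > 0L
    ok <- ok & (!in_s | bitwAnd(subsets, bad) == 0L)
  }
  pc8 <- vapply(0:255, function(b) sum(bitwAnd(b, 2^(0:7)) > 0), integer(1))
  pc <- pc8[bitwAnd(subsets, 255L) + 1L] +
    pc8[bitwAnd(bitwShiftR(subsets, 8L), 255L) + 1L]
  max(pc[ok])
}

rand_graph <- function(n, p) {
  adj <- matrix(runif(n * n) < p, n, n)
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  list(vertices = tibble::tibble(i = seq_len(n), j = seq_len(n)), adj = adj)
}

# Construct a single-triangle template (edges 5, 7, 6) and a patch whose
# corresponding edges are controlled exactly; the apex criterion is kept
# satisfied so only the edge tolerance is probed.
single_triangle_case <- function(p_e_a, p_e_b, p_e_ab) {
  lig <- mk_atoms(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
                  is_hetero = TRUE, res_name = "ATP",
                  atom_name = c("PA", "PB", "O1A", "O1B"))
  a <- c(5, 0, 0)
  b <- c((49 - 36 + 25) / 10, sqrt(49 - ((49 - 36 + 25) / 10)^2), 0) # |b|=7, |ab|=6
  site <- mk_atoms(rbind(a, b), atom_name = c("NZ", "OG"),
                   res_name = c("LYS", "SER"))
  tpl <- structure(
    list(template_id = "tri", ligand_name = "ATP", site_atoms = site,
         ligand_atoms = lig, ligand_center = c(0, 0, 0), R = 7, r = 5,
         labels = list()),
    class = "nucsite_template"
  )
  px <- (p_e_a^2 - p_e_b^2 + p_e_ab^2) / (2 * p_e_ab)
  stopifnot(p_e_a^2 - px^2 >= 0)
  # patch frame: q at distance p_e_ab from p along x, grid point at height
  # solving both apex distances
  p <- c(0, 0, 0)
  q <- c(p_e_ab, 0, 0)
  g <- c(px, sqrt(p_e_a^2 - px^2), 0)
  patch <- mk_atoms(rbind(p, q), atom_name = c("NZ", "OG"),
                    res_name = c("LYS", "SER"))
  list(template = tpl, patch = patch, grid_point = g)
}
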