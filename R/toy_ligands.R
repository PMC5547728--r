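# Idealized rigid nucleotide geometries for synthetic fixtures.
#
# The toy ATP/ADP/AMP are built from regular polygons and standard-ish bond
# lengths (aromatic ~1.39 A, single bonds 1.4-1.6 A). They are not
# crystallographic conformers; the pipeline only requires an internally
# consistent rigid geometry with plausible PDB atom names.

#' Idealized nucleotide geometry
#'
#' Returns a rigid toy model of ATP (31 non-hydrogen atoms), ADP (27) or
#' AMP (23) with standard PDB atom names: the adenine ring system, the ribose
#' ring with its hydroxyls, and a 1-3 unit phosphate chain.
#'
#' @param name One of `"ATP"`, `"ADP"`, `"AMP"`.
#' @return Tibble of hetero atoms (chain `"A"`, residue number 999).
#' @export
toy_ligand <- function(name = c("ATP", "ADP", "AMP")) {
  name <- match.arg(name)
  unit <- function(v) v / sqrt(sum(v^2))

  pos <- list()
  put <- function(atom, p) pos[[atom]] <<- as.numeric(p)

  # adenine six-ring: regular hexagon, radius 1.39, in the z = 0 plane
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  hex_ang <- (c(90, 150, 210, 270, 330, 30)) * pi / 180
  for (k in seq_along(hex_names)) {
    put(hex_names[k], 1.39 * c(cos(hex_ang[k]), sin(hex_ang[k]), 0))
  }

  # five-ring fused on the C4-C5 edge: regular pentagon, edge 1.39
  c4 <- pos$C4; c5 <- pos$C5
  mid <- (c4 + c5) / 2
  apo5 <- 1.39 / (2 * tan(pi / 5))
  ctr5 <- mid + unit(mid) * apo5
  ang4 <- atan2(c4[2] - ctr5[2], c4[1] - ctr5[1])
  r5 <- 1.39 / (2 * sin(pi / 5))
  penta_at <- function(s, k) {
    a <- ang4 + s * k * 2 * pi / 5
    ctr5 + r5 * c(cos(a), sin(a), 0)
  }
  # orientation: going from C4 away from C5 visits N9, C8, N7, then C5
  s <- if (sum((penta_at(1, 4) - c5)^2) < sum((penta_at(-1, 4) - c5)^2)) 1 else -1
  put("N9", penta_at(s, 1)); put("C8", penta_at(s, 2)); put("N7", penta_at(s, 3))

  # exocyclic amine off C6
  put("N6", pos$C6 * (1 + 1.34 / 1.39))

  # ribose: regular pentagon (circumradius 1.30, edge ~1.53) in a tilted plane
  u <- unit(pos$N9 - ctr5)                     # glycosidic direction
  put("C1'", pos$N9 + 1.47 * u)
  w <- unit(u + c(0, 0, 1))
  rctr <- pos$`C1'` + 1.30 * w
  a1 <- unit(pos$`C1'` - rctr)
  a2_raw <- u - sum(u * w) * w
  a2 <- unit(a2_raw - sum(a2_raw * a1) * a1)
  ring_at <- function(deg) {
    a <- deg * pi / 180
    rctr + 1.30 * (cos(a) * a1 + sin(a) * a2)
  }
  put("C2'", ring_at(72)); put("C3'", ring_at(144))
  put("C4'", ring_at(216)); put("O4'", ring_at(288))
  n5 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  put("O2'", pos$`C2'` + 1.41 * unit(unit(pos$`C2'` - rctr) + 0.8 * n5))
  put("O3'", pos$`C3'` + 1.42 * unit(unit(pos$`C3'` - rctr) - 0.8 * n5))
  put("C5'", pos$`C4'` + 1.51 * unit(unit(pos$`C4'` - rctr) + 0.7 * n5))
  put("O5'", pos$`C5'` + 1.43 * w)

  # phosphate chain along w, two perpendicular oxygens per phosphorus
  pvec <- a2  # a2 is orthogonal to w by construction; a1 is antiparallel to w
  qvec <- unit(c(w[2] * pvec[3] - w[3] * pvec[2],
                 w[3] * pvec[1] - w[1] * pvec[3],
                 w[1] * pvec[2] - w[2] * pvec[1]))
  perp <- function(phi_deg) {
    a <- phi_deg * pi / 180
    cos(a) * pvec + sin(a) * qvec
  }
  n_phos <- switch(name, ATP = 3L, ADP = 2L, AMP = 1L)
  tags <- c("A", "B", "G")
  p_cur <- pos$`O5'`
  for (k in seq_len(n_phos)) {
    tg <- tags[k]
    pk <- p_cur + 1.61 * w
    put(paste0("P", tg), pk)
    phi <- (k - 1) * 60
    put(paste0("O1", tg), pk + 1.48 * perp(phi))
    put(paste0("O2", tg), pk + 1.48 * perp(phi + 120))
    if (k < n_phos) {
      o3 <- pk + 1.60 * w
      put(paste0("O3", tg), o3)
      p_cur <- o3
    } else {
      put(paste0("O3", tg), pk + 1.48 * w)
    }
  }

  m <- do.call(rbind, pos)
  tibble(
    atom_name = names(pos),
    element = substr(sub("^[0-9']+", "", names(pos)), 1L, 1L),
    res_name = name,
    chain = "A",
    res_num = 999L,
    ins_code = "",
    x = unname(m[, 1L]), y = unname(m[, 2L]), z = unname(m[, 3L]),
    is_hetero = TRUE,
    occupancy = 1
  )
}

#' Functional-group map for a nucleotide
#'
#' Maps each non-hydrogen atom name of ATP/ADP/AMP to its functional group
#' (alpha/beta/gamma phosphate, ribose, adenine), for contact profiling.
#'
#' @param name One of `"ATP"`, `"ADP"`, `"AMP"`.
#' @return Named character vector: atom name -> group label.
#' @export
default_group_map <- function(name = c("ATP", "ADP", "AMP")) {
  name <- match.arg(name)
  grp <- c(
    setNames(rep("adenine", 10L),
             c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8", "N9")),
    setNames(rep("ribose", 9L),
             c("C1'", "C2'", "O2'", "C3'", "O3'", "C4'", "O4'", "C5'", "O5'")),
    setNames(rep("alpha_phosphate", 4L), c("PA", "O1A", "O2A", "O3A"))
  )
  if (name %in% c("ATP", "ADP")) {
    grp <- c(grp, setNames(rep("beta_phosphate", 4L), c("PB", "O1B", "O2B", "O3B")))
  }
  if (name == "ATP") {
    grp <- c(grp, setNames(rep("gamma_phosphate", 4L), c("PG", "O1G", "O2G", "O3G")))
  }
  grp
}
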