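# Generates inst/extdata/nonbonded_params.tsv: a minimal AMBER-ff99-style
# nonbonded parameter table (Lennard-Jones well depth epsilon, Rmin/2, and a
# class-level partial charge) for the heavy atoms of the 20 standard residues
# and of ATP/ADP/AMP. LJ parameters follow the usual ff99 atom classes
# (CT/C/N/O/O2/OH/OS/S/P); charges are coarse class-level values, not the
# residue-specific RESP set — the table backs a keep/discard interaction
# filter, not free-energy work.
#
# Run from the package root:  Rscript data-raw/nonbonded_params.R

suppressMessages(library(tibble))

# epsilon (kcal/mol), rmin_half (A), charge (e) per atom class
classes <- list(
  # hydrogens are absent from the model, so charges are group charges with
  # the hydrogens folded into the parent heavy atom (e.g. Lys NZ(H3)+ is net
  # positive); LJ parameters follow the usual ff99 heavy-atom classes
  N_bb       = c(0.1700, 1.8240, -0.1400),  # backbone amide N(H)
  N_ring     = c(0.1700, 1.8240, -0.5000),  # bare aromatic ring N acceptor
  N_ringH    = c(0.1700, 1.8240, -0.1000),  # protonated ring N(H)
  N_amide    = c(0.1700, 1.8240, -0.0500),  # side-chain amide N(H2)
  N_plus     = c(0.1700, 1.8240,  0.5500),  # Lys NZ(H3)+, Arg NH/NE(H)+
  C_carbonyl = c(0.0860, 1.9080,  0.6000),
  C_aliph    = c(0.1094, 1.9080,  0.0500),
  C_arom     = c(0.0860, 1.9080,  0.0000),
  O_carbonyl = c(0.2100, 1.6612, -0.5700),
  O_carbox   = c(0.2100, 1.6612, -0.8000),
  O_hydroxyl = c(0.2104, 1.7210, -0.2100),  # O(H)
  O_ester    = c(0.1700, 1.6837, -0.4000),  # bridging/ring O
  O_phos     = c(0.2100, 1.6612, -0.9000),  # terminal phosphate O
  S          = c(0.2500, 2.0000,  0.0000),
  P          = c(0.2000, 2.1000,  1.2000)
)

backbone <- c(N = "N_bb", CA = "C_aliph", C = "C_carbonyl",
              O = "O_carbonyl", OXT = "O_carbox")

side <- list(
  ALA = c(CB = "C_aliph"),
  ARG = c(CB = "C_aliph", CG = "C_aliph", CD = "C_aliph", NE = "N_plus",
          CZ = "C_carbonyl", NH1 = "N_plus", NH2 = "N_plus"),
  ASN = c(CB = "C_aliph", CG = "C_carbonyl", OD1 = "O_carbonyl", ND2 = "N_amide"),
  ASP = c(CB = "C_aliph", CG = "C_carbonyl", OD1 = "O_carbox", OD2 = "O_carbox"),
  CYS = c(CB = "C_aliph", SG = "S"),
  GLN = c(CB = "C_aliph", CG = "C_aliph", CD = "C_carbonyl",
          OE1 = "O_carbonyl", NE2 = "N_amide"),
  GLU = c(CB = "C_aliph", CG = "C_aliph", CD = "C_carbonyl",
          OE1 = "O_carbox", OE2 = "O_carbox"),
  GLY = character(0),
  HIS = c(CB = "C_aliph", CG = "C_arom", ND1 = "N_ringH", CD2 = "C_arom",
          CE1 = "C_arom", NE2 = "N_ring"),
  ILE = c(CB = "C_aliph", CG1 = "C_aliph", CG2 = "C_aliph", CD1 = "C_aliph"),
  LEU = c(CB = "C_aliph", CG = "C_aliph", CD1 = "C_aliph", CD2 = "C_aliph"),
  LYS = c(CB = "C_aliph", CG = "C_aliph", CD = "C_aliph", CE = "C_aliph",
          NZ = "N_plus"),
  MET = c(CB = "C_aliph", CG = "C_aliph", SD = "S", CE = "C_aliph"),
  PHE = c(CB = "C_aliph", CG = "C_arom", CD1 = "C_arom", CD2 = "C_arom",
          CE1 = "C_arom", CE2 = "C_arom", CZ = "C_arom"),
  PRO = c(CB = "C_aliph", CG = "C_aliph", CD = "C_aliph"),
  SER = c(CB = "C_aliph", OG = "O_hydroxyl"),
  THR = c(CB = "C_aliph", OG1 = "O_hydroxyl", CG2 = "C_aliph"),
  TRP = c(CB = "C_aliph", CG = "C_arom", CD1 = "C_arom", CD2 = "C_arom",
          NE1 = "N_ringH", CE2 = "C_arom", CE3 = "C_arom", CZ2 = "C_arom",
          CZ3 = "C_arom", CH2 = "C_arom"),
  TYR = c(CB = "C_aliph", CG = "C_arom", CD1 = "C_arom", CD2 = "C_arom",
          CE1 = "C_arom", CE2 = "C_arom", CZ = "C_arom", OH = "O_hydroxyl"),
  VAL = c(CB = "C_aliph", CG1 = "C_aliph", CG2 = "C_aliph")
)

nuc_common <- c(
  # adenine
  N1 = "N_ring", C2 = "C_arom", N3 = "N_ring", C4 = "C_arom", C5 = "C_arom",
  C6 = "C_arom", N6 = "N_amide", N7 = "N_ring", C8 = "C_arom", N9 = "N_ring",
  # ribose
  "C1'" = "C_aliph", "C2'" = "C_aliph", "O2'" = "O_hydroxyl",
  "C3'" = "C_aliph", "O3'" = "O_hydroxyl", "C4'" = "C_aliph",
  "O4'" = "O_ester", "C5'" = "C_aliph", "O5'" = "O_ester",
  # alpha phosphate
  PA = "P", O1A = "O_phos", O2A = "O_phos", O3A = "O_ester"
)
nuc <- list(
  AMP = replace(nuc_common, "O3A", "O_phos"),
  ADP = c(nuc_common, PB = "P", O1B = "O_phos", O2B = "O_phos",
          O3B = "O_phos"),
  ATP = c(nuc_common, PB = "P", O1B = "O_phos", O2B = "O_phos",
          O3B = "O_ester", PG = "P", O1G = "O_phos", O2G = "O_phos",
          O3G = "O_phos")
)

rows <- list()
add <- function(res, atom, cls) {
  p <- classes[[cls]]
  rows[[length(rows) + 1L]] <<- tibble(
    res_name = res, atom_name = atom,
    epsilon = p[1], rmin_half = p[2], charge = p[3]
  )
}
for (res in names(side)) {
  for (a in names(backbone)) add(res, a, backbone[[a]])
  sc <- side[[res]]
  for (a in names(sc)) add(res, a, sc[[a]])
}
for (res in names(nuc)) {
  m <- nuc[[res]]
  for (a in names(m)) add(res, a, m[[a]])
}
tab <- do.call(rbind, rows)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(tab, "inst/extdata/nonbonded_params.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(tab), "parameter rows\n")
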