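test_that("extract_template derives R and r as max/min center-site distance", {
  # ligand atoms at radius 6 from the origin so the center is the origin and
  # sites at center distances 4, 6, 9 all stay within 3.9 A of some atom
  lig <- mk_atoms(rbind(c(6, 0, 0), c(-6, 0, 0), c(0, 6, 0), c(0, -6, 0),
                        c(0, 0, 6), c(0, 0, -6)),
                  is_hetero = TRUE, res_name = "ATP",
                  atom_name = c("PA", "PB", "PG", "O1A", "O1B", "O1G"))
  site <- mk_atoms(rbind(
    c(4, 0, 0),                       # center distance 4, 2.0 from (6,0,0)
    c(0, 6 * sin(pi / 6), 6 * cos(pi / 6)),  # center distance 6, 3.1 from (0,0,6)
    c(0, 9, 0)                        # center distance 9, 3.0 from (0,6,0)
  ))
  tpl <- extract_template(site, lig)
  expect_equal(nrow(tpl$site_atoms), 3L)
  expect_equal(tpl$R, 9)
  expect_equal(tpl$r, 4)
  expect_equal(tpl$ligand_center, c(0, 0, 0))
})

test_that("fixture template site equals the planted shell (brute force)", {
  cx <- make_complex(seed = 21, n_shell_atoms = 12, decoy_size = 40)
  tpl <- extract_template(cx$protein, cx$ligand)
  # oracle: any protein atom within 3.9 of any ligand atom
  pm <- cbind(cx$protein$x, cx$protein$y, cx$protein$z)
  lm <- cbind(cx$ligand$atoms$x, cx$ligand$atoms$y, cx$ligand$atoms$z)
  expected <- vapply(seq_len(nrow(pm)), function(i) {
    min(sqrt(colSums((t(lm) - pm[i, ])^2))) <= 3.9
  }, logical(1))
  expect_equal(sum(expected), 12L)
  expect_equal(res_keys(tpl$site_atoms), res_keys(cx$protein[expected, ]))
})

test_that("a ligand with no contacts raises an empty-site error", {
  lig <- mk_atoms(diag(3) + 100, is_hetero = TRUE, res_name = "AMP",
                  atom_name = c("PA", "O1A", "O2A"))
  protein <- mk_atoms(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(extract_template(protein, lig), class = "nucsite_empty_site")
})

test_that("build_library yields one template per (structure, ligand) pair", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "c1.pdb")
  p2 <- file.path(dir, "c2.pdb")
  p3 <- file.path(dir, "c3.pdb")
  make_complex(seed = 31, ligand_name = "ADP", decoy_size = 15, path = p1)
  make_complex(seed = 32, ligand_name = "ADP", decoy_size = 15, path = p2)
  make_complex(seed = 33, ligand_name = "ADP", decoy_size = 15, path = p3)
  lib <- build_library(c(p1, p2, p3), ligand_names = "ADP")
  expect_s3_class(lib, "nucsite_library")
  expect_length(lib, 3L)

  # one file holding two bound ATP copies -> two templates from that file
  cxa <- make_complex(seed = 34, ligand_name = "ATP", decoy_size = 15)
  cxb <- make_complex(seed = 35, ligand_name = "ATP", decoy_size = 15)
  cxb$atoms$x <- cxb$atoms$x + 60
  cxb$atoms$chain <- "B"
  p4 <- file.path(dir, "two_atp.pdb")
  write_pdb(dplyr::bind_rows(cxa$atoms, cxb$atoms), p4)
  lib2 <- build_library(p4, ligand_names = "ATP")
  expect_length(lib2, 2L)

  # mixed ATP + ADP input restricted to ATP
  cxc <- make_complex(seed = 36, ligand_name = "ADP", decoy_size = 15)
  cxc$atoms$x <- cxc$atoms$x + 120
  cxc$atoms$chain <- "C"
  p5 <- file.path(dir, "mixed.pdb")
  write_pdb(dplyr::bind_rows(cxa$atoms, cxc$atoms), p5)
  lib3 <- build_library(p5, ligand_names = "ATP")
  expect_length(lib3, 1L)
  expect_equal(lib3[[1]]$ligand_name, "ATP")

  expect_error(suppressWarnings(build_library(file.path(dir, "missing.pdb"))),
               class = "nucsite_format_error")
})

test_that("filter_library implements the homology levels and the jackknife", {
  lib <- as_library(
    stub_template("t1", structure_id = "s1", cluster40 = "c1",
                  family = "c.37.1.10", superfamily = "c.37.1", fold = "c.37"),
    stub_template("t2", structure_id = "s2", cluster40 = "c2",
                  family = "c.37.1.1", superfamily = "c.37.1", fold = "c.37"),
    stub_template("t3", structure_id = "s3", cluster40 = "c3",
                  family = "c.91.1.1", superfamily = "c.91.1", fold = "c.91"),
    stub_template("t4", structure_id = "s4", cluster40 = "c4")  # no SCOP labels
  )
  target <- list(structure_id = "s1", cluster40 = "c1",
                 family = "c.37.1.10", superfamily = "c.37.1", fold = "c.37")

  ids <- function(l) vapply(l, `[[`, "", "template_id")

  # same family excluded; cross-superfamily template retained at family level
  fam <- filter_library(lib, target, "family")
  expect_setequal(ids(fam), c("t2", "t3"))
  # cross-fold template (c.91 vs c.37) retained even at fold level
  fold <- filter_library(lib, target, "fold")
  expect_setequal(ids(fold), "t3")
  # identity filter: different clusters retained, unlabeled kept
  id40 <- filter_library(lib, target, "identity40")
  expect_setequal(ids(id40), c("t2", "t3", "t4"))
  # jackknife: the target's own template is always removed
  expect_false("t1" %in% ids(id40))

  # monotone nesting for hierarchical labels, and idempotence
  sf <- filter_library(lib, target, "superfamily")
  expect_true(all(ids(fold) %in% ids(sf)))
  expect_true(all(ids(sf) %in% ids(fam)))
  expect_identical(ids(filter_library(fam, target, "family")), ids(fam))

  # target lacking the required label is a configuration error
  expect_error(filter_library(lib, list(structure_id = "s9"), "family"),
               class = "nucsite_config_error")
})

test_that("library serialization round-trips coordinates and radii", {
  cx <- make_complex(seed = 41, decoy_size = 20)
  tpl <- extract_template(cx$protein, cx$ligand, template_id = "rt")
  tpl$structure_id <- "s41"
  tpl$chain <- "A"
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_library(as_library(tpl), path)
  back <- read_library(path)[[1]]
  expect_equal(back$site_atoms$x, tpl$site_atoms$x, tolerance = 1e-9)
  expect_equal(back$ligand_atoms$z, tpl$ligand_atoms$z, tolerance = 1e-9)
  expect_equal(back$R, tpl$R, tolerance = 1e-6)
  expect_equal(back$r, tpl$r, tolerance = 1e-6)
  expect_equal(back$template_id, "rt")
  expect_equal(back$structure_id, "s41")
})

test_that("R and r are invariant under rigid motion of the complex", {
  cx <- make_complex(seed = 43, decoy_size = 10)
  tpl <- extract_template(cx$protein, cx$ligand)
  withr::local_seed(7)
  rot <- rand_rot()
  shift <- c(-3, 12, 5)
  tpl2 <- extract_template(rigid_move(cx$protein, rot, shift),
                           rigid_move(cx$ligand$atoms, rot, shift))
  expect_equal(tpl2$R, tpl$R, tolerance = 1e-9)
  expect_equal(tpl2$r, tpl$r, tolerance = 1e-9)
})

test_that("contact_profile counts protein atoms per functional group", {
  lig <- toy_ligand("ATP")
  lm <- cbind(lig$x, lig$y, lig$z)
  gm <- default_group_map("ATP")
  # plant 5 atoms off the perpendicular P-O directions of the beta phosphate,
  # keeping only candidates that contact beta-phosphate atoms exclusively
  pb <- lm[lig$atom_name == "PB", ]
  axis <- lm[lig$atom_name == "PG", ] - pb
  axis <- axis / sqrt(sum(axis^2))
  cands <- list()
  for (anchor in c("O1B", "O2B")) {
    a <- lm[lig$atom_name == anchor, ]
    u <- (a - pb) / sqrt(sum((a - pb)^2))
    for (t in c(-0.6, 0, 0.6)) {
      v <- u + t * axis
      cands[[length(cands) + 1L]] <- a + 3.5 * v / sqrt(sum(v^2))
    }
  }
  shell <- matrix(numeric(0), ncol = 3)
  for (p in cands) {
    d <- sqrt(colSums((t(lm) - p)^2))
    hit <- which(d <= 3.9)
    if (length(hit) == 0L || !all(gm[lig$atom_name[hit]] == "beta_phosphate")) next
    if (nrow(shell) > 0L &&
        min(sqrt(rowSums((shell - matrix(p, nrow(shell), 3,
                                         byrow = TRUE))^2))) < 1.5) next
    shell <- rbind(shell, p)
    if (nrow(shell) == 5L) break
  }
  stopifnot(nrow(shell) == 5L)
  protein <- mk_atoms(shell, atom_name = "NZ", res_name = "LYS")
  prof <- contact_profile(protein, lig)
  expect_equal(prof$n_contacts[prof$group == "beta_phosphate"], 5L)
  expect_equal(prof$n_contacts[prof$group == "gamma_phosphate"], 0L)

  # an atom within 3.9 A of two groups is counted once in each
  mid <- (lm[lig$atom_name == "PA", ] + lm[lig$atom_name == "C5'", ]) / 2
  protein2 <- mk_atoms(rbind(mid + c(0, 0, 3.2)), atom_name = "OG",
                       res_name = "SER")
  d2 <- sqrt(colSums((t(lm) - as.numeric(protein2[1, c("x", "y", "z")]))^2))
  stopifnot(any(d2[gm[lig$atom_name] == "alpha_phosphate"] <= 3.9),
            any(d2[gm[lig$atom_name] == "ribose"] <= 3.9))
  prof2 <- contact_profile(protein2, lig)
  expect_equal(prof2$n_contacts[prof2$group == "alpha_phosphate"], 1L)
  expect_equal(prof2$n_contacts[prof2$group == "ribose"], 1L)

  # unmapped ligand atom is a configuration error
  expect_error(contact_profile(protein, lig, group_map = c(PA = "alpha")),
               class = "nucsite_config_error")
})
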