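# Binding-site template extraction, the searchable template library
# (JSON-lines on disk), homology-filtered template selection, and the
# per-functional-group contact profile.

#' Extract a binding-site template from a complex
#'
#' The template stores the interacting protein atoms (within `cutoff`, default
#' 3.9 A, of any non-hydrogen ligand atom), the ligand atoms, the geometric
#' ligand center, and the two derived radii: `R`, the maximal center-to-site
#' distance (covering all interacting atoms) and `r`, the minimal one (the
#' distance from the center to the protein surface).
#'
#' @param protein Tibble of protein atoms.
#' @param ligand Ligand instance (list with `ligand_name`, `atoms`, `source`)
#'   or a tibble of ligand atoms.
#' @param cutoff Contact cutoff in Angstrom; default 3.9.
#' @param template_id Identifier; defaults to the ligand source.
#' @param labels Optional named list/vector of homology metadata
#'   (`cluster40`, `family`, `superfamily`, `fold`).
#' @return A `nucsite_template` object.
#' @export
extract_template <- function(protein, ligand, cutoff = 3.9,
                             template_id = NULL, labels = NULL) {
  atoms <- ligand_atom_table(ligand)
  stopifnot(nrow(atoms) >= 3L)
  site <- interacting_atoms(protein, atoms, cutoff)
  if (nrow(site) == 0L) {
    abort("ligand has no interacting protein atoms; template skipped",
          class = "nucsite_empty_site")
  }
  ctr <- colMeans(coords_mat(atoms))
  d <- cross_dist(rbind(ctr), coords_mat(site))[1L, ]
  structure(
    list(
      template_id = template_id %||%
        (if (is.data.frame(ligand)) "template" else ligand$source),
      ligand_name = if (is.data.frame(ligand)) atoms$res_name[[1L]] else ligand$ligand_name,
      site_atoms = site,
      ligand_atoms = atoms,
      ligand_center = as.numeric(ctr),
      R = max(d),
      r = min(d),
      labels = as.list(labels)
    ),
    class = "nucsite_template"
  )
}

#' @export
print.nucsite_template <- function(x, ...) {
  cat(sprintf(
    "<nucsite_template> %s (%s): %d site atoms, %d ligand atoms, R = %.2f, r = %.2f\n",
    x$template_id, x$ligand_name, nrow(x$site_atoms), nrow(x$ligand_atoms),
    x$R, x$r
  ))
  invisible(x)
}

#' Build a template library from complex structures
#'
#' One template is extracted per (structure, ligand instance) pair that yields
#' a non-empty binding site. Homology metadata, if provided, is attached by
#' (structure id, chain).
#'
#' @param paths Character vector of PDB file paths.
#' @param ligand_names Ligand 3-letter codes to extract.
#' @param metadata Optional tibble with columns `structure_id`, `chain`,
#'   `cluster40`, `family`, `superfamily`, `fold` (SCOP-style dotted labels).
#' @return A `nucsite_library` (list of templates).
#' @export
build_library <- function(paths, ligand_names = c("ATP", "ADP", "AMP"),
                          metadata = NULL) {
  stopifnot(length(paths) >= 1L)
  templates <- list()
  n_failed <- 0L
  for (p in paths) {
    parsed <- tryCatch(read_structure(p, ligand_names), error = function(e) e)
    if (inherits(parsed, "error")) {
      warn(paste0("skipping unreadable structure ", p, ": ",
                  conditionMessage(parsed)))
      n_failed <- n_failed + 1L
      next
    }
    for (lg in parsed$ligands) {
      tid <- paste0(lg$source, ":", lg$ligand_name, ":",
                    lg$atoms$res_num[[1L]])
      tpl <- tryCatch(
        extract_template(parsed$protein, lg, template_id = tid),
        nucsite_empty_site = function(e) NULL
      )
      if (is.null(tpl)) {
        warn(paste0("no interacting atoms for ", tid, "; template skipped"))
        next
      }
      tpl$structure_id <- parsed$id
      tpl$chain <- lg$atoms$chain[[1L]]
      if (!is.null(metadata)) {
        hit <- metadata[metadata$structure_id == parsed$id &
                          metadata$chain == tpl$chain, ]
        if (nrow(hit) >= 1L) {
          tpl$labels <- as.list(hit[1L, setdiff(names(hit),
                                                c("structure_id", "chain"))])
        }
      }
      templates[[length(templates) + 1L]] <- tpl
    }
  }
  if (n_failed == length(paths)) {
    abort("no input structure could be read", class = "nucsite_format_error")
  }
  structure(templates, class = "nucsite_library")
}

#' @export
print.nucsite_library <- function(x, ...) {
  cat(sprintf("<nucsite_library> %d templates (%s)\n", length(x),
              paste(unique(vapply(x, `[[`, "", "ligand_name")), collapse = ", ")))
  invisible(x)
}

#' Serialize a template library as JSON-lines
#'
#' One JSON record per template; coordinates round-trip to better than 1e-6 A.
#'
#' @param library A `nucsite_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  lines <- vapply(library, function(tpl) {
    jsonlite::toJSON(
      list(
        template_id = tpl$template_id,
        ligand_name = tpl$ligand_name,
        structure_id = tpl$structure_id,
        chain = tpl$chain,
        labels = tpl$labels,
        site_atoms = tpl$site_atoms,
        ligand_atoms = tpl$ligand_atoms
      ),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines template library
#'
#' Radii `R` and `r` are recomputed from the stored coordinates.
#'
#' @param path Path to a JSONL library file.
#' @return A `nucsite_library`.
#' @export
read_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  templates <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    site <- as_tibble(rec$site_atoms)
    lig <- as_tibble(rec$ligand_atoms)
    ctr <- colMeans(coords_mat(lig))
    d <- cross_dist(rbind(ctr), coords_mat(site))[1L, ]
    structure(
      list(
        template_id = rec$template_id,
        ligand_name = rec$ligand_name,
        site_atoms = site,
        ligand_atoms = lig,
        ligand_center = as.numeric(ctr),
        R = max(d),
        r = min(d),
        labels = rec$labels,
        structure_id = rec$structure_id,
        chain = rec$chain
      ),
      class = "nucsite_template"
    )
  })
  structure(templates, class = "nucsite_library")
}

#' Homology-filtered template selection
#'
#' Removes templates that are too similar to the target for a fair
#' template-based prediction: at `identity40` level templates in the same
#' 40%-sequence-identity cluster, and at `family`/`superfamily`/`fold` level
#' templates sharing that SCOP-style label with the target. Templates lacking
#' the required label are removed at the homology levels. Templates extracted
#' from the target structure itself are always removed (jackknife protocol).
#'
#' @param library A `nucsite_library`.
#' @param target_labels Named list/vector for the target: `structure_id` plus
#'   whichever of `cluster40`, `family`, `superfamily`, `fold` the level needs.
#' @param level One of `"identity40"`, `"family"`, `"superfamily"`, `"fold"`.
#' @return Filtered `nucsite_library`.
#' @export
filter_library <- function(library, target_labels,
                           level = c("identity40", "family", "superfamily", "fold")) {
  level <- match.arg(level)
  target_labels <- as.list(target_labels)
  key <- switch(level, identity40 = "cluster40", level)
  if (is.null(target_labels[[key]]) || is.na(target_labels[[key]])) {
    abort(paste0("target lacks required label '", key, "' for level ", level),
          class = "nucsite_config_error")
  }
  keep <- vapply(library, function(tpl) {
    if (!is.null(target_labels$structure_id) &&
        identical(tpl$structure_id, target_labels$structure_id)) {
      return(FALSE)  # jackknife: never use the target's own site
    }
    lab <- tpl$labels[[key]]
    if (level == "identity40") {
      is.null(lab) || is.na(lab) || !identical(as.character(lab),
                                               as.character(target_labels[[key]]))
    } else {
      !is.null(lab) && !is.na(lab) &&
        !identical(as.character(lab), as.character(target_labels[[key]]))
    }
  }, logical(1L))
  structure(library[keep], class = "nucsite_library")
}

#' Contacts per ligand functional group
#'
#' Counts, for each functional group of the ligand (e.g. gamma/beta/alpha
#' phosphate, ribose, adenine), the number of protein atoms within `cutoff`
#' of any atom of that group. A protein atom close to two groups is counted
#' once in each.
#'
#' @param protein Tibble of protein atoms.
#' @param ligand Ligand instance or atom tibble.
#' @param group_map Named character vector mapping every ligand atom name to a
#'   group label; defaults to [default_group_map()] for the ligand's name.
#' @param cutoff Contact cutoff in Angstrom; default 3.9.
#' @return Tibble with columns `group`, `n_contacts`.
#' @export
contact_profile <- function(protein, ligand, group_map = NULL, cutoff = 3.9) {
  atoms <- ligand_atom_table(ligand)
  if (is.null(group_map)) {
    group_map <- default_group_map(atoms$res_name[[1L]])
  }
  unmapped <- setdiff(atoms$atom_name, names(group_map))
  if (length(unmapped) > 0L) {
    abort(paste0("ligand atoms not covered by group_map: ",
                 paste(unmapped, collapse = ", ")),
          class = "nucsite_config_error")
  }
  groups <- unique(unname(group_map[atoms$atom_name]))
  d <- cross_dist(coords_mat(protein), coords_mat(atoms))
  counts <- vapply(groups, function(g) {
    cols <- which(group_map[atoms$atom_name] == g)
    sum(apply(d[, cols, drop = FALSE] <= cutoff + 1e-9, 1L, any))
  }, integer(1L), USE.NAMES = FALSE)
  tibble(group = groups, n_contacts = counts)
}
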