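# Geometric triage of mutations against a protein-ligand complex.
#
# The docking-suitability decision is purely positional: a mutated residue is
# worth docking only if it touches the ligand (any heavy atom within a cutoff
# -- 5 Angstrom by default -- of any ligand heavy atom); everything else is
# rejected with the structural region it falls in (cap domain, ER-luminal,
# cytoplasmic interface, membrane) as the reason.  Hydrogens are ignored
# throughout: predicted models carry none and the distance conventions
# predate protonation.

#' Read a PDB structure and tag the ligand
#'
#' Parses standard PDB coordinate records (first model only) via `bio3d`.
#' Alternate locations are resolved per atom by highest occupancy (tie:
#' altloc `A`).  The ligand is selected by residue name, or by chain and
#' residue number; it is configuration, never hard-coded.
#'
#' @param pdb_path Path to a PDB file.
#' @param ligand Ligand selector: a residue-name string (e.g. `"BRF"`), or a
#'   list with elements `chain` and `resno`.  `NULL` leaves no atom tagged.
#'
#' @return A `vkor_structure` tibble of atoms: `type`, `eleno`, `elety`
#'   (atom name), `resid` (residue name), `chain`, `resno`, `x`, `y`, `z`,
#'   `occupancy`, `altloc`, `element`, `is_ligand`.
#' @export
read_structure <- function(pdb_path, ligand = NULL) {
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, verbose = FALSE)
  a <- as_tibble(pdb$atom)
  if (nrow(a) == 0L) abort("no atoms in PDB file")
  atoms <- tibble(
    type = a$type,
    eleno = as.integer(a$eleno),
    elety = a$elety,
    resid = a$resid,
    chain = dplyr::coalesce(a$chain, ""),
    resno = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    occupancy = dplyr::coalesce(a$o, 1),
    altloc = dplyr::coalesce(dplyr::na_if(a$alt, ""), "")
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in PDB file")
  }
  elesy <- toupper(trimws(dplyr::coalesce(a$elesy, "")))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]+", "", atoms$elety)), 1L, 1L))
  atoms$element <- ifelse(elesy == "", guess, elesy)

  # resolve altlocs: one atom per (chain, resno, resid, name)
  atoms <- atoms |>
    group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    arrange(desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$eleno)

  atoms$is_ligand <- FALSE
  if (!is.null(ligand)) {
    sel <- if (is.character(ligand)) {
      atoms$resid == ligand
    } else {
      atoms$chain == ligand$chain & atoms$resno == ligand$resno
    }
    if (!any(sel)) {
      abort(sprintf(
        "ligand selector '%s' matches no atom",
        if (is.character(ligand)) ligand
        else paste0(ligand$chain, ligand$resno)
      ))
    }
    atoms$is_ligand <- sel
  }
  class(atoms) <- c("vkor_structure", class(atoms))
  atoms
}

.heavy <- function(atoms) filter(atoms, .data$element != "H")

.protein_atoms <- function(atoms) {
  filter(.heavy(atoms), !.data$is_ligand,
         !.data$resid %in% c("HOH", "WAT", "DOD"))
}

# all-pairs squared distances between two xyz matrices (rows = atoms)
.cross_dist2 <- function(p, q) {
  outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
}

.xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Residues within a cutoff of the ligand
#'
#' Protein residues with any heavy atom within `cutoff` of any ligand heavy
#' atom, with the per-residue minimum heavy-atom distance.  Contact sets are
#' monotone in the cutoff.
#'
#' @param atoms A `vkor_structure` with a tagged ligand.
#' @param cutoff Distance cutoff in Angstrom (default 5).
#'
#' @return Tibble: `chain`, `resno`, `resid`, `min_dist`, sorted by
#'   `min_dist`.
#' @export
ligand_neighborhood <- function(atoms, cutoff = 5) {
  stopifnot(cutoff > 0)
  lig <- filter(.heavy(atoms), .data$is_ligand)
  if (nrow(lig) == 0L) abort("no ligand atoms tagged; see read_structure()")
  prot <- .protein_atoms(atoms)
  if (nrow(prot) == 0L) abort("no protein atoms")
  d2 <- .cross_dist2(.xyz(prot), .xyz(lig))
  prot |>
    mutate(min_dist = sqrt(pmax(apply(d2, 1L, min), 0))) |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    filter(.data$min_dist <= cutoff) |>
    arrange(.data$min_dist)
}

#' Geometric hydrogen bonds between protein and ligand
#'
#' Distance-only detection between polar heavy atoms (N/O/S by default): no
#' angle term, since predicted models lack hydrogens.
#'
#' @param atoms A `vkor_structure` with a tagged ligand.
#' @param cutoff Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param polar_elements Elements considered polar.
#'
#' @return Tibble of candidate bonds sorted by distance: protein atom
#'   (`chain`, `resno`, `resid`, `atom`), ligand atom (`ligand_atom`),
#'   `dist`.
#' @export
detect_hbonds <- function(atoms, cutoff = 3.5,
                          polar_elements = c("N", "O", "S")) {
  lig <- filter(.heavy(atoms), .data$is_ligand,
                .data$element %in% polar_elements)
  prot <- filter(.protein_atoms(atoms), .data$element %in% polar_elements)
  if (nrow(lig) == 0L || nrow(prot) == 0L) {
    return(tibble(
      chain = character(), resno = integer(), resid = character(),
      atom = character(), ligand_atom = character(), dist = numeric()
    ))
  }
  d <- sqrt(pmax(.cross_dist2(.xyz(prot), .xyz(lig)), 0))
  hits <- which(d <= cutoff, arr.ind = TRUE)
  tibble(
    chain = prot$chain[hits[, 1]],
    resno = prot$resno[hits[, 1]],
    resid = prot$resid[hits[, 1]],
    atom = prot$elety[hits[, 1]],
    ligand_atom = lig$elety[hits[, 2]],
    dist = d[hits]
  ) |>
    arrange(.data$dist)
}

# core least-squares rigid superposition (reflection-free)
.kabsch_core <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  f0 <- sweep(fixed, 2L, cf)
  m0 <- sweep(mobile, 2L, cm)
  sv_f <- svd(f0)$d
  sv_m <- svd(m0)$d
  if (sv_f[2] < 1e-8 * max(sv_f[1], 1) || sv_m[2] < 1e-8 * max(sv_m[1], 1)) {
    abort("degenerate (collinear) coordinate set; superposition undefined")
  }
  h <- t(m0) %*% f0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cf - as.vector(rot %*% cm)
  moved <- m0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((f0 - moved)^2)))
  structure(
    list(rotation = rot, translation = trans, rmsd = rmsd,
         atom_pair_count = nrow(fixed)),
    class = "vkor_superposition"
  )
}

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Optimal rotation (determinant +1; reflections forbidden) and translation
#' minimising the RMSD between paired coordinate sets.  Given two structures,
#' atoms are paired by residue number (with a configurable offset for
#' numbering shifts between species models) and atom name over a selection:
#' backbone (N/CA/C/O), sidechain heavy atoms (glycine contributes none), or
#' all heavy atoms.
#'
#' @param fixed,mobile Either n x 3 coordinate matrices already paired row by
#'   row, or two `vkor_structure` objects.
#' @param selection Atom selection when superposing structures:
#'   `"backbone"`, `"sidechain"` or `"all"`.
#' @param resno_offset Added to `mobile` residue numbers before pairing.
#' @param residues Optional residue numbers (on the fixed structure's
#'   numbering) restricting the pairing, e.g. a binding-site contact set.
#'
#' @return A `vkor_superposition`: `rotation` (3 x 3), `translation`
#'   (length-3, Angstrom), `rmsd` (Angstrom), `atom_pair_count`.  Applying
#'   `rotation %*% x + translation` to the mobile coordinates reproduces the
#'   reported RMSD.
#' @export
kabsch_superpose <- function(fixed, mobile, selection = c("backbone",
                                                          "sidechain", "all"),
                             resno_offset = 0L, residues = NULL) {
  if (is.matrix(fixed) && is.matrix(mobile)) {
    if (!identical(dim(fixed), dim(mobile))) {
      abort("paired coordinate sets must have identical dimensions")
    }
    if (nrow(fixed) < 3L) abort("at least 3 atom pairs are required")
    return(.kabsch_core(fixed, mobile))
  }
  selection <- match.arg(selection)
  backbone <- c("N", "CA", "C", "O")
  pick <- function(atoms) {
    h <- .protein_atoms(atoms)
    h <- switch(selection,
      backbone = filter(h, .data$elety %in% backbone),
      sidechain = filter(h, !.data$elety %in% backbone),
      all = h
    )
    h
  }
  f <- pick(fixed)
  m <- pick(mobile) |> mutate(resno = .data$resno + as.integer(resno_offset))
  if (!is.null(residues)) {
    f <- filter(f, .data$resno %in% residues)
    m <- filter(m, .data$resno %in% residues)
  }
  paired <- dplyr::inner_join(
    f |> select("resno", "elety", "x", "y", "z"),
    m |> select("resno", "elety", "x", "y", "z"),
    by = c("resno", "elety"), suffix = c("_f", "_m")
  )
  if (nrow(paired) < 3L) abort("fewer than 3 paired atoms after selection")
  .kabsch_core(
    as.matrix(paired[, c("x_f", "y_f", "z_f")]),
    as.matrix(paired[, c("x_m", "y_m", "z_m")])
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param sup A `vkor_superposition`.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(xyz %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' @export
print.vkor_superposition <- function(x, ...) {
  cat(sprintf("rigid superposition over %d atom pairs: RMSD %.4f Angstrom\n",
              x$atom_pair_count, x$rmsd))
  invisible(x)
}

#' @export
glance.vkor_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, atom_pair_count = x$atom_pair_count)
}

#' Classify mutations as suitable or unsuitable for docking
#'
#' A mutated residue is `suitable` iff it belongs to the ligand contact set;
#' otherwise it is `not_suitable` with the annotated structural region as the
#' reason.
#'
#' @param mutations Tibble with columns `label` and `residue_number` (or an
#'   integer vector of residue numbers).
#' @param structure A `vkor_structure` (used to verify residues exist).
#' @param contacts Contact set from [ligand_neighborhood()]; computed from
#'   `structure` at `cutoff` when omitted.
#' @param regions Region annotation tibble with columns `start`, `end`,
#'   `region` (residue ranges, 1-based inclusive).  A packaged illustrative
#'   annotation is in `vkor_example("vkor_regions_illustrative.tsv")`.
#' @param cutoff Contact cutoff used when `contacts` is omitted.
#'
#' @return Tibble: `label`, `residue_number`, `decision`
#'   (`suitable`/`not_suitable`), `reason`.
#' @export
triage_mutations <- function(mutations, structure, contacts = NULL,
                             regions = NULL, cutoff = 5) {
  if (!is.data.frame(mutations)) {
    mutations <- tibble(
      label = as.character(mutations),
      residue_number = as.integer(mutations)
    )
  }
  if (is.null(contacts)) contacts <- ligand_neighborhood(structure, cutoff)
  prot_res <- unique(.protein_atoms(structure)$resno)
  missing <- setdiff(mutations$residue_number, prot_res)
  if (length(missing) > 0L) {
    abort(sprintf("residue %d is absent from the structure", missing[1]))
  }
  region_of <- function(resno) {
    if (is.null(regions)) return("outside contact set")
    hit <- regions |> filter(.data$start <= resno, resno <= .data$end)
    if (nrow(hit) == 0L) "unannotated region" else hit$region[1]
  }
  mutations |>
    mutate(
      decision = ifelse(.data$residue_number %in% contacts$resno,
                        "suitable", "not_suitable"),
      reason = purrr::map2_chr(
        .data$decision, .data$residue_number,
        function(d, r) if (d == "suitable") "in ligand contact set"
                       else region_of(r)
      )
    )
}
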