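#' Parameters of the surface-area quadrature
#'
#' @param probe_radius Solvent probe radius, nm (default 0.14, a water-sized
#'   probe).
#' @param n_sphere_points Quadrature points per atom (>= 32); points are
#'   placed on a deterministic golden-section spiral, so the calculation
#'   involves no random numbers.
#' @param radii_table Named role -> radius (nm) mapping used for atoms whose
#'   frame record carries no radius.
#' @param occluder_roles Roles that bury surface.  Solvent defines the probe
#'   rather than occluding, so water and ions are excluded by default.
#' @return A `sasa_params` list.
#' @export
sasa_params <- function(probe_radius = 0.14, n_sphere_points = 960,
                        radii_table = default_radii(),
                        occluder_roles = setdiff(atom_roles(),
                                                 c("WATER_O", "ION_NA", "ION_CL"))) {
  if (probe_radius < 0) abort("probe_radius must be >= 0")
  if (n_sphere_points < 32) abort("n_sphere_points must be >= 32")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_table = radii_table,
                 occluder_roles = occluder_roles),
            class = "sasa_params")
}

# deterministic golden-section spiral on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(cos(phi) * rho, sin(phi) * rho, z)
}

frame_radii <- function(frame, params) {
  r <- frame$radius
  fill <- is.na(r)
  if (any(fill)) {
    r[fill] <- unname(params$radii_table[frame$role[fill]])
  }
  if (any(is.na(r))) {
    abort(paste0("no van der Waals radius configured for role(s): ",
                 paste(unique(frame$role[is.na(r)]), collapse = ", ")))
  }
  r
}

#' Solvent-accessible surface area by Shrake-Rupley quadrature
#'
#' For each atom in `subset`, quadrature points are distributed on its
#' probe-expanded sphere (radius `r_i + probe`); the accessible area is the
#' fraction of points not buried inside any occluding neighbour's expanded
#' sphere, times `4 pi (r_i + probe)^2`.  All non-solvent atoms of the frame
#' act as occluders (configurable), including atoms outside the subset.
#' Neighbour candidates are pruned with an exact distance cutoff
#' `r_i + r_j + 2 probe`, which leaves the result identical to an
#' unpruned all-pairs scan.
#'
#' @param frame An [np_frame()].
#' @param subset Atom `index` values whose area is requested (nonempty).
#' @param params A [sasa_params()] object.
#' @param subset_descriptor Label recorded in the result.
#' @return A `sasa_result`: list with `per_atom` (tibble `index`, `area` in
#'   nm²), `total_area` (nm²) and `subset_descriptor`.
#' @export
shrake_rupley <- function(frame, subset, params = sasa_params(),
                          subset_descriptor = "custom") {
  if (length(subset) == 0) abort("subset must be nonempty")
  srows <- match(subset, frame$index)
  if (any(is.na(srows))) abort("subset contains atom indices absent from frame")
  radii <- frame_radii(frame, params)
  probe <- params$probe_radius
  pts <- sphere_points(params$n_sphere_points)

  occ <- which(frame$role %in% params$occluder_roles)
  occ_xyz <- coords_matrix(frame, occ)
  occ_r <- radii[occ]
  sub_xyz <- coords_matrix(frame, srows)

  # candidate occluders per subset atom: centre distance below the exact
  # two-expanded-sphere overlap cutoff
  d2 <- cross_dist2(sub_xyz, occ_xyz)
  cut2 <- outer(radii[srows] + probe, occ_r + probe, "+")^2

  areas <- numeric(length(srows))
  for (k in seq_along(srows)) {
    i <- srows[k]
    ri <- radii[i] + probe
    neigh <- which(d2[k, ] < cut2[k, ] & occ != i)
    p <- sweep(pts * ri, 2, c(frame$x[i], frame$y[i], frame$z[i]), "+")
    if (length(neigh) > 0) {
      pd2 <- cross_dist2(p, occ_xyz[neigh, , drop = FALSE])
      buried <- rowSums(
        pd2 < matrix((occ_r[neigh] + probe)^2, nrow(pd2), length(neigh),
                     byrow = TRUE)) > 0
      frac <- mean(!buried)
    } else {
      frac <- 1
    }
    areas[k] <- frac * 4 * pi * ri^2
  }
  structure(list(per_atom = tibble(index = frame$index[srows], area = areas),
                 total_area = sum(areas),
                 subset_descriptor = subset_descriptor),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %s: %d atoms, total %.4f nm^2\n",
              x$subset_descriptor, nrow(x$per_atom), x$total_area))
  invisible(x)
}

#' Nonpolar ligand atom subset
#'
#' The hydrophobic observable of the analysis is the SASA of the ligand
#' backbone carbons only: all MUS and OT backbone atoms, excluding sulfonate
#' S/O, thiol anchors and gold.  For the study particle this is
#' 29 x 11 + 29 x 8 = 551 atoms.
#'
#' @param np An `np_model` from [build_np()].
#' @return Integer vector of atom indices.
#' @export
nonpolar_subset <- function(np) {
  sort(unlist(np$ligands$backbone_atoms))
}

#' Change in nonpolar SASA between two configurations
#'
#' SASA of the nonpolar ligand subset in `frame` minus that in `reference`
#' (conventionally the 29+/0- configuration).  Both frames must contain the
#' particle's atoms with identical topology.
#'
#' @param frame,reference [np_frame()]s sharing the particle topology.
#' @param np The `np_model` defining the nonpolar subset.
#' @param params A [sasa_params()] object.
#' @return Signed area change, nm².
#' @export
delta_sasa <- function(frame, reference, np, params = sasa_params()) {
  subset <- nonpolar_subset(np)
  check_np_topology <- function(f, nm) {
    rows <- match(np$atoms$index, f$index)
    if (any(is.na(rows)) ||
        !identical(f$role[rows], np$atoms$role) ||
        !identical(as.integer(f$ligand[rows]), as.integer(np$atoms$ligand))) {
      abort(sprintf("%s frame does not share the nanoparticle topology", nm))
    }
  }
  check_np_topology(frame, "input")
  check_np_topology(reference, "reference")
  shrake_rupley(frame, subset, params, "nonpolar")$total_area -
    shrake_rupley(reference, subset, params, "nonpolar")$total_area
}

#' Hydrophobic free energy from a SASA change
#'
#' The implicit-solvation estimate `dG_phob = gamma * dSASA`, with `gamma`
#' the water-to-alkane transfer solvation parameter (4.7 kcal/mol/nm² by
#' default).  A negative area change (hydrophobic burial) gives a negative,
#' favourable free energy: the printed maximum flipping-induced decrease of
#' 11.1 nm² corresponds to -52.2 kcal/mol.
#'
#' @param delta_sasa SASA change, nm² (signed).
#' @param gamma Solvation parameter, kcal/mol/nm².
#' @return A `hydrophobic_energy`: list with `gamma`, `delta_sasa`, `dg`
#'   (kcal/mol, exactly `gamma * delta_sasa`).
#' @export
hydrophobic_dg <- function(delta_sasa, gamma = 4.7) {
  if (!is.finite(gamma)) abort("gamma must be finite")
  structure(list(gamma = gamma, delta_sasa = delta_sasa,
                 dg = gamma * delta_sasa),
            class = "hydrophobic_energy")
}

#' @export
print.hydrophobic_energy <- function(x, ...) {
  cat(sprintf(
    "<hydrophobic_energy> dSASA = %.3f nm^2, gamma = %.3g kcal/mol/nm^2 -> dG = %.2f kcal/mol\n",
    x$delta_sasa, x$gamma, x$dg))
  invisible(x)
}
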