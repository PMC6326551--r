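# Fibonacci (golden-angle) lattice of n quasi-uniform points on the unit
# sphere; deterministic, nearest-neighbour spacing varies < 30% across points.
fibonacci_sphere <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(cos(phi) * rho, sin(phi) * rho, z)
}

# orthonormal basis perpendicular to a unit vector
perp_basis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

BOND_CC <- 0.127     # backbone carbon spacing along the chain axis, nm
BOND_CS <- 0.18      # terminal carbon - sulfonate sulfur, nm
BOND_SO <- 0.149     # sulfonate S - O, nm
N_BACKBONE <- c(MUS = 11L, OT = 8L)

#' Build a monolayer-protected nanoparticle
#'
#' Constructs a model of a gold nanoparticle whose rigid spherical core bears
#' thiol-anchored ligands: anionic MUS (11 backbone carbons terminated by a
#' sulfonate group, charge -1) and hydrophobic OT (8 backbone carbons).  Graft
#' points are placed on a deterministic Fibonacci sphere lattice
#' (quasi-uniform); MUS/OT identities are assigned by a seeded shuffle.
#' Backbone atoms are laid out collinearly along each graft direction at
#' 0.127 nm spacing as an extended-chain stand-in.  The default study system
#' is `build_np(2.0, 58, 0.5)`: 58 ligands on a 2 nm core, 4.62 ligands/nm²,
#' 29 MUS giving a net charge of -29 e.
#'
#' @param core_diameter Core diameter, nm (> 0).
#' @param n_ligands Number of grafted ligands.
#' @param mus_fraction Fraction of ligands that are MUS; `n_ligands *
#'   mus_fraction` must be an integer.
#' @param seed Integer seed for the MUS/OT shuffle.
#' @return An `np_model`: list with `core_center` (nm), `core_radius` (nm),
#'   `ligands` (tibble with per-ligand kind, graft direction, and atom-index
#'   list columns), `atoms` (tibble of atom records in core-centred
#'   coordinates), `net_charge` (e) and `grafting_density` (ligands/nm²).
#' @export
build_np <- function(core_diameter, n_ligands, mus_fraction, seed = 1L) {
  if (core_diameter <= 0) abort("core_diameter must be > 0")
  if (mus_fraction < 0 || mus_fraction > 1) abort("mus_fraction must be in [0, 1]")
  n_mus_real <- n_ligands * mus_fraction
  if (abs(n_mus_real - round(n_mus_real)) > 1e-9) {
    abort(sprintf(
      "composition error: n_ligands * mus_fraction = %.6g is not an integer",
      n_mus_real))
  }
  n_mus <- as.integer(round(n_mus_real))
  r_core <- core_diameter / 2

  dirs <- fibonacci_sphere(n_ligands)
  kinds <- rep("OT", n_ligands)
  if (n_ligands > 0 && n_mus > 0) {
    idx <- withr::with_seed(seed, sample.int(n_ligands, n_mus))
    kinds[idx] <- "MUS"
  }

  rows <- list()
  lig_rows <- list()
  next_index <- 1L
  add_atom <- function(role, pos, lig) {
    rows[[length(rows) + 1L]] <<- tibble(
      index = next_index, role = role,
      x = pos[1], y = pos[2], z = pos[3], ligand = lig)
    next_index <<- next_index + 1L
    next_index - 1L
  }
  # rigid hollow core modelled as one pseudo-atom of radius r_core
  add_atom("GOLD", c(0, 0, 0), NA_integer_)

  for (l in seq_len(n_ligands)) {
    d <- dirs[l, ]
    kind <- kinds[l]
    anchor <- add_atom("THIOL_S", r_core * d, l)
    nb <- N_BACKBONE[[kind]]
    backbone <- integer(nb)
    crole <- if (kind == "MUS") "LIGAND_C_MUS" else "LIGAND_C_OT"
    for (j in seq_len(nb)) {
      backbone[j] <- add_atom(crole, (r_core + j * BOND_CC) * d, l)
    }
    endgroup <- integer(0)
    if (kind == "MUS") {
      s_pos <- (r_core + nb * BOND_CC + BOND_CS) * d
      s_idx <- add_atom("SULFONATE_S", s_pos, l)
      b <- perp_basis(d)
      o_idx <- integer(3)
      for (k in 1:3) {
        ang <- 2 * pi * (k - 1) / 3
        off <- BOND_SO * (0.33 * d + 0.944 * (cos(ang) * b$u + sin(ang) * b$v))
        o_idx[k] <- add_atom("SULFONATE_O", s_pos + off, l)
      }
      endgroup <- c(s_idx, o_idx)
    }
    lig_rows[[l]] <- tibble(
      ligand_id = l, kind = kind,
      gx = d[1], gy = d[2], gz = d[3],
      anchor_atom = anchor,
      backbone_atoms = list(backbone),
      endgroup_atoms = list(endgroup))
  }

  atoms <- if (length(rows) > 0) bind_rows(rows) else
    tibble(index = integer(), role = character(),
           x = double(), y = double(), z = double(), ligand = integer())
  atoms$radius <- unname(default_radii()[atoms$role])
  atoms$radius[atoms$role == "GOLD"] <- r_core
  ligands <- if (n_ligands > 0) bind_rows(lig_rows) else
    tibble(ligand_id = integer(), kind = character(),
           gx = double(), gy = double(), gz = double(),
           anchor_atom = integer(),
           backbone_atoms = list(), endgroup_atoms = list())

  structure(list(
    core_center = c(0, 0, 0),
    core_radius = r_core,
    ligands = ligands,
    atoms = atoms,
    net_charge = -n_mus,
    grafting_density = n_ligands / (pi * core_diameter^2)
  ), class = "np_model")
}

#' @export
print.np_model <- function(x, ...) {
  n_mus <- sum(x$ligands$kind == "MUS")
  cat(sprintf(
    "<np_model> core radius %.3g nm, %d ligands (%d MUS / %d OT), net charge %+d e, %.3g ligands/nm^2\n",
    x$core_radius, nrow(x$ligands), n_mus, nrow(x$ligands) - n_mus,
    x$net_charge, x$grafting_density))
  invisible(x)
}

#' Frame of nanoparticle atoms at a given centre
#'
#' Instantiates the atom records of an `np_model` as an [np_frame()] with the
#' core placed at `center`.  Atom indices are those stored in the model, so
#' index-based subsets such as [nonpolar_subset()] remain valid.
#'
#' @param np An `np_model` from [build_np()].
#' @param center Numeric length-3 core centre, nm.
#' @param box Box edges, nm.
#' @return An [np_frame()].
#' @export
np_atoms_frame <- function(np, center = c(0, 0, 0), box = c(12, 12, 12)) {
  atoms <- np$atoms
  atoms$x <- atoms$x + center[1]
  atoms$y <- atoms$y + center[2]
  atoms$z <- atoms$z + center[3]
  np_frame(atoms, box = box)
}

# geometry of the bead lipid: z offsets of (choline N, phosphate P, two tail
# beads) relative to the midplane, upper leaflet; lower leaflet is mirrored
lipid_bead_offsets <- function(head_z = 1.9) {
  c(N = head_z + 0.1, P = head_z, T1 = head_z - 0.7, T2 = head_z - 1.4)
}

#' Build a bead bilayer
#'
#' Constructs a simplified planar bilayer of four-bead lipids (choline N,
#' phosphate P, two tail beads) on a square lattice: two leaflets with head
#' planes at ± `head_z` about the midplane z = 0.  When a nanoparticle model
#' is supplied, lipids overlapping the particle volume are removed, so the
#' two leaflets may end up with different lipid counts.
#'
#' @param n_lipids Total lipid count (must be even when `gap_for_np` is NULL).
#' @param area_per_lipid Area per lipid, nm² (> 0).
#' @param gap_for_np Optional `np_model` whose `core_center` is used to carve
#'   out space for the particle.
#' @param head_z Phosphate plane height above the midplane, nm.
#' @param box_z Box height, nm.
#' @param exclusion_pad Extra exclusion radius beyond the core radius, nm.
#' @return An [np_frame()] of lipid bead atoms with `ligand = NA`, `leaflet`
#'   set, and the midplane at z = 0.
#' @export
build_bilayer <- function(n_lipids, area_per_lipid, gap_for_np = NULL,
                          head_z = 1.9, box_z = 8, exclusion_pad = 1.0) {
  if (area_per_lipid <= 0) abort("area_per_lipid must be > 0")
  if (is.null(gap_for_np) && n_lipids %% 2 != 0) {
    abort("n_lipids must be even when no nanoparticle gap is requested")
  }
  n_leaf <- ceiling(n_lipids / 2)
  l_box <- sqrt(n_leaf * area_per_lipid)
  n_side <- ceiling(sqrt(n_leaf))
  cell <- l_box / n_side
  off <- lipid_bead_offsets(head_z)

  grid <- expand.grid(ix = seq_len(n_side) - 1L, iy = seq_len(n_side) - 1L)
  grid <- grid[seq_len(n_leaf), , drop = FALSE]
  n_upper <- min(n_leaf, n_lipids)
  n_lower <- n_lipids - n_upper
  leaflet_of <- rep(c("UPPER", "LOWER"), c(n_upper, n_lower))
  gi <- c(seq_len(n_upper), seq_len(n_lower))    # grid cell per lipid
  sgn <- ifelse(leaflet_of == "UPPER", 1, -1)
  cx <- (grid$ix[gi] + 0.5) * cell
  cy <- (grid$iy[gi] + 0.5) * cell
  n_lip <- length(gi)
  beads <- c("CHOLINE_N", "PHOSPHATE_P", "LIPID_TAIL", "LIPID_TAIL")
  atoms <- tibble(
    index = seq_len(4L * n_lip),
    role = rep(beads, n_lip),
    x = rep(cx, each = 4L),
    y = rep(cy, each = 4L),
    z = rep(sgn, each = 4L) * rep(unname(off), n_lip),
    ligand = NA_integer_,
    leaflet = rep(leaflet_of, each = 4L),
    lipid = rep(seq_len(n_lip), each = 4L))

  if (!is.null(gap_for_np)) {
    ctr <- gap_for_np$core_center
    r_ex <- gap_for_np$core_radius + exclusion_pad
    d2 <- (atoms$x - ctr[1])^2 + (atoms$y - ctr[2])^2 + (atoms$z - ctr[3])^2
    drop_lipids <- unique(atoms$lipid[d2 < r_ex^2])
    atoms <- atoms[!(atoms$lipid %in% drop_lipids), , drop = FALSE]
    atoms$index <- seq_len(nrow(atoms))
  }
  atoms$lipid <- NULL
  np_frame(atoms, box = c(l_box, l_box, box_z))
}

#' Locate the bilayer midplane
#'
#' The midplane is the midpoint between the mean phosphate z of the upper and
#' lower leaflets.  Leaflet membership is taken from the frame's `leaflet`
#' column when present; otherwise phosphates are split at the midpoint of
#' their z range.  A frame whose phosphates form a single plane (one leaflet)
#' has no defined midplane and is rejected.
#'
#' @param frame An [np_frame()] containing phosphates in both leaflets.
#' @param min_gap Minimum separation (nm) between the two leaflet phosphate
#'   planes for the midplane to be considered defined.
#' @return Signed midplane height, nm.
#' @export
midplane_z <- function(frame, min_gap = 1.0) {
  p <- frame[frame$role == "PHOSPHATE_P", , drop = FALSE]
  if (nrow(p) < 2) abort("undefined midplane: need phosphates in both leaflets")
  if (all(!is.na(p$leaflet))) {
    up <- p$z[p$leaflet == "UPPER"]
    lo <- p$z[p$leaflet == "LOWER"]
  } else {
    split_at <- (min(p$z) + max(p$z)) / 2
    up <- p$z[p$z >= split_at]
    lo <- p$z[p$z < split_at]
  }
  if (length(up) == 0 || length(lo) == 0 ||
      abs(mean(up) - mean(lo)) < min_gap) {
    abort("undefined midplane: phosphates do not form two separated leaflets")
  }
  (mean(up) + mean(lo)) / 2
}

#' Salt ion counts for an electroneutral system
#'
#' Computes the Na+ and Cl- counts that neutralise an anionic nanoparticle at
#' a target NaCl concentration.  The chloride count follows the mole-fraction
#' formula `round(target_conc * n_water / 55.5)` (55.5 M is the molar
#' concentration of pure water) unless overridden; sodium then balances the
#' particle charge: `n_na = n_cl + |net charge|`.  The study system (21,418
#' waters, charge -29 e, 150 mM, chloride fixed at 60) gives 89 Na+ and
#' 60 Cl-.
#'
#' @param n_water Number of water molecules (> 0).
#' @param np_net_charge Nanoparticle net charge, e (must be <= 0; the package
#'   models anionic particles only).
#' @param target_conc Target NaCl concentration, mol/L.
#' @param n_cl_override Optional fixed chloride count.
#' @return Named list `n_na`, `n_cl`.
#' @export
ion_counts <- function(n_water, np_net_charge, target_conc,
                       n_cl_override = NULL) {
  if (n_water <= 0) abort("n_water must be > 0")
  if (np_net_charge > 0) {
    abort("unsupported case: positive nanoparticle charge with the anionic Na+/Cl- convention")
  }
  n_cl <- if (!is.null(n_cl_override)) as.integer(n_cl_override)
          else as.integer(round(target_conc * n_water / 55.5))
  n_na <- n_cl + as.integer(max(0, -np_net_charge))
  list(n_na = n_na, n_cl = n_cl)
}
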