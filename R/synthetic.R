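GOLDEN_ANGLE <- pi * (3 - sqrt(5))

#' Parameters of the synthetic configuration generator
#'
#' The generator emulates the statistical structure of an equilibrated
#' nanoparticle-bilayer system at a prescribed ligand distribution, so that
#' the analyses can be exercised without molecular dynamics:
#' \itemize{
#'   \item the nanoparticle core height above the midplane follows a linear
#'     depth law, `depth_max * (14 - n_minus) / 14`, so the core descends to
#'     the midplane as charged ligands flip;
#'   \item the `n_plus` sulfonate end groups sit above the midplane (spread
#'     between `0.35 * head_z` and the head-group plane `head_z`), the
#'     `n_minus` end groups mirrored below;
#'   \item each end group carries a water shell of
#'     `round(hydration_floor + hydration_slope * |d_z|)` oxygens placed
#'     within the coordination threshold, giving end groups farther from the
#'     midplane larger hydration numbers;
#'   \item lipids, waters (as shell oxygens only) and ions follow the study
#'     composition: 334 lipids, a nominal 21,418 waters for the salt
#'     arithmetic, 89 Na+ and 60 Cl-.
#' }
#'
#' @param n_plus,n_minus Charged end groups above / below the midplane;
#'   must sum to the number of MUS ligands on `np` (29 by default).
#' @param depth_max Core height above the midplane at 29+/0-, nm.
#' @param noise_sigma Gaussian positional jitter (sd, nm), clipped at 3 sigma.
#' @param hydration_slope Shell waters per nm of |d_z|.
#' @param hydration_floor Shell waters at d_z = 0.
#' @param n_frames Frames per trajectory.
#' @param seed Integer seed; all frame streams derive from `(seed,
#'   frame_index)`.
#' @param np Nanoparticle model; defaults to the study particle
#'   `build_np(2, 58, 0.5, seed)`.
#' @param n_lipids,area_per_lipid,head_z,box_z Bilayer geometry, see
#'   [build_bilayer()].
#' @param coord_threshold Coordination shell cutoff, nm; shell waters are
#'   placed at 0.8 times this radius.
#' @param n_water,salt_conc,n_cl_override Salt arithmetic, see
#'   [ion_counts()].
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_plus = 29, n_minus = 0, depth_max = 1.0,
                             noise_sigma = 0.05, hydration_slope = 3.0,
                             hydration_floor = 2.0, n_frames = 1, seed = 1L,
                             np = NULL, n_lipids = 334, area_per_lipid = 0.65,
                             head_z = 1.9, box_z = 8,
                             coord_threshold = 0.7, n_water = 21418,
                             salt_conc = 0.150, n_cl_override = 60) {
  if (is.null(np)) np <- build_np(2.0, 58, 0.5, seed)
  n_mus <- sum(np$ligands$kind == "MUS")
  if (n_plus + n_minus != n_mus) {
    abort(sprintf("n_plus + n_minus must equal the number of MUS ligands (%d)",
                  n_mus))
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (hydration_slope < 0) abort("hydration_slope must be >= 0")
  structure(list(
    n_plus = n_plus, n_minus = n_minus, depth_max = depth_max,
    noise_sigma = noise_sigma, hydration_slope = hydration_slope,
    hydration_floor = hydration_floor, n_frames = n_frames,
    seed = as.integer(seed), np = np, n_lipids = n_lipids,
    area_per_lipid = area_per_lipid, head_z = head_z, box_z = box_z,
    coord_threshold = coord_threshold, n_water = n_water,
    salt_conc = salt_conc, n_cl_override = n_cl_override
  ), class = "generator_params")
}

# deterministic per-frame RNG stream seed (< 2^31)
frame_stream_seed <- function(seed, frame_index) {
  (abs(seed) * 1000003 + frame_index * 7919) %% 2147483629L
}

# default target d_z per MUS ligand for a (n_plus, n_minus) split: the first
# n_plus MUS ids (in id order) sit above the midplane, the rest below; |d_z|
# values evenly spaced between 0.35*head_z and head_z
default_dz_base <- function(params) {
  mus_ids <- params$np$ligands$ligand_id[params$np$ligands$kind == "MUS"]
  dz_min <- 0.35 * params$head_z
  spread <- function(n) if (n == 0) numeric(0) else
    if (n == 1) params$head_z else seq(dz_min, params$head_z, length.out = n)
  dz <- c(spread(params$n_plus), -spread(params$n_minus))
  setNames(dz, mus_ids)
}

# sulfonate anchor layout: per side, end groups ordered by |d_z| rank are
# placed at golden-angle azimuths with the axis distance cycling through
# three radii, which keeps every pair of sulfonate sulfurs > 1.3 nm apart so
# hydration shells do not overlap neighbouring end groups
sulfonate_xy <- function(rank, side_offset) {
  rho <- c(1.6, 2.2, 2.8)[(rank - 1L) %% 3L + 1L]
  az <- (rank + side_offset) * GOLDEN_ANGLE
  c(rho * cos(az), rho * sin(az))
}

clip3 <- function(x, lim) pmin(pmax(x, -lim), lim)

# build one synthetic frame from explicit per-ligand d_z targets
synth_frame <- function(params, dz_base, frame_index = 1L) {
  np <- params$np
  # with zero jitter every frame of a trajectory is the same configuration,
  # so the placement stream must not depend on the frame index
  stream_index <- if (params$noise_sigma == 0) 0L else frame_index
  withr::with_seed(frame_stream_seed(params$seed, stream_index), {
    n_minus <- sum(dz_base < 0)
    z_core <- params$depth_max * (14 - n_minus) / 14

    n_leaf <- ceiling(params$n_lipids / 2)
    l_box <- sqrt(n_leaf * params$area_per_lipid)
    center <- c(l_box / 2, l_box / 2, z_core)
    np$core_center <- center

    bilayer <- build_bilayer(params$n_lipids, params$area_per_lipid,
                             gap_for_np = np, head_z = params$head_z,
                             box_z = params$box_z)

    atoms <- np$atoms
    atoms$x <- atoms$x + center[1]
    atoms$y <- atoms$y + center[2]
    atoms$z <- atoms$z + center[3]
    atoms$leaflet <- NA_character_

    # reposition MUS end groups (and stretch their backbones) to the targets,
    # working on plain vectors to avoid per-element tibble assignment
    ax <- atoms$x; ay <- atoms$y; az <- atoms$z
    mus <- np$ligands[np$ligands$kind == "MUS", , drop = FALSE]
    for (side in c(1, -1)) {
      ids <- names(dz_base)[sign(dz_base) == side]
      if (length(ids) == 0) next
      ids <- ids[order(abs(dz_base[ids]))]
      for (k in seq_along(ids)) {
        lid <- as.integer(ids[k])
        lig <- mus[mus$ligand_id == lid, ]
        xy <- sulfonate_xy(k, if (side > 0) 0 else 0.5)
        s_pos <- c(center[1] + xy[1], center[2] + xy[2], dz_base[ids[k]])
        rows <- match(lig$endgroup_atoms[[1]], atoms$index)
        # sulfur first, then three oxygens on a horizontal ring so the
        # end-group centre of mass sits exactly at the target height
        ang <- 2 * pi * (0:2) / 3
        ax[rows] <- s_pos[1] + c(0, BOND_SO * cos(ang))
        ay[rows] <- s_pos[2] + c(0, BOND_SO * sin(ang))
        az[rows] <- s_pos[3]
        anchor_dir <- s_pos - center
        anchor_dir <- anchor_dir / sqrt(sum(anchor_dir^2))
        anchor <- center + np$core_radius * anchor_dir
        arow <- match(lig$anchor_atom, atoms$index)
        ax[arow] <- anchor[1]; ay[arow] <- anchor[2]; az[arow] <- anchor[3]
        bb <- match(lig$backbone_atoms[[1]], atoms$index)
        tfrac <- seq_along(bb) / (length(bb) + 1)
        ax[bb] <- anchor[1] + tfrac * (s_pos[1] - anchor[1])
        ay[bb] <- anchor[2] + tfrac * (s_pos[2] - anchor[2])
        az[bb] <- anchor[3] + tfrac * (s_pos[3] - anchor[3])
      }
    }
    atoms$x <- ax; atoms$y <- ay; atoms$z <- az

    n_np <- nrow(atoms)
    bl <- as_tibble(bilayer)
    bl$index <- bl$index + n_np
    all_atoms <- bind_rows(atoms, bl)

    # positional jitter: Gaussian, clipped at 3 sigma, every placed atom
    sig <- params$noise_sigma
    if (sig > 0) {
      n <- nrow(all_atoms)
      all_atoms$x <- all_atoms$x + clip3(rnorm(n, 0, sig), 3 * sig)
      all_atoms$y <- all_atoms$y + clip3(rnorm(n, 0, sig), 3 * sig)
      all_atoms$z <- all_atoms$z + clip3(rnorm(n, 0, sig), 3 * sig)
    } else {
      # keep the random stream aligned between sigma = 0 and sigma > 0 runs
      invisible(NULL)
    }

    # hydration shells: counts follow the hydration law from the *target*
    # d_z; oxygens are placed on a sphere of 0.8 * threshold around the
    # (jittered) sulfur so every shell water falls inside the cutoff
    shell_r <- 0.8 * params$coord_threshold
    next_idx <- max(all_atoms$index)
    shells <- list()
    for (lid_chr in names(dz_base)) {
      lid <- as.integer(lid_chr)
      n_w <- max(0L, as.integer(round(
        params$hydration_floor +
          params$hydration_slope * abs(dz_base[lid_chr]))))
      if (n_w == 0) next
      lig <- mus[mus$ligand_id == lid, ]
      srow <- match(lig$endgroup_atoms[[1]][1], all_atoms$index)
      u <- rnorm(n_w); v <- rnorm(n_w); w <- rnorm(n_w)
      nrm <- sqrt(u^2 + v^2 + w^2)
      shells[[lid_chr]] <- tibble(
        index = next_idx + seq_len(n_w), role = "WATER_O",
        x = all_atoms$x[srow] + shell_r * u / nrm,
        y = all_atoms$y[srow] + shell_r * v / nrm,
        z = all_atoms$z[srow] + shell_r * w / nrm,
        ligand = NA_integer_, leaflet = NA_character_)
      next_idx <- next_idx + n_w
    }
    if (length(shells) > 0) {
      all_atoms <- bind_rows(c(list(all_atoms), unname(shells)))
    }

    # ions in the solvent slabs above and below the bilayer
    ions <- ion_counts(params$n_water, np$net_charge, params$salt_conc,
                       params$n_cl_override)
    n_ion <- ions$n_na + ions$n_cl
    if (n_ion > 0) {
      z_lo <- params$head_z + 0.7
      z_hi <- params$box_z / 2 - 0.1
      zs <- runif(n_ion, z_lo, z_hi) * sample(c(-1, 1), n_ion, replace = TRUE)
      ion_tbl <- tibble(
        index = next_idx + seq_len(n_ion),
        role = rep(c("ION_NA", "ION_CL"), c(ions$n_na, ions$n_cl)),
        x = runif(n_ion, 0, l_box), y = runif(n_ion, 0, l_box), z = zs,
        ligand = NA_integer_, leaflet = NA_character_)
      all_atoms <- bind_rows(all_atoms, ion_tbl)
    }

    frame <- np_frame(all_atoms, box = c(l_box, l_box, params$box_z),
                      time = frame_index * 0.1)
    # the core pseudo-atom keeps its core-sized radius
    frame$radius[frame$role == "GOLD"] <- np$core_radius
    attr(frame, "synth") <- list(params = params, dz_base = dz_base,
                                 frame_index = frame_index)
    frame
  })
}

#' Generate one synthetic nanoparticle-bilayer frame
#'
#' Builds a frame at the ligand distribution requested in `params` (see
#' [generator_params()]).  Output is deterministic given `(seed,
#' frame_index)`.
#'
#' @param params A [generator_params()] object.
#' @param frame_index Frame number within the trajectory (drives the jitter
#'   stream).
#' @return An [np_frame()] carrying the generator state as an attribute so
#'   that [flip_ligand_synthetic()] and [run_flip_sequence()] can continue
#'   from it.
#' @export
gen_frame <- function(params, frame_index = 1L) {
  synth_frame(params, default_dz_base(params), frame_index)
}

#' Flip one charged ligand across the midplane (synthetic)
#'
#' Stands in for the biased flip of the molecular-dynamics workflow: the
#' selected end group's target height is reflected across the midplane, its
#' hydration shell is rebuilt according to the hydration law, and the frame
#' is regenerated with fresh jitter (all other atoms unchanged up to that
#' jitter).  Flipping a ligand whose target is already negative is rejected.
#'
#' @param frame A generator-produced [np_frame()].
#' @param ligand_id MUS ligand to flip (must currently have d_z > 0).
#' @param seed Integer controlling the re-jitter stream.
#' @return The flipped [np_frame()].
#' @export
flip_ligand_synthetic <- function(frame, ligand_id, seed = 1L) {
  synth <- attr(frame, "synth")
  if (is.null(synth)) abort("frame does not carry synthetic generator state")
  key <- as.character(ligand_id)
  if (!key %in% names(synth$dz_base)) {
    abort(sprintf("ligand %s is not a MUS ligand of this frame", key))
  }
  if (synth$dz_base[key] <= 0) {
    abort(sprintf("ligand %s already lies below the midplane; cannot flip",
                  key))
  }
  dz_base <- synth$dz_base
  dz_base[key] <- -dz_base[key]
  synth_frame(synth$params, dz_base,
              frame_index = synth$frame_index + 1000L + as.integer(seed))
}

#' Generate a synthetic trajectory
#'
#' `n_frames` frames at a fixed ligand distribution with independent jitter,
#' standing in for an equilibrium sampling run.
#'
#' @param params A [generator_params()] object.
#' @param dz_base Optional explicit per-ligand d_z targets (named by ligand
#'   id); defaults to the distribution encoded in `params`.
#' @return List of [np_frame()]s of length `params$n_frames`.
#' @export
gen_trajectory <- function(params, dz_base = NULL) {
  if (is.null(dz_base)) dz_base <- default_dz_base(params)
  map(seq_len(params$n_frames),
      function(i) synth_frame(params, dz_base, frame_index = i))
}
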