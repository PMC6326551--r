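#' Chemical role vocabulary
#'
#' Every atom in an `np_frame` carries one of these role labels.  Roles encode
#' the chemical identity that the analyses dispatch on: the gold core, thiol
#' anchors, hydrophobic ligand backbone carbons (11-carbon
#' mercaptoundecanesulfonate, MUS, or 8-carbon octanethiol, OT), the anionic
#' sulfonate end group (one S, three O), the zwitterionic lipid head-group
#' beads (choline N, phosphate P), lipid tail beads, water oxygens and the two
#' salt ions.
#'
#' @return Character vector of the twelve valid role labels.
#' @export
atom_roles <- function() {
  c("GOLD", "THIOL_S", "LIGAND_C_MUS", "LIGAND_C_OT",
    "SULFONATE_S", "SULFONATE_O", "CHOLINE_N", "PHOSPHATE_P",
    "LIPID_TAIL", "WATER_O", "ION_NA", "ION_CL")
}

#' Default van der Waals radii per role
#'
#' Radii in nm used by the surface-area quadrature: C 0.17, S 0.18, O 0.152,
#' N 0.155, P 0.18, Au 0.166, Na 0.227, Cl 0.175.  Lipid tail beads are
#' treated as united-atom carbons.  Every value can be overridden through
#' [sasa_params()] or the configuration file.
#'
#' @return Named numeric vector, nm, one entry per role.
#' @export
default_radii <- function() {
  c(GOLD = 0.166, THIOL_S = 0.18, LIGAND_C_MUS = 0.17, LIGAND_C_OT = 0.17,
    SULFONATE_S = 0.18, SULFONATE_O = 0.152, CHOLINE_N = 0.155,
    PHOSPHATE_P = 0.18, LIPID_TAIL = 0.17, WATER_O = 0.152,
    ION_NA = 0.227, ION_CL = 0.175)
}

# atomic / united-atom masses (u) used for the sulfonate centre of mass
role_masses <- function() {
  c(GOLD = 196.97, THIOL_S = 32.06, LIGAND_C_MUS = 14.03, LIGAND_C_OT = 14.03,
    SULFONATE_S = 32.06, SULFONATE_O = 16.00, CHOLINE_N = 14.01,
    PHOSPHATE_P = 30.97, LIPID_TAIL = 42.08, WATER_O = 18.02,
    ION_NA = 22.99, ION_CL = 35.45)
}

#' Construct a coordinate frame
#'
#' An `np_frame` is a tibble of atom records (one row per atom) plus an
#' orthorhombic box and a time stamp.  It is the universal input of every
#' analysis in the package.  Columns:
#' \describe{
#'   \item{index}{integer atom identifier, unique within the frame}
#'   \item{role}{chemical role, see [atom_roles()]}
#'   \item{x, y, z}{coordinates in nm; the bilayer midplane of built systems
#'     sits near z = 0, so z may be negative}
#'   \item{radius}{van der Waals radius in nm (filled from [default_radii()]
#'     when absent; the rigid gold core is represented by a single pseudo-atom
#'     whose radius equals the core radius)}
#'   \item{ligand}{ligand id for nanoparticle ligand atoms, NA otherwise}
#'   \item{leaflet}{"UPPER"/"LOWER" for lipid atoms, NA otherwise}
#' }
#'
#' @param atoms Data frame with at least `index`, `role`, `x`, `y`, `z`.
#' @param box Numeric length-3 orthorhombic box edges, nm, all > 0.
#' @param time Frame time in ns (metadata).
#' @return An `np_frame` (tibble subclass) with `box` and `time` attributes.
#' @export
np_frame <- function(atoms, box, time = 0) {
  atoms <- as_tibble(atoms)
  req <- c("index", "role", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(atoms$role), atom_roles())
  if (length(bad) > 0) {
    abort(paste0("unknown atom role(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(atoms$index)) abort("duplicate atom index in frame")
  if (!is.numeric(box) || length(box) != 3 || any(box <= 0)) {
    abort("box must be 3 positive edge lengths (nm)")
  }
  if (!"radius" %in% names(atoms)) atoms$radius <- NA_real_
  fill <- is.na(atoms$radius)
  atoms$radius[fill] <- unname(default_radii()[atoms$role[fill]])
  if (any(atoms$radius <= 0, na.rm = TRUE)) abort("atom radii must be > 0")
  if (!"ligand" %in% names(atoms)) atoms$ligand <- NA_integer_
  if (!"leaflet" %in% names(atoms)) atoms$leaflet <- NA_character_
  structure(atoms,
            box = as.numeric(box), time = as.numeric(time),
            class = c("np_frame", class(tibble())))
}

#' @export
print.np_frame <- function(x, ...) {
  box <- frame_box(x)
  cat(sprintf("<np_frame> %d atoms, box %.3f x %.3f x %.3f nm, t = %g ns\n",
              nrow(x), box[1], box[2], box[3], frame_time(x)))
  NextMethod()
}

#' Box and time accessors
#'
#' @param frame An [np_frame()].
#' @return `frame_box()`: numeric length-3 box edges (nm); `frame_time()`: ns.
#' @export
frame_box <- function(frame) attr(frame, "box")

#' @rdname frame_box
#' @export
frame_time <- function(frame) attr(frame, "time")

is_np_frame <- function(x) inherits(x, "np_frame")

# normalise "one frame or a list of frames" arguments
as_frame_list <- function(frames) {
  if (is_np_frame(frames)) return(list(frames))
  if (is.list(frames) && length(frames) > 0 && all(map_lgl(frames, is_np_frame))) {
    return(frames)
  }
  abort("expected an np_frame or a non-empty list of np_frames")
}

#' Wrap x and y coordinates into the primary box image
#'
#' The bilayer normal (z) is not periodic in any analysis that references the
#' midplane, so only the in-plane coordinates are wrapped.
#'
#' @param frame An [np_frame()].
#' @return The frame with `x`, `y` wrapped into `[0, box)`.
#' @export
wrap_frame <- function(frame) {
  box <- frame_box(frame)
  frame$x <- frame$x %% box[1]
  frame$y <- frame$y %% box[2]
  frame
}

# squared distances between rows of a (n x 3) and b (m x 3)
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# minimum-image pair distances between coordinate matrices under an
# orthorhombic box; periodic in all three directions
min_image_dist <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

coords_matrix <- function(frame, rows = TRUE) {
  cbind(frame$x, frame$y, frame$z)[rows, , drop = FALSE]
}
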