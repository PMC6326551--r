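#' Radial distribution function
#'
#' Minimum-image pair histogram between two role sets, normalised by the
#' ideal-gas expectation at the frame's number density of the second set and
#' averaged over frames.  Used to determine neighbour-shell cutoffs (the
#' contact and coordination thresholds are first minima of such profiles).
#'
#' @param frames An [np_frame()] or list of frames.
#' @param roles_a,roles_b Character vectors of roles (nonempty selections).
#' @param dr Bin width, nm.
#' @param r_max Histogram range, nm; at most half the smallest box edge.
#' @return An `rdf_profile`: tibble with `r` (bin centres), `g`, `count`
#'   and attributes `dr`, `n_frames`.
#' @export
rdf <- function(frames, roles_a, roles_b, dr = 0.02, r_max = NULL) {
  frames <- as_frame_list(frames)
  box <- frame_box(frames[[1]])
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9) {
    abort("r_max exceeds half the smallest box edge")
  }
  edges <- seq(0, r_max, by = dr)
  if (tail(edges, 1) < r_max) edges <- c(edges, tail(edges, 1) + dr)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  norm <- numeric(nb)
  for (f in frames) {
    ra <- which(f$role %in% roles_a)
    rb <- which(f$role %in% roles_b)
    if (length(ra) == 0) abort("no atoms match roles_a")
    if (length(rb) == 0) abort("no atoms match roles_b")
    d <- min_image_dist(coords_matrix(f, ra), coords_matrix(f, rb), box)
    # drop self pairs when the two selections overlap
    self <- outer(f$index[ra], f$index[rb], "==")
    dvec <- d[!self & d < r_max]
    counts <- counts + tabulate(findInterval(dvec, edges,
                                             rightmost.closed = FALSE),
                                nbins = nb)
    rho_b <- length(rb) / prod(box)
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
    norm <- norm + length(ra) * rho_b * shell
  }
  g <- ifelse(norm > 0, counts / norm, 0)
  structure(tibble(r = (edges[-1] + edges[-(nb + 1)]) / 2,
                   g = g, count = counts),
            dr = dr, n_frames = length(frames),
            class = c("rdf_profile", class(tibble())))
}

#' First minimum of a radial distribution function
#'
#' Returns the bin centre of the first local minimum after the first local
#' maximum of the (moving-average smoothed) g(r).  This is the procedure
#' that fixes contact and coordination cutoffs from pair structure.
#'
#' @param profile An `rdf_profile` from [rdf()].
#' @param smooth_window Centred moving-average window, bins (odd; 1 = no
#'   smoothing).
#' @return Position of the first minimum, nm.
#' @export
first_min <- function(profile, smooth_window = 3) {
  g <- profile$g
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(g, k, sides = 2)
    keep <- !is.na(sm)
    g <- as.numeric(sm[keep])
    r <- profile$r[keep]
  } else {
    r <- profile$r
  }
  n <- length(g)
  if (n < 3) abort("profile too short to locate a minimum")
  d <- diff(g)
  max_i <- NULL
  for (i in seq_len(n - 2)) {
    if (d[i] > 0 && d[i + 1] <= 0) { max_i <- i + 1; break }
  }
  if (is.null(max_i)) abort("no interior maximum: profile has no first peak")
  for (i in seq(max_i, n - 2)) {
    if (d[i] < 0 && d[i + 1] >= 0) return(r[i + 1])
  }
  abort("no minimum after the first maximum (monotone tail)")
}

#' Sulfonate-choline contact statistics
#'
#' Counts, per frame, the pairs of sulfonate sulfur and choline nitrogen
#' atoms whose minimum-image distance is below the threshold (0.7 nm, the
#' first minimum of the sulfonate-choline RDF), then averages over frames
#' with a block-averaging error.
#'
#' @param frames An [np_frame()] or list of frames.
#' @param threshold Contact cutoff, nm (> 0).
#' @return A `contact_summary`: list with `n_contacts` (mean), `error`
#'   (block estimate), `threshold`, `per_frame` (integer vector).
#' @export
count_contacts <- function(frames, threshold = 0.7) {
  if (threshold <= 0) abort("threshold must be > 0")
  frames <- as_frame_list(frames)
  per_frame <- map_dbl(frames, function(f) {
    s <- which(f$role == "SULFONATE_S")
    n <- which(f$role == "CHOLINE_N")
    if (length(s) == 0 || length(n) == 0) return(0)
    d <- min_image_dist(coords_matrix(f, s), coords_matrix(f, n),
                        frame_box(f))
    sum(d < threshold)
  })
  err <- if (length(per_frame) >= 4) block_error(per_frame)
         else if (length(per_frame) >= 2) sd(per_frame) / sqrt(length(per_frame))
         else 0
  structure(list(n_contacts = mean(per_frame), error = err,
                 threshold = threshold, per_frame = per_frame),
            class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf("<contact_summary> %.2f +/- %.2f contacts (< %.2g nm, %d frames)\n",
              x$n_contacts, x$error, x$threshold, length(x$per_frame)))
  invisible(x)
}

#' Default per-role coordination thresholds
#'
#' Shell cutoffs (nm) for the polar groups counted around a sulfonate
#' sulfur.  The species-resolved first-minimum values are not tabulated in
#' the available text, so all roles default to the sulfonate-choline value
#' of 0.7 nm; override per role as needed.
#'
#' @return Named numeric vector, nm.
#' @export
default_coordination_thresholds <- function() {
  c(WATER_O = 0.7, CHOLINE_N = 0.7, PHOSPHATE_P = 0.7,
    SULFONATE_S = 0.7, ION_NA = 0.7)
}

# single-frame coordination count around one ligand's sulfonate sulfur
coordination_core <- function(f, ligand_id, thresholds) {
  srow <- which(f$role == "SULFONATE_S" & !is.na(f$ligand) &
                  f$ligand == ligand_id)
  if (length(srow) != 1) {
    abort(sprintf("ligand %s has no sulfonate sulfur in frame",
                  as.character(ligand_id)))
  }
  s_xyz <- coords_matrix(f, srow)
  total <- 0
  for (role in names(thresholds)) {
    rows <- which(f$role == role)
    # exclude the ligand's own atoms (its sulfur is not its own neighbour)
    own <- !is.na(f$ligand[rows]) & f$ligand[rows] == ligand_id
    rows <- rows[!own]
    if (length(rows) == 0) next
    d <- min_image_dist(s_xyz, coords_matrix(f, rows), frame_box(f))
    total <- total + sum(d < thresholds[[role]])
  }
  total
}

#' End-group coordination number
#'
#' Counts, per frame, the polar-group central atoms lying within their
#' role-specific threshold of a MUS ligand's sulfonate sulfur (other
#' ligands' sulfonates count; the ligand's own atoms do not), sums over
#' roles, and averages over frames with block errors.  The record is paired
#' with the ligand's mean `d_z`, since end-group hydration grows with
#' distance from the midplane.
#'
#' @param frames An [np_frame()] or list of frames.
#' @param ligand_id MUS ligand id.
#' @param thresholds Named role -> cutoff (nm) table defining the polar
#'   group inventory; see [default_coordination_thresholds()].
#' @return A one-row tibble: `ligand_id`, `coordination_mean`,
#'   `coordination_error`, `dz_mean`, `dz_error`, `n_frames`.
#' @export
coordination <- function(frames, ligand_id,
                         thresholds = default_coordination_thresholds()) {
  frames <- as_frame_list(frames)
  if (is.null(names(thresholds)) || any(!names(thresholds) %in% atom_roles())) {
    abort("thresholds must be a named role -> cutoff table")
  }
  per_frame <- map_dbl(frames, coordination_core, ligand_id = ligand_id,
                       thresholds = thresholds)
  dzs <- map_dbl(frames, ~compute_dz(.x, ligand_id))
  nf <- length(frames)
  berr <- function(x) {
    if (nf >= 4) block_error(x) else if (nf >= 2) sd(x) / sqrt(nf) else 0
  }
  tibble(ligand_id = ligand_id,
         coordination_mean = mean(per_frame),
         coordination_error = berr(per_frame),
         dz_mean = mean(dzs), dz_error = berr(dzs),
         n_frames = nf)
}

#' Cylindrical number-density map
#'
#' Exploits the cylindrical symmetry of the nanoparticle-bilayer system:
#' atom counts are binned by distance in the x-y plane from the vertical
#' axis through the gold core and by height relative to the bilayer
#' midplane, then divided by the number of frames and the cylindrical bin
#' volume `2 pi r_mid dr dz`.
#'
#' @param frames An [np_frame()] or list of frames (each must contain the
#'   gold core to define the axis).
#' @param roles Roles to map.
#' @param dr,dz Radial and axial bin widths, nm (> 0).
#' @return A `radial_density_map`: tibble with `r`, `z` (bin centres) and
#'   `density` (nm^-3), plus edge vectors as attributes.
#' @export
density_map <- function(frames, roles, dr = 0.1, dz = 0.1) {
  if (dr <= 0 || dz <= 0) abort("zero-width bins are not allowed")
  frames <- as_frame_list(frames)
  box <- frame_box(frames[[1]])
  r_edges <- seq(0, min(box[1:2]) / 2, by = dr)
  z_half <- box[3] / 2
  z_edges <- seq(-z_half, z_half, by = dz)
  nr <- length(r_edges) - 1
  nz <- length(z_edges) - 1
  counts <- matrix(0, nr, nz)
  for (f in frames) {
    core <- which(f$role == "GOLD")
    if (length(core) == 0) abort("no gold core present to define the axis")
    ax <- mean(f$x[core]); ay <- mean(f$y[core])
    mid <- midplane_z(f)
    rows <- which(f$role %in% roles)
    dx <- f$x[rows] - ax; dx <- dx - box[1] * round(dx / box[1])
    dy <- f$y[rows] - ay; dy <- dy - box[2] * round(dy / box[2])
    r <- sqrt(dx^2 + dy^2)
    zz <- f$z[rows] - mid
    ir <- findInterval(r, r_edges, rightmost.closed = FALSE)
    iz <- findInterval(zz, z_edges, rightmost.closed = FALSE)
    ok <- ir >= 1 & ir <= nr & iz >= 1 & iz <= nz
    counts <- counts + table(factor(ir[ok], levels = seq_len(nr)),
                             factor(iz[ok], levels = seq_len(nz)))
  }
  r_mid <- (r_edges[-1] + r_edges[-(nr + 1)]) / 2
  z_mid <- (z_edges[-1] + z_edges[-(nz + 1)]) / 2
  vol <- outer(2 * pi * r_mid * dr * dz, rep(1, nz))
  dens <- counts / (length(frames) * vol)
  grid <- expand.grid(r = r_mid, z = z_mid)
  structure(tibble(r = grid$r, z = grid$z, density = as.vector(dens)),
            r_edges = r_edges, z_edges = z_edges,
            n_frames = length(frames),
            class = c("radial_density_map", class(tibble())))
}

#' Linear trend of core depth with flips
#'
#' Ordinary least-squares fit of the core-midplane distance against the
#' number of flipped ligands; the core descends approximately linearly as
#' charged ligands flip.
#'
#' @param depths Data frame with columns `n_flipped` and `z` (nm), one row
#'   per ligand distribution (>= 2 rows).
#' @return A `depth_trend` object wrapping the `lm` fit, with elements
#'   `slope` (nm per flip), `intercept` (nm) and `residuals`; supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
core_depth_trend <- function(depths) {
  depths <- as_tibble(depths)
  if (nrow(depths) < 2) abort("need at least 2 (n_flipped, z) points")
  fit <- lm(z ~ n_flipped, data = depths)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 residuals = unname(residuals(fit)),
                 data = depths),
            class = "depth_trend")
}

#' @export
print.depth_trend <- function(x, ...) {
  cat(sprintf("<depth_trend> z = %.4f %+.4f * n_flipped (nm), RMS residual %.4f\n",
              x$intercept, x$slope, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Block-averaging standard error
#'
#' Standard error of the mean of a (possibly autocorrelated) series by the
#' blocking transform: the series is successively coarse-grained by pairwise
#' averaging and the naive standard error is tracked across levels; the
#' estimate is read off at the first plateau (first level whose estimate
#' changes by less than 5% over two successive levels), falling back to the
#' largest level estimate when no plateau is reached.
#'
#' @param series Numeric vector, length >= 4.
#' @param plateau_tol Relative change defining the plateau.
#' @return Standard-error estimate of the series mean.
#' @export
block_error <- function(series, plateau_tol = 0.05) {
  x <- as.numeric(series)
  if (length(x) < 4) abort("series too short for block averaging (need >= 4)")
  if (sd(x) == 0) return(0)
  ests <- numeric(0)
  while (length(x) >= 4) {
    ests <- c(ests, sd(x) / sqrt(length(x)))
    n2 <- floor(length(x) / 2)
    x <- (x[2 * seq_len(n2) - 1] + x[2 * seq_len(n2)]) / 2
  }
  if (length(ests) >= 3) {
    for (k in seq_len(length(ests) - 2)) {
      c1 <- abs(ests[k + 1] - ests[k]) / ests[k]
      c2 <- abs(ests[k + 2] - ests[k + 1]) / ests[k + 1]
      if (c1 < plateau_tol && c2 < plateau_tol) return(ests[k])
    }
  }
  max(ests)
}
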