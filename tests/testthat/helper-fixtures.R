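# shared fixtures and independent oracles, all built in code

# minimal frame from loose vectors
toy_frame <- function(role, x, y, z, box = c(10, 10, 10), ligand = NA_integer_,
                      radius = NA_real_, leaflet = NA_character_) {
  n <- length(role)
  np_frame(tibble::tibble(index = seq_len(n), role = role,
                          x = x, y = y, z = z, radius = radius,
                          ligand = rep_len(ligand, n),
                          leaflet = rep_len(leaflet, n)),
           box = box)
}

# four-lipid toy bilayer with explicit phosphate heights
toy_bilayer <- function(z_upper = c(1.9, 2.1), z_lower = c(-2, -2)) {
  toy_frame(role = rep("PHOSPHATE_P", 4),
            x = c(1, 2, 1, 2), y = c(1, 1, 2, 2),
            z = c(z_upper, z_lower),
            leaflet = rep(c("UPPER", "LOWER"), each = 2))
}

# z-reflection of a frame (leaflet labels swap with it)
mirror_frame <- function(f) {
  synth <- attr(f, "synth")
  f$z <- -f$z
  f$leaflet <- c(UPPER = "LOWER", LOWER = "UPPER")[f$leaflet]
  attr(f, "synth") <- synth
  f
}

# uniform random gas frame of one role
gas_frame <- function(n, box_edge, role = "WATER_O") {
  toy_frame(role = rep(role, n),
            x = runif(n, 0, box_edge), y = runif(n, 0, box_edge),
            z = runif(n, 0, box_edge), box = rep(box_edge, 3))
}

# independent minimum-image pair-count oracle: explicit image scan, no
# shared code with the package distance machinery
brute_force_count <- function(frame, roles_a, roles_b, threshold) {
  box <- frame_box(frame)
  a <- which(frame$role %in% roles_a)
  b <- which(frame$role %in% roles_b)
  count <- 0L
  for (i in a) {
    for (j in b) {
      if (frame$index[i] == frame$index[j]) next
      best <- Inf
      for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
        dx <- frame$x[i] - frame$x[j] + sx * box[1]
        dy <- frame$y[i] - frame$y[j] + sy * box[2]
        dz <- frame$z[i] - frame$z[j] + sz * box[3]
        best <- min(best, sqrt(dx^2 + dy^2 + dz^2))
      }
      if (best < threshold) count <- count + 1L
    }
  }
  count
}

# analytic accessible area of two equal spheres (radius r, probe p) at
# centre separation d: each loses a cap of height R - d/2, R = r + p
two_sphere_area <- function(r, p, d) {
  R <- r + p
  if (d >= 2 * R) return(2 * 4 * pi * R^2)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# study-condition generator params with a small particle cache
study_params <- function(n_plus = 29, n_minus = 0, ...) {
  generator_params(n_plus = n_plus, n_minus = n_minus, ...)
}
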