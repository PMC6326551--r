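PROVENANCE_LEVELS <- c("PRIOR_WORK_CONSTANT", "SCALED", "COMPUTED", "USER")

#' Create a free-energy component
#'
#' A labelled free-energy contribution with its provenance: a constant cited
#' from prior work, a value scaled from one (`SCALED`), a value computed by
#' this package (`COMPUTED`), or user supplied.
#'
#' @param name Component label.
#' @param dg Free energy, kcal/mol (finite).
#' @param uncertainty Optional 1-sigma uncertainty, kcal/mol.
#' @param provenance One of `"PRIOR_WORK_CONSTANT"`, `"SCALED"`,
#'   `"COMPUTED"`, `"USER"`.
#' @return One-row tibble with class `energy_component` semantics.
#' @export
energy_component <- function(name, dg, uncertainty = NA_real_,
                             provenance = "USER") {
  if (!is.finite(dg)) abort("dg must be finite")
  provenance <- match.arg(provenance, PROVENANCE_LEVELS)
  tibble(name = name, dg = dg, uncertainty = as.numeric(uncertainty),
         provenance = provenance)
}

#' Default landscape inputs
#'
#' The component estimates entering the six-state insertion landscape, all
#' in kcal/mol: lipid-tail protrusion cost +6.0; single-leaflet insertion
#' -102.6 +/- 2.8 (scaled from the -115.05 +/- 2.8 per-leaflet value of a
#' 65-ligand particle); per-flip barrier 11.2 +/- 0.2; per-flip hydrophobic
#' drive 0 to -17.3 with mean -3.6 +/- 0.4; iterative-flipping total
#' -52.1 +/- 2.9.  Prior-work constants are configuration inputs, never
#' recomputed.
#'
#' @return Named list of defaults.
#' @export
landscape_defaults <- function() {
  list(
    protrusion_dg = 6.0,
    leaflet_insertion_dg = -102.6,
    leaflet_insertion_err = 2.8,
    flip_barrier = 11.2,
    flip_barrier_err = 0.2,
    per_flip_drive_mean = -3.6,
    per_flip_drive_err = 0.4,
    per_flip_drive_range = c(0, -17.3),
    iterative_flipping_dg = -52.1,
    iterative_flipping_err = 2.9,
    per_leaflet_reference_dg = -115.05,
    per_leaflet_reference_err = 2.8,
    two_state_reference_dg = -232.1,
    two_state_reference_err = 5.6,
    n_ligands_reference = 65,
    n_ligands_target = 58,
    gamma = 4.7
  )
}

#' Scale an insertion free energy by ligand count
#'
#' The single-leaflet insertion estimate is obtained from a prior two-state
#' calculation for a larger particle: optionally halve (two leaflets to
#' one), then scale linearly with ligand count.  With the printed per-leaflet
#' value -115.05 kcal/mol for 65 ligands, the 58-ligand particle gives
#' -102.6 kcal/mol.
#'
#' @param dg_reference Reference free energy, kcal/mol.
#' @param n_ligands_reference,n_ligands_target Ligand counts (> 0).
#' @param halve Divide by two first (full membrane-spanning to single
#'   leaflet)?
#' @param uncertainty Optional reference uncertainty, scaled alongside.
#' @return An [energy_component()] with provenance `SCALED`.
#' @export
scale_insertion <- function(dg_reference, n_ligands_reference,
                            n_ligands_target, halve = FALSE,
                            uncertainty = NA_real_) {
  if (n_ligands_reference <= 0 || n_ligands_target <= 0) {
    abort("ligand counts must be > 0")
  }
  base <- if (halve) dg_reference / 2 else dg_reference
  fac <- n_ligands_target / n_ligands_reference
  energy_component("leaflet_insertion", base * fac,
                   uncertainty = if (is.na(uncertainty)) NA_real_ else
                     abs(if (halve) uncertainty / 2 else uncertainty) * fac,
                   provenance = "SCALED")
}

#' Hydrophobic-particle reference free energy
#'
#' The insertion free energy a purely hydrophobic sphere would gain by
#' burying its bare surface: `-gamma * pi * d^2`.  A 4 nm sphere (the
#' ligand-inclusive diameter of the study particle) gives about
#' -236 kcal/mol.
#'
#' @param diameter Sphere diameter, nm (> 0 allowed; 0 gives 0).
#' @param gamma Solvation parameter, kcal/mol/nm².
#' @return An [energy_component()] with provenance `SCALED`.
#' @export
hydrophobic_reference <- function(diameter, gamma = 4.7) {
  if (diameter < 0) abort("diameter must be >= 0")
  energy_component("hydrophobic_reference", -gamma * pi * diameter^2,
                   provenance = "SCALED")
}

#' Per-flip hydrophobic driving forces
#'
#' Converts the SASA change of each individual flip to its hydrophobic
#' drive, `gamma * dSASA_i`.  Fourteen entries are expected (one per flip of
#' the full pathway); fewer are accepted with a warning.
#'
#' @param delta_sasa_per_flip Numeric vector of per-flip SASA changes, nm².
#' @param gamma Solvation parameter, kcal/mol/nm².
#' @return Tibble of [energy_component()] rows (provenance `COMPUTED`) with
#'   one row per flip; the sum of `dg` equals
#'   `hydrophobic_dg(sum(delta_sasa_per_flip), gamma)$dg` exactly.
#' @export
per_flip_drives <- function(delta_sasa_per_flip, gamma = 4.7) {
  n <- length(delta_sasa_per_flip)
  if (n < 14) {
    warn(sprintf("expected 14 per-flip entries, got %d", n))
  }
  bind_rows(map(seq_len(n), function(i) {
    energy_component(sprintf("flip_%02d", i),
                     gamma * delta_sasa_per_flip[i],
                     provenance = "COMPUTED")
  }))
}

#' Assemble the six-state insertion landscape
#'
#' Builds the ordered free-energy landscape of nanoparticle insertion:
#' (1) particle adsorbed at the bilayer surface (reference, 0),
#' (2) lipid-tail protrusion contact (barrier peak),
#' (3) particle inserted into the upper leaflet, 29+/0-,
#' (4) single-flip transition state (barrier peak),
#' (5) first flipped local minimum,
#' (6) membrane-spanning configuration, 15+/14-.
#' Minima-to-minima components (insertion 1 to 3, iterative flipping 3 to 6)
#' accumulate from state 1; barriers (protrusion, per-flip) sit on
#' transitions, not minima.  The default inputs give a total of
#' -154.7 kcal/mol between states 1 and 6.  Component uncertainties
#' propagate in quadrature.
#'
#' @param components Tibble of [energy_component()] rows; must contain
#'   `leaflet_insertion` (1 to 3) and `iterative_flipping` (3 to 6).
#' @param barrier_components Tibble of [energy_component()] rows; must
#'   contain `protrusion` and `flip_barrier`.
#' @param per_flip_drive Free energy of the first flipped minimum relative
#'   to state 3 (kcal/mol); defaults to the mean per-flip drive.
#' @return An `np_landscape`: list with `states` (tibble `index`,
#'   `description`, `kind`, `cumulative_dg`), `transitions` (tibble with
#'   barrier heights), `total` (state 6 minus state 1), `total_uncertainty`,
#'   `components`, and `notes` (flagged input inconsistencies).
#' @export
assemble_landscape <- function(components = NULL, barrier_components = NULL,
                               per_flip_drive = NULL) {
  d <- landscape_defaults()
  if (is.null(components)) {
    components <- bind_rows(
      energy_component("leaflet_insertion", d$leaflet_insertion_dg,
                       d$leaflet_insertion_err, "SCALED"),
      energy_component("iterative_flipping", d$iterative_flipping_dg,
                       d$iterative_flipping_err, "COMPUTED"))
  }
  if (is.null(barrier_components)) {
    barrier_components <- bind_rows(
      energy_component("protrusion", d$protrusion_dg,
                       provenance = "PRIOR_WORK_CONSTANT"),
      energy_component("flip_barrier", d$flip_barrier, d$flip_barrier_err,
                       "PRIOR_WORK_CONSTANT"))
  }
  need <- function(tbl, nm, what) {
    if (!nm %in% tbl$name) {
      abort(sprintf("missing mandatory %s component '%s'", what, nm))
    }
    tbl[tbl$name == nm, , drop = FALSE]
  }
  ins <- need(components, "leaflet_insertion", "minima")
  flip_block <- components[components$name != "leaflet_insertion", , drop = FALSE]
  if (nrow(flip_block) == 0) {
    abort("missing mandatory minima component 'iterative_flipping'")
  }
  flip_total <- sum(flip_block$dg)
  flip_unc <- sqrt(sum(flip_block$uncertainty^2, na.rm = TRUE))
  prot <- need(barrier_components, "protrusion", "barrier")
  barr <- need(barrier_components, "flip_barrier", "barrier")
  if (is.null(per_flip_drive)) per_flip_drive <- d$per_flip_drive_mean

  g3 <- ins$dg
  g6 <- ins$dg + flip_total
  states <- tibble(
    index = 1:6,
    description = c(
      "NP adsorbed at bilayer surface (solution side)",
      "lipid tail protrusion contact (barrier peak)",
      "NP inserted in upper leaflet (29+/0-)",
      "single-ligand flip transition state (barrier peak)",
      "first flipped configuration (28+/1-, local minimum)",
      "membrane-spanning configuration (15+/14-)"),
    kind = c("minimum", "barrier", "minimum", "barrier", "minimum",
             "minimum"),
    cumulative_dg = c(0, prot$dg, g3, g3 + barr$dg, g3 + per_flip_drive, g6))
  transitions <- tibble(
    from = c(1L, 3L), to = c(3L, 5L),
    barrier = c(prot$dg, barr$dg),
    barrier_name = c("protrusion", "flip_barrier"))
  total_unc <- sqrt(sum(c(ins$uncertainty, flip_unc)^2, na.rm = TRUE))
  notes <- character(0)
  if (abs(d$per_leaflet_reference_dg - d$two_state_reference_dg / 2) > 0.5) {
    notes <- c(notes, sprintf(
      "per-leaflet reference %.2f kcal/mol differs from half the two-state reference (%.2f); the printed per-leaflet value is honoured",
      d$per_leaflet_reference_dg, d$two_state_reference_dg / 2))
  }
  structure(list(states = states, transitions = transitions,
                 total = g6, total_uncertainty = total_unc,
                 components = components,
                 barrier_components = barrier_components,
                 notes = notes),
            class = "np_landscape")
}

#' @export
print.np_landscape <- function(x, ...) {
  cat("<np_landscape> six-state insertion pathway (kcal/mol, relative to state 1)\n")
  for (i in seq_len(nrow(x$states))) {
    cat(sprintf("  %d %-52s %8.1f  [%s]\n", x$states$index[i],
                x$states$description[i], x$states$cumulative_dg[i],
                x$states$kind[i]))
  }
  cat(sprintf("  total dG(1 -> 6) = %.1f +/- %.1f kcal/mol\n",
              x$total, x$total_uncertainty))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Write / read a landscape report
#'
#' TSV report (with `#` metadata header) of the state table; every state's
#' cumulative free energy is recoverable from the file alone.
#'
#' @param landscape An `np_landscape` from [assemble_landscape()].
#' @param path File path.
#' @return `write_landscape()` returns `path` invisibly; `read_landscape()`
#'   returns the states tibble with a `total` attribute.
#' @export
write_landscape <- function(landscape, path) {
  hdr <- c("# six-state insertion free-energy landscape",
           "# cumulative_dg in kcal/mol relative to state 1",
           sprintf("# total_dg_1_to_6\t%.10g", landscape$total),
           sprintf("# total_uncertainty\t%.10g", landscape$total_uncertainty),
           paste0("# note\t", landscape$notes))
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(landscape$states, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  states <- utils::read.table(text = body, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  tot <- meta[startsWith(meta, "# total_dg_1_to_6")]
  states <- as_tibble(states)
  attr(states, "total") <- as.numeric(sub(".*\t", "", tot))
  states
}
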