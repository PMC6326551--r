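#' Signed end-group height of a charged ligand
#'
#' `d_z` is the distance between the centre of mass of a MUS ligand's
#' sulfonate end group (one S and three O atoms, mass-weighted) and the
#' bilayer midplane, projected along the z axis.  Positive values lie above
#' the midplane.
#'
#' @param frame An [np_frame()].
#' @param ligand_id Ligand identifier; must be a MUS ligand (OT ligands have
#'   no end group and are rejected).
#' @return Signed height, nm.
#' @export
compute_dz <- function(frame, ligand_id) {
  rows <- frame$ligand == ligand_id &
    frame$role %in% c("SULFONATE_S", "SULFONATE_O")
  rows[is.na(rows)] <- FALSE
  if (!any(rows)) {
    abort(sprintf(
      "ligand %s has no sulfonate end group (OT or unknown ligand)",
      as.character(ligand_id)))
  }
  m <- unname(role_masses()[frame$role[rows]])
  sum(m * frame$z[rows]) / sum(m) - midplane_z(frame)
}

# MUS ligand ids present in a frame
mus_ids <- function(frame) {
  sort(unique(frame$ligand[frame$role == "SULFONATE_S" & !is.na(frame$ligand)]))
}

# d_z of every MUS ligand at once (one midplane evaluation per frame)
all_dz <- function(frame) {
  mid <- midplane_z(frame)
  rows <- frame$role %in% c("SULFONATE_S", "SULFONATE_O") &
    !is.na(frame$ligand)
  m <- unname(role_masses()[frame$role[rows]])
  lig <- frame$ligand[rows]
  com <- tapply(m * frame$z[rows], lig, sum) / tapply(m, lig, sum)
  out <- as.numeric(com) - mid
  names(out) <- names(com)
  out[order(as.integer(names(out)))]
}

#' Per-ligand d_z statistics over a trajectory
#'
#' Computes the time-averaged `d_z` of every MUS ligand with a
#' block-averaging error estimate (plain standard error when fewer than 4
#' frames are available).
#'
#' @param frames An [np_frame()] or list of frames.
#' @return Tibble with `ligand_id`, `dz_mean`, `dz_error`, `n_frames`.
#' @export
dz_records <- function(frames) {
  frames <- as_frame_list(frames)
  ids <- mus_ids(frames[[1]])
  per_frame <- map(frames, function(f) unname(all_dz(f)[as.character(ids)]))
  mat <- do.call(rbind, per_frame)   # frames x ligands
  nf <- nrow(mat)
  err <- apply(mat, 2, function(x) {
    if (nf >= 4) block_error(x)
    else if (nf >= 2) sd(x) / sqrt(nf)
    else 0
  })
  tibble(ligand_id = ids, dz_mean = colMeans(mat), dz_error = err,
         n_frames = nf)
}

#' Classify the charged-ligand distribution
#'
#' Counts MUS ligands by the sign of their mean `d_z` over the supplied
#' frames and formats the result in the `N+/M-` nomenclature (e.g.
#' `"29+/0-"` when all 29 end groups lie above the midplane).  A ligand whose
#' mean `d_z` is exactly zero is ambiguous and raises an error; the caller
#' must resolve the tie.
#'
#' @param frames An [np_frame()] or list of frames.
#' @return A `ligand_distribution`: list with `n_plus`, `n_minus`, `label`.
#' @export
classify <- function(frames) {
  rec <- dz_records(frames)
  if (any(rec$dz_mean == 0)) {
    abort(paste0("ambiguous classification: ligand(s) ",
                 paste(rec$ligand_id[rec$dz_mean == 0], collapse = ", "),
                 " have mean d_z exactly 0"))
  }
  n_plus <- sum(rec$dz_mean > 0)
  n_minus <- sum(rec$dz_mean < 0)
  structure(list(n_plus = n_plus, n_minus = n_minus,
                 label = sprintf("%d+/%d-", n_plus, n_minus)),
            class = "ligand_distribution")
}

#' @export
print.ligand_distribution <- function(x, ...) {
  cat("<ligand_distribution>", x$label, "\n")
  invisible(x)
}

#' @export
format.ligand_distribution <- function(x, ...) x$label

#' Select the next ligand to flip
#'
#' The flip workflow always chooses the MUS ligand with the smallest positive
#' average `d_z` (closest to the flipping transition state).  Ties are broken
#' by the smallest ligand id.  When no ligand has positive `d_z` the state
#' machine is terminal and a condition of class `npflip_terminal` is raised.
#'
#' @param records Tibble from [dz_records()] (columns `ligand_id`,
#'   `dz_mean`).
#' @return The selected ligand id.
#' @export
select_next <- function(records) {
  pos <- records[records$dz_mean > 0, , drop = FALSE]
  if (nrow(pos) == 0) {
    abort("terminal state: no ligand with positive mean d_z remains",
          class = "npflip_terminal")
  }
  pos <- pos[order(pos$dz_mean, pos$ligand_id), , drop = FALSE]
  pos$ligand_id[[1]]
}

#' Harmonic bias schedule for one flip
#'
#' Describes the steered pull applied to a selected end group: a harmonic
#' restraint of 3000 kJ/mol/nm² on the sulfonate group, moved to the mirror
#' image of its current height (`target_dz = -current_dz`) over 1.5 ns,
#' followed by 20 ns of unbiased equilibration.  The spring constant is kept
#' in kJ/mol/nm² as conventionally printed by pull codes; use
#' `kj_to_kcal()` for kcal conversions.
#'
#' @param ligand_id Ligand to bias.
#' @param current_dz Current end-group height, nm (> 0).
#' @param spring_constant Spring constant, kJ/mol/nm² (> 0).
#' @param pull_duration Pull time, ns (> 0).
#' @param equilibration Post-pull equilibration, ns.
#' @return A `bias_schedule` list.
#' @export
make_bias_schedule <- function(ligand_id, current_dz,
                               spring_constant = 3000,
                               pull_duration = 1.5,
                               equilibration = 20) {
  if (current_dz <= 0) abort("current_dz must be > 0 (ligand above midplane)")
  if (spring_constant <= 0) abort("spring_constant must be > 0")
  if (pull_duration <= 0) abort("pull_duration must be > 0")
  structure(list(ligand_id = ligand_id,
                 spring_constant = spring_constant,
                 pull_duration = pull_duration,
                 equilibration = equilibration,
                 target_dz = -current_dz),
            class = "bias_schedule")
}

#' @export
print.bias_schedule <- function(x, ...) {
  cat(sprintf(
    "<bias_schedule> ligand %s: k = %g kJ/mol/nm^2, %g ns pull to d_z = %g nm, %g ns equilibration\n",
    as.character(x$ligand_id), x$spring_constant, x$pull_duration,
    x$target_dz, x$equilibration))
  invisible(x)
}

#' Convert kJ/mol to kcal/mol
#'
#' @param x Energy in kJ/mol.
#' @return Energy in kcal/mol (1 kcal = 4.184 kJ).
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Write / read a restraint descriptor
#'
#' Plain-text `key=value` file (one schedule per file) with keys
#' `ligand_id`, `group`, `axis`, `k_kj_mol_nm2`, `duration_ns`,
#' `equilibration_ns`, `target_dz_nm`, formatted so a user can translate it
#' into an MD engine's pull options.
#'
#' @param schedule A [make_bias_schedule()] object.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `bias_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  lines <- c(
    paste0("ligand_id=", schedule$ligand_id),
    "group=sulfonate",
    "axis=z",
    paste0("k_kj_mol_nm2=", format(schedule$spring_constant, digits = 15)),
    paste0("duration_ns=", format(schedule$pull_duration, digits = 15)),
    paste0("equilibration_ns=", format(schedule$equilibration, digits = 15)),
    paste0("target_dz_nm=", format(schedule$target_dz, digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(map(kv, 2), map(kv, 1))
  sched <- make_bias_schedule(
    ligand_id = as.integer(vals$ligand_id),
    current_dz = -as.numeric(vals$target_dz_nm),
    spring_constant = as.numeric(vals$k_kj_mol_nm2),
    pull_duration = as.numeric(vals$duration_ns),
    equilibration = as.numeric(vals$equilibration_ns))
  sched
}

#' Run the iterative flipping state machine
#'
#' Repeats the flip cycle `n_flips` times starting from a synthetic frame
#' (normally at the 29+/0- distribution): sample equilibrium frames at the
#' current distribution, compute per-ligand mean `d_z`, select the ligand
#' with the smallest positive mean, emit its bias schedule, flip it, and
#' continue.  Fourteen flips transform 29+/0- into 15+/14-.  If no positive
#' ligand remains, the terminal-state condition from [select_next()]
#' propagates.
#'
#' @param initial A generator-produced [np_frame()] (see [gen_frame()]).
#' @param n_flips Number of flips to perform.
#' @param seed Integer seed for the per-step jitter streams.
#' @param n_frames_per_step Equilibrium frames sampled per step for the
#'   `d_z` averages.
#' @return Tibble with one row per flip: `step`, `label_before`,
#'   `selected_ligand`, `dz_selected`, `label_after`, and list columns
#'   `distribution` ([classify()] result after the flip), `schedule`
#'   ([make_bias_schedule()]), `frame` (post-flip frame).
#' @export
run_flip_sequence <- function(initial, n_flips, seed = 1L,
                              n_frames_per_step = 6L) {
  synth <- attr(initial, "synth")
  if (is.null(synth)) abort("initial frame must carry synthetic generator state")
  params <- synth$params
  dz_base <- synth$dz_base
  frame <- initial
  out <- vector("list", n_flips)
  for (step in seq_len(n_flips)) {
    step_params <- params
    step_params$seed <- frame_stream_seed(params$seed + as.integer(seed),
                                          step)
    eq_frames <- map(seq_len(n_frames_per_step),
                     function(i) synth_frame(step_params, dz_base, i))
    records <- dz_records(eq_frames)
    label_before <- classify(eq_frames)$label
    sel <- select_next(records)
    dz_sel <- records$dz_mean[records$ligand_id == sel]
    schedule <- make_bias_schedule(sel, dz_sel)
    frame <- flip_ligand_synthetic(eq_frames[[1]], sel, seed = step)
    dz_base <- attr(frame, "synth")$dz_base
    dist_after <- classify(frame)
    out[[step]] <- tibble(
      step = step, label_before = label_before,
      selected_ligand = sel, dz_selected = dz_sel,
      label_after = dist_after$label,
      distribution = list(dist_after),
      schedule = list(schedule),
      frame = list(frame))
  }
  bind_rows(out)
}
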