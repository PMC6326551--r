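# role <-> GRO/PDB atom-name mapping (bijective)
role_atom_names <- function() {
  c(GOLD = "AU", THIOL_S = "ST", LIGAND_C_MUS = "CM", LIGAND_C_OT = "CO",
    SULFONATE_S = "S", SULFONATE_O = "OS", CHOLINE_N = "N",
    PHOSPHATE_P = "P", LIPID_TAIL = "CT", WATER_O = "OW",
    ION_NA = "NA", ION_CL = "CL")
}

role_res_names <- function(frame) {
  res <- character(nrow(frame))
  res[frame$role == "GOLD"] <- "NP"
  res[frame$role %in% c("THIOL_S", "LIGAND_C_MUS", "LIGAND_C_OT",
                        "SULFONATE_S", "SULFONATE_O")] <- "LIG"
  res[frame$role %in% c("CHOLINE_N", "PHOSPHATE_P", "LIPID_TAIL")] <- "DOPC"
  res[frame$role == "WATER_O"] <- "SOL"
  res[frame$role == "ION_NA"] <- "NA"
  res[frame$role == "ION_CL"] <- "CL"
  res
}

gro_resid <- function(frame) {
  resid <- rep(1L, nrow(frame))
  lig <- !is.na(frame$ligand)
  resid[lig] <- as.integer(frame$ligand[lig]) + 1L
  resid %% 100000L
}

#' Write frames in GRO format
#'
#' Fixed-column GRO (nm); multiple frames are written as consecutive blocks.
#' Ligand ids are stored in the residue-number field of ligand atoms
#' (`resid = ligand + 1`), so they round-trip; per-atom radii and leaflet
#' labels are not part of the format and are re-derived on read.
#'
#' @param frames An [np_frame()] or list of frames.
#' @param path Output path.
#' @param title Title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path, title = "npflip configuration") {
  frames <- as_frame_list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  names_map <- role_atom_names()
  for (f in frames) {
    box <- frame_box(f)
    writeLines(sprintf("%s t= %.3f", title, frame_time(f)), con)
    writeLines(sprintf("%5d", nrow(f)), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     gro_resid(f), role_res_names(f),
                     unname(names_map[f$role]),
                     f$index %% 100000L, f$x, f$y, f$z)
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Read frames from a GRO file
#'
#' Parses one or more fixed-column GRO blocks; velocities, if present, are
#' ignored.  Roles are taken from the labels sidecar when supplied,
#' otherwise inferred from the atom names written by [write_gro()].
#'
#' @param path GRO file path.
#' @param labels Optional role mapping from [read_labels()].
#' @return A single [np_frame()] for one-frame files, otherwise a list of
#'   frames in file order.
#' @export
read_gro <- function(path, labels = NULL) {
  lines <- readLines(path)
  name_to_role <- setNames(names(role_atom_names()),
                           unname(role_atom_names()))
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (ln + 1L > length(lines)) {
      abort(sprintf("truncated GRO file at line %d", ln))
    }
    title <- lines[ln]
    n_atoms <- suppressWarnings(as.integer(trimws(lines[ln + 1L])))
    if (is.na(n_atoms) || n_atoms < 0) {
      abort(sprintf("malformed atom count at line %d", ln + 1L))
    }
    last_atom <- ln + 1L + n_atoms
    if (last_atom + 1L > length(lines)) {
      abort(sprintf(
        "declared atom count %d at line %d exceeds the file body", n_atoms,
        ln + 1L))
    }
    atom_lines <- lines[(ln + 2L):last_atom]
    box_fields <- strsplit(trimws(lines[last_atom + 1L]), "\\s+")[[1]]
    box <- suppressWarnings(as.numeric(box_fields[1:3]))
    if (any(is.na(box))) {
      abort(sprintf("malformed box line at line %d (is the declared atom count wrong?)",
                    last_atom + 1L))
    }
    resid <- as.integer(substr(atom_lines, 1, 5))
    resname <- trimws(substr(atom_lines, 6, 10))
    aname <- trimws(substr(atom_lines, 11, 15))
    index <- as.integer(substr(atom_lines, 16, 20))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (any(is.na(x) | is.na(y) | is.na(z) | is.na(index))) {
      bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(index))[1]
      abort(sprintf("malformed atom record at line %d", ln + 1L + bad))
    }
    role <- unname(name_to_role[aname])
    if (!is.null(labels)) {
      role <- unname(labels[as.character(index)])
    }
    if (any(is.na(role))) {
      abort(sprintf("cannot assign a role to atom(s) %s",
                    paste(head(index[is.na(role)], 5), collapse = ", ")))
    }
    ligand <- ifelse(resname == "LIG", resid - 1L, NA_integer_)
    t_match <- regmatches(title, regexpr("t= *[-0-9.eE+]+", title))
    time <- if (length(t_match) == 1) {
      as.numeric(sub("t= *", "", t_match))
    } else 0
    frames[[length(frames) + 1L]] <- np_frame(
      tibble(index = index, role = role, x = x, y = y, z = z,
             ligand = as.integer(ligand)),
      box = box, time = time)
    ln <- last_atom + 2L
    # tolerate trailing blank lines
    while (ln <= length(lines) && !nzchar(trimws(lines[ln]))) ln <- ln + 1L
  }
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write / read the atom role sidecar
#'
#' Tab-separated file with header `atom_index<TAB>role` assigning every atom
#' its chemical role.  Duplicate indices and roles outside the closed
#' vocabulary are rejected with the offending line reported.
#'
#' @param mapping Named character vector: names are atom indices, values
#'   roles; or an [np_frame()] (its `index`/`role` columns are used).
#' @param path File path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()`
#'   returns a named character vector keyed by atom index.
#' @export
write_labels <- function(mapping, path) {
  if (is_np_frame(mapping)) {
    mapping <- setNames(mapping$role, mapping$index)
  }
  readr::write_tsv(tibble(atom_index = as.integer(names(mapping)),
                          role = unname(mapping)), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    atom_index = readr::col_integer(), role = readr::col_character()))
  bad <- which(!tbl$role %in% atom_roles())
  if (length(bad) > 0) {
    abort(sprintf("unknown role '%s' at line %d of %s",
                  tbl$role[bad[1]], bad[1] + 1L, path))
  }
  dup <- which(duplicated(tbl$atom_index))
  if (length(dup) > 0) {
    abort(sprintf("duplicate atom index %d at line %d of %s",
                  tbl$atom_index[dup[1]], dup[1] + 1L, path))
  }
  setNames(tbl$role, tbl$atom_index)
}

#' Validate a role mapping against a frame
#'
#' Every atom index of the frame must be present in the mapping.
#'
#' @param frame An [np_frame()].
#' @param labels Mapping from [read_labels()].
#' @return Invisibly `TRUE`; errors on missing indices.
#' @export
validate_labels <- function(frame, labels) {
  missing_idx <- setdiff(as.character(frame$index), names(labels))
  if (length(missing_idx) > 0) {
    abort(sprintf("labels file is missing atom index(es): %s",
                  paste(head(missing_idx, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write / read PDB coordinates
#'
#' Interoperability layer: coordinates are converted between the package's
#' nm convention and PDB angstroms at the boundary.  Atom names follow the
#' same bijective role mapping as GRO, so roles round-trip.
#'
#' @param frame An [np_frame()].
#' @param path File path.
#' @param labels Optional role mapping from [read_labels()].
#' @return `write_pdb()` returns `path` invisibly; `read_pdb()` an
#'   [np_frame()].
#' @export
write_pdb <- function(frame, path) {
  names_map <- role_atom_names()
  box <- frame_box(frame)
  lines <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
            box[1] * 10, box[2] * 10, box[3] * 10),
    sprintf("ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            frame$index %% 100000L, unname(names_map[frame$role]),
            role_res_names(frame), gro_resid(frame) %% 10000L,
            frame$x * 10, frame$y * 10, frame$z * 10),
    "END")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pdb
#' @export
read_pdb <- function(path, labels = NULL) {
  lines <- readLines(path)
  name_to_role <- setNames(names(role_atom_names()),
                           unname(role_atom_names()))
  cryst <- lines[startsWith(lines, "CRYST1")]
  box <- if (length(cryst) >= 1) {
    as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                 substr(cryst[1], 25, 33))) / 10
  } else c(10, 10, 10)
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  index <- as.integer(substr(at, 7, 11))
  aname <- trimws(substr(at, 13, 16))
  resname <- trimws(substr(at, 18, 21))
  resid <- as.integer(substr(at, 23, 26))
  x <- as.numeric(substr(at, 31, 38)) / 10
  y <- as.numeric(substr(at, 39, 46)) / 10
  z <- as.numeric(substr(at, 47, 54)) / 10
  role <- if (!is.null(labels)) unname(labels[as.character(index)])
          else unname(name_to_role[aname])
  if (any(is.na(role))) abort("cannot assign a role to every PDB atom")
  ligand <- ifelse(resname == "LIG", resid - 1L, NA_integer_)
  np_frame(tibble(index = index, role = role, x = x, y = y, z = z,
                  ligand = as.integer(ligand)), box = box)
}

#' Default run configuration
#'
#' Nested named list mirrored by the YAML configuration file: `geometry`
#' (particle and bilayer construction), `physics` (solvation parameter,
#' probe, bias schedule, salt), `analysis` (thresholds, bin widths,
#' quadrature), `generator` (synthetic-configuration parameters) and
#' `landscape` (component estimates, see [landscape_defaults()]).  Every
#' parameter has a default; unknown keys in a configuration file are
#' rejected.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    geometry = list(core_diameter = 2.0, n_ligands = 58L,
                    mus_fraction = 0.5, n_lipids = 334L,
                    area_per_lipid = 0.65, head_z = 1.9, box_z = 8.0),
    physics = list(gamma = 4.7, probe_radius = 0.14,
                   spring_constant = 3000, pull_duration = 1.5,
                   equilibration = 20, salt_conc = 0.15,
                   n_water = 21418L, n_cl_override = 60L,
                   radii = as.list(default_radii())),
    analysis = list(contact_threshold = 0.7,
                    coordination_thresholds =
                      as.list(default_coordination_thresholds()),
                    rdf_dr = 0.02, smooth_window = 3L,
                    n_sphere_points = 960L,
                    density_dr = 0.1, density_dz = 0.1),
    generator = list(depth_max = 1.0, noise_sigma = 0.05,
                     hydration_slope = 3.0, hydration_floor = 2.0,
                     n_frames = 6L),
    landscape = landscape_defaults()
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key '%s'", full))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(sprintf("configuration key '%s' must be a section", full))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a YAML run configuration
#'
#' Strictly parsed: every key must exist in [default_config()]; a misspelled
#' key is an error, never silently ignored.  Missing keys keep their
#' defaults.
#'
#' @param path YAML file path (NULL returns the defaults).
#' @return Nested named list as [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

#' Write a synthetic trajectory with a provenance sidecar
#'
#' Writes the frames as a multi-frame GRO plus a JSON sidecar echoing the
#' generator parameters and seed, so a reader can reproduce the file.
#'
#' @param frames List of generator frames.
#' @param path GRO output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  frames <- as_frame_list(frames)
  write_gro(frames, path)
  synth <- attr(frames[[1]], "synth")
  if (!is.null(synth)) {
    p <- synth$params
    meta <- p[setdiff(names(p), "np")]
    meta$np <- list(core_radius = p$np$core_radius,
                    n_ligands = nrow(p$np$ligands),
                    n_mus = sum(p$np$ligands$kind == "MUS"),
                    net_charge = p$np$net_charge)
    meta$dz_base <- as.list(synth$dz_base)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
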