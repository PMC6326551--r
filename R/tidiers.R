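#' Tidy the core-depth fit
#'
#' @param x A `depth_trend` from [core_depth_trend()].
#' @param ... Passed to the underlying `lm` tidier.
#' @return Tibble of fit terms (broom convention).
#' @export
tidy.depth_trend <- function(x, ...) broom::tidy(x$fit, ...)

#' @rdname tidy.depth_trend
#' @export
glance.depth_trend <- function(x, ...) broom::glance(x$fit, ...)

#' Tidy a landscape into its state table
#'
#' @param x An `np_landscape` from [assemble_landscape()].
#' @param ... Unused.
#' @return The states tibble (`index`, `description`, `kind`,
#'   `cumulative_dg`).
#' @export
tidy.np_landscape <- function(x, ...) x$states

#' @rdname tidy.np_landscape
#' @export
glance.np_landscape <- function(x, ...) {
  tibble(total_dg = x$total, total_uncertainty = x$total_uncertainty,
         n_states = nrow(x$states), n_notes = length(x$notes))
}

#' Tidy a surface-area result
#'
#' @param x A `sasa_result` from [shrake_rupley()].
#' @param ... Unused.
#' @return Per-atom area tibble.
#' @export
tidy.sasa_result <- function(x, ...) x$per_atom

#' @rdname tidy.sasa_result
#' @export
glance.sasa_result <- function(x, ...) {
  tibble(total_area = x$total_area, n_atoms = nrow(x$per_atom),
         subset = x$subset_descriptor)
}

#' Tidy a contact summary
#'
#' @param x A `contact_summary` from [count_contacts()].
#' @param ... Unused.
#' @return One row per frame (`frame`, `n_contacts`).
#' @export
tidy.contact_summary <- function(x, ...) {
  tibble(frame = seq_along(x$per_frame), n_contacts = x$per_frame)
}

#' @rdname tidy.contact_summary
#' @export
glance.contact_summary <- function(x, ...) {
  tibble(n_contacts = x$n_contacts, error = x$error,
         threshold = x$threshold, n_frames = length(x$per_frame))
}
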