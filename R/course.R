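#' Default 13-section urban course table
#'
#' The reference course is an approximately 800 m suburban loop divided into
#' 13 sections with known per-section mean and standard deviation of frame
#' speed, seat COPx and seat COPy. Cumulative section boundaries are
#' 0, 47, 171, 270, 325, 364, 407, 481, 521, 571, 669, 699, 747 and 789 m.
#' Boundaries flagged as turns carry the turn direction
#' (`"right"`/`"left"`/`"none"`) of the transition *into* the section.
#'
#' @return A data.frame with one row per section and columns
#'   `index`, `start_distance`, `length`, `v_mean`, `v_sd`, `copx_mean`,
#'   `copx_sd`, `copy_mean`, `copy_sd`, `turn_in`, `label`.
#' @export
default_course_table <- function() {
  data.frame(
    index = 1:13,
    start_distance = c(0, 47, 171, 270, 325, 364, 407, 481, 521, 571, 669, 699, 747),
    length = c(47, 124, 99, 55, 39, 43, 74, 40, 50, 98, 30, 48, 42),
    v_mean = c(0.80, 1.02, 1.26, 1.43, 1.04, 1.05, 1.40, 1.28, 0.95, 1.41, 1.32, 1.29, 1.81),
    v_sd = c(0.23, 0.25, 0.36, 0.37, 0.23, 0.22, 0.40, 0.43, 0.25, 0.32, 0.23, 0.24, 0.64),
    copx_mean = c(-1.56, -4.32, -3.79, -1.52, -4.21, 2.35, 5.58, 4.05, 3.47, -1.80, -4.10, -2.04, 1.93),
    copx_sd = c(6.02, 7.59, 6.61, 7.44, 6.79, 7.64, 9.17, 12.29, 8.26, 7.27, 7.29, 8.02, 9.03),
    copy_mean = c(-17.45, -18.35, -17.64, -17.35, -20.83, -23.83, -20.82, -21.88, -17.43, -19.00, -20.01, -21.33, -19.80),
    copy_sd = c(7.94, 8.03, 7.99, 7.66, 7.27, 7.26, 8.61, 9.51, 15.51, 8.19, 7.93, 7.94, 8.10),
    # direction of the turn entering the section (transition from section k-1 to k)
    turn_in = c("none", "right", "right", "none", "right", "right", "left",
                "none", "none", "right", "right", "none", "right"),
    label = c("car park (start)", "Manningtree Rd", "Guest St (upper)",
              "Guest St (lower)", "Burwood Rd", "Cook St", "Luton Lane (flat)",
              "Luton Lane (rough)", "Luton Lane (steep)", "Glenferrie Rd",
              "Manningtree Rd (east)", "Manningtree Rd (west)",
              "car park (sprint)"),
    stringsAsFactors = FALSE
  )
}

#' Build a validated course definition
#'
#' Assembles the section table into a course object used by the simulator and
#' the section statistics. Sections must be contiguous: each section's start
#' distance must equal the previous start plus the previous length.
#'
#' @param section_table A data.frame like [default_course_table()]. When
#'   `NULL` the default 13-section course is used. Required columns:
#'   `index`, `start_distance`, `length`, `v_mean`, `v_sd`, `copx_mean`,
#'   `copx_sd`, `copy_mean`, `copy_sd`. Optional: `turn_in`, `label`.
#' @return An object of class `course_definition`: the section table plus
#'   `boundaries` (length `n_sections + 1`) and `total_length`.
#' @examples
#' crs <- build_course()
#' crs$total_length  # 789
#' @export
build_course <- function(section_table = NULL) {
  tab <- if (is.null(section_table)) default_course_table() else as.data.frame(section_table)
  required <- c("index", "start_distance", "length", "v_mean", "v_sd",
                "copx_mean", "copx_sd", "copy_mean", "copy_sd")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("course table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) < 1L) stop("course table has no sections")
  tab <- tab[order(tab$start_distance), , drop = FALSE]
  if (!all(tab$length > 0)) stop("all section lengths must be > 0")
  if (!all(tab$v_mean > 0)) stop("all section mean speeds must be > 0")
  if (!all(tab$v_sd >= 0)) stop("section speed SDs must be >= 0")
  if (tab$start_distance[1L] != 0) {
    stop("first section must start at 0, not ", tab$start_distance[1L])
  }
  if (nrow(tab) > 1L) {
    expected <- tab$start_distance[-nrow(tab)] + tab$length[-nrow(tab)]
    got <- tab$start_distance[-1L]
    bad <- which(abs(expected - got) > 1e-9)
    if (length(bad) > 0L) {
      stop(sprintf("non-contiguous sections: gap at %g", expected[bad[1L]]))
    }
  }
  if (is.null(tab$turn_in)) tab$turn_in <- rep("none", nrow(tab))
  if (is.null(tab$label)) tab$label <- paste("section", tab$index)
  boundaries <- c(tab$start_distance, tab$start_distance[nrow(tab)] + tab$length[nrow(tab)])
  structure(
    list(
      sections = tab,
      boundaries = boundaries,
      total_length = boundaries[length(boundaries)],
      n_sections = nrow(tab)
    ),
    class = "course_definition"
  )
}

#' @export
print.course_definition <- function(x, ...) {
  cat(sprintf("Course definition: %d sections, %.0f m total\n",
              x$n_sections, x$total_length))
  print(x$sections[, c("index", "start_distance", "length", "v_mean", "label")],
        row.names = FALSE)
  invisible(x)
}

#' Wheelchair geometry
#'
#' Geometry of the instrumented wheelchair: wheel radius, camber angle and
#' hub-to-hub track width. Camber tilts the wheel plane inwards at the top,
#' which reduces the effective rolling radius to `r * cos(theta)` and widens
#' the ground-contact track to `w + 2 r * sin(theta)`.
#'
#' @param wheel_radius Wheel radius in metres (24-inch wheel: 0.305 m).
#' @param camber_deg Camber angle in degrees (default 3.2).
#' @param track_width_hub Hub-to-hub track width in metres (default 0.56).
#' @return An object of class `wheelchair_geometry` with the inputs plus the
#'   derived `r_eff` (effective rolling radius, m) and `w_ground`
#'   (ground-contact track width, m).
#' @export
wheelchair_geometry <- function(wheel_radius = 0.305, camber_deg = 3.2,
                                track_width_hub = 0.56) {
  if (!(wheel_radius > 0)) stop("wheel_radius must be > 0")
  if (!(camber_deg >= 0 && camber_deg < 45)) stop("camber_deg must be in [0, 45)")
  if (!(track_width_hub > 0)) stop("track_width_hub must be > 0")
  theta <- camber_deg * pi / 180
  structure(
    list(
      wheel_radius = wheel_radius,
      camber_deg = camber_deg,
      track_width_hub = track_width_hub,
      r_eff = wheel_radius * cos(theta),
      w_ground = track_width_hub + 2 * wheel_radius * sin(theta)
    ),
    class = "wheelchair_geometry"
  )
}
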