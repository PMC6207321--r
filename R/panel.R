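#' Default 12-channel neutrophil panel
#'
#' Two scatter channels (FSC, SSC) plus the ten fluorescence markers of the
#' neutrophil deep-phenotyping panel: complement receptor 1 (CD35), Fc-gamma
#' receptor I (CD64), the activation epitope of CD11b (CBRM1/5), CD11b,
#' LAIR-1 (CD305), CD14, Fc-gamma receptor III (CD16), L-selectin (CD62L),
#' VLA-4 alpha chain (CD49d) and CD66b.
#'
#' @return A tibble with columns `channel` and `role`
#'   (`"scatter"` or `"fluorescence"`).
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  tibble::tibble(
    channel = c("FSC", "SSC", fluorescence_markers()),
    role = c("scatter", "scatter", rep("fluorescence", 10L))
  )
}

#' Fluorescence marker names of the default panel
#'
#' @return Character vector of the 10 fluorescence channel names.
#' @export
fluorescence_markers <- function() {
  c("CD35", "CD64", "CBRM1/5", "CD11b", "LAIR-1",
    "CD14", "CD16", "CD62L", "CD49d", "CD66b")
}

#' Validate a panel definition
#'
#' @param panel Tibble with columns `channel`, `role`.
#' @return The panel, invisibly, or an error.
#' @export
validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("channel", "role") %in% names(panel)))
  if (anyDuplicated(panel$channel)) {
    stop("panel channel names must be unique", call. = FALSE)
  }
  if (!all(panel$role %in% c("scatter", "fluorescence"))) {
    stop("panel roles must be 'scatter' or 'fluorescence'", call. = FALSE)
  }
  missing <- setdiff(fluorescence_markers(), panel$channel)
  if (length(missing)) {
    stop("panel is missing expected fluorescence markers: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(panel)
}

#' Published cohort reference values: neutrophil concentrations
#'
#' Per-time-point cohort mean concentrations (10^6 cells/ml) of the total
#' neutrophil population and the three CD16/CD62L subsets at the three
#' morning time points, and evening totals at days 0, 4 and 7. These printed
#' cohort means are the calibration anchors of [cohort_config()] and the
#' inputs of the exact fold-change/difference arithmetic checks.
#'
#' @return Tibble with columns `day`, `session`, `population`, `concentration`.
#' @export
#' @examples
#' reference_counts()
reference_counts <- function() {
  morning <- tidyr::expand_grid(
    day = c(1L, 5L, 8L),
    population = c("total", subset_labels())
  )
  morning$session <- "morning"
  morning$concentration <- c(
    1.78, 1.49, 0.22, 0.02,
    1.89, 1.39, 0.37, 0.05,
    2.24, 1.44, 0.58, 0.07
  )
  evening <- tibble::tibble(
    day = c(0L, 4L, 7L),
    population = "total",
    session = "evening",
    concentration = c(2.40, 3.51, 3.67)
  )
  dplyr::bind_rows(morning, evening)[, c("day", "session", "population",
                                         "concentration")]
}

#' Published cohort reference values: pooled-neutrophil marker MFIs
#'
#' Cohort median fluorescence intensities (arbitrary units) of six phenotype
#' markers over the pooled neutrophil population at the three morning time
#' points. Used to calibrate the simulator's marker time-course multipliers
#' and as inputs of the exact arithmetic checks.
#'
#' @return Tibble with columns `marker`, `day`, `mfi`.
#' @export
reference_mfi <- function() {
  out <- tidyr::expand_grid(
    marker = c("CD35", "CD66b", "CD11b", "CBRM1/5", "CD49d", "LAIR-1"),
    day = c(1L, 5L, 8L)
  )
  out$mfi <- c(
    951, 905, 909,
    2442, 2638, 2441,
    2989, 2842, 2380,
    250, 602, 827,
    6039, 10891, 14346,
    3967, 7209, 7953
  )
  out
}

#' Labels of the three CD16/CD62L neutrophil subsets
#'
#' `CD16brightCD62Lbright` are normal segmented neutrophils,
#' `CD16brightCD62Ldim` the hypersegmented/suppressive-associated phenotype,
#' `CD16dimCD62Lbright` banded immature cells.
#'
#' @return Character vector of length 3.
#' @export
subset_labels <- function() {
  c("CD16brightCD62Lbright", "CD16brightCD62Ldim", "CD16dimCD62Lbright")
}

# Sampling design of the tour: six (day, session) combinations.
design_time_points <- function() {
  tibble::tibble(
    day = c(1L, 5L, 8L, 0L, 4L, 7L),
    session = rep(c("morning", "evening"), each = 3L)
  )
}
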