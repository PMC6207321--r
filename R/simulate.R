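#' Default per-time-point neutrophil subset concentrations
#'
#' Cohort mean concentrations (10^6 cells/ml) for the three CD16/CD62L
#' subsets at all six sampling occasions. Morning values anchor the TOTAL
#' neutrophil concentration to the published per-day cohort means and split
#' it across subsets proportionally to the published subset means (the
#' printed subset means sum to slightly less than the printed total, so the
#' split is renormalised). Evening occasions use the published evening totals
#' with the composition of the nearest morning (day 0 uses day 1, day 4 uses
#' day 5, day 7 uses day 8).
#'
#' @return Tibble with columns `day`, `session`, `population`, `concentration`.
#' @export
default_subset_concentrations <- function() {
  ref <- reference_counts()
  morning <- dplyr::filter(ref, .data$session == "morning")
  out <- purrr::map_dfr(c(1L, 5L, 8L), function(d) {
    rows <- dplyr::filter(morning, .data$day == d)
    total <- rows$concentration[rows$population == "total"]
    subs <- rows[rows$population != "total", ]
    subs$concentration <- subs$concentration * total / sum(subs$concentration)
    subs
  })
  evening_totals <- dplyr::filter(ref, .data$session == "evening")
  nearest <- c(`0` = 1L, `4` = 5L, `7` = 8L)
  evening <- purrr::map_dfr(evening_totals$day, function(d) {
    comp <- out[out$day == nearest[[as.character(d)]], ]
    comp$concentration <- comp$concentration / sum(comp$concentration) *
      evening_totals$concentration[evening_totals$day == d]
    comp$day <- d
    comp$session <- "evening"
    comp
  })
  dplyr::bind_rows(out, evening)
}

#' Default population medians for the 12-channel panel
#'
#' Baseline (morning day 1) median intensities, arbitrary units, for the
#' three neutrophil subsets and a generic "other" leukocyte cluster used to
#' exercise the neutrophil gate. Neutrophil fluorescence medians for the six
#' phenotype markers equal the published pooled-neutrophil day-1 MFIs; the
#' subsets share them (published per-subset differences are small). CD16 and
#' CD62L medians place bright and dim modes 20-fold apart; CD64 and CD14 are
#' set low on neutrophils and high on the "other" cluster, which is also
#' CD66b-negative and lower in side scatter.
#'
#' @return Tibble with columns `population`, `channel`, `median`.
#' @export
default_population_medians <- function() {
  ch <- default_panel()$channel
  neut_base <- c(
    FSC = 150000, SSC = 120000,
    CD35 = 951, CD64 = 300, `CBRM1/5` = 250, CD11b = 2989,
    `LAIR-1` = 3967, CD14 = 150, CD16 = 10000, CD62L = 5000,
    CD49d = 6039, CD66b = 2442
  )
  other <- c(
    FSC = 120000, SSC = 50000,
    CD35 = 200, CD64 = 1500, `CBRM1/5` = 40, CD11b = 800,
    `LAIR-1` = 5000, CD14 = 2500, CD16 = 300, CD62L = 2000,
    CD49d = 3000, CD66b = 60
  )
  bb <- neut_base
  bdim <- neut_base
  bdim[["CD62L"]] <- 250
  dimb <- neut_base
  dimb[["CD16"]] <- 500
  pops <- list(
    CD16brightCD62Lbright = bb,
    CD16brightCD62Ldim = bdim,
    CD16dimCD62Lbright = dimb,
    other = other
  )
  purrr::imap_dfr(pops, function(m, nm) {
    tibble::tibble(population = nm, channel = ch, median = unname(m[ch]))
  })
}

#' Default marker time-course multipliers
#'
#' Multiplicative change of each neutrophil fluorescence median relative to
#' morning day 1, derived from the published pooled-neutrophil MFI table for
#' the six phenotype markers (CD35, CD66b, CD11b, CBRM1/5, CD49d, LAIR-1).
#' Evenings carry the multiplier of the nearest morning (day 0 is baseline,
#' day 4 uses day 5, day 7 uses day 8); channels without published
#' time-course data keep multiplier 1.
#'
#' @return Tibble with columns `channel`, `day`, `session`, `multiplier`.
#' @export
default_marker_multipliers <- function() {
  mfi <- reference_mfi()
  base <- dplyr::filter(mfi, .data$day == 1L)
  morning <- dplyr::mutate(
    mfi,
    session = "morning",
    multiplier = .data$mfi / base$mfi[match(.data$marker, base$marker)]
  )
  nearest <- c(`0` = 1L, `4` = 5L, `7` = 8L)
  evening <- purrr::map_dfr(c(0L, 4L, 7L), function(d) {
    rows <- morning[morning$day == nearest[[as.character(d)]], ]
    rows$day <- d
    rows$session <- "evening"
    rows
  })
  out <- dplyr::bind_rows(morning, evening)
  tibble::tibble(
    channel = out$marker, day = out$day, session = out$session,
    multiplier = out$multiplier
  )
}

#' Configure a synthetic cytometry cohort
#'
#' Defines the generative model of the synthetic cohort: per-time-point
#' subset concentrations (calibrated to the published cohort means), per
#' population and channel median intensities, marker time-course multipliers,
#' and the dispersion/noise structure. Fluorescence intensities are drawn
#' log-normally around the (multiplier- and subject-adjusted) medians, with a
#' shared per-cell granule-content factor across the granule-associated
#' channels and an additive zero-centred Gaussian background term that
#' produces occasional negative intensities, as real instrument background
#' subtraction and compensation do.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param sessions Which sessions to simulate, subset of
#'   `c("morning", "evening")`.
#' @param days Optional integer vector restricting the simulated days.
#' @param events_per_sample Events acquired per blood sample (>= 1000).
#' @param concentrations Tibble as [default_subset_concentrations()]
#'   (10^6 cells/ml cohort means per day/session/subset).
#' @param medians Tibble as [default_population_medians()].
#' @param multipliers Tibble as [default_marker_multipliers()].
#' @param other_concentration Concentration of the generic non-neutrophil
#'   leukocyte cluster (10^6 cells/ml).
#' @param subject_cv Between-subject CV of the multiplicative concentration
#'   random effect (mean-one log-normal, shared across a subject's samples).
#' @param sample_cv Within-subject per-sample CV of each population's
#'   concentration.
#' @param subject_marker_cv Between-subject CV of the per-marker expression
#'   random effect (median-one log-normal, shared across time points).
#' @param marker_cv Per-cell CV of fluorescence intensities within a subset.
#' @param scatter_cv Per-cell CV of the scatter channels.
#' @param granule_cv CV of the per-cell granule-content factor applied
#'   multiplicatively to the granule-associated channels, producing the
#'   correlated co-expression of degranulation markers seen in resting
#'   neutrophils (a variance direction distinct from the activation
#'   response).
#' @param granule_channels Channels sharing the granule-content factor.
#' @param noise_sd SD (a.u.) of the additive background noise on
#'   fluorescence channels.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 4, events_per_sample = 1000)
#' cohort <- simulate_cohort(cfg, seed = 1)
cohort_config <- function(n_subjects = 28L,
                          sessions = c("morning", "evening"),
                          days = NULL,
                          events_per_sample = 20000L,
                          concentrations = default_subset_concentrations(),
                          medians = default_population_medians(),
                          multipliers = default_marker_multipliers(),
                          other_concentration = 2.5,
                          subject_cv = 0.30,
                          sample_cv = 0.25,
                          subject_marker_cv = 0.30,
                          marker_cv = 0.50,
                          scatter_cv = 0.12,
                          granule_cv = 0.35,
                          granule_channels = c("CD35", "CD64", "CD11b",
                                               "CD66b"),
                          noise_sd = 15) {
  sessions <- match.arg(sessions, several.ok = TRUE)
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      sessions = sessions,
      days = days,
      events_per_sample = as.integer(events_per_sample),
      concentrations = concentrations,
      medians = medians,
      multipliers = multipliers,
      other_concentration = other_concentration,
      subject_cv = subject_cv,
      sample_cv = sample_cv,
      subject_marker_cv = subject_marker_cv,
      marker_cv = marker_cv,
      scatter_cv = scatter_cv,
      granule_cv = granule_cv,
      granule_channels = granule_channels,
      noise_sd = noise_sd
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' @param config A `cohort_config`.
#' @return The config, invisibly returned after validation; errors name the
#'   offending field.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 1L) {
    stop("invalid cohort config: n_subjects must be >= 1", call. = FALSE)
  }
  if (config$events_per_sample < 1000L) {
    stop("invalid cohort config: events_per_sample must be >= 1000",
         call. = FALSE)
  }
  conc <- config$concentrations
  if (any(conc$concentration < 0)) {
    stop("invalid cohort config: concentrations must be non-negative",
         call. = FALSE)
  }
  totals <- dplyr::summarise(
    dplyr::group_by(conc, .data$day, .data$session),
    total = sum(.data$concentration), .groups = "drop"
  )
  if (any(totals$total + config$other_concentration <= 0)) {
    stop("invalid cohort config: concentrations must sum to > 0 ",
         "per time point (including other_concentration)", call. = FALSE)
  }
  if (any(config$medians$median <= 0)) {
    stop("invalid cohort config: medians must be strictly positive",
         call. = FALSE)
  }
  if (config$other_concentration < 0) {
    stop("invalid cohort config: other_concentration must be non-negative",
         call. = FALSE)
  }
  for (f in c("subject_cv", "sample_cv", "subject_marker_cv", "marker_cv",
              "scatter_cv", "granule_cv", "noise_sd")) {
    if (config[[f]] < 0) {
      stop("invalid cohort config: ", f, " must be non-negative",
           call. = FALSE)
    }
  }
  invisible(config)
}

# log-normal sdlog for a given coefficient of variation
sdlog_from_cv <- function(cv) sqrt(log1p(cv^2))

# mean-one multiplicative log-normal factors
rlnorm_mean1 <- function(n, cv) {
  s <- sdlog_from_cv(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# median-one multiplicative log-normal factors
rlnorm_median1 <- function(n, cv) {
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog_from_cv(cv))
}

# Draw one sample's event table given realised per-population concentrations
# (named vector, 10^6 cells/ml) and a populations x channels median matrix
# already adjusted for time point and subject. Labels are latent truth.
simulate_events <- function(n_events, concentrations, median_matrix,
                            panel = default_panel(),
                            marker_cv = 0.5, scatter_cv = 0.12,
                            granule_cv = 0.35,
                            granule_channels = c("CD35", "CD64", "CD11b",
                                                 "CD66b"),
                            noise_sd = 15) {
  pops <- rownames(median_matrix)
  stopifnot(setequal(names(concentrations), pops))
  probs <- concentrations[pops] / sum(concentrations)
  labels <- sample(pops, n_events, replace = TRUE, prob = probs)
  idx <- match(labels, pops)
  is_fluor <- panel$role == "fluorescence"
  granule <- rlnorm_median1(n_events, granule_cv)
  values <- lapply(seq_len(nrow(panel)), function(j) {
    med <- median_matrix[idx, panel$channel[j]]
    cv <- if (is_fluor[j]) marker_cv else scatter_cv
    x <- stats::rlnorm(n_events, meanlog = log(med),
                       sdlog = sdlog_from_cv(cv))
    if (is_fluor[j]) {
      if (panel$channel[j] %in% granule_channels) x <- x * granule
      x <- x + stats::rnorm(n_events, 0, noise_sd)
    }
    x
  })
  names(values) <- panel$channel
  events <- tibble::as_tibble(values)
  events$.label <- factor(labels, levels = pops)
  events
}

# populations x channels baseline median matrix from the tidy medians table
median_matrix_from_config <- function(medians, panel) {
  wide <- tidyr::pivot_wider(medians, names_from = "channel",
                             values_from = "median")
  m <- as.matrix(wide[, panel$channel, drop = FALSE])
  rownames(m) <- wide$population
  m
}

#' Simulate a synthetic cytometry cohort
#'
#' Generates one blood sample (event table plus automated-counter
#' concentration) per subject and sampling occasion. Subject-level random
#' effects (one multiplicative factor for concentration, one per fluorescence
#' marker for expression) are shared across a subject's time points; each
#' population's realised concentration additionally carries per-sample noise.
#' The counter concentration is the realised total leukocyte concentration
#' (neutrophil subsets plus the generic other cluster), and event labels are
#' drawn multinomially with probabilities proportional to the realised
#' concentrations, so gated concentrations are unbiased for the configured
#' cohort means. Identical `(config, seed)` pairs give bit-identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer random seed.
#' @return Tibble with one row per subject and occasion: columns `subject`,
#'   `day`, `session`, `group` (`control` for morning day 1, otherwise
#'   `response`), `counter_concentration` (10^6 cells/ml) and `events`
#'   (list-column of event tibbles carrying a latent `.label` column).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  set.seed(seed)
  panel <- default_panel()
  meds <- median_matrix_from_config(config$medians, panel)
  neut_pops <- intersect(rownames(meds), subset_labels())
  markers <- panel$channel[panel$role == "fluorescence"]

  tps <- dplyr::distinct(config$concentrations, .data$day, .data$session)
  tps <- tps[tps$session %in% config$sessions, , drop = FALSE]
  if (!is.null(config$days)) tps <- tps[tps$day %in% config$days, , drop = FALSE]
  if (nrow(tps) == 0L) {
    stop("invalid cohort config: no time points left after session/day filter",
         call. = FALSE)
  }

  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  conc_effect <- rlnorm_mean1(config$n_subjects, config$subject_cv)
  marker_effect <- matrix(
    rlnorm_median1(config$n_subjects * length(markers),
                   config$subject_marker_cv),
    nrow = config$n_subjects, dimnames = list(subjects, markers)
  )

  mult <- config$multipliers
  rows <- list()
  for (i in seq_along(subjects)) {
    med_subj <- meds
    med_subj[neut_pops, markers] <-
      sweep(med_subj[neut_pops, markers, drop = FALSE], 2,
            marker_effect[i, markers], `*`)
    for (k in seq_len(nrow(tps))) {
      d <- tps$day[k]
      s <- tps$session[k]
      base <- config$concentrations
      base <- base[base$day == d & base$session == s, , drop = FALSE]
      conc <- stats::setNames(
        base$concentration[match(neut_pops, base$population)], neut_pops
      )
      conc[is.na(conc)] <- 0
      conc <- conc * conc_effect[i] *
        rlnorm_mean1(length(neut_pops), config$sample_cv)
      conc <- c(conc, other = config$other_concentration *
                  rlnorm_mean1(1L, config$sample_cv))
      med_tp <- med_subj
      m <- mult[mult$day == d & mult$session == s, , drop = FALSE]
      if (nrow(m)) {
        j <- match(m$channel, colnames(med_tp))
        ok <- !is.na(j)
        med_tp[neut_pops, j[ok]] <-
          sweep(med_tp[neut_pops, j[ok], drop = FALSE], 2,
                m$multiplier[ok], `*`)
      }
      events <- simulate_events(
        config$events_per_sample, conc, med_tp, panel,
        marker_cv = config$marker_cv, scatter_cv = config$scatter_cv,
        granule_cv = config$granule_cv,
        granule_channels = config$granule_channels,
        noise_sd = config$noise_sd
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = subjects[i], day = d, session = s,
        group = if (d == 1L && s == "morning") "control" else "response",
        counter_concentration = sum(conc),
        events = list(events)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Configure a synthetic post-endotoxin (LPS challenge) sample
#'
#' Encodes the acute-inflammation phenotype seen ~3 h after intravenous LPS:
#' relative to the resting configuration, all neutrophils upregulate CD35 and
#' CD11b and downregulate CD16 and LAIR-1, and two additional subsets are
#' prominent - a CD16-dim (banded) and a CD62L-dim (hypersegmented) subset,
#' the latter with further elevated CD11b. The resulting CD16/CD62L
#' distribution is the characteristic bean shape. Override directions are
#' fixed; only their magnitudes and the mixing fractions are configurable.
#'
#' @param events_per_sample Events in the sample (>= 1000).
#' @param total_concentration Total neutrophil concentration
#'   (10^6 cells/ml) of the challenged sample.
#' @param fractions Named mixing fractions of the three neutrophil subsets
#'   (must sum to 1).
#' @param cd35_up,cd11b_up Multipliers > 1 applied to all neutrophils.
#' @param cd16_down,lair1_down Multipliers < 1 applied to all neutrophils.
#' @param cd11b_dim_extra Extra CD11b multiplier (> 1) on the CD62L-dim
#'   subset.
#' @param ... Passed to [cohort_config()] (dispersion/noise settings).
#' @return An object of class `lps_config`.
#' @export
lps_config <- function(events_per_sample = 20000L,
                       total_concentration = 6.0,
                       fractions = c(CD16brightCD62Lbright = 0.40,
                                     CD16brightCD62Ldim = 0.35,
                                     CD16dimCD62Lbright = 0.25),
                       cd35_up = 2.5, cd11b_up = 2.0,
                       cd16_down = 0.5, lair1_down = 0.5,
                       cd11b_dim_extra = 1.8, ...) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("invalid lps config: fractions must sum to 1", call. = FALSE)
  }
  if (!setequal(names(fractions), subset_labels())) {
    stop("invalid lps config: fractions must name the three subsets",
         call. = FALSE)
  }
  if (total_concentration <= 0) {
    stop("invalid lps config: total_concentration must be > 0", call. = FALSE)
  }
  if (cd35_up <= 1 || cd11b_up <= 1 || cd11b_dim_extra <= 1) {
    stop("invalid lps config: up-regulation multipliers must exceed 1",
         call. = FALSE)
  }
  if (cd16_down >= 1 || lair1_down >= 1 || cd16_down <= 0 || lair1_down <= 0) {
    stop("invalid lps config: down-regulation multipliers must be in (0, 1)",
         call. = FALSE)
  }
  base <- cohort_config(n_subjects = 1L, events_per_sample = events_per_sample,
                        ...)
  structure(
    list(base = base, total_concentration = total_concentration,
         fractions = fractions, cd35_up = cd35_up, cd11b_up = cd11b_up,
         cd16_down = cd16_down, lair1_down = lair1_down,
         cd11b_dim_extra = cd11b_dim_extra),
    class = "lps_config"
  )
}

#' Simulate a post-endotoxin blood sample
#'
#' @param config An [lps_config()].
#' @param seed Integer random seed.
#' @return A one-row sample tibble in the format of [simulate_cohort()],
#'   with `group = "response"`, `day = 0`, `session = "morning"` and subject
#'   id `"LPS01"`.
#' @export
simulate_lps_sample <- function(config = lps_config(), seed = 1L) {
  stopifnot(inherits(config, "lps_config"))
  set.seed(seed)
  base <- config$base
  panel <- default_panel()
  meds <- median_matrix_from_config(base$medians, panel)
  neut <- intersect(rownames(meds), subset_labels())
  meds[neut, "CD35"] <- meds[neut, "CD35"] * config$cd35_up
  meds[neut, "CD11b"] <- meds[neut, "CD11b"] * config$cd11b_up
  meds[neut, "CD16"] <- meds[neut, "CD16"] * config$cd16_down
  meds[neut, "LAIR-1"] <- meds[neut, "LAIR-1"] * config$lair1_down
  meds["CD16brightCD62Ldim", "CD11b"] <-
    meds["CD16brightCD62Ldim", "CD11b"] * config$cd11b_dim_extra
  conc <- c(config$fractions[neut] * config$total_concentration,
            other = base$other_concentration)
  events <- simulate_events(
    base$events_per_sample, conc, meds, panel,
    marker_cv = base$marker_cv, scatter_cv = base$scatter_cv,
    granule_cv = base$granule_cv,
    granule_channels = base$granule_channels,
    noise_sd = base$noise_sd
  )
  tibble::tibble(
    subject = "LPS01", day = 0L, session = "morning", group = "response",
    counter_concentration = sum(conc), events = list(events)
  )
}
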