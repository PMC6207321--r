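#' Define the neutrophil gating strategy
#'
#' A gate set holds the FSC/SSC gate (axis-aligned rectangle or convex
#' polygon), the CD66b positivity threshold, the CD16 positivity threshold
#' used together with CD66b to identify neutrophils, and the CD16 and CD62L
#' thresholds that separate dim from bright and define the three CD16/CD62L
#' quadrant subsets. All thresholds are closed on the bright/positive side:
#' an event exactly at a threshold is positive/bright.
#'
#' @param scatter Either a list `list(fsc = c(lo, hi), ssc = c(lo, hi))`
#'   (rectangle) or a two-column matrix of polygon vertices
#'   (columns FSC, SSC).
#' @param cd66b_min CD66b positivity threshold (a.u., > 0).
#' @param cd16_positive CD16 positivity threshold for the neutrophil gate
#'   (a.u., > 0; below the dim/bright split).
#' @param cd16_bright CD16 threshold separating dim from bright (a.u., > 0).
#' @param cd62l_bright CD62L threshold separating dim from bright
#'   (a.u., > 0).
#' @param cd14_max Optional CD14 exclusion ceiling: events at or above it are
#'   excluded from the neutrophil gate (monocyte exclusion; `NULL` = off,
#'   the default, since CD66b gating alone removes CD66b-negative monocytes).
#' @return Object of class `subset_gates`.
#' @export
#' @examples
#' subset_gates()
subset_gates <- function(scatter = list(fsc = c(5e4, 4e5), ssc = c(3e4, 4e5)),
                         cd66b_min = 400,
                         cd16_positive = 100,
                         cd16_bright = 2200,
                         cd62l_bright = 1100,
                         cd14_max = NULL) {
  thr <- c(cd66b_min = cd66b_min, cd16_positive = cd16_positive,
           cd16_bright = cd16_bright, cd62l_bright = cd62l_bright)
  if (any(thr <= 0)) {
    stop("gate thresholds must be strictly positive", call. = FALSE)
  }
  if (is.matrix(scatter)) {
    if (ncol(scatter) != 2L || nrow(scatter) < 3L) {
      stop("polygon scatter gate needs a matrix with >= 3 rows and 2 columns",
           call. = FALSE)
    }
  } else {
    stopifnot(is.list(scatter), all(c("fsc", "ssc") %in% names(scatter)))
    if (diff(scatter$fsc) <= 0 || diff(scatter$ssc) <= 0) {
      stop("scatter gate is degenerate (non-positive extent)", call. = FALSE)
    }
  }
  structure(
    list(scatter = scatter, cd66b_min = cd66b_min,
         cd16_positive = cd16_positive, cd16_bright = cd16_bright,
         cd62l_bright = cd62l_bright, cd14_max = cd14_max),
    class = "subset_gates"
  )
}

# point-in-convex-polygon by ray casting; boundary points count as inside
points_in_polygon <- function(x, y, vertices) {
  n <- nrow(vertices)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- (pmin(xi, xj) - 1e-9 <= x) & (x <= pmax(xi, xj) + 1e-9) &
      (pmin(yi, yj) - 1e-9 <= y) & (y <= pmax(yi, yj) + 1e-9)
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

require_channels <- function(events, channels) {
  missing <- setdiff(channels, names(events))
  if (length(missing)) {
    stop("required channel(s) missing from panel: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Gate neutrophils (FSC/SSC, CD66b-positive, CD16-positive)
#'
#' Events are neutrophils when they fall inside the scatter gate AND are at
#' or above the CD66b threshold AND at or above the CD16 positivity
#' threshold (with an optional CD14 ceiling). Deterministic; boundaries are
#' closed on the positive side.
#'
#' @param events Event tibble.
#' @param gates A [subset_gates()].
#' @return Logical vector, one element per event. If no event passes, an
#'   empty-gate warning is raised.
#' @export
gate_neutrophils <- function(events, gates = subset_gates()) {
  stopifnot(inherits(gates, "subset_gates"))
  require_channels(events, c("FSC", "SSC", "CD66b", "CD16"))
  if (is.matrix(gates$scatter)) {
    in_scatter <- points_in_polygon(events$FSC, events$SSC, gates$scatter)
  } else {
    in_scatter <- events$FSC >= gates$scatter$fsc[1] &
      events$FSC <= gates$scatter$fsc[2] &
      events$SSC >= gates$scatter$ssc[1] &
      events$SSC <= gates$scatter$ssc[2]
  }
  mask <- in_scatter & events$CD66b >= gates$cd66b_min &
    events$CD16 >= gates$cd16_positive
  if (!is.null(gates$cd14_max)) {
    require_channels(events, "CD14")
    mask <- mask & events$CD14 < gates$cd14_max
  }
  if (!any(mask)) {
    warning("neutrophil gate is empty: no event passed", call. = FALSE)
  }
  mask
}

#' Classify gated neutrophils into CD16/CD62L quadrant subsets
#'
#' Each gated event is assigned exactly one label by quadrant: CD16 at or
#' above the bright threshold versus below, crossed with CD62L at or above
#' the bright threshold versus below. The CD16-dim CD62L-dim quadrant is not
#' a reported neutrophil subset; such events are labelled non-neutrophil and
#' their count is recorded.
#'
#' @param events Event tibble.
#' @param mask Logical neutrophil mask from [gate_neutrophils()].
#' @param gates A [subset_gates()].
#' @return Object of class `gating_result`: per-event `labels` (factor with
#'   levels non-neutrophil plus the three subsets), `n_events`,
#'   `neutrophil_fraction` (three-subset events over all events),
#'   `subset_fractions` (named, summing to 1 over the three subsets) and
#'   `n_dim_dim` (excluded double-dim quadrant count).
#' @export
classify_subsets <- function(events, mask, gates = subset_gates()) {
  stopifnot(inherits(gates, "subset_gates"), length(mask) == nrow(events))
  require_channels(events, c("CD16", "CD62L"))
  labels <- rep("non-neutrophil", nrow(events))
  b16 <- events$CD16 >= gates$cd16_bright
  b62 <- events$CD62L >= gates$cd62l_bright
  labels[mask & b16 & b62] <- "CD16brightCD62Lbright"
  labels[mask & b16 & !b62] <- "CD16brightCD62Ldim"
  labels[mask & !b16 & b62] <- "CD16dimCD62Lbright"
  n_dim_dim <- sum(mask & !b16 & !b62)
  labels <- factor(labels, levels = c("non-neutrophil", subset_labels()))
  counts <- table(labels)[subset_labels()]
  n_neut <- sum(counts)
  subset_fractions <- if (n_neut > 0) as.numeric(counts) / n_neut else
    rep(NA_real_, 3L)
  names(subset_fractions) <- subset_labels()
  structure(
    list(labels = labels, n_events = nrow(events),
         neutrophil_fraction = n_neut / nrow(events),
         subset_fractions = subset_fractions,
         n_dim_dim = n_dim_dim),
    class = "gating_result"
  )
}

#' @export
print.gating_result <- function(x, ...) {
  cat("Gating result:", x$n_events, "events,",
      sprintf("%.1f%%", 100 * x$neutrophil_fraction), "neutrophils",
      sprintf("(%d dim/dim excluded)\n", x$n_dim_dim))
  print(round(x$subset_fractions, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy gating_result
#' @export
tidy.gating_result <- function(x, ...) {
  counts <- table(x$labels)
  tibble::tibble(
    label = names(counts),
    events = as.integer(counts),
    fraction = as.numeric(counts) / x$n_events
  )
}

#' Convert gated fractions to blood concentrations
#'
#' Subset concentration = counter concentration x neutrophil fraction x
#' subset fraction; the total row is the sum of the three subsets.
#'
#' @param result A `gating_result`.
#' @param counter_concentration Automated-counter total leukocyte
#'   concentration (10^6 cells/ml, > 0).
#' @return Tibble with columns `population` (three subsets plus `total`) and
#'   `concentration` (10^6 cells/ml).
#' @export
subset_concentration <- function(result, counter_concentration) {
  stopifnot(inherits(result, "gating_result"))
  if (!is.numeric(counter_concentration) || counter_concentration <= 0) {
    stop("counter_concentration must be > 0", call. = FALSE)
  }
  conc <- counter_concentration * result$neutrophil_fraction *
    result$subset_fractions
  tibble::tibble(
    population = c(subset_labels(), "total"),
    concentration = unname(c(conc, sum(conc)))
  )
}

#' Derive default gate thresholds from control samples
#'
#' Data-driven stand-in for manual gating: each threshold is placed at the
#' minimum-density valley of the marker's log10 intensity histogram between
#' its two main modes, falling back to a low quantile of the single mode when
#' the distribution is unimodal. CD66b and CD16 valleys are searched over all
#' scatter-gated events; the CD16 and CD62L dim/bright splits over
#' CD66b-positive events only.
#'
#' @param events Pooled control event tibble (typically all morning day 1
#'   samples).
#' @param scatter Scatter gate passed through to the result.
#' @param fallback_quantile Quantile used when no valley is found.
#' @return A [subset_gates()].
#' @export
derive_gates <- function(events,
                         scatter = list(fsc = c(5e4, 4e5),
                                        ssc = c(3e4, 4e5)),
                         fallback_quantile = 0.05) {
  require_channels(events, c("FSC", "SSC", "CD66b", "CD16", "CD62L"))
  valley <- function(x) {
    x <- x[is.finite(x)]
    lx <- log10(pmax(x, 1))
    d <- stats::density(lx, n = 512)
    y <- d$y
    maxima <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(maxima) >= 2L) {
      top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
      between <- seq(top2[1], top2[2])
      10^d$x[between[which.min(y[between])]]
    } else {
      as.numeric(stats::quantile(x, fallback_quantile))
    }
  }
  cd66b_min <- valley(events$CD66b)
  pos <- events$CD66b >= cd66b_min
  subset_gates(
    scatter = scatter,
    cd66b_min = cd66b_min,
    cd16_positive = max(
      as.numeric(stats::quantile(events$CD16[pos], fallback_quantile)) / 2, 1),
    cd16_bright = valley(events$CD16[pos]),
    cd62l_bright = valley(events$CD62L[pos])
  )
}

#' Gate every sample of a cohort and build the cohort table
#'
#' Runs [gate_neutrophils()] and [classify_subsets()] on each sample,
#' converts fractions to concentrations with the sample's counter
#' concentration, and computes pooled-neutrophil MFIs for the requested
#' markers. One row per sample.
#'
#' @param cohort Cohort tibble with an `events` list-column (see
#'   [simulate_cohort()] / [read_cohort()]).
#' @param gates A [subset_gates()].
#' @param markers Markers for pooled-neutrophil MFIs (default: the six
#'   phenotype markers with published time courses).
#' @param per_subset_mfi Also compute per-subset MFIs (returned in long
#'   columns `mfi_<marker>.<subset>`)? Default `FALSE`.
#' @return Tibble with one row per sample: metadata columns, total and
#'   per-subset concentrations (10^6 cells/ml), `n_dim_dim`, and one
#'   `mfi_<marker>` column per requested marker.
#' @export
gate_cohort <- function(cohort, gates = subset_gates(),
                        markers = c("CD35", "CD66b", "CD11b", "CBRM1/5",
                                    "CD49d", "LAIR-1"),
                        per_subset_mfi = FALSE) {
  purrr::pmap_dfr(
    list(seq_len(nrow(cohort))),
    function(i) {
      ev <- cohort$events[[i]]
      mask <- suppressWarnings(gate_neutrophils(ev, gates))
      res <- classify_subsets(ev, mask, gates)
      conc <- subset_concentration(res, cohort$counter_concentration[[i]])
      row <- dplyr::select(cohort[i, ], -"events")
      wide <- stats::setNames(conc$concentration, conc$population)
      row$total <- wide[["total"]]
      for (s in subset_labels()) row[[s]] <- wide[[s]]
      row$n_dim_dim <- res$n_dim_dim
      neut <- res$labels != "non-neutrophil"
      for (m in markers) {
        row[[paste0("mfi_", m)]] <- if (any(neut))
          median_fluorescence(ev, neut, m) else NA_real_
      }
      if (per_subset_mfi) {
        for (s in subset_labels()) {
          in_s <- res$labels == s
          for (m in markers) {
            row[[paste0("mfi_", m, ".", s)]] <- if (any(in_s))
              median_fluorescence(ev, in_s, m) else NA_real_
          }
        }
      }
      row
    }
  )
}
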