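#' Shift intensities so the global minimum is exactly 1
#'
#' Subtracts `min(values) - 1` from every entry, the standard guard that
#' makes background-subtracted/compensated (possibly negative) intensities
#' strictly positive before log transformation. Pairwise differences are
#' preserved.
#'
#' @param values Numeric matrix or data frame of intensities (finite).
#' @return List with `values` (shifted, same shape; global minimum exactly 1)
#'   and `shift` (the subtracted constant, `min - 1`).
#' @export
#' @examples
#' shift_to_positive(matrix(c(-3, 0, 2, 5), 2))
shift_to_positive <- function(values) {
  is_df <- is.data.frame(values)
  m <- as.matrix(values)
  if (!is.numeric(m) || !all(is.finite(m))) {
    stop("shift_to_positive requires finite numeric values", call. = FALSE)
  }
  shift <- min(m) - 1
  m <- m - shift
  list(values = if (is_df) tibble::as_tibble(m) else m, shift = shift)
}

#' Fit control-based preprocessing parameters
#'
#' Computes, per marker, the mean and sample SD (n - 1 denominator) of the
#' log10 intensities of the pooled CONTROL cells. Applying the resulting
#' standardisation to any cell pool expresses each marker in units of control
#' variation: the control pool itself maps to mean 0, SD 1.
#'
#' @param control_events Shifted control event table or matrix (all entries
#'   >= some positive floor; shift first with [shift_to_positive()]).
#' @param markers Marker columns to use (default: all columns).
#' @return Object of class `preprocess_params`: `markers`, `mean`, `sd`.
#' @export
fit_preprocess <- function(control_events, markers = NULL) {
  m <- as.matrix(control_events)
  if (is.null(markers)) markers <- colnames(m)
  m <- m[, markers, drop = FALSE]
  if (nrow(m) < 2L) stop("need at least 2 control events", call. = FALSE)
  if (any(m <= 0)) {
    stop("control intensities must be positive; apply shift_to_positive first",
         call. = FALSE)
  }
  lg <- log10(m)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  degenerate <- sd <= .Machine$double.eps
  if (any(degenerate)) {
    stop("degenerate marker(s) with zero control variance: ",
         paste(markers[degenerate], collapse = ", "), call. = FALSE)
  }
  structure(list(markers = markers, mean = mu, sd = sd),
            class = "preprocess_params")
}

#' Standardise a cell pool with control-fitted parameters
#'
#' `z = (log10(shifted intensity) - control mean) / control SD` per marker.
#'
#' @param events Shifted event table or matrix (positive entries).
#' @param params A `preprocess_params`.
#' @return Numeric matrix, cells x markers.
#' @export
preprocess <- function(events, params) {
  stopifnot(inherits(params, "preprocess_params"))
  m <- as.matrix(events)[, params$markers, drop = FALSE]
  if (any(m <= 0)) {
    stop("intensities must be positive; apply shift_to_positive first",
         call. = FALSE)
  }
  sweep(sweep(log10(m), 2, params$mean), 2, params$sd, `/`)
}

# sign-fix: flip each column so its largest-magnitude element is positive
fix_signs <- function(loadings) {
  apply(loadings, 2, function(v) {
    if (v[which.max(abs(v))] < 0) -v else v
  })
}

#' Fit the control-anchored response model
#'
#' The single-cell response model separates control variation from
#' response-specific variation. The control subspace is spanned by the top
#' `k_c` principal directions of the standardised control pool. Response
#' cells are deflated by projecting out that subspace; the response loadings
#' are then the top `k_r` principal directions of the (centred) deflated
#' response pool, so they describe the variation specific to the response
#' group and are exactly orthogonal to the control loadings. Explained
#' fractions are the eigenvalue shares of the deflated response covariance.
#' An 80% benchmark region is fitted on the projected control cells. Loadings
#' are sign-fixed (largest-magnitude element positive), so fits on identical
#' data are bit-identical.
#'
#' @param control_z,response_z Standardised cell pools from [preprocess()].
#' @param k_c Number of control components; `NULL` (default) picks the
#'   smallest number explaining at least `control_var` of control variance,
#'   capped at `ncol - k_r`.
#' @param k_r Number of response components (default 2, the plotted pair).
#' @param control_var Target control variance fraction for the automatic
#'   `k_c` rule.
#' @param coverage Nominal coverage of the control benchmark region.
#' @return Object of class `flood_model`: `control_loadings` (markers x
#'   k_c), `response_loadings` (markers x k_r), `explained` (response
#'   eigenvalue shares, length k_r), `eigenvalues` (all deflated-response
#'   eigenvalues), `benchmark` (control [benchmark_region()]; `NULL` when
#'   the control pool has fewer than 50 cells), `k_c`, `k_r`, `markers`.
#' @export
fit_flood <- function(control_z, response_z, k_c = NULL, k_r = 2L,
                      control_var = 0.90, coverage = 0.80) {
  control_z <- as.matrix(control_z)
  response_z <- as.matrix(response_z)
  if (nrow(control_z) < 2L || nrow(response_z) < 2L) {
    stop("control and response pools must both contain >= 2 cells",
         call. = FALSE)
  }
  stopifnot(identical(colnames(control_z), colnames(response_z)))
  p <- ncol(control_z)
  ec <- eigen(stats::cov(control_z), symmetric = TRUE)
  if (is.null(k_c)) {
    shares <- cumsum(ec$values) / sum(ec$values)
    k_c <- min(which(shares >= control_var), p - k_r)
  }
  k_c <- as.integer(k_c)
  k_r <- as.integer(k_r)
  if (k_c + k_r > p) {
    stop("k_c + k_r must not exceed the number of markers (", p, ")",
         call. = FALSE)
  }
  rank_c <- sum(ec$values > max(ec$values) * 1e-12)
  if (k_c > rank_c) {
    stop("rank deficiency: control pool supports only ", rank_c,
         " components", call. = FALSE)
  }
  pc <- fix_signs(ec$vectors[, seq_len(k_c), drop = FALSE])
  rownames(pc) <- colnames(control_z)

  deflate <- function(z) z - z %*% pc %*% t(pc)
  rz <- deflate(response_z)
  er <- eigen(stats::cov(rz), symmetric = TRUE)
  rank_r <- sum(er$values > max(er$values) * 1e-12)
  if (k_r > rank_r) {
    stop("rank deficiency: deflated response pool supports only ", rank_r,
         " components", call. = FALSE)
  }
  pr <- fix_signs(er$vectors[, seq_len(k_r), drop = FALSE])
  rownames(pr) <- colnames(control_z)
  colnames(pr) <- paste0("RC", seq_len(k_r))
  eigenvalues <- pmax(er$values, 0)
  explained <- eigenvalues[seq_len(k_r)] / sum(eigenvalues)

  model <- structure(
    list(
      markers = colnames(control_z),
      k_c = k_c, k_r = k_r,
      control_loadings = pc,
      control_explained = ec$values[seq_len(k_c)] / sum(ec$values),
      response_loadings = pr,
      explained = explained,
      eigenvalues = eigenvalues,
      coverage = coverage,
      benchmark = NULL
    ),
    class = "flood_model"
  )
  ctrl_scores <- project(control_z, model, standardized = TRUE)
  if (nrow(ctrl_scores) >= 50L) {
    model$benchmark <- benchmark_region(ctrl_scores, coverage = coverage)
  }
  model
}

#' Project standardised cells into response-model score space
#'
#' Cells are deflated by the control subspace, then multiplied by the
#' response loadings: `scores = (z - z P_c P_c') P_r`.
#'
#' @param events_z Standardised cell matrix from [preprocess()] (or an
#'   unshifted event table if `standardized = TRUE` is not set and a
#'   `params` is given).
#' @param model A `flood_model`.
#' @param standardized Set `FALSE` and supply `params` to preprocess first.
#' @param params Optional `preprocess_params` used when
#'   `standardized = FALSE`.
#' @return Numeric matrix, cells x k_r, columns `RC1..`.
#' @export
project <- function(events_z, model, standardized = TRUE, params = NULL) {
  stopifnot(inherits(model, "flood_model"))
  if (!standardized) {
    if (is.null(params)) stop("params needed when standardized = FALSE",
                              call. = FALSE)
    events_z <- preprocess(events_z, params)
  }
  z <- as.matrix(events_z)[, model$markers, drop = FALSE]
  pc <- model$control_loadings
  (z - z %*% pc %*% t(pc)) %*% model$response_loadings
}

#' Fit an elliptical benchmark region at a given coverage
#'
#' The region is the Mahalanobis ellipse of the scores: centre = score mean,
#' shape = score covariance, squared radius = the empirical `coverage`
#' quantile (inverse-ECDF) of the defining cells' squared Mahalanobis
#' distances. By construction the fraction of defining cells inside is
#' within 1/n of the nominal coverage.
#'
#' @param scores Numeric matrix of scores (>= 50 rows).
#' @param coverage Nominal coverage in the open interval (0, 1);
#'   default 0.80.
#' @return Object of class `benchmark_region`: `center`, `shape`
#'   (covariance), `threshold` (squared radius), `coverage`, `n`.
#' @export
benchmark_region <- function(scores, coverage = 0.80) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 50L) {
    stop("need >= 50 scores to fit a benchmark region", call. = FALSE)
  }
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1) {
    stop("coverage must lie in the open interval (0, 1)", call. = FALSE)
  }
  center <- colMeans(scores)
  shape <- stats::cov(scores)
  if (!all(is.finite(shape)) ||
      min(eigen(shape, symmetric = TRUE, only.values = TRUE)$values) <=
        max(abs(shape)) * 1e-12) {
    stop("degenerate benchmark: singular score covariance", call. = FALSE)
  }
  d2 <- stats::mahalanobis(scores, center, shape)
  threshold <- as.numeric(stats::quantile(d2, coverage, type = 1))
  structure(
    list(center = center, shape = shape, threshold = threshold,
         coverage = coverage, n = nrow(scores)),
    class = "benchmark_region"
  )
}

#' Fraction of cells inside a benchmark region
#'
#' @param scores Numeric score matrix (>= 1 row).
#' @param region A [benchmark_region()].
#' @return Fraction in `[0, 1]` of scores whose squared Mahalanobis distance
#'   from the region centre is at or below the region threshold.
#' @export
overlap_fraction <- function(scores, region) {
  stopifnot(inherits(region, "benchmark_region"))
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L) stop("empty score set", call. = FALSE)
  d2 <- stats::mahalanobis(scores, region$center, region$shape)
  mean(d2 <= region$threshold)
}

#' @export
print.flood_model <- function(x, ...) {
  cat(sprintf(
    "Control-anchored response model: %d markers, k_c = %d, k_r = %d\n",
    length(x$markers), x$k_c, x$k_r
  ))
  cat("Response-specific variance explained:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy flood_model
#' @export
tidy.flood_model <- function(x, ...) {
  out <- tibble::as_tibble(x$response_loadings)
  out <- dplyr::mutate(out, marker = x$markers, .before = 1)
  out$length <- sqrt(rowSums(x$response_loadings^2))
  out
}

#' @method glance flood_model
#' @export
glance.flood_model <- function(x, ...) {
  tibble::tibble(
    n_markers = length(x$markers), k_c = x$k_c, k_r = x$k_r,
    explained_rc1 = x$explained[1],
    explained_rc2 = if (x$k_r >= 2) x$explained[2] else NA_real_,
    explained_total = sum(x$explained),
    benchmark_coverage = x$benchmark$coverage
  )
}

# points on a benchmark ellipse outline, for plotting
benchmark_outline <- function(region, n = 181L) {
  stopifnot(inherits(region, "benchmark_region"))
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- rbind(cos(theta), sin(theta))
  L <- chol(region$shape[1:2, 1:2])
  pts <- t(L) %*% circle * sqrt(region$threshold)
  tibble::tibble(RC1 = region$center[1] + pts[1, ],
                 RC2 = region$center[2] + pts[2, ])
}

#' Biplot of a response model
#'
#' Score density of a cell pool in the first two response components, with
#' marker loading vectors (length = loading magnitude, scaled for display),
#' the pooled-control benchmark ellipse and optionally a per-sample ellipse.
#'
#' @param object A `flood_model`.
#' @param scores Score matrix to display (e.g. one sample's projected cells).
#' @param sample_region Optional per-sample [benchmark_region()] drawn in
#'   red.
#' @param arrow_scale Multiplier applied to loading vectors for display.
#' @param bins Bins for the 2D density.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot flood_model
#' @export
autoplot.flood_model <- function(object, scores, sample_region = NULL,
                                 arrow_scale = NULL, bins = 60, ...) {
  df <- tibble::as_tibble(as.matrix(scores)[, 1:2, drop = FALSE],
                          .name_repair = ~ c("RC1", "RC2"))
  load <- tidy.flood_model(object)
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(c(df$RC1, df$RC2))) /
      max(load$length, .Machine$double.eps)
  }
  load$x <- load$RC1 * arrow_scale
  load$y <- if ("RC2" %in% names(load)) load$RC2 * arrow_scale else 0
  ctrl <- benchmark_outline(object$benchmark)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$RC1, y = .data$RC2)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_gradient(low = "grey90", high = "navy",
                                 name = "cells") +
    ggplot2::geom_path(data = ctrl, colour = "cyan3", linewidth = 0.8) +
    ggplot2::geom_segment(
      data = load, inherit.aes = FALSE,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "black"
    ) +
    ggplot2::geom_text(
      data = load, inherit.aes = FALSE,
      ggplot2::aes(x = 1.07 * .data$x, y = 1.07 * .data$y,
                   label = .data$marker),
      size = 3
    ) +
    ggplot2::labs(
      x = sprintf("RC1 (%.0f%% of response-specific variance)",
                  100 * object$explained[1]),
      y = if (object$k_r >= 2)
        sprintf("RC2 (%.0f%% of response-specific variance)",
                100 * object$explained[2]) else "RC2"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(sample_region)) {
    p <- p + ggplot2::geom_path(data = benchmark_outline(sample_region),
                                colour = "red", linewidth = 0.8)
  }
  p
}

#' Export biplots and underlying tables for a set of samples
#'
#' Writes, per sample, a biplot (PDF) with the pooled-control ellipse and the
#' sample's own ellipse at the model coverage, plus delimited tables of the
#' response loadings (with vector lengths), explained variance fractions and
#' per-sample inside-the-control-benchmark fractions.
#'
#' @param model A `flood_model`.
#' @param sample_scores Named list of score matrices, one per sample.
#' @param dir Output directory (created if needed).
#' @return Tibble with one row per sample (`sample`, `n_cells`,
#'   `inside_control`), invisibly; files are written to `dir`.
#' @export
export_biplot <- function(model, sample_scores, dir) {
  stopifnot(inherits(model, "flood_model"), is.list(sample_scores))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  load <- tidy.flood_model(model)
  utils::write.table(load, file.path(dir, "loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    tibble::tibble(component = paste0("RC", seq_len(model$k_r)),
                   explained = model$explained),
    file.path(dir, "explained.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  overlaps <- purrr::imap_dfr(sample_scores, function(sc, nm) {
    sc <- as.matrix(sc)
    region <- if (nrow(sc) >= 50L)
      benchmark_region(sc, model$benchmark$coverage) else NULL
    p <- autoplot.flood_model(model, sc, sample_region = region)
    ggplot2::ggsave(file.path(dir, paste0("biplot_", nm, ".pdf")), p,
                    width = 6, height = 5)
    tibble::tibble(sample = nm, n_cells = nrow(sc),
                   inside_control = overlap_fraction(sc, model$benchmark))
  })
  utils::write.table(overlaps, file.path(dir, "overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(overlaps)
}

#' Run a full control-anchored analysis on a gated cohort
#'
#' Pools the neutrophil-gated events of all samples, shifts them to positive
#' once (single map for the whole analysis), fits preprocessing on the
#' pooled control cells (all morning day 1 samples), standardises everything,
#' fits the response model on the response pool, and projects every sample.
#' The response group is either the tour samples alone or the tour samples
#' plus post-endotoxin samples.
#'
#' @param cohort Cohort tibble (with `events` list-column and `group`
#'   metadata; optionally rbind an LPS sample from [simulate_lps_sample()]).
#' @param gates A [subset_gates()] used to select neutrophils per sample.
#' @param markers Markers entering the model (default: the 10 fluorescence
#'   channels).
#' @param k_c,k_r,control_var,coverage Passed to [fit_flood()].
#' @param max_cells_per_sample Optional per-sample cap (cells are taken
#'   head-first; sampling is left to the caller) to bound memory.
#' @return List of class `flood_analysis`: `model`, `params`, `shift`,
#'   `sample_scores` (named list), `overlap` (per-sample fraction inside the
#'   control benchmark), `sample_meta`.
#' @export
flood_analysis <- function(cohort, gates = subset_gates(),
                           markers = fluorescence_markers(),
                           k_c = NULL, k_r = 2L, control_var = 0.90,
                           coverage = 0.80, max_cells_per_sample = NULL) {
  gated <- purrr::map(cohort$events, function(ev) {
    mask <- suppressWarnings(gate_neutrophils(ev, gates))
    out <- ev[mask, markers, drop = FALSE]
    if (!is.null(max_cells_per_sample) &&
        nrow(out) > max_cells_per_sample) {
      out <- out[seq_len(max_cells_per_sample), , drop = FALSE]
    }
    out
  })
  n_per <- vapply(gated, nrow, integer(1))
  if (any(n_per == 0L)) {
    stop("neutrophil gate is empty for ", sum(n_per == 0L), " sample(s)",
         call. = FALSE)
  }
  pooled <- as.matrix(dplyr::bind_rows(gated))
  shifted <- shift_to_positive(pooled)
  sample_of_cell <- rep(seq_len(nrow(cohort)), n_per)
  is_control_cell <- cohort$group[sample_of_cell] == "control"
  if (!any(is_control_cell)) stop("no control (morning day 1) cells",
                                  call. = FALSE)
  if (!any(!is_control_cell)) stop("no response cells", call. = FALSE)
  params <- fit_preprocess(shifted$values[is_control_cell, , drop = FALSE])
  z <- preprocess(shifted$values, params)
  model <- fit_flood(z[is_control_cell, , drop = FALSE],
                     z[!is_control_cell, , drop = FALSE],
                     k_c = k_c, k_r = k_r, control_var = control_var,
                     coverage = coverage)
  scores <- project(z, model)
  ids <- sprintf("%s_d%d_%s", cohort$subject, cohort$day, cohort$session)
  sample_scores <- lapply(seq_len(nrow(cohort)), function(i) {
    scores[sample_of_cell == i, , drop = FALSE]
  })
  names(sample_scores) <- ids
  overlap <- vapply(sample_scores, overlap_fraction, numeric(1),
                    region = model$benchmark)
  structure(
    list(model = model, params = params, shift = shifted$shift,
         sample_scores = sample_scores, overlap = overlap,
         sample_meta = dplyr::select(cohort, -"events")),
    class = "flood_analysis"
  )
}

#' @export
print.flood_analysis <- function(x, ...) {
  print(x$model)
  cat("Samples:", length(x$sample_scores),
      "| mean fraction inside control benchmark:",
      sprintf("%.3f", mean(x$overlap)), "\n")
  invisible(x)
}
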