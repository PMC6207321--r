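#' Median fluorescence intensity over a gated population
#'
#' @param events Event tibble.
#' @param mask Logical vector selecting the gated events.
#' @param marker Channel name.
#' @return The median intensity (a.u.); even-length selections use the
#'   mean-of-middle convention of [stats::median()].
#' @export
#' @examples
#' ev <- tibble::tibble(CD35 = c(1, 5, 9))
#' median_fluorescence(ev, rep(TRUE, 3), "CD35")
median_fluorescence <- function(events, mask, marker) {
  require_channels(events, marker)
  stopifnot(length(mask) == nrow(events))
  if (!any(mask)) {
    stop("empty gate: no event selected for MFI of ", marker, call. = FALSE)
  }
  stats::median(events[[marker]][mask])
}

#' Fold change between two positive means
#'
#' @param mean_follow,mean_base Follow-up and baseline means (both > 0);
#'   vectorised.
#' @return `mean_follow / mean_base`.
#' @export
#' @examples
#' fold_change(2.24, 1.78)
fold_change <- function(mean_follow, mean_base) {
  if (any(!is.finite(mean_follow)) || any(!is.finite(mean_base)) ||
      any(mean_follow <= 0) || any(mean_base <= 0)) {
    stop("fold_change requires strictly positive finite means", call. = FALSE)
  }
  mean_follow / mean_base
}

# Balanced within-subject one-way decomposition from a complete n x k matrix.
rm_ss_decompose <- function(y) {
  n <- nrow(y)
  k <- ncol(y)
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  ss_subject <- k * sum((row_means - grand)^2)
  ss_time <- n * sum((col_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_error <- ss_total - ss_subject - ss_time
  list(
    n = n, k = k, col_means = col_means,
    ss_subject = ss_subject, ss_time = ss_time, ss_error = ss_error,
    df_time = k - 1L, df_error = (n - 1L) * (k - 1L)
  )
}

# Tukey-adjusted all-pairs contrasts on the RM error mean square, plus
# fold-change CIs obtained by mapping the mean-difference CI through
# (baseline + bound) / baseline.
rm_contrasts <- function(col_means, ms_error, n, k, df_error,
                         conf_level = 0.95, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  se <- sqrt(2 * ms_error / n)
  pairs <- utils::combn(seq_len(k), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    b <- pairs[1, j]
    f <- pairs[2, j]
    diff <- col_means[f] - col_means[b]
    if (adjust == "tukey") {
      crit <- stats::qtukey(conf_level, k, df_error) / sqrt(2)
      p <- stats::ptukey(abs(diff) / (se / sqrt(2)), k, df_error,
                         lower.tail = FALSE)
    } else {
      crit <- stats::qt(1 - (1 - conf_level) / 2, df_error)
      p <- 2 * stats::pt(abs(diff) / se, df_error, lower.tail = FALSE)
    }
    lo <- diff - crit * se
    hi <- diff + crit * se
    base_mean <- col_means[b]
    fold <- if (base_mean > 0 && col_means[f] > 0)
      col_means[f] / base_mean else NA_real_
    tibble::tibble(
      baseline = names(col_means)[b],
      follow_up = names(col_means)[f],
      mean_base = unname(base_mean),
      mean_follow = unname(col_means[f]),
      difference = unname(diff),
      conf_low = unname(lo),
      conf_high = unname(hi),
      fold = unname(fold),
      fold_low = if (base_mean > 0) unname((base_mean + lo) / base_mean)
                 else NA_real_,
      fold_high = if (base_mean > 0) unname((base_mean + hi) / base_mean)
                  else NA_real_,
      p_adj = unname(p)
    )
  })
}

#' One-way repeated-measures ANOVA with Tukey contrasts and fold changes
#'
#' Fits the balanced within-subject decomposition (subject blocking factor,
#' one within factor) on complete cases: subjects missing any analysed time
#' point are excluded and reported. The omnibus F compares the time mean
#' square with the subject-by-time error mean square. All pairwise time
#' contrasts use that error term with Tukey's studentised-range adjustment
#' (or unadjusted t intervals); fold changes are ratios of time-point means,
#' with CIs obtained by shifting the mean-difference CI by the baseline mean
#' and dividing by it.
#'
#' @param data Long data frame.
#' @param value,subject,time Bare column names of the response, the subject
#'   id and the time point.
#' @param conf_level Confidence level for contrast intervals.
#' @param adjust `"tukey"` (default) or `"none"`.
#' @return Object of class `rm_anova` with [generics::glance()] (omnibus
#'   test) and [generics::tidy()] (contrast table) methods.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject = 1:6, time = c("d1", "d5", "d8"))
#' d$y <- rnorm(nrow(d), mean = match(d$time, c("d1", "d5", "d8")))
#' fit <- rm_anova_oneway(d, y, subject, time)
#' glance(fit)
#' tidy(fit)
rm_anova_oneway <- function(data, value, subject, time,
                            conf_level = 0.95,
                            adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  value <- rlang::enquo(value)
  subject <- rlang::enquo(subject)
  time <- rlang::enquo(time)
  d <- dplyr::transmute(
    data,
    subject = as.character(!!subject),
    time = !!time,
    value = !!value
  )
  time_levels <- if (is.factor(d$time)) levels(d$time) else
    as.character(sort(unique(d$time)))
  d$time <- factor(as.character(d$time), levels = as.character(time_levels))
  if (anyDuplicated(d[c("subject", "time")])) {
    stop("at most one row per subject and time point is allowed",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(d, names_from = "time", values_from = "value",
                             names_sort = FALSE)
  wide <- wide[, c("subject", levels(d$time)), drop = FALSE]
  complete <- stats::complete.cases(wide)
  excluded <- wide$subject[!complete]
  y <- as.matrix(wide[complete, -1, drop = FALSE])
  if (nrow(y) < 3L) {
    stop("insufficient data: fewer than 3 subjects with complete time series",
         call. = FALSE)
  }
  dec <- rm_ss_decompose(y)
  ms_time <- dec$ss_time / dec$df_time
  ms_error <- dec$ss_error / dec$df_error
  if (ms_error <= .Machine$double.eps * max(1, abs(mean(y)))^2) {
    stop("degenerate variance: repeated-measures error mean square is zero",
         call. = FALSE)
  }
  contrasts <- rm_contrasts(dec$col_means, ms_error, dec$n, dec$k,
                            dec$df_error, conf_level, adjust)
  structure(
    list(
      statistic = ms_time / ms_error,
      df = c(dec$df_time, dec$df_error),
      p_value = stats::pf(ms_time / ms_error, dec$df_time, dec$df_error,
                          lower.tail = FALSE),
      ss = c(subject = dec$ss_subject, time = dec$ss_time,
             error = dec$ss_error),
      means = dec$col_means,
      ms_error = ms_error,
      n_subjects = dec$n,
      n_times = dec$k,
      excluded_subjects = excluded,
      conf_level = conf_level,
      adjust = adjust,
      contrasts = contrasts
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "One-way RM-ANOVA: F(%d, %d) = %.4g, p = %.4g (n = %d subjects)\n",
    x$df[1], x$df[2], x$statistic, x$p_value, x$n_subjects
  ))
  if (length(x$excluded_subjects)) {
    cat("Excluded (incomplete):",
        paste(x$excluded_subjects, collapse = ", "), "\n")
  }
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

#' @importFrom generics glance
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df[1], df_error = x$df[2],
    p_value = x$p_value, n_subjects = x$n_subjects, n_times = x$n_times,
    n_excluded = length(x$excluded_subjects)
  )
}

#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$contrasts

#' Two-way repeated-measures ANOVA (both factors within-subject)
#'
#' Balanced complete-case decomposition for subject x factor A (e.g. subset)
#' x factor B (e.g. time) data. Main effects and the interaction are tested
#' against their matching subject-interaction mean squares (A against
#' subject:A, B against subject:B, A:B against subject:A:B). Simple-effect
#' time contrasts within each level of A reuse the one-way machinery, so a
#' single-level factor A reduces exactly to [rm_anova_oneway()].
#'
#' @param data Long data frame.
#' @param value,subject,factor_a,factor_b Bare column names.
#' @param conf_level,adjust As in [rm_anova_oneway()].
#' @return Object of class `rm_anova2`: `$effects` tibble (term, df, F, p),
#'   `$contrasts` (per-level-of-A time contrasts), with tidy/glance methods.
#' @export
rm_anova_twoway <- function(data, value, subject, factor_a, factor_b,
                            conf_level = 0.95,
                            adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  value <- rlang::enquo(value)
  subject <- rlang::enquo(subject)
  factor_a <- rlang::enquo(factor_a)
  factor_b <- rlang::enquo(factor_b)
  d <- dplyr::transmute(
    data,
    subject = as.character(!!subject),
    a = as.character(!!factor_a),
    b = as.character(!!factor_b),
    value = !!value
  )
  if (anyDuplicated(d[c("subject", "a", "b")])) {
    stop("at most one row per subject and factor combination is allowed",
         call. = FALSE)
  }
  # complete cases: subjects observed in every a x b cell
  cells <- tidyr::expand_grid(a = sort(unique(d$a)), b = sort(unique(d$b)))
  counts <- dplyr::count(d, .data$subject)
  keep <- counts$subject[counts$n == nrow(cells)]
  excluded <- setdiff(unique(d$subject), keep)
  d <- d[d$subject %in% keep, , drop = FALSE]
  n <- length(keep)
  if (n < 3L) {
    stop("insufficient data: fewer than 3 subjects with complete cells",
         call. = FALSE)
  }
  ka <- length(unique(d$a))
  kb <- length(unique(d$b))
  arr <- tapply(d$value, list(d$subject, d$a, d$b), mean)
  grand <- mean(arr)
  m_s <- apply(arr, 1, mean)
  m_a <- apply(arr, 2, mean)
  m_b <- apply(arr, 3, mean)
  m_sa <- apply(arr, c(1, 2), mean)
  m_sb <- apply(arr, c(1, 3), mean)
  m_ab <- apply(arr, c(2, 3), mean)
  ss_s <- ka * kb * sum((m_s - grand)^2)
  ss_a <- n * kb * sum((m_a - grand)^2)
  ss_b <- n * ka * sum((m_b - grand)^2)
  ss_sa <- kb * sum((m_sa - outer(m_s, rep(1, ka)) -
                       outer(rep(1, n), m_a) + grand)^2)
  ss_sb <- ka * sum((m_sb - outer(m_s, rep(1, kb)) -
                       outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, kb)) -
                      outer(rep(1, ka), m_b) + grand)^2)
  ss_total <- sum((arr - grand)^2)
  ss_sab <- ss_total - ss_s - ss_a - ss_b - ss_sa - ss_sb - ss_ab
  dfs <- list(a = ka - 1L, b = kb - 1L, ab = (ka - 1L) * (kb - 1L),
              sa = (n - 1L) * (ka - 1L), sb = (n - 1L) * (kb - 1L),
              sab = (n - 1L) * (ka - 1L) * (kb - 1L))
  eff <- tibble::tibble(
    term = c("factor_a", "factor_b", "interaction"),
    df = c(dfs$a, dfs$b, dfs$ab),
    df_error = c(dfs$sa, dfs$sb, dfs$sab),
    sumsq = c(ss_a, ss_b, ss_ab),
    sumsq_error = c(ss_sa, ss_sb, ss_sab)
  )
  eff$statistic <- (eff$sumsq / eff$df) / (eff$sumsq_error / eff$df_error)
  eff$p_value <- stats::pf(eff$statistic, eff$df, eff$df_error,
                           lower.tail = FALSE)
  if (ka == 1L) eff <- eff[eff$term == "factor_b", , drop = FALSE]
  contrasts <- purrr::map_dfr(sort(unique(d$a)), function(lev) {
    sub <- d[d$a == lev, , drop = FALSE]
    fit <- rm_anova_oneway(sub, .data$value, .data$subject, .data$b,
                           conf_level = conf_level, adjust = adjust)
    out <- fit$contrasts
    out$level <- lev
    out[, c("level", setdiff(names(out), "level"))]
  })
  structure(
    list(effects = eff, contrasts = contrasts, n_subjects = n,
         excluded_subjects = excluded,
         levels_a = sort(unique(d$a)), levels_b = sort(unique(d$b))),
    class = "rm_anova2"
  )
}

#' @export
print.rm_anova2 <- function(x, ...) {
  cat(sprintf("Two-way RM-ANOVA (n = %d subjects)\n", x$n_subjects))
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' @method glance rm_anova2
#' @export
glance.rm_anova2 <- function(x, ...) {
  out <- tidyr::pivot_wider(
    x$effects[, c("term", "statistic", "p_value")],
    names_from = "term", values_from = c("statistic", "p_value")
  )
  out$n_subjects <- x$n_subjects
  out
}

#' @method tidy rm_anova2
#' @export
tidy.rm_anova2 <- function(x, ...) x$contrasts

#' Squared Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3), finite, each with
#'   positive variance.
#' @return Tibble with `r_squared`, `estimate` (r), `statistic` (t),
#'   `p_value`, `n`.
#' @export
#' @examples
#' pearson_r2(1:5, c(2, 4, 5, 4, 5))
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(
    r_squared = unname(ct$estimate^2),
    estimate = unname(ct$estimate),
    statistic = unname(ct$statistic),
    p_value = ct$p.value,
    n = length(x)
  )
}

#' Cohort-level contrast report for concentrations and MFIs
#'
#' Runs [rm_anova_oneway()] over each measured column of a cohort table
#' (typically the output of [gate_cohort()] restricted to one session) and
#' binds the contrast tables.
#'
#' @param cohort_table Tibble with `subject`, `day` and measure columns.
#' @param measures Character vector of measure column names; defaults to all
#'   numeric columns except `day` and `counter_concentration`.
#' @param ... Passed to [rm_anova_oneway()].
#' @return Tibble of contrasts with `measure`, omnibus `f_statistic` and
#'   `f_p_value` columns prepended.
#' @export
cohort_contrasts <- function(cohort_table, measures = NULL, ...) {
  if (is.null(measures)) {
    num <- vapply(cohort_table, is.numeric, logical(1))
    measures <- setdiff(names(cohort_table)[num],
                        c("day", "counter_concentration", "n_dim_dim"))
  }
  purrr::map_dfr(measures, function(m) {
    fit <- tryCatch(
      rm_anova_oneway(cohort_table, !!rlang::sym(m), .data$subject,
                      .data$day, ...),
      error = function(e) {
        warning("skipping measure '", m, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(fit)) return(NULL)
    out <- fit$contrasts
    out$measure <- m
    out$f_statistic <- fit$statistic
    out$f_p_value <- fit$p_value
    out[, c("measure", "f_statistic", "f_p_value",
            setdiff(names(out), c("measure", "f_statistic", "f_p_value")))]
  })
}
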