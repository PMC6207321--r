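#' Write an event table to disk
#'
#' Events are written either as tab-delimited text (header row of channel
#' names, one row per event) or as an FCS 3.0 file (list mode, 32-bit float,
#' little-endian, with `$TOT`, `$PAR` and `$PnN` keywords). Raw stored
#' intensities are written as-is: no transform or compensation is applied at
#' I/O time.
#'
#' @param events Data frame of events (channel columns; a latent `.label`
#'   column, if present, is dropped unless `keep_labels = TRUE` and the
#'   format is delimited).
#' @param path Output file path.
#' @param format `"delimited"` or `"fcs"`.
#' @param keep_labels Keep the `.label` column in delimited output.
#' @return `path`, invisibly.
#' @export
#' @examples
#' ev <- tibble::tibble(FSC = c(1, 2), SSC = c(3, 4))
#' f <- tempfile(fileext = ".fcs")
#' write_events(ev, f, format = "fcs")
#' read_events(f, format = "fcs")
write_events <- function(events, path, format = c("delimited", "fcs"),
                         keep_labels = FALSE) {
  format <- match.arg(format)
  events <- tibble::as_tibble(events)
  if (".label" %in% names(events) && !(keep_labels && format == "delimited")) {
    events <- events[setdiff(names(events), ".label")]
  }
  if (nrow(events) < 1L) stop("cannot write an empty event table",
                              call. = FALSE)
  if (format == "delimited") {
    utils::write.table(events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_fcs(as.matrix(events), path)
  }
  invisible(path)
}

#' Read an event table from disk
#'
#' @param path Input file path.
#' @param format `"delimited"` or `"fcs"`; `"auto"` sniffs FCS files by their
#'   magic bytes.
#' @param panel Optional panel definition; if the file's channel set differs
#'   from the panel a warning is raised and the file's channels are kept.
#' @return Tibble of events, channel columns in file order.
#' @export
read_events <- function(path, format = c("auto", "delimited", "fcs"),
                        panel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3L)
    format <- if (identical(rawToChar(magic), "FCS")) "fcs" else "delimited"
  }
  events <- if (format == "fcs") {
    read_fcs(path)
  } else {
    tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                        check.names = FALSE))
  }
  if (anyNA(events)) stop("event table contains missing values", call. = FALSE)
  if (!is.null(panel)) {
    have <- setdiff(names(events), ".label")
    if (!setequal(have, panel$channel)) {
      warning("channel set of ", path,
              " differs from the expected panel; passing through file channels",
              call. = FALSE)
    }
  }
  events
}

# -- FCS 3.0 codec -----------------------------------------------------------
# List-mode, single data set. Writes $DATATYPE F (32-bit float) little-endian;
# reads datatypes F and D with either byte order. TEXT values containing the
# delimiter are not supported (we never write them).

fcs_pad_offset <- function(x) formatC(x, width = 8, flag = " ")

write_fcs <- function(values, path) {
  stopifnot(is.matrix(values), is.numeric(values), nrow(values) >= 1L)
  n <- nrow(values)
  p <- ncol(values)
  channels <- colnames(values)
  if (is.null(channels)) channels <- paste0("P", seq_len(p))
  # "|" as TEXT delimiter: "/" appears in panel names such as CBRM1/5
  delim <- "|"
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$TOT" = as.character(n), "$PAR" = as.character(p)
  )
  for (j in seq_len(p)) {
    kw[[sprintf("$P%dN", j)]] <- channels[j]
    kw[[sprintf("$P%dB", j)]] <- "32"
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- as.character(ceiling(max(values[, j], 1)))
  }
  if (any(grepl(delim, c(channels), fixed = TRUE))) {
    stop("channel names may not contain the TEXT delimiter '", delim, "'",
         call. = FALSE)
  }
  build_text <- function(begin_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = sprintf("%010d", begin_data),
             "$ENDDATA" = sprintf("%010d", end_data))
    paste0(delim, paste0(names(kw2), delim, unname(kw2), delim,
                         collapse = ""))
  }
  header_len <- 58L  # "FCS3.0" + 4 spaces + 6 x 8-char offsets
  text <- build_text(0L, 0L)
  text_start <- header_len
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_len <- n * p * 4L
  data_end <- data_start + data_len - 1L
  text <- build_text(data_start, data_end)  # same width, offsets now real
  header <- paste0(
    "FCS3.0    ",
    fcs_pad_offset(text_start), fcs_pad_offset(text_end),
    fcs_pad_offset(data_start), fcs_pad_offset(data_end),
    fcs_pad_offset(0), fcs_pad_offset(0)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}

read_fcs <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 6L || !startsWith(rawToChar(raw[1:6]), "FCS")) {
    stop("corrupt FCS file (bad magic at offset 0): ", path, call. = FALSE)
  }
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' in ", path, call. = FALSE)
  }
  if (length(raw) < 58L) {
    stop("corrupt FCS file (header truncated at byte ", length(raw), "): ",
         path, call. = FALSE)
  }
  off <- function(i) {
    s <- rawToChar(raw[(11 + 8 * (i - 1)):(10 + 8 * i)])
    as.integer(trimws(s))
  }
  text_start <- off(1)
  text_end <- off(2)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start) {
    stop("corrupt FCS file (bad TEXT offsets at header byte 10): ", path,
         call. = FALSE)
  }
  text <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))
  need <- c("$TOT", "$PAR", "$DATATYPE", "$BYTEORD")
  if (!all(need %in% names(kw))) {
    stop("corrupt FCS file (TEXT segment lacks ",
         paste(setdiff(need, names(kw)), collapse = ", "), "): ", path,
         call. = FALSE)
  }
  n <- as.integer(kw[["$TOT"]])
  p <- as.integer(kw[["$PAR"]])
  data_start <- off(3)
  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(kw[["$BEGINDATA"]])
  }
  type <- toupper(kw[["$DATATYPE"]])
  size <- switch(type, F = 4L, D = 8L,
                 stop("unsupported FCS $DATATYPE '", type, "' in ", path,
                      call. = FALSE))
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  need_bytes <- data_start + n * p * size
  if (length(raw) < need_bytes) {
    stop("corrupt FCS file (DATA segment truncated at byte ", length(raw),
         ", expected ", need_bytes, "): ", path, call. = FALSE)
  }
  con <- rawConnection(raw[(data_start + 1):need_bytes])
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n * p, size = size, endian = endian)
  m <- matrix(vals, nrow = n, ncol = p, byrow = TRUE)
  nm <- vapply(seq_len(p), function(j) {
    s <- unname(kw[sprintf("$P%dS", j)])
    if (!is.na(s) && nzchar(s)) s else unname(kw[sprintf("$P%dN", j)])
  }, character(1))
  colnames(m) <- nm
  tibble::as_tibble(m)
}

# -- cohort-level I/O --------------------------------------------------------

#' Write a cohort (per-sample event files plus a metadata table)
#'
#' @param cohort Cohort tibble as produced by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format Event file format, `"delimited"` or `"fcs"`.
#' @return Path of the metadata table (`metadata.tsv`), invisibly. The table
#'   has columns subject, day, session, group, counter_concentration, file.
#' @export
write_cohort <- function(cohort, dir, format = c("delimited", "fcs")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "fcs") ".fcs" else ".tsv"
  files <- sprintf("%s_d%d_%s%s", cohort$subject, cohort$day, cohort$session,
                   ext)
  for (i in seq_len(nrow(cohort))) {
    write_events(cohort$events[[i]], file.path(dir, files[i]), format = format)
  }
  meta <- dplyr::select(cohort, -"events")
  meta$file <- files
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(meta_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param metadata_path Path of the metadata table; event files are resolved
#'   relative to its directory.
#' @return Cohort tibble with an `events` list-column.
#' @export
read_cohort <- function(metadata_path) {
  meta <- tibble::as_tibble(utils::read.table(metadata_path, header = TRUE,
                                              sep = "\t",
                                              check.names = FALSE))
  dir <- dirname(metadata_path)
  meta$events <- purrr::map(meta$file, ~ read_events(file.path(dir, .x)))
  meta$file <- NULL
  meta
}
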