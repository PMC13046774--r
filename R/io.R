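# Event-table I/O: CSV (with metadata header lines) and a minimal FCS 3.1
# dialect (list-mode, 32-bit little-endian floats, linear scale).  Ground
# truth columns of synthetic tables are excluded from FCS export and land in
# a sidecar CSV instead.

#' Read per-event data
#'
#' Reads an event table from CSV (metadata carried in leading \code{#key: value}
#' comment lines) or from an FCS 3.1 file (list mode, float data).  Channel
#' names and event counts are preserved exactly.
#'
#' @param path Path to the file.
#' @param format \code{"csv"} or \code{"fcs"}; default guesses from the file
#'   extension.
#' @return An \code{\link{event_table}}.
#' @seealso \code{\link{write_events}}
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  switch(format, csv = read_events_csv(path), fcs = read_events_fcs(path))
}

#' Write per-event data
#'
#' Writes an event table to CSV or FCS 3.1.  For FCS, ground-truth columns
#' (\code{true_*}) are dropped from the binary file and written to a sidecar
#' \code{<path>.truth.csv}; acquisition metadata become $VOL (nL) and custom
#' keywords.
#'
#' @param x An \code{\link{event_table}}.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"fcs"} (default from extension).
#' @return \code{path}, invisibly.
#' @export
write_events <- function(x, path, format = c("auto", "csv", "fcs")) {
  stopifnot(inherits(x, "event_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  switch(format, csv = write_events_csv(x, path), fcs = write_events_fcs(x, path))
  invisible(path)
}

read_events_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  num <- function(key) if (is.null(meta[[key]])) NA_real_ else as.numeric(meta[[key]])
  event_table(df,
              flow_rate = num("flow_rate"),
              acquired_volume = num("acquired_volume"),
              dilution_factor = if (is.na(num("dilution_factor"))) 1 else num("dilution_factor"),
              seed = if (is.na(num("seed"))) NA_integer_ else as.integer(num("seed")))
}

write_events_csv <- function(x, path) {
  md <- event_metadata(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("flow_rate", "acquired_volume", "dilution_factor", "seed")) {
    if (!is.na(md[[key]]))
      writeLines(sprintf("#%s: %.15g", key, as.numeric(md[[key]])), con)
  }
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
}

# -- minimal FCS 3.1 ---------------------------------------------------------

fcs_pad8 <- function(n) formatC(n, width = 8, flag = " ")

write_events_fcs <- function(x, path) {
  md <- event_metadata(x)
  keep <- !vapply(names(x), is_truth_column, logical(1))
  if (any(!keep)) {
    utils::write.csv(as.data.frame(x)[!keep], paste0(path, ".truth.csv"),
                     row.names = FALSE)
  }
  dat <- as.data.frame(x)[keep]
  par <- ncol(dat); tot <- nrow(dat)
  delim <- "/"
  kw <- c("$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(par), "$TOT",
          as.character(tot))
  for (i in seq_len(par)) {
    rng <- if (tot > 0) max(dat[[i]], 1) else 1
    kw <- c(kw, sprintf("$P%dN", i), names(dat)[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), sprintf("%.0f", ceiling(rng)))
  }
  if (!is.na(md$acquired_volume))
    kw <- c(kw, "$VOL", sprintf("%.6g", md$acquired_volume * 1000))  # nL
  if (!is.na(md$flow_rate)) kw <- c(kw, "FLOWRATE", sprintf("%.6g", md$flow_rate))
  if (!is.na(md$dilution_factor))
    kw <- c(kw, "DILUTION", sprintf("%.6g", md$dilution_factor))
  if (!is.na(md$seed)) kw <- c(kw, "SEED", sprintf("%d", as.integer(md$seed)))

  build_text <- function(begin_data, end_data) {
    all_kw <- c(kw, "$BEGINDATA", fcs_pad8(begin_data),
                "$ENDDATA", fcs_pad8(end_data),
                "$BEGINANALYSIS", fcs_pad8(0), "$ENDANALYSIS", fcs_pad8(0))
    paste0(delim, paste0(all_kw, delim, collapse = ""))
  }
  header_len <- 58L          # "FCS3.1    " + 6 x 8-byte offsets
  text <- build_text(0, 0)
  text_start <- header_len
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_len <- 4L * par * tot
  data_end <- if (data_len > 0) data_start + data_len - 1L else 0L
  text <- build_text(if (data_len > 0) data_start else 0, data_end)
  stopifnot(nchar(text) == text_end - text_start + 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  for (off in c(text_start, text_end,
                if (data_len > 0) c(data_start, data_end) else c(0, 0),
                0, 0)) {
    writeChar(fcs_pad8(off), con, eos = NULL)
  }
  writeChar(text, con, eos = NULL)
  if (data_len > 0) {
    m <- t(as.matrix(dat))            # event-major interleaving
    writeBin(as.numeric(m), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_events_fcs <- function(path) {
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  header <- rawToChar(raw[1:58])
  if (!startsWith(header, "FCS3"))
    stop("not an FCS 3.x file", call. = FALSE)
  off <- as.integer(substring(header,
                              10 + 8 * (0:5) + 1, 10 + 8 * (1:6)))
  text <- rawToChar(raw[(off[1] + 1):(off[2] + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kw <- stats::setNames(as.list(trimws(vals)), toupper(keys))
  if (toupper(kw[["$DATATYPE"]]) != "F" || toupper(kw[["$MODE"]]) != "L")
    stop("only list-mode float FCS data is supported", call. = FALSE)
  endian <- if (kw[["$BYTEORD"]] == "4,3,2,1") "big" else "little"
  par <- as.integer(kw[["$PAR"]]); tot <- as.integer(kw[["$TOT"]])
  ds <- as.integer(kw[["$BEGINDATA"]]); de <- as.integer(kw[["$ENDDATA"]])
  if (is.na(ds) || ds == 0) { ds <- off[3]; de <- off[4] }
  cols <- vapply(seq_len(par), function(i) kw[[sprintf("$P%dN", i)]],
                 character(1))
  if (tot > 0) {
    vals <- readBin(raw[(ds + 1):(de + 1)], "numeric", n = par * tot,
                    size = 4L, endian = endian)
    df <- as.data.frame(matrix(vals, nrow = tot, ncol = par, byrow = TRUE))
  } else {
    df <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = par))
  }
  names(df) <- cols
  num_kw <- function(key, default = NA_real_) {
    if (is.null(kw[[key]])) default else as.numeric(kw[[key]])
  }
  vol <- num_kw("$VOL"); if (!is.na(vol)) vol <- vol / 1000  # nL -> uL
  event_table(df,
              flow_rate = num_kw("FLOWRATE"),
              acquired_volume = vol,
              dilution_factor = num_kw("DILUTION", 1),
              seed = { s <- num_kw("SEED"); if (is.na(s)) NA_integer_ else as.integer(s) })
}

# -- configuration and calibration documents ---------------------------------

#' Read a structured configuration file
#'
#' Instrument profiles, bead reference sets and scenario descriptions are
#' plain YAML key-value documents; units are fixed to nm and degrees.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Serialize / restore a fitted calibration
#'
#' Calibrations are written as versioned plain-text YAML documents so a fit
#' made on one day can be reapplied later.  Scatter, surface-area and ABC
#' calibrations are supported.
#'
#' @param cal A fitted calibration object.
#' @param path Output path.
#' @return For \code{write_calibration}, \code{path} invisibly; for
#'   \code{read_calibration}, the restored calibration object.
#' @export
write_calibration <- function(cal, path) {
  doc <- list(format = "evcyto-calibration", version = 1L,
              class = class(cal)[1L],
              fields = unclass_for_yaml(cal))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "evcyto-calibration"))
    stop("not a calibration document", call. = FALSE)
  restore_from_yaml(doc$fields, doc$class)
}

unclass_for_yaml <- function(x) {
  out <- unclass(x)
  lapply(out, function(f) if (is.data.frame(f)) as.list(f) else f)
}

restore_from_yaml <- function(fields, cls) {
  if (cls == "scatter_calibration" && !is.null(fields$inversion_table))
    fields$inversion_table <- as.data.frame(fields$inversion_table)
  fields$beads <- if (!is.null(fields$beads)) as.data.frame(fields$beads)
  fields[vapply(fields, is.null, logical(1))] <- NULL
  structure(fields, class = cls)
}
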