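#' Per-event cytometry data
#'
#' An \code{event_table} is a data frame with one row per detected event and
#' one numeric column per channel (scatter heights/areas, fluorescence
#' heights, and optional image-derived scalars such as
#' \code{brightfield_spot_count} and \code{gradient_rms}).  Acquisition
#' metadata -- flow rate, acquired volume, dilution factor -- travel with the
#' table as attributes, because concentration arithmetic depends on them.
#' Synthetic tables may carry hidden ground-truth columns (prefixed
#' \code{"true_"}) which are excluded from FCS export.
#'
#' @param data A data frame or named list of equal-length numeric vectors.
#' @param flow_rate Sample flow rate in uL/min (or \code{NA}).
#' @param acquired_volume Acquired sample volume in uL (> 0, or \code{NA}).
#' @param dilution_factor Pre-acquisition dilution factor (>= 1).
#' @param seed Generator seed for synthetic tables (provenance; or \code{NA}).
#' @return An object of classes \code{c("event_table", "data.frame")}.
#' @examples
#' ev <- event_table(data.frame(VSSC_H = c(1, 2), FSC_H = c(3, 4)),
#'                   flow_rate = 10, acquired_volume = 20,
#'                   dilution_factor = 100)
#' n_events(ev)
#' @export
event_table <- function(data, flow_rate = NA_real_,
                        acquired_volume = NA_real_,
                        dilution_factor = 1, seed = NA_integer_) {
  data <- as.data.frame(data, optional = TRUE)
  if (nrow(data) == 0L) data[] <- lapply(data, as.numeric)
  if (ncol(data) > 0 && !all(vapply(data, is.numeric, logical(1))))
    stop("all event-table columns must be numeric", call. = FALSE)
  if (!is.na(acquired_volume) && acquired_volume <= 0)
    stop("'acquired_volume' must be positive", call. = FALSE)
  if (!is.na(dilution_factor) && dilution_factor < 1)
    stop("'dilution_factor' must be >= 1", call. = FALSE)
  structure(data,
            flow_rate = flow_rate,
            acquired_volume = acquired_volume,
            dilution_factor = dilution_factor,
            seed = seed,
            class = c("event_table", "data.frame"))
}

#' @rdname event_table
#' @param x An \code{event_table}.
#' @export
n_events <- function(x) nrow(x)

#' Acquisition metadata of an event table
#'
#' @param x An \code{event_table}.
#' @return A list with \code{flow_rate} (uL/min), \code{acquired_volume}
#'   (uL), \code{dilution_factor}, and \code{seed}.
#' @export
event_metadata <- function(x) {
  list(flow_rate = attr(x, "flow_rate"),
       acquired_volume = attr(x, "acquired_volume"),
       dilution_factor = attr(x, "dilution_factor"),
       seed = attr(x, "seed"))
}

#' @export
print.event_table <- function(x, ...) {
  md <- event_metadata(x)
  cat(sprintf("Event table: %d events, %d channels\n", nrow(x), ncol(x)))
  cat(sprintf("  channels: %s\n", paste(names(x), collapse = ", ")))
  cat(sprintf("  flow %s uL/min, volume %s uL, dilution %s\n",
              format(md$flow_rate), format(md$acquired_volume),
              format(md$dilution_factor)))
  if (nrow(x) > 0) {
    print(utils::head(as.data.frame(x), 5L))
    if (nrow(x) > 5L) cat(sprintf("  ... %d more events\n", nrow(x) - 5L))
  }
  invisible(x)
}

# channel lookup with a named error, used across the gating modules
require_channel <- function(x, channel) {
  if (!channel %in% names(x))
    stop(sprintf("channel '%s' not present in event table (have: %s)",
                 channel, paste(names(x), collapse = ", ")), call. = FALSE)
  x[[channel]]
}

# ground-truth columns are prefixed true_ (plus the esterase flag)
is_truth_column <- function(nm) startsWith(nm, "true_")
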