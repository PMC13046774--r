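# Tetraspanin co-expression profiling: spillover estimation from
# single-stained EV samples, compensation, isotype-control thresholds, and
# combination counting with replicate confidence intervals.

#' Estimate a spillover matrix from single-stained samples
#'
#' Entry (i, j) is the fraction of fluorophore i's primary signal that
#' appears in detector j, estimated from background-subtracted channel
#' medians of single-stained EV samples:
#' (median_j(single_i) - median_j(unstained)) /
#' (median_i(single_i) - median_i(unstained)).  Medians, rather than
#' regression, are used because they stay robust at the low fluorescence
#' intensities characteristic of vesicles.  Negative entries clamp to zero
#' with a warning; the diagonal is exactly 1.
#'
#' @param single_stains Named list of \code{\link{event_table}} objects, one
#'   per fluorophore; names are the detector/channel names.
#' @param unstained An unstained \code{\link{event_table}} on the same
#'   channels.
#' @return A square matrix of class \code{"spillover_matrix"} with unit
#'   diagonal.
#' @export
estimate_spillover <- function(single_stains, unstained) {
  stopifnot(is.list(single_stains), length(single_stains) >= 1L,
            !is.null(names(single_stains)), inherits(unstained, "event_table"))
  channels <- names(single_stains)
  bg <- vapply(channels, function(ch)
    stats::median(require_channel(unstained, ch)), numeric(1))
  S <- diag(length(channels))
  dimnames(S) <- list(channels, channels)
  clamped <- FALSE
  for (i in seq_along(channels)) {
    tab <- single_stains[[i]]
    med <- vapply(channels, function(ch)
      stats::median(require_channel(tab, ch)), numeric(1))
    primary <- med[i] - bg[i]
    if (primary <= 0)
      stop(sprintf("no primary-channel signal in single stain '%s'",
                   channels[i]), call. = FALSE)
    spill <- (med - bg) / primary
    if (any(spill[-i] < 0)) clamped <- TRUE
    spill[spill < 0] <- 0
    spill[i] <- 1
    S[i, ] <- spill
  }
  if (clamped) warning("negative spillover entries clamped to 0")
  structure(S, class = c("spillover_matrix", "matrix", "array"))
}

#' Compensate multicolour event data
#'
#' Removes spillover: each event's raw fluorescence vector is multiplied by
#' the inverse of the spillover matrix (raw = true %*% S, so
#' true = raw %*% S^-1).  Channels not in the matrix pass through
#' untouched.
#'
#' @param events An \code{\link{event_table}} containing every channel the
#'   matrix indexes.
#' @param S A \code{\link{estimate_spillover}} matrix (invertible).
#' @return The compensated \code{\link{event_table}}.
#' @export
compensate <- function(events, S) {
  stopifnot(inherits(events, "event_table"))
  channels <- rownames(S)
  missing <- setdiff(channels, names(events))
  if (length(missing))
    stop(sprintf("channels absent from event table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("spillover matrix is singular", call. = FALSE))
  raw <- as.matrix(as.data.frame(events)[channels])
  comp <- raw %*% Sinv
  out <- events
  for (j in seq_along(channels)) out[[channels[j]]] <- comp[, j]
  out
}

#' Isotype-control positivity thresholds
#'
#' Places each marker's positivity threshold at a stated percentile of its
#' (compensated) isotype-control distribution, exactly as the calcein
#' threshold is placed on the buffer control.
#'
#' @param isotype_controls Named list of \code{\link{event_table}} objects,
#'   one per marker channel.
#' @param percentile Percentile in (0, 100); default 99.9.
#' @return Named numeric vector of thresholds.
#' @export
isotype_thresholds <- function(isotype_controls, percentile = 99.9) {
  stopifnot(is.list(isotype_controls), !is.null(names(isotype_controls)))
  vapply(names(isotype_controls), function(mk) {
    ctrl <- isotype_controls[[mk]]
    if (is.null(ctrl)) stop(sprintf("missing isotype control for '%s'", mk),
                            call. = FALSE)
    calcein_threshold_from_control(ctrl, channel = mk, percentile = percentile)
  }, numeric(1))
}

#' Tetraspanin combination counts
#'
#' Assigns every calcein-positive event to exactly one of the 8 combinations
#' of the three tetraspanin markers (CD9/CD63/CD81 by default): the 7
#' marker-positive combinations plus triple-negative.  The combination
#' counts always partition the calcein-positive set.
#'
#' @param events A compensated \code{\link{event_table}}.
#' @param thresholds Named per-marker thresholds (from
#'   \code{\link{isotype_thresholds}}).
#' @param calcein_mask Logical vector selecting the calcein-positive events.
#' @return An object of class \code{"combination_counts"}: a data frame
#'   with one row per combination (\code{combination}, \code{count},
#'   \code{fraction}) plus attributes \code{total} and \code{markers}.
#' @export
combination_counts <- function(events, thresholds, calcein_mask) {
  stopifnot(inherits(events, "event_table"), length(calcein_mask) == nrow(events))
  markers <- names(thresholds)
  pos <- matrix(FALSE, nrow(events), length(markers),
                dimnames = list(NULL, markers))
  for (mk in markers) pos[, mk] <- require_channel(events, mk) > thresholds[[mk]]
  pos <- pos[calcein_mask, , drop = FALSE]
  combos <- combination_labels(markers)
  key <- if (nrow(pos) > 0)
    apply(pos, 1L, function(p) paste(ifelse(p, "+", "-"), collapse = ""))
  else character(0)
  lab <- vapply(combos$pattern, function(p)
    paste(ifelse(p, "+", "-"), collapse = ""), character(1))
  counts <- vapply(lab, function(l) sum(key == l), integer(1))
  total <- nrow(pos)
  out <- data.frame(combination = combos$label, count = unname(counts),
                    fraction = if (total > 0) unname(counts) / total else 0,
                    stringsAsFactors = FALSE)
  structure(out, total = total, markers = markers,
            class = c("combination_counts", "data.frame"))
}

# the 2^k marker on/off patterns, labelled "CD9+CD63-CD81-" style
combination_labels <- function(markers) {
  k <- length(markers)
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  grid <- grid[order(-rowSums(grid)), , drop = FALSE]
  pattern <- lapply(seq_len(nrow(grid)), function(i) as.logical(grid[i, ]))
  label <- vapply(pattern, function(p) {
    if (!any(p)) return("triple-negative")
    paste0(markers, ifelse(p, "+", "-"), collapse = "")
  }, character(1))
  list(pattern = pattern, label = label)
}

#' @export
print.combination_counts <- function(x, ...) {
  cat(sprintf("Tetraspanin combinations among %d calcein-positive events\n",
              attr(x, "total")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Replicate mean with a t confidence interval
#'
#' Mean across replicate wells with a two-sided t interval:
#' mean +/- t(1 - alpha/2, n-1) * SD / sqrt(n).
#'
#' @param values Per-replicate values (n >= 2).
#' @param level Confidence level (default 0.95).
#' @return A list with \code{mean}, \code{lower}, \code{upper}, \code{n}.
#' @export
replicate_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("confidence interval undefined for fewer than 2 replicates",
                   call. = FALSE)
  m <- mean(values)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) *
    stats::sd(values) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Summarise combination counts across replicates
#'
#' Stacks per-replicate \code{\link{combination_counts}} and reports, per
#' combination, the replicate mean and 95% t interval of both counts and
#' concentrations (when available).
#'
#' @param replicates List of \code{"combination_counts"} objects sharing
#'   the same marker set.
#' @param concentrations Optional numeric matrix/list of per-replicate
#'   concentrations per combination.
#' @param level Confidence level.
#' @return A data frame with one row per combination: \code{mean_count},
#'   \code{lower}, \code{upper}.
#' @export
combination_summary <- function(replicates, concentrations = NULL,
                                level = 0.95) {
  stopifnot(length(replicates) >= 2L)
  labs <- replicates[[1L]]$combination
  counts <- vapply(replicates, function(r) {
    stopifnot(identical(r$combination, labs))
    r$count
  }, numeric(length(labs)))
  rows <- lapply(seq_along(labs), function(i) {
    ci <- replicate_ci(counts[i, ], level = level)
    data.frame(combination = labs[i], mean_count = ci$mean,
               lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mixed-panel vs pan-fluorophore sensitivity comparison
#'
#' Compares two staining designs on identical synthetic ground truth: a
#' mixed panel (each marker on its own fluorophore/detector) versus a pan
#' panel (all three antibodies carrying the same fluorophore, summing on one
#' detector).  Detection is limited per channel by an intensity threshold
#' (an LoD expressed in instrument units); an event "detected" by the mixed
#' panel exceeds the threshold on at least one marker channel, while the pan
#' panel pools every bound antibody's signal before thresholding.  With
#' equal per-copy brightness the pan panel's sensitivity is therefore never
#' below the mixed panel's.
#'
#' @param events A synthetic \code{\link{event_table}} carrying
#'   \code{true_*_copies} ground-truth columns (from
#'   \code{\link{generate_ev_sample}}).
#' @param brightness_per_copy Fluorescence units per bound antibody.
#' @param detection_threshold Per-channel detection limit in intensity
#'   units.
#' @param markers Marker names (default CD9/CD63/CD81).
#' @return A list with \code{mixed} and \code{pan} sensitivities (fraction
#'   of antigen-bearing events detected) and \code{n_positive}.
#' @export
compare_panel_sensitivity <- function(events, brightness_per_copy = 50,
                                      detection_threshold = 500,
                                      markers = c("CD9", "CD63", "CD81")) {
  cols <- paste0("true_", markers, "_copies")
  missing <- setdiff(cols, names(events))
  if (length(missing))
    stop("events lack ground-truth copy columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  copies <- as.matrix(as.data.frame(events)[cols])
  bearing <- rowSums(copies) > 0
  if (!any(bearing))
    return(list(mixed = NA_real_, pan = NA_real_, n_positive = 0L))
  sig <- copies[bearing, , drop = FALSE] * brightness_per_copy
  mixed <- rowSums(sig > detection_threshold) > 0
  pan <- rowSums(sig) > detection_threshold
  list(mixed = mean(mixed), pan = mean(pan), n_positive = sum(bearing))
}
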