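#' Per-pair side-chain distance series
#'
#' Minimum distance between the representative atoms (side-chain pseudo-atom
#' where present, Calpha otherwise) of every residue pair, per frame.
#'
#' @param x a [coord_ensemble()].
#' @param subset positions to include (default all); sequence-adjacent pairs
#'   `|i-j| <= exclude_neighbors` are dropped.
#' @param exclude_neighbors default 1.
#' @return list with `dist` (F x P matrix, Angstrom) and `pairs` (tibble:
#'   pair, i, j).
#' @export
sidechain_distance_series <- function(x, subset = NULL,
                                      exclude_neighbors = 1L) {
  if (is.null(subset)) subset <- seq_len(n_positions(x))
  pr <- t(combn(subset, 2L))
  keep <- abs(pr[, 1L] - pr[, 2L]) > exclude_neighbors
  pr <- pr[keep, , drop = FALSE]
  f <- n_frames(x)
  d <- matrix(NA_real_, f, nrow(pr))
  for (k in seq_len(f)) {
    dm <- residue_min_dist(x, k)
    d[k, ] <- dm[pr]
  }
  list(dist = d, pairs = tibble(pair = seq_len(nrow(pr)),
                                i = pr[, 1L], j = pr[, 2L]))
}

#' Hysteretic contact states from distance series
#'
#' A pair becomes "formed" when its distance drops below the on-cutoff and
#' "broken" when it rises above the off-cutoff; between the two cutoffs the
#' previous state persists, so fluctuations inside the band generate no
#' events. The initial state is formed only if the first distance is already
#' below the on-cutoff (an initial in-band distance starts "broken"). A
#' single-cutoff band reading (`in contact iff on <= d <= off`... i.e. state
#' = d < off with no memory) is available via `mode = "band"`, in which the
#' pair is in contact whenever the distance is below the off-cutoff.
#'
#' @param dist F x P distance matrix (e.g. from
#'   [sidechain_distance_series()]).
#' @param on on-cutoff in Angstrom (default 6.5).
#' @param off off-cutoff in Angstrom (default 7.5); must exceed `on`.
#' @param mode `"hysteresis"` (default) or `"band"`.
#' @return a `contact_states`: list with `states` (F x P logical), `on`,
#'   `off`, `mode`.
#' @export
hysteretic_contacts <- function(dist, on = 6.5, off = 7.5,
                                mode = c("hysteresis", "band")) {
  mode <- match.arg(mode)
  dist <- as.matrix(dist)
  if (on >= off) stop("on-cutoff must be below off-cutoff")
  if (mode == "band") {
    states <- dist < off
  } else {
    f <- nrow(dist)
    states <- matrix(NA, f, ncol(dist))
    states[1L, ] <- dist[1L, ] < on
    for (t in 2L:f) {
      states[t, ] <- ifelse(dist[t, ] < on, TRUE,
                            ifelse(dist[t, ] > off, FALSE, states[t - 1L, ]))
    }
  }
  structure(list(states = states, on = on, off = off, mode = mode),
            class = "contact_states")
}

# Median-filter a logical series with the given half-width (frames).
median_filter_states <- function(s, half_width) {
  k <- 2L * as.integer(half_width) + 1L
  if (k <= 1L) return(s)
  runmed(as.numeric(s), k, endrule = "constant") >= 0.5
}

#' Contact formation/breaking activity of a trajectory
#'
#' Each pair's contact state series is median-filtered at the given
#' half-width (suppressing flickers shorter than the filter), then state
#' transitions of the filtered series are counted per frame — a FALSE to
#' TRUE step is a formation event, TRUE to FALSE a breaking event — and
#' summed over pairs. A Gaussian kernel smooths the total count series into
#' the activity curve used to flag conformational transitions.
#'
#' @param states a `contact_states` (or F x P logical matrix).
#' @param half_width median-filter half-width in frames (e.g. 14 ns at 20 ps
#'   sampling = 700 frames). Must be shorter than the trajectory.
#' @param bandwidth Gaussian kernel standard deviation in frames; default
#'   half the half-width.
#' @return an `event_series`: list with `events` (tibble: frame, formation,
#'   breaking, total, activity), `half_width`, `bandwidth`,
#'   `filtered_states`.
#' @export
event_activity <- function(states, half_width, bandwidth = NULL) {
  s <- if (inherits(states, "contact_states")) states$states else
    as.matrix(states)
  f <- nrow(s)
  half_width <- as.integer(half_width)
  if (2L * half_width + 1L >= f)
    stop("median-filter half-width (", half_width,
         " frames) must be shorter than the trajectory (", f, " frames)")
  if (is.null(bandwidth)) bandwidth <- max(half_width / 2, 1)
  filt <- apply(s, 2L, median_filter_states, half_width = half_width)
  prev <- filt[-f, , drop = FALSE]
  cur <- filt[-1L, , drop = FALSE]
  formation <- c(0L, rowSums(cur & !prev))
  breaking <- c(0L, rowSums(!cur & prev))
  total <- formation + breaking
  activity <- gaussian_smooth(total, bandwidth)
  structure(
    list(events = tibble(frame = seq_len(f), formation = formation,
                         breaking = breaking, total = total,
                         activity = activity),
         half_width = half_width, bandwidth = bandwidth,
         filtered_states = filt),
    class = "event_series")
}

gaussian_smooth <- function(y, bandwidth) {
  half <- ceiling(3 * bandwidth)
  kern <- dnorm(-half:half, sd = bandwidth)
  kern <- kern / sum(kern)
  n <- length(y)
  ypad <- c(rep(0, half), y, rep(0, half))
  as.numeric(stats::filter(ypad, kern, sides = 2L))[half + seq_len(n)]
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d frames; %d formations, %d breakings (half-width %d frames)\n",
              nrow(x$events), sum(x$events$formation), sum(x$events$breaking),
              x$half_width))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.event_series <- function(x, ...) x$events

#' @exportS3Method generics::glance
glance.event_series <- function(x, ...) {
  tibble(n_frames = nrow(x$events), formations = sum(x$events$formation),
         breakings = sum(x$events$breaking),
         peak_activity = max(x$events$activity))
}

#' Segment a trajectory by contact-event activity
#'
#' Boundaries are placed at peaks of the smoothed activity curve whose
#' height exceeds `prominence`; segments are the inter-peak basins, tiling
#' the trajectory without overlap. A flat activity curve yields a single
#' segment.
#'
#' @param ev an `event_series`.
#' @param prominence minimum peak height, in smoothed events/frame.
#' @return tibble with `segment`, `start`, `end` (frame indices, inclusive),
#'   `boundary` (the peak frame that opened the segment, `NA` for the
#'   first).
#' @export
segment_by_activity <- function(ev, prominence) {
  a <- ev$events$activity
  f <- length(a)
  pk <- pracma::findpeaks(a, minpeakheight = prominence)
  peaks <- if (is.null(pk)) integer(0) else sort(pk[, 2L])
  starts <- c(1L, peaks)
  ends <- c(peaks - 1L, f)
  keep <- starts <= ends
  tibble(segment = seq_len(sum(keep)), start = starts[keep],
         end = ends[keep], boundary = c(NA_integer_, peaks)[keep])
}
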