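#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits a mobile frame onto a reference over a stated subset of
#' positions. The rotation is obtained from the SVD of the covariance of the
#' centered subsets, with the usual reflection guard (the smallest singular
#' direction is sign-flipped when the determinant of the candidate rotation
#' is negative), so the result is always a proper rotation.
#'
#' @param mobile,reference N x 3 coordinate matrices over the same positions.
#' @param subset integer position indices used for the fit (default: all).
#'   Needs at least 3 non-collinear points.
#' @param rmsd_subset positions over which the reported RMSD is computed
#'   (default: the fit subset).
#' @return list with `coords` (fitted N x 3 matrix), `rmsd` (Angstrom), and
#'   the transform (`rotation` 3x3, `shift_mobile`, `shift_reference`).
#' @export
superpose <- function(mobile, reference, subset = NULL, rmsd_subset = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, identical(dim(mobile), dim(reference)))
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  if (length(subset) < 3L) stop("fit subset needs at least 3 positions")
  a <- mobile[subset, , drop = FALSE]
  b <- reference[subset, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  sv <- svd(crossprod(a0, b0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    stop("fit subset is (near-)collinear: rotation underdetermined")
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(sweep(mobile, 2L, ca) %*% rot, 2L, cb, `+`)
  rs <- if (is.null(rmsd_subset)) subset else rmsd_subset
  dif <- fitted[rs, , drop = FALSE] - reference[rs, , drop = FALSE]
  list(coords = fitted, rmsd = sqrt(mean(rowSums(dif^2))),
       rotation = rot, shift_mobile = ca, shift_reference = cb)
}

#' RMSD between two frames over a subset
#'
#' @param a,b N x 3 coordinate matrices.
#' @param subset positions to compare (default all).
#' @param fit superpose `a` onto `b` first (default `TRUE`); with
#'   `fit = FALSE` the coordinates are compared as given.
#' @param fit_subset positions used for the superposition when `fit = TRUE`
#'   (default: `subset`).
#' @return RMSD in Angstrom.
#' @export
rmsd_frames <- function(a, b, subset = NULL, fit = TRUE, fit_subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(as.matrix(a)))
  if (fit) {
    superpose(a, b, subset = if (is.null(fit_subset)) subset else fit_subset,
              rmsd_subset = subset)$rmsd
  } else {
    dif <- as.matrix(a)[subset, , drop = FALSE] -
      as.matrix(b)[subset, , drop = FALSE]
    sqrt(mean(rowSums(dif^2)))
  }
}

#' Superpose every frame of an ensemble onto a reference
#'
#' @param x a [coord_ensemble()].
#' @param selection positions used for the fit (default all).
#' @param reference reference frame index (default 1). The reference frame
#'   itself is left untouched, so refitting is idempotent to numerical
#'   precision.
#' @return the fitted `coord_ensemble`; side-chain coordinates, when present,
#'   receive the same rigid transform as their frame.
#' @export
fit_ensemble <- function(x, selection = NULL, reference = 1L) {
  ref <- frame_coords(x, reference)
  xyz <- x$xyz
  cb <- x$cb
  for (f in seq_len(n_frames(x))) {
    sp <- superpose(frame_coords(x, f), ref, subset = selection)
    xyz[f, ] <- as.vector(t(sp$coords))
    if (!is.null(cb)) {
      m <- frame_coords(x, f, "cb")
      m <- sweep(sweep(m, 2L, sp$shift_mobile) %*% sp$rotation, 2L,
                 sp$shift_reference, `+`)
      cb[f, ] <- as.vector(t(m))
    }
  }
  out <- x
  out$xyz <- xyz
  out$cb <- cb
  attr(out, "fit_selection") <- selection
  attr(out, "fit_reference") <- reference
  out
}

# Per-position ellipsoid volume of the coordinate scatter across frames:
# (4*pi/3) * product of the standard deviations along the three principal
# axes of that position's 3x3 covariance (population convention).
position_ellipsoid_volumes <- function(x) {
  f <- n_frames(x)
  vapply(seq_len(n_positions(x)), function(i) {
    m <- x$xyz[, (3L * i - 2L):(3L * i), drop = FALSE]
    m <- sweep(m, 2L, colMeans(m))
    ev <- eigen(crossprod(m) / f, symmetric = TRUE, only.values = TRUE)$values
    ev[ev < 0] <- 0
    4 * pi / 3 * prod(sqrt(ev))
  }, numeric(1))
}

#' Identify the structurally invariant core of an ensemble
#'
#' Iterated rounds of superposition and exclusion: fit all frames on the
#' current candidate set, measure each position's interconformer scatter as
#' an ellipsoid of variance (from the principal axes of its Cartesian
#' coordinate spread), drop the positions with the largest volumes, and
#' repeat until every remaining volume is below `stop_volume` (or the core
#' has shrunk to `target_size`). The surviving positions define the
#' reference frame for all subsequent superpositions.
#'
#' @param x a [coord_ensemble()] with at least 3 frames.
#' @param stop_volume stop when all remaining ellipsoid volumes are below
#'   this value (Angstrom^3; default 0.5).
#' @param target_size alternative stop: stop once the candidate set has at
#'   most this many positions (default `NULL`, volume criterion only).
#' @param batch_frac fraction of the candidate set dropped per iteration
#'   (at least one position; default 0.05, a coarse-to-fine ladder since the
#'   worst offenders leave first).
#' @param min_size abort if the candidate set would fall below this size
#'   (default 3).
#' @return a `core_selection`: list with `core` (position indices),
#'   `history` (tibble: iteration, n_candidates, max_volume, n_dropped) and
#'   `volumes` (final per-position volumes over the core fit).
#' @export
find_invariant_core <- function(x, stop_volume = 0.5, target_size = NULL,
                                batch_frac = 0.05, min_size = 3L) {
  if (n_frames(x) < 3L) stop("core finding needs at least 3 frames")
  cand <- seq_len(n_positions(x))
  hist <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    fitted <- fit_ensemble(x, selection = cand)
    vols <- position_ellipsoid_volumes(fitted)
    vmax <- max(vols[cand])
    done <- vmax <= stop_volume ||
      (!is.null(target_size) && length(cand) <= target_size)
    n_drop <- if (done) 0L else max(1L, ceiling(batch_frac * length(cand)))
    if (is.null(target_size))  # never drop positions already below the stop
      n_drop <- min(n_drop, sum(vols[cand] > stop_volume))
    hist[[it]] <- tibble(iteration = it, n_candidates = length(cand),
                         max_volume = vmax, n_dropped = n_drop)
    if (done) {
      final_vols <- vols
      break
    }
    if (length(cand) - n_drop < min_size) {
      stop("stop criterion unreachable before candidate set fell below ",
           min_size, " positions; history:\n",
           paste(utils::capture.output(print(purrr::list_rbind(hist))),
                 collapse = "\n"))
    }
    drop <- cand[order(vols[cand], decreasing = TRUE)[seq_len(n_drop)]]
    cand <- setdiff(cand, drop)
  }
  structure(list(core = cand, history = purrr::list_rbind(hist),
                 volumes = final_vols),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("<core_selection> %d core positions after %d iterations (max volume %.3g A^3)\n",
              length(x$core), nrow(x$history), tail(x$history$max_volume, 1)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.core_selection <- function(x, ...) x$history

#' Write a core selection as a two-column TSV
#'
#' @param sel a `core_selection`.
#' @param ensemble the [coord_ensemble()] it was derived from (for author
#'   residue numbers).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_core_selection <- function(sel, ensemble, path) {
  write.table(
    data.frame(column = sel$core, resno = ensemble$resno[sel$core]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
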