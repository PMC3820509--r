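#' Coordinate ensemble container
#'
#' A `coord_ensemble` holds F aligned conformations of the same N equivalent
#' Calpha positions as an F x 3N coordinate matrix (the layout used throughout
#' structural-bioinformatics PCA: x1, y1, z1, x2, ...). Both crystal-structure
#' ensembles and trajectory snapshots are represented this way, so every
#' downstream operation (superposition, PCA, cross-correlation, order
#' parameters) applies to either. An optional second F x 3N matrix carries one
#' representative side-chain atom per residue (Cbeta, or Calpha for glycine),
#' used by contact-based operators.
#'
#' @param xyz numeric matrix, F frames x 3N coordinates (Angstrom).
#' @param labels frame labels: structure ids or times. Defaults to `1:F`.
#' @param resno integer author residue numbers, length N. Defaults to `1:N`.
#' @param resid three-letter residue names, length N. Defaults to `"ALA"`.
#' @param cb optional F x 3N matrix of representative side-chain coordinates.
#' @param time_step frame spacing in ns for trajectories, or `NULL` for
#'   unordered ensembles.
#' @param regions optional named list of integer position vectors marking
#'   structural elements (e.g. `a4`, `b3`, `neck_linker`).
#' @param bfactors optional numeric length-N vector of crystallographic
#'   B-factors (Angstrom^2) attached to the reference frame.
#'
#' @return An object of class `coord_ensemble`.
#' @export
coord_ensemble <- function(xyz, labels = NULL, resno = NULL, resid = NULL,
                           cb = NULL, time_step = NULL, regions = NULL,
                           bfactors = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) stop("xyz must have 3N columns")
  n_pos <- ncol(xyz) %/% 3L
  if (n_pos < 3L) stop("ensemble needs at least 3 positions")
  if (anyNA(xyz)) stop("missing coordinates at retained positions")
  if (is.null(labels)) labels <- seq_len(nrow(xyz))
  if (length(labels) != nrow(xyz)) stop("labels length must equal frame count")
  if (is.null(resno)) resno <- seq_len(n_pos)
  if (is.null(resid)) resid <- rep("ALA", n_pos)
  if (!is.null(cb)) {
    cb <- as.matrix(cb)
    stopifnot(identical(dim(cb), dim(xyz)))
  }
  structure(
    list(xyz = xyz, labels = labels, resno = as.integer(resno),
         resid = resid, cb = cb, time_step = time_step,
         regions = regions, bfactors = bfactors),
    class = "coord_ensemble"
  )
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("<coord_ensemble> %d frames x %d positions%s\n",
              n_frames(x), n_positions(x),
              if (is.null(x$cb)) "" else " (+side-chain atoms)"))
  if (!is.null(x$time_step))
    cat(sprintf("  time step: %g ns\n", x$time_step))
  if (!is.null(x$regions))
    cat("  regions:", paste(names(x$regions), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname coord_ensemble
#' @param x a `coord_ensemble`.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' @rdname coord_ensemble
#' @export
n_positions <- function(x) ncol(x$xyz) %/% 3L

#' Extract one frame as an N x 3 coordinate matrix
#'
#' @param x a `coord_ensemble`.
#' @param i frame index.
#' @param what `"ca"` (default) or `"cb"` for the side-chain atom set.
#' @return numeric N x 3 matrix.
#' @export
frame_coords <- function(x, i, what = c("ca", "cb")) {
  what <- match.arg(what)
  m <- if (what == "ca") x$xyz else x$cb
  if (is.null(m)) stop("ensemble carries no side-chain coordinates")
  matrix(m[i, ], ncol = 3L, byrow = TRUE)
}

#' Column indices of the flattened xyz matrix for a set of positions
#' @noRd
xyz_idx <- function(positions) {
  as.vector(rbind(3L * positions - 2L, 3L * positions - 1L, 3L * positions))
}

#' Subset an ensemble by frames and/or positions
#'
#' @param x a `coord_ensemble`.
#' @param frames integer frame indices (default all).
#' @param positions integer position indices (default all).
#' @return a new `coord_ensemble`.
#' @export
subset_ensemble <- function(x, frames = NULL, positions = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(x))
  if (is.null(positions)) positions <- seq_len(n_positions(x))
  ci <- xyz_idx(positions)
  regions <- NULL
  if (!is.null(x$regions)) {
    remap <- match(seq_len(n_positions(x)), positions)
    regions <- lapply(x$regions, function(p) {
      p2 <- remap[p]
      p2[!is.na(p2)]
    })
    regions <- regions[vapply(regions, length, 1L) > 0L]
  }
  coord_ensemble(
    x$xyz[frames, ci, drop = FALSE],
    labels = x$labels[frames],
    resno = x$resno[positions], resid = x$resid[positions],
    cb = if (is.null(x$cb)) NULL else x$cb[frames, ci, drop = FALSE],
    time_step = x$time_step, regions = regions,
    bfactors = if (is.null(x$bfactors)) NULL else x$bfactors[positions]
  )
}

#' Tidy a coordinate ensemble into a long tibble
#'
#' @param x a `coord_ensemble`.
#' @param ... unused.
#' @return tibble with columns `frame`, `label`, `position`, `resno`,
#'   `resid`, `x`, `y`, `z`.
#' @exportS3Method generics::tidy
tidy.coord_ensemble <- function(x, ...) {
  f <- n_frames(x); n <- n_positions(x)
  tibble(
    frame = rep(seq_len(f), each = n),
    label = rep(x$labels, each = n),
    position = rep(seq_len(n), times = f),
    resno = rep(x$resno, times = f),
    resid = rep(x$resid, times = f),
    x = as.vector(t(x$xyz[, seq(1L, 3L * n, 3L), drop = FALSE])),
    y = as.vector(t(x$xyz[, seq(2L, 3L * n, 3L), drop = FALSE])),
    z = as.vector(t(x$xyz[, seq(3L, 3L * n, 3L), drop = FALSE]))
  )
}
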