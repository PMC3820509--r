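#' Synthetic data generators
#'
#' These generators produce inputs with the statistical structure the
#' analysis pipeline assumes — Gaussian conformer ensembles with a known
#' low-rank covariance, two-state switching trajectories with known
#' transition times, and trajectories with block-structured residue-residue
#' correlation — so every stage is testable without downloading structures.
#' All are seed-deterministic, and each attaches its generating parameters
#' as a machine-readable `ground_truth` attribute (see [ground_truth()]).
#'
#' @name synthetic
NULL

unit_perp <- function(u, perp) {
  v <- perp - sum(perp * u) * u
  if (sqrt(sum(v^2)) < 1e-6) {
    alt <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- alt - sum(alt * u) * u
  }
  v / sqrt(sum(v^2))
}

helix_ca <- function(n, start, axis = c(1, 0, 0), perp = c(0, 1, 0),
                     radius = 2.3, rise = 1.5, turn = 100) {
  u <- axis / sqrt(sum(axis^2))
  v <- unit_perp(u, perp)
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  th <- (seq_len(n) - 1) * turn * pi / 180
  t(vapply(seq_len(n), function(i)
    start + rise * (i - 1) * u + radius * cos(th[i]) * v +
      radius * sin(th[i]) * w, numeric(3)))
}

strand_ca <- function(n, start, dir = c(1, 0, 0), perp = c(0, 0, 1),
                      step = 3.3, amp = 0.95) {
  u <- dir / sqrt(sum(dir^2))
  v <- unit_perp(u, perp)
  t(vapply(seq_len(n), function(i)
    start + step * (i - 1) * u + amp * (-1)^i * v, numeric(3)))
}

coil_ca <- function(n, start, dir = c(1, 0, 0), perp = c(0, 1, 0),
                    radius = 4.0) {
  u <- dir / sqrt(sum(dir^2))
  v <- unit_perp(u, perp)
  step_angle <- 2 * asin(3.8 / (2 * radius))
  th <- (seq_len(n) - 1) * step_angle
  t(vapply(seq_len(n), function(i)
    start + radius * sin(th[i]) * u + radius * (1 - cos(th[i])) * v,
    numeric(3)))
}

pseudo_cb <- function(ca, length = 1.5) {
  n <- nrow(ca)
  cb <- ca
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    mid <- (ca[lo, ] + ca[hi, ]) / 2
    d <- ca[i, ] - mid
    nd <- sqrt(sum(d^2))
    dir <- if (nd > 1e-6) d / nd else c(0, 0, 1)
    cb[i, ] <- ca[i, ] + length * dir
  }
  cb
}

#' Idealized toy motor-domain structure
#'
#' A 70-residue helix/strand/linker construct whose labeled regions carry
#' the names of the motor-domain elements (`b1`, `b3`, `loop8`, `a4`,
#' `loop13`, `a6`, `neck_linker`), so analysis recipes written for real
#' structures run unchanged on synthetic data. The `a4` helix protrudes
#' above the `b1`/`b3` sheet, giving a meaningful protrusion order
#' parameter. One pseudo side-chain atom per residue sits at fixed local
#' geometry, sufficient for contact and docking operators.
#'
#' @return a single-frame [coord_ensemble()] with `regions` and side-chain
#'   pseudo-atoms.
#' @export
toy_structure <- function() {
  segs <- list(
    b1 = strand_ca(10, c(0, 0, 0)),
    loop_a = coil_ca(4, c(31, 1.5, 0), dir = c(0, 1, 0)),
    b3 = strand_ca(10, c(29, 4.8, 0), dir = c(-1, 0, 0)),
    loop8 = coil_ca(6, c(-3, 6, 2), dir = c(0, 0, 1), perp = c(1, 0, 0)),
    a4 = helix_ca(18, c(0, 2.5, 15.8)),
    loop13 = coil_ca(6, c(28.5, 4, 16.5), dir = c(0, -1, 0),
                     perp = c(0, 0, -1)),
    a6 = helix_ca(8, c(26, -3, 7), axis = c(-1, 0, 0)),
    neck_linker = coil_ca(8, c(12, -5, 4), dir = c(-1, 0, 0),
                          perp = c(0, -1, 0))
  )
  ca <- do.call(rbind, segs)
  n <- nrow(ca)
  lens <- vapply(segs, nrow, 1L)
  stopifnot(n == 70L)
  bounds <- cumsum(lens)
  regions <- purrr::map2(c(1L, head(bounds, -1) + 1L), bounds, seq)
  names(regions) <- names(segs)
  coord_ensemble(matrix(as.vector(t(ca)), nrow = 1L),
                 labels = "toy",
                 resid = rep("ALA", n),
                 cb = matrix(as.vector(t(pseudo_cb(ca))), nrow = 1L),
                 regions = regions)
}

#' Two toy conformational states with a displaced a4 subdomain
#'
#' State "up" is [toy_structure()]; in state "down" the `a4` helix and
#' `loop13` are rigidly shifted toward the sheet (reduced protrusion) and
#' the `neck_linker` is displaced away from the domain body (undocked).
#'
#' The default displacement puts the "up" state near a 16 Angstrom
#' subdomain-to-core separation and the "down" state near 13 Angstrom,
#' matching the scale on which this order parameter distinguishes motor
#' conformations.
#'
#' @param shift displacement (Angstrom) of a4 toward the core (default 3.4).
#' @return list with `up` and `down`, both single-frame ensembles.
#' @export
toy_two_state <- function(shift = 3.4) {
  up <- toy_structure()
  down <- up
  move <- function(ens, positions, delta) {
    ci <- xyz_idx(positions)
    d3 <- rep(delta, times = length(positions))
    ens$xyz[, ci] <- ens$xyz[, ci] + d3
    ens$cb[, ci] <- ens$cb[, ci] + d3
    ens
  }
  down <- move(down, c(up$regions$a4, up$regions$loop13), c(0, 0, -shift))
  down <- move(down, up$regions$neck_linker, c(0, -8, -2))
  down$labels <- "toy_down"
  list(up = up, down = down)
}

restore_seed <- function(seed) {
  set.seed(as.integer(seed))
}

#' Gaussian conformer ensemble with known low-rank covariance
#'
#' Frames are `mean + sum_k z_k mode_k + noise`, with `z_k ~ N(0, var_k)`
#' and isotropic Gaussian noise, so the true covariance (and hence the
#' expected PCA spectrum) is analytically known. Modes are orthonormalized
#' internally (Gram-Schmidt via QR).
#'
#' @param mean_structure a single-frame [coord_ensemble()] (default
#'   [toy_structure()]).
#' @param modes 3N x K matrix of mode directions, or `K` to draw that many
#'   random directions.
#' @param variances length-K variances (Angstrom^2) of the mode amplitudes.
#' @param n_frames number of frames (>= 2).
#' @param noise_sd isotropic per-coordinate noise sd (default 0).
#' @param seed RNG seed.
#' @return a [coord_ensemble()]; `ground_truth` attribute holds the
#'   orthonormal modes, variances and noise level.
#' @export
gaussian_ensemble <- function(mean_structure = toy_structure(),
                              modes = 3L, variances = c(9, 3, 1),
                              n_frames = 2000L, noise_sd = 0, seed = 1L) {
  if (n_frames < 2L) stop("need at least 2 frames")
  restore_seed(seed)
  mu <- as.vector(mean_structure$xyz[1L, ])
  p <- length(mu)
  if (is.matrix(modes)) {
    k <- ncol(modes)
  } else {
    k <- as.integer(modes)
    modes <- matrix(stats::rnorm(p * k), p, k)
  }
  stopifnot(length(variances) == k, all(variances > 0))
  q <- qr.Q(qr(modes))[, seq_len(k), drop = FALSE]
  z <- matrix(stats::rnorm(n_frames * k), n_frames, k)
  z <- sweep(z, 2L, sqrt(variances), `*`)
  xyz <- sweep(z %*% t(q), 2L, mu, `+`)
  if (noise_sd > 0) xyz <- xyz + stats::rnorm(length(xyz), sd = noise_sd)
  out <- coord_ensemble(xyz, resno = mean_structure$resno,
                        resid = mean_structure$resid,
                        regions = mean_structure$regions)
  attr(out, "ground_truth") <- list(
    kind = "gaussian_ensemble", modes = q, variances = variances,
    noise_sd = noise_sd, seed = seed)
  out
}

#' Two-state (or multi-state) switching trajectory
#'
#' Piecewise-constant state sequence with isotropic Gaussian noise around
#' each state conformation. Transition frames (the first frame of each new
#' state) are known exactly and emitted as ground truth, together with the
#' state index per frame.
#'
#' @param states list of single-frame [coord_ensemble()]s sharing positions
#'   (e.g. [toy_two_state()]).
#' @param transitions increasing frame indices at which the trajectory
#'   switches to the next state (cycling through `states`).
#' @param n_frames total frames; must exceed `max(transitions)`.
#' @param noise_sd per-coordinate noise sd (default 0.3).
#' @param time_step frame spacing in ns (default 0.02).
#' @param seed RNG seed.
#' @return a [coord_ensemble()] with side-chain pseudo-atoms; ground truth
#'   carries `transitions` and `state_of_frame`.
#' @export
switching_trajectory <- function(states, transitions, n_frames = 1000L,
                                 noise_sd = 0.3, time_step = 0.02,
                                 seed = 1L) {
  if (length(states) < 2L) stop("need at least 2 state conformations")
  transitions <- as.integer(transitions)
  if (any(transitions <= 1L) || any(transitions > n_frames) ||
      is.unsorted(transitions, strictly = TRUE))
    stop("transitions must be strictly increasing, in (1, n_frames]")
  state_of_frame <- findInterval(seq_len(n_frames), c(1L, transitions))
  state_of_frame <- ((state_of_frame - 1L) %% length(states)) + 1L
  restore_seed(seed)
  s1 <- states[[1L]]
  p <- ncol(s1$xyz)
  xyz <- matrix(NA_real_, n_frames, p)
  cb <- if (!is.null(s1$cb)) matrix(NA_real_, n_frames, p) else NULL
  for (f in seq_len(n_frames)) {
    st <- states[[state_of_frame[f]]]
    eps <- if (noise_sd > 0) stats::rnorm(p, sd = noise_sd) else 0
    xyz[f, ] <- st$xyz[1L, ] + eps
    if (!is.null(cb)) cb[f, ] <- st$cb[1L, ] + eps
  }
  out <- coord_ensemble(xyz, labels = (seq_len(n_frames) - 1L) * time_step,
                        resno = s1$resno, resid = s1$resid, cb = cb,
                        time_step = time_step, regions = s1$regions)
  attr(out, "ground_truth") <- list(
    kind = "switching_trajectory", transitions = transitions,
    state_of_frame = state_of_frame, noise_sd = noise_sd, seed = seed)
  out
}

#' Trajectory with block-structured residue-residue correlation
#'
#' Residues are laid out on a compact cubic lattice (3 Angstrom spacing; one
#' slab per block, adjacent slabs touching, so contacts exist both within
#' and between blocks). Each frame displaces every residue of block b by a
#' shared latent 3-vector plus independent isotropic noise, calibrated so
#' the expected pairwise displacement correlation equals `intra` within
#' blocks and `inter` between blocks:
#' `rho_intra = tau^2 / (tau^2 + sigma^2)`, with a latent fraction
#' `inter/intra` shared across blocks.
#'
#' @param block_sizes integer vector of residues per block.
#' @param intra target intra-block correlation, in (0, 1].
#' @param inter target inter-block correlation, `0 <= inter <= intra`.
#' @param n_frames number of frames.
#' @param tau latent displacement sd per axis in Angstrom (default 0.3;
#'   small thermal-scale fluctuations that leave the contact topology
#'   intact).
#' @param spacing lattice spacing in Angstrom (default 3, dense enough that
#'   lattice diagonals are contacts and each block forms a tightly
#'   intraconnected module).
#' @param seed RNG seed.
#' @return a [coord_ensemble()]; ground truth carries the block membership
#'   and the calibrated `tau`/`sigma`.
#' @export
block_correlated_trajectory <- function(block_sizes = c(20L, 20L, 20L),
                                        intra = 0.8, inter = 0,
                                        n_frames = 5000L, tau = 0.3,
                                        spacing = 3, seed = 1L) {
  if (intra <= 0 || intra > 1)
    stop("intra-block correlation target must be in (0, 1]; got ", intra)
  if (inter < 0 || inter > intra)
    stop("inter target must satisfy 0 <= inter <= intra (feasible bound ",
         intra, ")")
  n <- sum(block_sizes)
  membership <- rep(seq_along(block_sizes), times = block_sizes)
  # one slab per block in the x direction; y-z grid filled per slab
  ca <- matrix(NA_real_, n, 3L)
  idx <- 1L
  for (b in seq_along(block_sizes)) {
    sz <- block_sizes[b]
    ny <- ceiling(sqrt(sz))
    # visit lattice sites with a stride coprime to the block size so that
    # sequence neighbors are not lattice neighbors (the network's
    # sequence-neighbor exclusion must not disconnect a block)
    stride <- sz %/% 3L
    while (pracma::gcd(stride, sz) != 1L) stride <- stride + 1L
    sites <- (stride * (seq_len(sz) - 1L)) %% sz
    for (k in seq_len(sz)) {
      s <- sites[k]
      ca[idx, ] <- spacing * c(b - 1L, s %% ny, s %/% ny)
      idx <- idx + 1L
    }
  }
  sigma <- if (intra == 1) 0 else tau * sqrt(1 / intra - 1)
  share <- if (intra > 0) inter / intra else 0
  restore_seed(seed)
  mu <- as.vector(t(ca))
  xyz <- matrix(NA_real_, n_frames, 3L * n)
  nb <- length(block_sizes)
  for (f in seq_len(n_frames)) {
    g_global <- stats::rnorm(3L)
    lat <- vapply(seq_len(nb), function(b)
      tau * (sqrt(share) * g_global +
               sqrt(1 - share) * stats::rnorm(3L)), numeric(3))
    disp <- t(lat[, membership]) +
      matrix(stats::rnorm(3L * n, sd = sigma), n, 3L)
    xyz[f, ] <- mu + as.vector(t(disp))
  }
  out <- coord_ensemble(xyz, time_step = 0.02)
  attr(out, "ground_truth") <- list(
    kind = "block_correlated_trajectory", membership = membership,
    intra = intra, inter = inter, tau = tau, sigma = sigma, seed = seed)
  out
}

#' Ground truth attached to a synthetic ensemble
#'
#' @param x an object produced by a generator in this package.
#' @return the generator's parameter list, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Write generator ground truth as JSON next to the data
#'
#' @param x a synthetic ensemble.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(x, path) {
  gt <- ground_truth(x)
  if (is.null(gt)) stop("object carries no ground truth")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
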