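#' Cartesian covariance matrix of a superposed ensemble
#'
#' Builds the 3N x 3N covariance of the Cartesian coordinates over frames,
#' using the population convention (divide by F). The population convention
#' is fixed package-wide: variance *fractions* (the quantities compared
#' across studies) are convention-invariant, but absolute eigenvalues are
#' not, so the convention is stated here once.
#'
#' @param x a [coord_ensemble()] with at least 2 frames, already superposed.
#' @return a `covariance_matrix`: list with `matrix` (3N x 3N, Angstrom^2),
#'   `mean` (3N vector), `n_positions`, `n_frames`.
#' @export
xyz_covariance <- function(x) {
  f <- n_frames(x)
  if (f < 2L) stop("covariance needs at least 2 frames")
  mu <- colMeans(x$xyz)
  xc <- sweep(x$xyz, 2L, mu)
  structure(
    list(matrix = crossprod(xc) / f, mean = mu,
         n_positions = n_positions(x), n_frames = f),
    class = "covariance_matrix")
}

#' Principal component analysis of a coordinate ensemble
#'
#' Diagonalizes the Cartesian covariance matrix of the superposed ensemble.
#' Eigenvectors form an orthonormal basis of collective displacement modes;
#' eigenvalues give the variance (Angstrom^2) captured along each mode, also
#' reported as percentage and cumulative percentage of the total
#' mean-square fluctuation. Eigenvector signs are fixed by making each
#' vector's largest-magnitude component positive, so projections are
#' deterministic.
#'
#' @param x a [coord_ensemble()] (superposed) or a `covariance_matrix`.
#' @return an `ens_pca`: list with `vectors` (3N x 3N orthonormal columns),
#'   `values` (descending, clipped at 0), `var_frac`, `cum_frac`, `mean`,
#'   `n_positions`, `n_frames`.
#' @export
ens_pca <- function(x) {
  cv <- if (inherits(x, "covariance_matrix")) x else xyz_covariance(x)
  m <- cv$matrix
  if (max(abs(m - t(m))) > 1e-8) stop("covariance matrix is not symmetric")
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- eg$values
  if (min(vals) < -1e-8 * max(abs(vals), 1))
    stop("covariance matrix is not positive semidefinite")
  vals[vals < 0] <- 0
  vec <- eg$vectors
  flip <- apply(vec, 2L, function(v) sign(v[which.max(abs(v))]))
  vec <- sweep(vec, 2L, flip, `*`)
  total <- sum(vals)
  # a static ensemble has zero total variance; report zero fractions rather
  # than NaN so degenerate trajectories flow through the pipeline
  structure(
    list(vectors = vec, values = vals,
         var_frac = if (total > 0) vals / total else vals,
         cum_frac = if (total > 0) cumsum(vals) / total else cumsum(vals),
         mean = cv$mean, n_positions = cv$n_positions,
         n_frames = cv$n_frames),
    class = "ens_pca")
}

#' @export
print.ens_pca <- function(x, ...) {
  cat(sprintf("<ens_pca> %d positions, %d frames\n", x$n_positions, x$n_frames))
  k <- min(5L, length(x$values))
  cat(sprintf("  PC%d: %5.1f%% (cum %5.1f%%)\n", seq_len(k),
              100 * x$var_frac[seq_len(k)], 100 * x$cum_frac[seq_len(k)]),
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ens_pca <- function(x, ...) {
  tibble(pc = seq_along(x$values), eigenvalue = x$values,
         var_percent = 100 * x$var_frac, cum_percent = 100 * x$cum_frac)
}

#' @exportS3Method generics::glance
glance.ens_pca <- function(x, ...) {
  tibble(n_positions = x$n_positions, n_frames = x$n_frames,
         total_variance = sum(x$values),
         cum2 = 100 * x$cum_frac[2], cum3 = 100 * x$cum_frac[3],
         cum5 = 100 * x$cum_frac[min(5L, length(x$cum_frac))])
}

#' Project frames onto principal components
#'
#' Scores are inner products of mean-centered frames with the leading
#' eigenvectors. For the training ensemble, the population variance of the
#' scores along PC k equals eigenvalue k.
#'
#' @param x a [coord_ensemble()] superposed on the same core/reference as
#'   the model's training set, or an F x 3N matrix.
#' @param model an `ens_pca`.
#' @param k number of components (default 5).
#' @return tibble with `frame`, `label`, and score columns `PC1..PCk`
#'   (Angstrom).
#' @export
project_frames <- function(x, model, k = 5L) {
  xyz <- if (inherits(x, "coord_ensemble")) x$xyz else as.matrix(x)
  labels <- if (inherits(x, "coord_ensemble")) x$labels else seq_len(nrow(xyz))
  if (ncol(xyz) != length(model$mean))
    stop("dimension mismatch: frames have ", ncol(xyz),
         " coordinates, model has ", length(model$mean))
  k <- min(k, ncol(model$vectors))
  sc <- sweep(xyz, 2L, model$mean) %*% model$vectors[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(tibble(frame = seq_len(nrow(sc)), label = labels),
                   as_tibble(sc))
}

#' Reconstruct coordinates from PC scores
#'
#' @param scores matrix (F x k) of scores, columns ordered PC1..PCk.
#' @param model an `ens_pca`.
#' @return F x 3N coordinate matrix.
#' @export
reconstruct_frames <- function(scores, model) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  sweep(scores %*% t(model$vectors[, seq_len(k), drop = FALSE]),
        2L, model$mean, `+`)
}

#' Per-residue contribution to a principal component
#'
#' Squared norm of each position's three eigenvector components; the profile
#' sums to one over positions and localizes the collective motion a PC
#' describes onto structural elements.
#'
#' @param model an `ens_pca`.
#' @param pc component index.
#' @return tibble with `position` and `contribution`.
#' @export
residue_contributions <- function(model, pc = 1L) {
  if (pc > ncol(model$vectors)) stop("pc index exceeds model rank")
  v <- model$vectors[, pc]
  n <- model$n_positions
  contrib <- rowSums(matrix(v^2, ncol = 3L, byrow = TRUE))
  tibble(position = seq_len(n), contribution = contrib)
}

#' Complete-linkage clustering of conformers in PC space
#'
#' Hierarchical clustering (complete linkage) of the Euclidean distance
#' matrix built from the projections along the first `n_pcs` eigenvectors;
#' labels are assigned by cutting the tree at `k` groups. The conformer
#' groups of an interconformer analysis (e.g. ATP-like vs ADP-like vs
#' inhibitor-bound) are obtained this way.
#'
#' @param projections tibble from [project_frames()] (or any data frame with
#'   `PC*` columns).
#' @param k number of groups.
#' @param n_pcs number of leading PCs to use (default 5, or fewer if not
#'   present).
#' @return a `conformer_clusters`: list with `labels` (tibble frame, label,
#'   cluster), `tree` (hclust), `k`, `n_pcs`.
#' @export
cluster_conformers <- function(projections, k = 3L, n_pcs = 5L) {
  pcs <- grep("^PC[0-9]+$", names(projections), value = TRUE)
  n_pcs <- min(n_pcs, length(pcs))
  sc <- as.matrix(projections[, paste0("PC", seq_len(n_pcs)), drop = FALSE])
  if (k > nrow(sc)) stop("k exceeds the number of frames")
  tree <- hclust(dist(sc), method = "complete")
  cl <- cutree(tree, k = k)
  structure(
    list(labels = dplyr::mutate(
      projections[, intersect(c("frame", "label"), names(projections))],
      cluster = unname(cl)),
      tree = tree, k = k, n_pcs = n_pcs),
    class = "conformer_clusters")
}

#' @export
print.conformer_clusters <- function(x, ...) {
  cat(sprintf("<conformer_clusters> k=%d on PC1..PC%d; sizes: %s\n", x$k,
              x$n_pcs, paste(table(x$labels$cluster), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conformer_clusters <- function(x, ...) x$labels

#' Root-mean-square fluctuation per position
#'
#' @param x a superposed [coord_ensemble()] with at least 2 frames.
#' @return tibble with `position`, `resno`, `rmsf` (Angstrom);
#'   `rmsf_i = sqrt(<|r_i - <r_i>|^2>)` (population convention).
#' @export
rmsf_profile <- function(x) {
  if (n_frames(x) < 2L) stop("rmsf needs at least 2 frames")
  xc <- sweep(x$xyz, 2L, colMeans(x$xyz))
  msf <- colMeans(xc^2)
  n <- n_positions(x)
  per_pos <- msf[seq(1L, 3L * n, 3L)] + msf[seq(2L, 3L * n, 3L)] +
    msf[seq(3L, 3L * n, 3L)]
  tibble(position = seq_len(n), resno = x$resno, rmsf = sqrt(per_pos))
}

#' Squared correlation between an RMSF profile and B-factors
#'
#' Crystallographic B-factors relate to mean-square fluctuation through
#' B = (8 pi^2 / 3) <u^2>, so agreement is assessed on the linear
#' B-versus-RMSF^2 scale.
#'
#' @param profile tibble from [rmsf_profile()] (or numeric RMSF vector).
#' @param bfactors numeric B-factors (Angstrom^2), same positions.
#' @return list with `r_squared` and `n_used`; `r_squared` is `NA` with a
#'   warning when either profile is constant.
#' @export
bfactor_correlation <- function(profile, bfactors) {
  r <- if (is.data.frame(profile)) profile$rmsf else as.numeric(profile)
  ok <- stats::complete.cases(r, bfactors)
  r <- r[ok]; b <- bfactors[ok]
  if (sd(r) == 0 || sd(b) == 0) {
    warning("constant profile: correlation undefined")
    return(list(r_squared = NA_real_, n_used = length(r)))
  }
  list(r_squared = cor(r^2, b)^2, n_used = length(r))
}

#' Average cumulative squared inner product between two PC subspaces
#'
#' For each of model `a`'s first `n_ref` components, accumulates the squared
#' projections onto model `b`'s first `k` eigenvectors, then averages. The
#' result lies in [0, 1], is non-decreasing in `k`, and reaches 1 at
#' `k = 3N`. Used to ask how well one ensemble's essential subspace is
#' spanned by another's.
#'
#' @param a,b `ens_pca` models over the same 3N coordinates.
#' @param k number of components of `b` to accumulate.
#' @param n_ref number of components of `a` averaged over (default 2).
#' @return numeric scalar.
#' @export
subspace_overlap <- function(a, b, k, n_ref = 2L) {
  if (nrow(a$vectors) != nrow(b$vectors))
    stop("dimension mismatch between models")
  va <- a$vectors[, seq_len(n_ref), drop = FALSE]
  vb <- b$vectors[, seq_len(k), drop = FALSE]
  mean(colSums(crossprod(vb, va)^2))
}
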