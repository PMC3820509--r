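# Brute-force double-loop evaluation of the covariance definition,
# independent of any matrix algebra.
brute_covariance <- function(xyz) {
  f <- nrow(xyz); p <- ncol(xyz)
  mu <- colMeans(xyz)
  out <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    s <- 0
    for (t in 1:f) s <- s + (xyz[t, i] - mu[i]) * (xyz[t, j] - mu[j])
    out[i, j] <- s / f
  }
  out
}

test_that("two frames differing in one coordinate give the d^2/4 entry", {
  xyz <- matrix(rnorm(9), 1, 9)[rep(1, 2), ]
  d <- 1.7
  xyz[2, 4] <- xyz[2, 4] + d
  cv <- xyz_covariance(coord_ensemble(xyz))
  expected <- matrix(0, 9, 9)
  expected[4, 4] <- d^2 / 4  # population convention
  expect_equal(cv$matrix, expected, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("covariance matches the explicit double-loop summation", {
  set.seed(21)
  xyz <- matrix(rnorm(3 * 9, sd = 2), 3, 9)
  cv <- xyz_covariance(coord_ensemble(xyz))
  expect_equal(cv$matrix, brute_covariance(xyz), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(diag(cv$matrix)), sum(ens_pca(cv)$values),
               tolerance = 1e-8)
})

test_that("sampled covariance approaches the generator covariance", {
  ens <- gaussian_ensemble(n_frames = 5000, variances = c(9, 3, 1),
                           noise_sd = 0, seed = 8)
  gt <- ground_truth(ens)
  true_cov <- gt$modes %*% diag(gt$variances) %*% t(gt$modes)
  cv <- xyz_covariance(ens)
  # entrywise within 3 standard errors of the generator covariance
  se <- sqrt((outer(diag(true_cov), diag(true_cov)) + true_cov^2) / 5000)
  expect_true(all(abs(cv$matrix - true_cov) <= 3 * se + 1e-8))
})

test_that("two distinct conformers give a single PC along their difference", {
  a <- toy_structure()$xyz[1, ]
  b <- a + rep(c(0.5, -0.2, 0.1), length.out = length(a))
  p <- ens_pca(coord_ensemble(rbind(a, b)))
  expect_equal(sum(p$values > 1e-10), 1L)
  expect_equal(p$cum_frac[1], 1, tolerance = 1e-10)
  dvec <- (b - a) / sqrt(sum((b - a)^2))
  expect_equal(abs(sum(p$vectors[, 1] * dvec)), 1, tolerance = 1e-8)
})

test_that("mode variance fractions 9:3:1 are recovered within sampling error", {
  f <- 2000L
  ens <- gaussian_ensemble(n_frames = f, variances = c(9, 3, 1), seed = 2)
  p <- ens_pca(ens)
  truth <- c(9, 3, 1) / 13
  # delta-method standard error for each eigenvalue fraction,
  # var(lambda_k) = 2 lambda_k^2 / F
  lam <- c(9, 3, 1); s <- sum(lam)
  for (k in 1:3) {
    grad <- -lam[k] / s^2 * rep(1, 3)
    grad[k] <- grad[k] + 1 / s
    se <- sqrt(sum(grad^2 * 2 * lam^2 / f))
    expect_lt(abs(p$var_frac[k] - truth[k]), 3 * se)
  }
})

test_that("PCA agrees with an independent reference implementation", {
  ens <- fit_ensemble(gaussian_ensemble(n_frames = 50, noise_sd = 0.1,
                                        seed = 13))
  ours <- ens_pca(ens)
  ref <- bio3d::pca.xyz(ens$xyz)
  # bio3d uses the sample convention; fractions are convention-invariant
  expect_equal(ours$var_frac[1:5], (ref$L / sum(ref$L))[1:5],
               tolerance = 1e-6, ignore_attr = TRUE)
  for (k in 1:3)
    expect_equal(abs(sum(ours$vectors[, k] * ref$U[, k])), 1,
                 tolerance = 1e-6)
})

test_that("projections are exact for the mean, complete, and variance-matching", {
  ens <- fit_ensemble(gaussian_ensemble(n_frames = 100, seed = 5))
  p <- ens_pca(ens)
  zero <- project_frames(matrix(p$mean, 1), p, k = 5)
  expect_equal(unlist(zero[, paste0("PC", 1:5)]), rep(0, 5),
               tolerance = 1e-8, ignore_attr = TRUE)
  # full-rank reconstruction of a training frame
  full <- project_frames(ens, p, k = ncol(p$vectors))
  sc <- as.matrix(full[, grep("^PC", names(full))])
  rec <- reconstruct_frames(sc, p)
  expect_lt(max(abs(rec - ens$xyz)), 1e-6)
  # training-score variance equals eigenvalues (population convention)
  f <- n_frames(ens)
  expect_equal(var(sc[, 1]) * (f - 1) / f, p$values[1], tolerance = 1e-6)
})

test_that("residue contributions localize and normalize", {
  base <- toy_structure()$xyz[1, ]
  moved <- base
  moved[(3 * 5 - 2):(3 * 5)] <- moved[(3 * 5 - 2):(3 * 5)] + c(1, 2, -1)
  p <- ens_pca(coord_ensemble(rbind(base, moved)))
  contrib <- residue_contributions(p, 1)
  expect_equal(contrib$contribution[5], 1, tolerance = 1e-10)
  expect_equal(sum(contrib$contribution), 1, tolerance = 1e-10)
  expect_lt(max(contrib$contribution[-5]), 1e-10)
})

test_that("conformer clustering recovers separated groups and ignores ordering", {
  set.seed(9)
  blob1 <- matrix(rnorm(40, sd = 0.5), 20, 2)
  blob2 <- matrix(rnorm(40, sd = 0.5), 20, 2) + 10
  proj <- tibble::tibble(frame = 1:40, label = 1:40,
                         PC1 = c(blob1[, 1], blob2[, 1]),
                         PC2 = c(blob1[, 2], blob2[, 2]))
  cl <- cluster_conformers(proj, k = 2, n_pcs = 2)
  truth <- rep(1:2, each = 20)
  expect_same_partition(cl$labels$cluster, truth)
  # frame reordering leaves the partition intact
  perm <- sample(40)
  cl2 <- cluster_conformers(proj[perm, ], k = 2, n_pcs = 2)
  expect_same_partition(cl2$labels$cluster[order(perm)], truth)
  # identical frames: zero-height tree
  proj0 <- tibble::tibble(frame = 1:5, label = 1:5, PC1 = rep(1, 5),
                          PC2 = rep(2, 5))
  cl0 <- cluster_conformers(proj0, k = 2, n_pcs = 2)
  expect_equal(max(cl0$tree$height), 0)
})

test_that("RMSF matches closed forms and the B-factor relation", {
  base <- toy_structure()$xyz[rep(1, 6), ]
  expect_true(all(rmsf_profile(coord_ensemble(base))$rmsf == 0))
  set.seed(3)
  sigma <- 0.7
  noisy <- base[rep(1, 4000), ] + rnorm(4000 * ncol(base), sd = sigma)
  prof <- rmsf_profile(coord_ensemble(noisy))
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.02)
  b <- (8 * pi^2 / 3) * prof$rmsf^2
  expect_equal(bfactor_correlation(prof, b)$r_squared, 1, tolerance = 1e-10)
  expect_warning(out <- bfactor_correlation(rep(1, 10), rnorm(10)),
                 "undefined")
  expect_true(is.na(out$r_squared))
})

test_that("subspace overlap behaves at its extremes and under rotation", {
  ens <- fit_ensemble(gaussian_ensemble(n_frames = 200, seed = 6))
  a <- ens_pca(ens)
  expect_equal(subspace_overlap(a, a, k = 2), 1, tolerance = 1e-10)
  # model with leading PCs orthogonal to a's PC1-PC2
  b <- a
  k_swap <- ncol(a$vectors)
  b$vectors <- a$vectors[, c(seq(3, k_swap), 1, 2)]
  expect_equal(subspace_overlap(a, b, k = 2), 0, tolerance = 1e-10)
  expect_equal(subspace_overlap(a, b, k = k_swap), 1, tolerance = 1e-8)
  # monotone in k
  ov <- vapply(1:6, function(k) subspace_overlap(a, b, k), numeric(1))
  expect_true(all(diff(ov) >= -1e-12))
})

test_that("a rank-5 subspace is fully recovered after an orthogonal change of basis", {
  n_modes <- 5L
  ens <- gaussian_ensemble(modes = n_modes, variances = c(16, 8, 4, 2, 1),
                           n_frames = 400, seed = 14)
  a <- ens_pca(ens)
  # second model: same frames, mixed by an orthogonal map within the mode span
  gt <- ground_truth(ens)
  set.seed(15)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  b <- a
  b$vectors[, 1:5] <- gt$modes %*% q
  expect_equal(subspace_overlap(a, b, k = 5), 1, tolerance = 1e-6)
})

test_that("PCA of the reconstructed ensemble reproduces the eigenvalues", {
  ens <- fit_ensemble(gaussian_ensemble(n_frames = 150, noise_sd = 0.05,
                                        seed = 22))
  p <- ens_pca(ens)
  sc <- as.matrix(project_frames(ens, p, k = 10)[, paste0("PC", 1:10)])
  rec <- coord_ensemble(reconstruct_frames(sc, p))
  p2 <- ens_pca(rec)
  expect_equal(p2$values[1:10], p$values[1:10], tolerance = 1e-8)
})
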