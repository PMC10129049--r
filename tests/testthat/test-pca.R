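synthetic_pca_ensemble <- function(n = 10, m = 30, seed = 1, noise = 0.2) {
  template <- coord_record(random_chain(n, seed), "T")
  modes <- random_orthonormal_modes(3 * n, 3, seed = seed + 1)
  plant_ensemble(template, modes, variances = c(4, 2, 1), noise_sd = noise,
                 n_members = m, seed = seed + 2)
}

test_that("eigenvalues match an independent SVD oracle", {
  for (seed in 1:4) {
    ens <- synthetic_pca_ensemble(n = sample(5:10, 1), m = sample(8:20, 1),
                                  seed = seed)
    m <- length(ens$member_ids)
    res <- suppressWarnings(ensemble_pca(ens, k = 3 * ens$n_positions))
    # oracle: SVD of the centered data matrix, coded independently
    x <- t(apply(ens$coords, 1, function(z) as.vector(t(z))))
    xc <- scale(x, center = TRUE, scale = FALSE)
    sv <- svd(xc)$d^2 / (m - 1)
    k <- min(length(sv), length(res$eigenvalues))
    expect_equal(res$eigenvalues[1:k], sv[1:k], tolerance = 1e-8)
  }
})

test_that("components are orthonormal and fractions sum to one", {
  ens <- synthetic_pca_ensemble(m = 40, seed = 7)
  res <- ensemble_pca(ens, k = 10)
  gram <- tcrossprod(res$components)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-8)
  expect_true(all(diff(res$all_eigenvalues) <= 1e-10))
  expect_true(all(res$all_eigenvalues >= -1e-10))
  expect_equal(sum(res$all_eigenvalues) / res$total_variance, 1,
               tolerance = 1e-6)
  # Parseval: projection variances over the full basis = total variance
  full <- suppressWarnings(ensemble_pca(ens, k = 1000))
  pv <- sum(apply(full$projections, 2, stats::var))
  expect_equal(pv / full$total_variance, 1, tolerance = 1e-6)
})

test_that("M = 2 yields a single nonzero eigenvalue carrying all variance", {
  ens <- synthetic_pca_ensemble(m = 2, seed = 11)
  res <- suppressWarnings(ensemble_pca(ens, k = 5))
  expect_length(res$eigenvalues, 1L)
  expect_equal(res$variance_fraction[1], 1.0, tolerance = 1e-8)
})

test_that("planted variances 9:4:1 are recovered at M = 500, zero noise", {
  n <- 12
  template <- coord_record(random_chain(n, 31), "T")
  modes <- random_orthonormal_modes(3 * n, 3, seed = 32)
  ens <- plant_ensemble(template, modes, variances = c(9, 4, 1),
                        noise_sd = 0, n_members = 500, seed = 33)
  res <- ensemble_pca(ens, k = 3)
  expect_lt(max(abs(res$variance_fraction - c(9, 4, 1) / 14)), 0.02)
  for (k in 1:3)
    expect_gt(abs(sum(res$components[k, ] * modes[, k])), 0.99)
})

test_that("PCA refuses unsuperposed input", {
  ens <- synthetic_pca_ensemble(seed = 13)
  ens$superposed <- FALSE
  expect_error(ensemble_pca(ens), "superposed")
})

test_that("k is truncated with a warning when it exceeds min(3N, M-1)", {
  ens <- synthetic_pca_ensemble(n = 5, m = 6, seed = 17)
  expect_warning(res <- ensemble_pca(ens, k = 100), "truncated")
  expect_length(res$eigenvalues, 5L)
})

test_that("mobility profiles isolate per-residue displacement", {
  ens <- synthetic_pca_ensemble(n = 8, m = 10, seed = 19)
  res <- ensemble_pca(ens, k = 3)
  # overwrite a component with a pure single-residue displacement
  v <- rep(0, 24); v[3 * 4 + 1] <- 1   # residue 5, x
  res$components[1, ] <- v
  prof <- mobility_profile(res, 1, scale = FALSE)
  expect_equal(which(prof > 0), 5L)
  # uniform translation gives a flat profile
  res$components[2, ] <- rep(c(1, 0, 0) / sqrt(8), 8)
  prof2 <- mobility_profile(res, 2, scale = FALSE)
  expect_equal(max(prof2) - min(prof2), 0, tolerance = 1e-12)
  expect_error(mobility_profile(res, 99), "out of range")
})

test_that("PC1 mobility peaks inside a planted two-state segment", {
  ens <- small_two_state(seed = 23, m_per_state = 12)
  res <- ensemble_pca(ens, k = 3)
  prof <- mobility_profile(res, 1)
  expect_true(which.max(prof) %in% 119:124)
})

test_that("projections are centered, separable, and reconstruct the data", {
  # a pure planted shift (no state-specific extra noise) so PC1 aligns
  # with the planted mode and the projection gap is interpretable
  template <- make_bundle(seed = 1)
  ens <- plant_two_state(template, 119:124, m_per_state = 15,
                         shift_amplitude = 6, noise_sd = 0.2,
                         within_state_sd = 0.3, segment_noise_sd = 0,
                         seed = 29)
  res <- ensemble_pca(ens, k = 3)
  proj <- project_members(res, ens, components = 1:3)
  expect_lt(max(abs(colMeans(as.matrix(proj[, c("PC1", "PC2", "PC3")])))),
            1e-8)
  # the two label groups differ along PC1 by roughly the planted 6 A shift
  gap <- abs(mean(proj$PC1[proj$label == "active"]) -
               mean(proj$PC1[proj$label == "inactive"]))
  expect_lt(abs(gap - 6) / 6, 0.10)

  # projecting the ensemble mean returns the zero vector
  mens <- ens
  mens$coords <- ens$coords[1:2, , , drop = FALSE]
  mens$coords[1, , ] <- res$mean_coords
  mens$coords[2, , ] <- res$mean_coords
  mens$mask <- ens$mask[1:2, ]
  mens$member_ids <- c("MU1", "MU2")
  mens$labels <- c("none", "none"); mens$species <- c("", "")
  pm <- project_members(res, mens, components = 1:2)
  expect_lt(max(abs(as.matrix(pm[, c("PC1", "PC2")]))), 1e-8)

  # reconstruction from the complete basis reproduces centered coordinates
  small <- synthetic_pca_ensemble(n = 5, m = 30, seed = 41)
  full <- ensemble_pca(small, k = 15)
  x <- t(apply(small$coords, 1, function(z) as.vector(t(z))))
  xc <- sweep(x, 2, colMeans(x))
  recon <- full$projections %*% full$components
  expect_lt(max(abs(recon - xc)), 1e-8)
})
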