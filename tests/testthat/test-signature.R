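test_that("identical members yield identical spectra; disconnected ones drop", {
  template <- make_bundle(n_helices = 3, residues_per_helix = 10,
                          loop_length = 4, seed = 14)
  n3 <- 3 * length(template)
  ens <- plant_ensemble(template, matrix(numeric(0), n3, 0), numeric(0),
                        noise_sd = 0, n_members = 3, seed = 1)
  spectra <- ensemble_gnm(ens)
  expect_length(spectra, 3L)
  expect_equal(spectra[[1]]$eigenvalues, spectra[[2]]$eigenvalues)
  expect_equal(spectra[[1]]$eigenvectors, spectra[[3]]$eigenvectors)

  # blow one member apart: dropped with a warning (or error on request)
  ens$coords[2, , ] <- ens$coords[2, , ] * 100
  expect_warning(sp2 <- ensemble_gnm(ens), "dropped")
  expect_length(sp2, 2L)
  expect_equal(attr(sp2, "dropped"), ens$member_ids[2])
  expect_error(ensemble_gnm(ens, on_disconnected = "error"), "disconnected")
})

test_that("perturbed copies have nearby eigenvalue spectra", {
  template <- make_bundle(n_helices = 3, residues_per_helix = 10,
                          loop_length = 4, seed = 15)
  n3 <- 3 * length(template)
  ens <- plant_ensemble(template, matrix(numeric(0), n3, 0), numeric(0),
                        noise_sd = 0.05, n_members = 5, seed = 2)
  spectra <- ensemble_gnm(ens)
  expect_length(spectra, 5L)
  ref <- build_gnm(template$ca_coords)$eigenvalues
  for (s in spectra)
    expect_lt(max(abs(s$eigenvalues - ref) / ref), 0.5)
})

test_that("mode matching recovers identity, sign flips and swaps", {
  s <- random_spectrum(20, 6, seed = 3)
  m <- match_modes(s, s, k_max = 6)
  expect_equal(m$matched_order, 1:6)
  expect_equal(m$match_signs, rep(1L, 6))

  neg <- s; neg$eigenvectors <- -s$eigenvectors
  mneg <- match_modes(neg, s, k_max = 6)
  expect_equal(mneg$matched_order, 1:6)
  expect_equal(mneg$match_signs, rep(-1L, 6))

  swap <- mode_spectrum("SWAP", s$eigenvalues,
                        s$eigenvectors[, c(2, 1, 3:6)])
  mswap <- match_modes(swap, s, k_max = 6)
  expect_equal(mswap$matched_order, c(2L, 1L, 3:6))

  expect_warning(match_modes(s, s, k_max = 50), "truncated")
})

test_that("spectral overlap obeys its closed-form anchors", {
  s <- random_spectrum(15, 5, seed = 4)
  expect_equal(spectral_overlap(s, s, 1, 5), 1.0, tolerance = 1e-12)

  e1 <- mode_spectrum("E1", 2, matrix(c(1, 0, 0, 0), 4))
  e2 <- mode_spectrum("E2", 2, matrix(c(0, 1, 0, 0), 4))
  expect_equal(spectral_overlap(e1, e2, 1, 1), 0.0, tolerance = 1e-12)
  expect_error(spectral_overlap(e1, e2, 3, 1), "window")
})

test_that("spectral overlap equals the brute-force double-loop oracle", {
  for (seed in 1:5) {
    a <- random_spectrum(10, 4, seed = seed, id = "A")
    b <- random_spectrum(10, 4, seed = seed + 40, id = "B")
    expect_equal(spectral_overlap(a, b, 1, 4),
                 brute_force_overlap(a, b, 1:4, 1:4), tolerance = 1e-10)
    expect_equal(spectral_overlap(a, b, 2, 3),
                 brute_force_overlap(a, b, 2:3, 2:3), tolerance = 1e-10)
  }
})

test_that("overlap is invariant to sign flips and within-window reordering", {
  a <- random_spectrum(12, 6, seed = 8, id = "A")
  b <- random_spectrum(12, 6, seed = 9, id = "B")
  base <- spectral_overlap(a, b, 1, 4)
  flip <- b
  flip$eigenvectors[, 2] <- -flip$eigenvectors[, 2]
  expect_equal(spectral_overlap(a, flip, 1, 4), base, tolerance = 1e-12)
  # permute modes within the window via a matched_order
  perm <- b
  perm$matched_order <- c(3L, 1L, 4L, 2L, 5L, 6L)
  reordered <- mode_spectrum("P", b$eigenvalues, b$eigenvectors)
  reordered$matched_order <- perm$matched_order
  expect_equal(spectral_overlap(a, reordered, 1, 4), base, tolerance = 1e-10)
})

test_that("spectral distance matrix satisfies the metric axioms", {
  ens <- small_two_state(seed = 5, m_per_state = 3)
  spectra <- matched_ensemble_spectra(ens)
  dm <- spectral_distance_matrix(spectra, 1, 10)
  v <- dm$values
  expect_equal(diag(v), rep(0, nrow(v)), ignore_attr = TRUE,
               tolerance = 1e-7)
  expect_equal(v, t(v))
  expect_true(all(v >= 0 & v <= pi / 2 + 1e-9))
  # entries are elementwise arccos of the overlap
  so <- spectral_overlap(spectra[[1]], spectra[[2]], 1, 10)
  expect_equal(v[1, 2], acos(so), tolerance = 1e-12)
})

test_that("signature profiles aggregate member MSFs correctly", {
  # identical members: zero variance, mean equals the single profile
  template <- make_bundle(n_helices = 3, residues_per_helix = 10,
                          loop_length = 4, seed = 16)
  n3 <- 3 * length(template)
  ens <- plant_ensemble(template, matrix(numeric(0), n3, 0), numeric(0),
                        noise_sd = 0, n_members = 3, seed = 6)
  spectra <- matched_ensemble_spectra(ens)
  prof <- signature_profile(spectra, "global")
  expect_equal(max(prof$variance_msf), 0, tolerance = 1e-16)
  single <- gnm_msf(build_gnm(template$ca_coords), 1:3)
  expect_equal(prof$mean_msf, single / sum(single), tolerance = 1e-8)
  expect_true(all(prof$min_msf <= prof$mean_msf + 1e-12))
  expect_true(all(prof$mean_msf <= prof$max_msf + 1e-12))

  # two constructed members: aggregation equals direct arithmetic
  q <- qr.Q(qr(matrix(c(1, 2, 0, 3, 1, -1, 2, 0, 1, 1, 4, 1, 0, 1, 2), 5, 3)))
  sa <- mode_spectrum("A", c(1, 2, 4), q)
  sb <- mode_spectrum("B", c(0.5, 2, 8), q[, c(2, 1, 3)])
  msf_a <- q^2 %*% (1 / c(1, 2, 4))
  msf_b <- q[, c(2, 1, 3)]^2 %*% (1 / c(0.5, 2, 8))
  # hand regime: match both to sa so 'global' (modes 1-3) = all modes
  sa <- match_modes(sa, sa, 3); sb <- match_modes(sb, sa, 3)
  na <- msf_a / sum(msf_a); nb <- msf_b / sum(msf_b)
  prof2 <- signature_profile(list(sa, sb), "global")
  expect_equal(prof2$mean_msf, as.vector((na + nb) / 2), tolerance = 1e-10)
  expect_equal(prof2$min_msf, as.vector(pmin(na, nb)), tolerance = 1e-10)
  expect_equal(prof2$max_msf, as.vector(pmax(na, nb)), tolerance = 1e-10)
  expect_equal(prof2$variance_msf, as.vector(((na - nb) / 2)^2),
               tolerance = 1e-10)
})

test_that("global-regime variance peaks inside the planted flexible segment", {
  ens <- small_two_state(seed = 30, m_per_state = 8)
  spectra <- matched_ensemble_spectra(ens)
  prof <- signature_profile(spectra, "global")
  expect_true(which.max(prof$variance_msf) %in% 119:124)
})

test_that("matched overlaps beat random permutations on noisy ensembles", {
  wins <- 0L
  for (seed in 1:5) {
    ens <- small_two_state(seed = 60 + seed, m_per_state = 3)
    spectra <- ensemble_gnm(ens)
    ref <- spectra[[1]]
    k <- 10
    matched_mean <- mean(vapply(spectra[-1], function(s) {
      m <- match_modes(s, ref, k)
      mean(abs(vapply(seq_len(k), function(r)
        sum(s$eigenvectors[, m$matched_order[r]] * ref$eigenvectors[, r]),
        numeric(1))))
    }, numeric(1)))
    set.seed(seed)
    rand_mean <- mean(vapply(spectra[-1], function(s) {
      pr <- sample(seq_len(k))
      mean(abs(vapply(seq_len(k), function(r)
        sum(s$eigenvectors[, pr[r]] * ref$eigenvectors[, r]),
        numeric(1))))
    }, numeric(1)))
    wins <- wins + (matched_mean > rand_mean)
  }
  expect_equal(wins, 5L)
})
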