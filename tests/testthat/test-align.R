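test_that("self-mapping yields the identity pairing at identity 1", {
  b <- make_bundle(n_helices = 3, residues_per_helix = 8, loop_length = 4,
                   seed = 2)
  am <- map_to_reference(b, b)
  expect_true(am$mappable)
  expect_equal(am$identity_fraction, 1.0)
  expect_equal(am$pairs[, "a"], seq_len(length(b)))
  expect_equal(am$pairs[, "b"], seq_len(length(b)))
})

test_that("a single deletion maps around the missing reference position", {
  ref <- coord_record(random_chain(6, 1), "REF",
                      strsplit("ACDEFG", "")[[1]])
  mem <- coord_record(random_chain(5, 2), "MEM",
                      strsplit("ACEFG", "")[[1]])
  am <- map_to_reference(mem, ref)
  # optimal global alignment: AC-EFG / ACDEFG (frozen from enumeration of
  # this 6x5 case: any other gap placement loses >= 2 matches)
  expect_equal(nrow(am$pairs), 5L)
  expect_equal(am$pairs[, "a"], 1:5)
  expect_equal(am$pairs[, "b"], c(1, 2, 4, 5, 6))
  expect_equal(am$identity_fraction, 1.0)
})

test_that("low-identity members are flagged unmappable", {
  ref <- coord_record(random_chain(20, 3), "REF",
                      sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                             20, replace = TRUE))
  mem <- coord_record(random_chain(20, 4), "MEM", rep("X", 20))
  expect_warning(am <- map_to_reference(mem, ref), "unmappable")
  expect_false(am$mappable)
})

test_that("Kabsch recovers exact rigid motions", {
  x <- random_chain(10, 5)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  y <- x %*% t(rot90)
  fit <- kabsch_superpose(x, y)
  expect_equal(fit$rotation, rot90, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the quaternion oracle on fixed point sets", {
  a <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2), 4, 3, byrow = TRUE)
  b <- matrix(c(0.1, 0, 0, 1.2, -0.1, 0, 0, 1.1, 0.2, 0.5, 0.3, 1.0),
              4, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_superpose(a, b)$rmsd,
               tolerance = 1e-9)
  expect_equal(kabsch_superpose(b, a)$rmsd, quaternion_superpose(b, a)$rmsd,
               tolerance = 1e-9)
})

test_that("Kabsch is invariant to pre-rotation and minimises the RMSD", {
  for (seed in 1:5) {
    x <- random_chain(12, seed)
    y <- random_chain(12, seed + 100)
    base <- kabsch_superpose(x, y)$rmsd
    pre <- x %*% t(random_rotation_matrix(seed + 200))
    expect_equal(kabsch_superpose(pre, y)$rmsd, base, tolerance = 1e-8)
    # superposed RMSD never exceeds the raw RMSD
    expect_lte(base, sqrt(mean(rowSums((x - y)^2))) + 1e-12)
  }
})

test_that("Kabsch rejects degenerate and invalid input", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  x <- random_chain(4, 7)
  expect_error(kabsch_superpose(x, x, weights = rep(0, 4)), "weights")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 points")
})

test_that("occupancy filtering drops or keeps positions at the threshold", {
  b <- make_bundle(n_helices = 3, residues_per_helix = 10, loop_length = 4,
                   seed = 3)
  n <- length(b)
  drop_residue <- function(rec, i, id) {
    structure_record(id, "A", rec$residue_ids[-i], rec$residue_codes[-i],
                     rec$ca_coords[-i, ], state_label = "none")
  }
  # 3 identical copies (the reference among them): nothing filtered
  copies <- c(list(b), lapply(2:3, function(i) {
    r <- b; r$member_id <- paste0("C", i); r
  }))
  ens <- build_mapped_ensemble(copies, b, occupancy_threshold = 0.9)
  expect_equal(length(ens$member_ids), 3L)
  expect_equal(ens$n_positions, n)
  expect_equal(ens$occupancy, rep(1, n))

  # 10 members (reference included), position 5 resolved in 8/10
  mems <- c(list(b), lapply(2:10, function(i) {
    if (i <= 3) drop_residue(b, 5L, paste0("M", i))
    else { r <- b; r$member_id <- paste0("M", i); r }
  }))
  ens9 <- build_mapped_ensemble(mems, b, occupancy_threshold = 0.9)
  expect_equal(ens9$n_positions, n - 1L)
  expect_false("5" %in% ens9$positions)

  ens75 <- build_mapped_ensemble(mems, b, occupancy_threshold = 0.75)
  expect_equal(ens75$n_positions, n)
  expect_equal(ens75$occupancy[5], 0.8)
})

test_that("iterative superposition removes planted rigid motions", {
  b <- make_bundle(n_helices = 3, residues_per_helix = 10, loop_length = 4,
                   seed = 4)
  copies <- lapply(1:4, function(i) {
    r <- b
    r$member_id <- paste0("R", i)
    set.seed(i)
    rot <- random_rotation_matrix(i)
    r$ca_coords <- sweep(b$ca_coords %*% t(rot), 2, stats::rnorm(3, sd = 30),
                         "+")
    r
  })
  ens <- build_mapped_ensemble(copies, b)
  ens <- iterative_superpose(ens)
  for (m in seq_along(ens$member_ids)[-1])
    expect_lt(max(abs(ens$coords[m, , ] - ens$coords[1, , ])), 1e-6)
  expect_true(ens$superposed && ens$imputed)
})

test_that("tol = Inf performs a single pass and still returns a valid ensemble", {
  ens <- small_two_state(seed = 9, m_per_state = 3)
  ens$superposed <- FALSE; ens$imputed <- FALSE
  out <- iterative_superpose(ens, tol = Inf, max_iter = 50)
  expect_length(out$mean_shifts, 1L)
  expect_true(out$superposed)
  expect_true(all(is.finite(out$coords)))
})

test_that("one pass on two members equals direct superposition (oracle)", {
  b <- make_bundle(n_helices = 3, residues_per_helix = 10, loop_length = 4,
                   seed = 6)
  mem <- b
  mem$member_id <- "MOB"
  set.seed(42)
  mem$ca_coords <- sweep(b$ca_coords %*% t(random_rotation_matrix(11)), 2,
                         stats::rnorm(3, sd = 10), "+") +
    matrix(stats::rnorm(3 * length(b), sd = 0.2), ncol = 3)
  ens <- build_mapped_ensemble(list(b, mem), b)
  idx <- match("MOB", ens$member_ids)
  # pass 0 superposes the mobile member directly onto the reference
  sup <- iterative_superpose(ens, tol = Inf, max_iter = 1)
  oracle <- quaternion_superpose(mem$ca_coords, b$ca_coords)
  ref_idx <- match(b$member_id, sup$member_ids)
  # after the mean pass both members moved; compare pairwise geometry:
  # RMSD(mobile, reference) is invariant and must equal the oracle rmsd
  d <- sqrt(mean(rowSums((sup$coords[idx, , ] - sup$coords[ref_idx, , ])^2)))
  expect_equal(d, oracle$rmsd, tolerance = 1e-6)
})

test_that("iterative superposition converges monotonically", {
  ens <- small_two_state(seed = 21, m_per_state = 5)
  # scramble frames so the procedure has work to do
  set.seed(1)
  for (m in seq_along(ens$member_ids)) {
    rot <- random_rotation_matrix(m + 50)
    ens$coords[m, , ] <- sweep(ens$coords[m, , ] %*% t(rot), 2,
                               stats::rnorm(3, sd = 15), "+")
  }
  ens$superposed <- FALSE; ens$imputed <- FALSE
  out <- iterative_superpose(ens, tol = 1e-10, max_iter = 8)
  sh <- out$mean_shifts
  if (length(sh) > 2)
    expect_true(all(diff(sh[-1]) <= 1e-9))
})
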