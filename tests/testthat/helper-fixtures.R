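# fixtures and independent oracles built in code

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", icode = " ", name = " CA ") {
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, name, alt, resname, chain, resno, icode, x, y, z, occ, 0)
}

three_residue_pdb <- function() {
  paste(c(pdb_atom_line(1, "ALA", "A", 1, 1, 2, 3),
          pdb_atom_line(2, "GLY", "A", 2, 4, 5, 6),
          pdb_atom_line(3, "SER", "A", 3, 7, 8, 9),
          "END"), collapse = "\n")
}

# a structure_record from bare coordinates
coord_record <- function(coords, member_id = "REC", seq = NULL,
                         state_label = "none") {
  n <- nrow(coords)
  if (is.null(seq)) seq <- rep("A", n)
  structure_record(member_id = member_id, chain_id = "A",
                   residue_ids = as.character(seq_len(n)),
                   residue_codes = seq, ca_coords = coords,
                   state_label = state_label)
}

# self-avoiding-ish random chain with ~3.8 A steps: connected at GNM
# cutoff 10 by construction
random_chain <- function(n, seed, step = 3.8) {
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rbind(c(0, 0, 0), apply(dirs * step, 2, cumsum))
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent superposition oracle: Horn's quaternion method
quaternion_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  x <- sweep(mobile, 2, cm); y <- sweep(target, 2, ct)
  s <- crossprod(x, y)
  k <- matrix(0, 4, 4)
  k[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  k[1, 2] <- k[2, 1] <- s[2, 3] - s[3, 2]
  k[1, 3] <- k[3, 1] <- s[3, 1] - s[1, 3]
  k[1, 4] <- k[4, 1] <- s[1, 2] - s[2, 1]
  k[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  k[2, 3] <- k[3, 2] <- s[1, 2] + s[2, 1]
  k[2, 4] <- k[4, 2] <- s[1, 3] + s[3, 1]
  k[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  k[3, 4] <- k[4, 3] <- s[2, 3] + s[3, 2]
  k[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  q <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  rot <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  tr <- ct - as.vector(rot %*% cm)
  moved <- sweep(mobile %*% t(rot), 2, tr, "+")
  list(rotation = rot, translation = tr,
       rmsd = sqrt(mean(rowSums((moved - target)^2))),
       coords = moved)
}

# brute-force covariance overlap: explicit double loop over the formula
brute_force_overlap <- function(a, b, modes_a, modes_b) {
  sa <- 1 / a$eigenvalues[modes_a]
  sb <- 1 / b$eigenvalues[modes_b]
  cross <- 0
  for (k in seq_along(modes_a)) for (l in seq_along(modes_b)) {
    dot <- sum(a$eigenvectors[, modes_a[k]] * b$eigenvectors[, modes_b[l]])
    cross <- cross + sqrt(sa[k] * sb[l]) * dot^2
  }
  1 - sqrt(max(0, (sum(sa) + sum(sb) - 2 * cross) / (sum(sa) + sum(sb))))
}

# random mode spectrum: orthonormal vectors, sorted positive eigenvalues
random_spectrum <- function(n, k, seed, id = "RND") {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
  mode_spectrum(id, sort(stats::runif(k, 0.5, 5)), q)
}

# small two-state fixture shared by state-compare tests
small_two_state <- function(seed, m_per_state = 10) {
  template <- make_bundle(seed = 1)
  segment <- 119:124   # central connecting loop of the default bundle
  plant_two_state(template, segment = segment, m_per_state = m_per_state,
                  seed = seed)
}

matched_ensemble_spectra <- function(ens, k_max = 20) {
  spectra <- ensemble_gnm(ens)
  lapply(spectra, match_modes, spectra[[1]], k_max = k_max)
}
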