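# Synthetic fixtures: idealized helix bundles, planted-mode ensembles,
# labeled two-state ensembles, and controlled-identity sequence families.
# All outputs are fully determined by their seed.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Idealized C-alpha helix-bundle template
#'
#' Deterministic C-alpha trace of `n_helices` antiparallel ideal helices
#' (rise 1.5 A/residue, 100 degrees/residue, helix radius 2.3 A) placed on
#' a circle of `bundle_radius`, connected by circular-arc loops that bulge
#' beyond the helix ends. The default geometry mimics a 7-transmembrane
#' helix bundle with short connecting loops; positions are annotated
#' `"helix"` or `"loop"`. The sequence is drawn pseudo-randomly (seeded)
#' from the 20 amino acids.
#'
#' @param n_helices number of helices (default 7).
#' @param residues_per_helix residues per helix (default 25).
#' @param loop_length residues per connecting loop (default 6).
#' @param bundle_radius circle radius for helix axes (A, default 12).
#' @param rise,twist_deg,helix_radius ideal helix geometry (1.5 A, 100
#'   degrees, 2.3 A).
#' @param loop_height apex height of the loop arcs beyond the helix ends
#'   (A, default 4.5).
#' @param seed integer seed for the sequence.
#' @return a [structure_record()] of length
#'   `n_helices * residues_per_helix + (n_helices - 1) * loop_length`,
#'   with `segments` annotation.
#' @export
make_bundle <- function(n_helices = 7L, residues_per_helix = 25L,
                        loop_length = 6L, bundle_radius = 12,
                        rise = 1.5, twist_deg = 100, helix_radius = 2.3,
                        loop_height = 4.5, seed = 1L) {
  if (n_helices < 2L || residues_per_helix < 3L || loop_length < 1L)
    stop("invalid bundle dimensions")
  height <- (residues_per_helix - 1L) * rise
  coords <- NULL
  segments <- character(0)
  helix_pts <- function(h) {
    th <- 2 * pi * (h - 1L) / n_helices
    center <- bundle_radius * c(cos(th), sin(th))
    up <- h %% 2L == 1L
    i <- seq_len(residues_per_helix) - 1L
    z <- if (up) i * rise else height - i * rise
    phi <- twist_deg * pi / 180 * i
    cbind(center[1] + helix_radius * cos(phi),
          center[2] + helix_radius * sin(phi),
          z)
  }
  arc_pts <- function(a, b, w) {
    # circular arc from a to b bulging along w; the apex height is raised
    # above loop_height when needed so that loop residues are spaced
    # ~3.2 A along the arc (short chords would otherwise collide)
    chord <- sqrt(sum((b - a)^2))
    u <- (b - a) / chord
    arc_len <- function(h) {
      r <- (chord^2 / 4 + h^2) / (2 * h)
      2 * r * atan2(chord / 2, r - h)
    }
    target <- (loop_length + 1L) * 3.2
    h <- loop_height
    if (arc_len(h) < target)
      h <- stats::uniroot(function(x) arc_len(x) - target,
                          c(h, 10 * target))$root
    r <- (chord^2 / 4 + h^2) / (2 * h)
    theta <- atan2(chord / 2, r - h)
    mid <- (a + b) / 2
    o <- mid - (r - h) * w
    t <- seq_len(loop_length)
    psi <- -theta + 2 * theta * t / (loop_length + 1L)
    outer(sin(psi), u * r) + outer(cos(psi), w * r) +
      matrix(o, loop_length, 3L, byrow = TRUE)
  }
  for (h in seq_len(n_helices)) {
    hp <- helix_pts(h)
    coords <- rbind(coords, hp)
    segments <- c(segments, rep("helix", residues_per_helix))
    if (h < n_helices) {
      np <- helix_pts(h + 1L)
      a <- hp[residues_per_helix, ]
      b <- np[1L, ]
      w <- if (a[3] > height / 2) c(0, 0, 1) else c(0, 0, -1)
      coords <- rbind(coords, arc_pts(a, b, w))
      segments <- c(segments, rep("loop", loop_length))
    }
  }
  if (min(stats::dist(coords)) < 2.0)
    stop("bundle geometry collision: minimum inter-CA distance below 2.0 A")
  n <- nrow(coords)
  set.seed(seed)
  structure_record(member_id = "BUNDLE", chain_id = "A",
                   residue_ids = as.character(seq_len(n)),
                   residue_codes = sample(AA20, n, replace = TRUE),
                   ca_coords = coords, segments = segments)
}

#' Seeded random orthonormal mode set
#'
#' @param n_dim dimension (3N).
#' @param k number of modes.
#' @param seed integer seed.
#' @param orthogonal_to optional matrix of columns the modes must also be
#'   orthogonal to.
#' @return n_dim x k matrix with orthonormal columns.
#' @export
random_orthonormal_modes <- function(n_dim, k, seed,
                                     orthogonal_to = NULL) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_dim * k), n_dim, k)
  if (!is.null(orthogonal_to)) {
    q0 <- qr.Q(qr(as.matrix(orthogonal_to)))
    x <- x - q0 %*% crossprod(q0, x)
  }
  qr.Q(qr(x))
}

#' Segment-localized collective shift mode
#'
#' A smooth (raised-sine) displacement of a contiguous residue segment
#' along one spatial axis, orthogonalized against the three uniform
#' translations and normalized. Mimics the shape of a localized
#' loop-opening motion (an "ICL3-like" signal).
#'
#' @param n_positions total residues N.
#' @param segment integer vector of segment positions (contiguous).
#' @param axis 3-vector displacement direction (default x).
#' @return unit 3N-vector (residue-major layout).
#' @export
segment_shift_mode <- function(n_positions, segment, axis = c(1, 0, 0)) {
  if (min(segment) < 1L || max(segment) > n_positions)
    stop("segment must lie within the template length")
  axis <- axis / sqrt(sum(axis^2))
  w <- sin(pi * seq_along(segment) / (length(segment) + 1L))
  v <- matrix(0, n_positions, 3L)
  v[segment, ] <- outer(w, axis)
  v <- flatten_coords(v)
  # project out rigid translations
  for (d in 1:3) {
    tvec <- rep(0, 3L * n_positions)
    tvec[seq(d, 3L * n_positions, by = 3L)] <- 1 / sqrt(n_positions)
    v <- v - sum(v * tvec) * tvec
  }
  v / sqrt(sum(v^2))
}

new_synthetic_ensemble <- function(template, coords, labels, member_ids) {
  m <- dim(coords)[1]
  n <- dim(coords)[2]
  structure(list(reference_id = template$member_id,
                 member_ids = member_ids,
                 n_positions = n,
                 coords = coords,
                 mask = matrix(TRUE, m, n),
                 occupancy = rep(1, n),
                 labels = labels,
                 species = rep("synthetic", m),
                 positions = template$residue_ids,
                 segments = template$segments,
                 superposed = TRUE,
                 imputed = TRUE,
                 drop_log = data.frame(member_id = character(0),
                                       stage = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)),
            class = "mapped_ensemble")
}

#' Planted-mode synthetic ensemble
#'
#' Member m is `template + sum_k z_mk sqrt(variance_k) mode_k + noise`,
#' with z and the isotropic noise standard normal (seeded). The
#' linear-Gaussian displacement model makes the PCA ground truth exact:
#' the population covariance is `sum_k variance_k mode_k mode_k^T +
#' noise_sd^2 I`.
#'
#' @param template a [structure_record()].
#' @param modes 3N x k matrix of mutually orthonormal columns (checked at
#'   1e-8).
#' @param variances positive, non-increasing mode variances (A^2).
#' @param noise_sd isotropic per-coordinate noise SD (A).
#' @param n_members ensemble size M.
#' @param seed integer seed.
#' @param member_prefix id prefix (default `"SYN"`).
#' @return a `mapped_ensemble` (occupancy 1, labels `"none"`, already in a
#'   common frame so flagged superposed and imputed).
#' @export
plant_ensemble <- function(template, modes, variances, noise_sd = 0,
                           n_members, seed, member_prefix = "SYN") {
  modes <- as.matrix(modes)
  n3 <- 3L * length(template)
  if (nrow(modes) != n3) stop("modes must be 3N-vectors for the template")
  k <- ncol(modes)
  if (length(variances) != k) stop("one variance per mode required")
  if (any(variances < 0) || is.unsorted(rev(variances)))
    stop("variances must be nonnegative and non-increasing")
  if (k > 0L) {
    gram <- crossprod(modes)
    if (max(abs(gram - diag(k))) > 1e-8)
      stop("modes must be mutually orthonormal (1e-8)")
  }
  base <- flatten_coords(template$ca_coords)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_members * k), n_members, k)
  disp <- if (k > 0L) z %*% (t(modes) * sqrt(variances)) else
    matrix(0, n_members, n3)
  if (noise_sd > 0)
    disp <- disp + matrix(stats::rnorm(n_members * n3, sd = noise_sd),
                          n_members, n3)
  coords <- array(NA_real_, dim = c(n_members, length(template), 3L))
  for (m in seq_len(n_members))
    coords[m, , ] <- unflatten_coords(base + disp[m, ])
  new_synthetic_ensemble(template, coords,
                         labels = rep("none", n_members),
                         member_ids = sprintf("%s%03d", member_prefix,
                                              seq_len(n_members)))
}

#' Labeled two-state synthetic ensemble
#'
#' Two equal-size groups differing by a shift of `shift_amplitude` along a
#' segment-localized collective mode: the `"active"` group is displaced by
#' +amplitude/2 and the `"inactive"` group by -amplitude/2. Both groups
#' share within-state variance along the shift mode plus optional
#' background collective modes and isotropic noise; the inactive group
#' additionally receives `segment_noise_sd` of extra isotropic noise on
#' the segment, emulating the larger conformational disorder of inactive
#' receptors in the loop region.
#'
#' @param template a [structure_record()].
#' @param segment contiguous integer positions carrying the shift (the
#'   "ICL3-like" region).
#' @param m_per_state members per state.
#' @param shift_amplitude total between-state shift along the mode (A,
#'   default 6).
#' @param within_state_sd SD of within-state motion along the shift mode
#'   (A, default 0.5).
#' @param background_variances variances (A^2) of additional random
#'   orthonormal background modes (default `c(2, 1)`).
#' @param noise_sd isotropic noise SD for all members (A, default 0.3).
#' @param segment_noise_sd extra segment-coordinate noise SD for the
#'   inactive group (A, default 1.5).
#' @param shift_axis displacement direction of the shift mode.
#' @param seed integer seed.
#' @return a labeled `mapped_ensemble`; the planted ground truth (shift
#'   mode, segment, variances) is attached as attribute `"ground_truth"`.
#' @export
plant_two_state <- function(template, segment, m_per_state,
                            shift_amplitude = 6, within_state_sd = 0.5,
                            background_variances = c(2, 1),
                            noise_sd = 0.3, segment_noise_sd = 1.5,
                            shift_axis = c(1, 0, 0), seed) {
  if (missing(seed)) stop("a seed is required")
  if (shift_amplitude < 0 || segment_noise_sd < 0)
    stop("amplitudes must be nonnegative")
  n <- length(template)
  n3 <- 3L * n
  shift <- segment_shift_mode(n, segment, shift_axis)
  nb <- length(background_variances)
  bg <- if (nb > 0)
    random_orthonormal_modes(n3, nb, seed = seed + 1L,
                             orthogonal_to = shift) else NULL
  base <- flatten_coords(template$ca_coords)
  m_total <- 2L * m_per_state
  labels <- rep(c("active", "inactive"), each = m_per_state)
  seg_coord_idx <- as.vector(vapply(segment,
                                    function(p) 3L * (p - 1L) + 1:3,
                                    integer(3)))
  set.seed(seed)
  coords <- array(NA_real_, dim = c(m_total, n, 3L))
  for (m in seq_len(m_total)) {
    x <- base +
      (if (labels[m] == "active") 0.5 else -0.5) * shift_amplitude * shift +
      stats::rnorm(1, sd = within_state_sd) * shift
    if (nb > 0)
      x <- x + bg %*% (stats::rnorm(nb) * sqrt(background_variances))
    if (noise_sd > 0) x <- x + stats::rnorm(n3, sd = noise_sd)
    if (labels[m] == "inactive" && segment_noise_sd > 0)
      x[seg_coord_idx] <- x[seg_coord_idx] +
        stats::rnorm(length(seg_coord_idx), sd = segment_noise_sd)
    coords[m, , ] <- unflatten_coords(x)
  }
  out <- new_synthetic_ensemble(template, coords, labels,
                                sprintf("TS%03d", seq_len(m_total)))
  attr(out, "ground_truth") <- list(shift_mode = shift, segment = segment,
                                    shift_amplitude = shift_amplitude,
                                    background_variances = background_variances,
                                    noise_sd = noise_sd,
                                    segment_noise_sd = segment_noise_sd)
  out
}

#' Sequences at exact target identities to a reference
#'
#' Each output differs from the reference at a seeded random position set
#' whose size is `round((1 - identity) * length)`, substituting a
#' different residue at each chosen position, so the realized identity
#' hits the target exactly (to the nearest residue count).
#'
#' @param reference one-letter reference sequence.
#' @param target_identities numeric vector of identities in (0, 1]; values
#'   below `1/nchar(reference)` are unrealizable and error.
#' @param seed integer seed.
#' @return character vector of mutated sequences.
#' @export
mutate_sequences <- function(reference, target_identities, seed) {
  l <- nchar(reference)
  if (any(target_identities <= 0) || any(target_identities > 1))
    stop("target identities must lie in (0, 1]")
  if (any(target_identities < 1 / l))
    stop(sprintf("target identity below 1/length = %.4g is unrealizable",
                 1 / l))
  ref <- strsplit(reference, "")[[1]]
  set.seed(seed)
  vapply(target_identities, function(t) {
    n_sub <- round((1 - t) * l)
    s <- ref
    if (n_sub > 0) {
      pos <- sample.int(l, n_sub)
      for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1L)
    }
    paste(s, collapse = "")
  }, character(1))
}

random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rotation = q, translation = stats::rnorm(3, sd = 20))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits a self-contained two-state study: a helix-bundle template, a
#' labeled two-state ensemble written as one PDB file per member (each
#' member given a random rigid motion, a mutated sequence at a controlled
#' identity to the template, and optional random residue omissions), a
#' metadata CSV, and a ground-truth JSON (segment, shift amplitude, seed).
#'
#' @param dir output directory (created if needed).
#' @param m_per_state members per state (default 8).
#' @param identity_range sequence identity range to the template from
#'   which member identities are drawn (default `c(0.75, 0.95)`).
#' @param omit_rate per-residue probability of omitting a residue from a
#'   member's PDB (default 0.02; the template member stays complete).
#' @param seed integer seed controlling everything.
#' @param ... passed to [plant_two_state()] (e.g. `shift_amplitude`).
#' @return invisibly, a list with `dir`, `metadata` path, `pdb_files`,
#'   `ground_truth` path, and the template record.
#' @export
write_synthetic_dataset <- function(dir, m_per_state = 8L,
                                    identity_range = c(0.75, 0.95),
                                    omit_rate = 0.02, seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  template <- make_bundle(seed = seed)
  n <- length(template)
  segment <- which(template$segments == "loop")
  # central loop only: an "ICL3-like" contiguous stretch
  runs <- split(segment, cumsum(c(1, diff(segment) != 1)))
  segment <- runs[[ceiling(length(runs) / 2)]]
  ens <- plant_two_state(template, segment = segment,
                         m_per_state = m_per_state, seed = seed + 10L, ...)
  m_total <- length(ens$member_ids)
  set.seed(seed + 20L)
  idents <- stats::runif(m_total, identity_range[1], identity_range[2])
  seqs <- mutate_sequences(record_sequence(template), idents,
                           seed = seed + 30L)
  set.seed(seed + 40L)
  pdb_files <- character(m_total)
  for (m in seq_len(m_total)) {
    keep <- if (m == 1L) rep(TRUE, n) else stats::runif(n) > omit_rate
    mv <- random_rigid_motion()
    xyz <- sweep(matrix(ens$coords[m, keep, ], ncol = 3L) %*%
                   t(mv$rotation), 2, mv$translation, "+")
    rec <- structure_record(member_id = ens$member_ids[m], chain_id = "A",
                            residue_ids = template$residue_ids[keep],
                            residue_codes = strsplit(seqs[m], "")[[1]][keep],
                            ca_coords = xyz,
                            state_label = ens$labels[m])
    pdb_files[m] <- file.path(dir, paste0(ens$member_ids[m], ".pdb"))
    write_record_pdb(rec, pdb_files[m])
  }
  meta <- data.frame(member_id = ens$member_ids, chain_id = "A",
                     species = ens$species, state_label = ens$labels,
                     gene_code = "SYNTH", stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(segment = range(segment),
                            shift_amplitude =
                              attr(ens, "ground_truth")$shift_amplitude,
                            seed = seed),
                       gt_path, auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, metadata = meta_path, pdb_files = pdb_files,
                 ground_truth = gt_path, template = template,
                 segment = segment))
}
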