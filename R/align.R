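# Sequence-guided mapping onto a reference and rigid-body superposition.

#' Map a member onto the reference by global sequence alignment
#'
#' Needleman-Wunsch global alignment of the two one-letter sequences with
#' BLOSUM62 scores and affine gap penalties. Aligned non-gap columns
#' become index pairs; the identity fraction is computed over those
#' columns. Members whose identity falls below `min_identity` are flagged
#' unmappable (with a warning) rather than erroring, so callers can log
#' and drop them.
#'
#' @param record,reference [structure_record()] objects.
#' @param min_identity identity floor below which the member is flagged
#'   unmappable (default 0.20).
#' @param gap_open,gap_extend affine gap penalties (default 10 and 1).
#' @return an `alignment_map`: list with `member_id`, `reference_id`,
#'   `pairs` (two-column integer matrix: member index, reference index),
#'   `identity_fraction`, `mappable`.
#' @export
map_to_reference <- function(record, reference, min_identity = 0.20,
                             gap_open = 10, gap_extend = 1) {
  if (length(record) == 0L || length(reference) == 0L)
    stop("records must be nonempty")
  aln <- aligned_pair_strings(record_sequence(record),
                              record_sequence(reference),
                              gap_open, gap_extend)
  pairs <- gapped_to_pairs(aln[1], aln[2])
  ident <- if (nrow(pairs) == 0L) 0 else
    mean(substring(aln[1], pairs[, "col"], pairs[, "col"]) ==
         substring(aln[2], pairs[, "col"], pairs[, "col"]))
  mappable <- nrow(pairs) > 0L && ident >= min_identity
  if (!mappable)
    warning(sprintf("member '%s' unmappable: identity %.3f below %.3f",
                    record$member_id, ident, min_identity))
  structure(list(member_id = record$member_id,
                 reference_id = reference$member_id,
                 pairs = pairs[, c("a", "b"), drop = FALSE],
                 identity_fraction = ident,
                 mappable = mappable),
            class = "alignment_map")
}

# global alignment -> the two gapped strings
aligned_pair_strings <- function(seq_a, seq_b, gap_open = 10, gap_extend = 1) {
  pa <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  c(as.character(Biostrings::pattern(pa)),
    as.character(Biostrings::subject(pa)))
}

# walk the aligned columns; both-residue columns give index pairs
gapped_to_pairs <- function(ga, gb) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  both <- which(ca != "-" & cb != "-")
  cbind(a = ia[both], b = ib[both], col = both)
}

#' Optimal weighted rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation `R` (det = +1, reflections excluded) and
#' translation `t` minimising the weighted RMSD of `R x + t` against the
#' target point set, via singular value decomposition of the weighted
#' cross-covariance.
#'
#' @param mobile,target numeric n x 3 matrices, n >= 3.
#' @param weights nonnegative weights, not all zero (default all 1).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (weighted minimum, Angstrom).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3L || ncol(target) != 3L)
    stop("point sets must be equal-length n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative, not all zero, one per point")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  xm <- sweep(mobile, 2, cm)
  xt <- sweep(target, 2, ct)
  # degeneracy: weighted mobile points (near-)collinear -> rotation ambiguous
  sv <- svd(xm * sqrt(w))$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))
    stop("degenerate point set: weighted points are collinear")
  h <- crossprod(xm * w, xt)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ct - as.vector(rot %*% cm)
  moved <- sweep(mobile %*% t(rot), 2, tr, "+")
  rmsd <- sqrt(sum(w * rowSums((moved - target)^2)))
  list(rotation = rot, translation = tr, rmsd = rmsd)
}

apply_rigid <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Build a mapped ensemble on the reference position set
#'
#' Maps every record onto the reference (the reference itself is added as
#' a member when absent), drops unmappable members, then filters
#' reference positions by occupancy and members by coverage of the
#' retained positions. Filtering iterates until stable so that every
#' retained position keeps occupancy at or above the threshold.
#'
#' @param records list of [structure_record()].
#' @param reference the reference [structure_record()].
#' @param occupancy_threshold minimum fraction of members resolving a
#'   position for it to be retained (default 0.9).
#' @param coverage_floor minimum fraction of retained positions a member
#'   must resolve (default 0.8).
#' @param min_identity identity floor passed to [map_to_reference()].
#' @return a `mapped_ensemble`: M members x N reference positions x 3
#'   coordinates with `mask`, `occupancy`, labels, species, and a
#'   `drop_log` data.frame (member_id, stage, reason).
#' @export
build_mapped_ensemble <- function(records, reference,
                                  occupancy_threshold = 0.9,
                                  coverage_floor = 0.8,
                                  min_identity = 0.20) {
  stop_if_not_scalar_number(occupancy_threshold, "occupancy_threshold", 0, 1)
  ids <- vapply(records, function(r) r$member_id, character(1))
  if (!reference$member_id %in% ids) {
    records <- c(list(reference), records)
    ids <- c(reference$member_id, ids)
  }
  n_ref <- length(reference)
  drop_log <- data.frame(member_id = character(0), stage = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  keep <- logical(length(records))
  maps <- vector("list", length(records))
  for (m in seq_along(records)) {
    am <- withCallingHandlers(
      map_to_reference(records[[m]], reference, min_identity = min_identity),
      warning = function(w) invokeRestart("muffleWarning"))
    maps[[m]] <- am
    keep[m] <- am$mappable
    if (!am$mappable)
      drop_log <- rbind(drop_log, data.frame(
        member_id = ids[m], stage = "mapping", reason = "unmappable",
        stringsAsFactors = FALSE))
  }
  records <- records[keep]; maps <- maps[keep]; ids <- ids[keep]
  if (length(records) < 2L) stop("fewer than 2 mappable members")

  m_n <- length(records)
  coords <- array(NA_real_, dim = c(m_n, n_ref, 3L))
  mask <- matrix(FALSE, m_n, n_ref)
  for (m in seq_len(m_n)) {
    p <- maps[[m]]$pairs
    mask[m, p[, "b"]] <- TRUE
    coords[m, p[, "b"], ] <- records[[m]]$ca_coords[p[, "a"], , drop = FALSE]
  }

  pos_keep <- rep(TRUE, n_ref)
  mem_keep <- rep(TRUE, m_n)
  repeat {
    occ <- colSums(mask[mem_keep, , drop = FALSE]) / sum(mem_keep)
    new_pos <- pos_keep & (occ >= occupancy_threshold)
    cov <- rowSums(mask[, new_pos, drop = FALSE]) / max(1L, sum(new_pos))
    new_mem <- mem_keep & (cov >= coverage_floor)
    if (identical(new_pos, pos_keep) && identical(new_mem, mem_keep)) break
    pos_keep <- new_pos; mem_keep <- new_mem
    if (sum(mem_keep) < 2L) stop("fewer than 2 members survive filtering")
  }
  dropped <- which(!mem_keep)
  if (length(dropped) > 0L)
    drop_log <- rbind(drop_log, data.frame(
      member_id = ids[dropped], stage = "occupancy_filter",
      reason = "low_coverage", stringsAsFactors = FALSE))

  labels <- vapply(records, function(r) r$state_label, character(1))
  species <- vapply(records, function(r) r$species, character(1))
  coords <- coords[mem_keep, pos_keep, , drop = FALSE]
  mask <- mask[mem_keep, pos_keep, drop = FALSE]
  occupancy <- colMeans(mask)
  structure(list(reference_id = reference$member_id,
                 member_ids = ids[mem_keep],
                 n_positions = sum(pos_keep),
                 coords = coords,
                 mask = mask,
                 occupancy = occupancy,
                 labels = labels[mem_keep],
                 species = species[mem_keep],
                 positions = reference$residue_ids[pos_keep],
                 segments = if (!is.null(reference$segments))
                   reference$segments[pos_keep] else NULL,
                 superposed = FALSE,
                 imputed = FALSE,
                 drop_log = drop_log),
            class = "mapped_ensemble")
}

#' @export
print.mapped_ensemble <- function(x, ...) {
  cat(sprintf("<mapped_ensemble> %d members x %d positions (ref %s)\n",
              length(x$member_ids), x$n_positions, x$reference_id))
  cat(sprintf(" occupancy: min %.2f  superposed: %s  imputed: %s\n",
              min(x$occupancy), x$superposed, x$imputed))
  if (nrow(x$drop_log) > 0L)
    cat(sprintf(" dropped members: %d (see $drop_log)\n", nrow(x$drop_log)))
  invisible(x)
}

masked_mean_coords <- function(coords, mask) {
  n <- dim(coords)[2]
  mu <- matrix(NA_real_, n, 3L)
  for (d in 1:3) {
    xm <- coords[, , d]
    xm[!mask] <- 0
    mu[, d] <- colSums(xm) / pmax(colSums(mask), 1L)
  }
  mu
}

#' Iterative superposition of a mapped ensemble onto its running mean
#'
#' Each member is first Kabsch-superposed onto the reference member over
#' the positions both resolve, then repeatedly onto the masked ensemble
#' mean until the mean moves by less than `tol` (RMSD, Angstrom) or
#' `max_iter` is reached. `tol = Inf` yields a single pass. After
#' convergence, unresolved coordinates (mask `FALSE`) are imputed with
#' the ensemble mean at that position (the mask is retained for
#' reporting), so downstream PCA and GNM operate on a single complete
#' position set.
#'
#' @param ensemble a [build_mapped_ensemble()] result.
#' @param tol convergence tolerance on the mean shift (Angstrom).
#' @param max_iter maximum mean-refinement passes.
#' @return the ensemble with transformed coordinates, `superposed = TRUE`,
#'   `imputed = TRUE`, plus `mean_coords` and `mean_shifts`.
#' @export
iterative_superpose <- function(ensemble, tol = 1e-4, max_iter = 10L) {
  stopifnot(inherits(ensemble, "mapped_ensemble"))
  m_n <- length(ensemble$member_ids)
  coords <- ensemble$coords
  mask <- ensemble$mask
  ref_idx <- match(ensemble$reference_id, ensemble$member_ids)
  if (is.na(ref_idx)) ref_idx <- 1L

  superpose_all <- function(coords, target, target_mask = NULL) {
    for (m in seq_len(m_n)) {
      sel <- mask[m, ]
      if (!is.null(target_mask)) sel <- sel & target_mask
      if (sum(sel) < 3L)
        stop(sprintf("member '%s': fewer than 3 shared resolved positions",
                     ensemble$member_ids[m]))
      mob <- matrix(coords[m, sel, ], ncol = 3L)
      fit <- tryCatch(
        kabsch_superpose(mob, target[sel, , drop = FALSE]),
        error = function(e) stop(sprintf("member '%s': %s",
                                         ensemble$member_ids[m],
                                         conditionMessage(e)), call. = FALSE))
      res <- mask[m, ]
      coords[m, res, ] <- apply_rigid(matrix(coords[m, res, ], ncol = 3L), fit)
    }
    coords
  }

  # pass 0: onto the reference member
  coords <- superpose_all(coords, coords[ref_idx, , ], mask[ref_idx, ])
  mu <- masked_mean_coords(coords, mask)
  shifts <- numeric(0)
  for (it in seq_len(max_iter)) {
    coords <- superpose_all(coords, mu)
    mu_new <- masked_mean_coords(coords, mask)
    shift <- sqrt(mean(rowSums((mu_new - mu)^2)))
    shifts <- c(shifts, shift)
    mu <- mu_new
    if (shift < tol) break
    if (is.infinite(tol)) break
  }

  for (m in seq_len(m_n)) {
    miss <- !mask[m, ]
    if (any(miss)) coords[m, miss, ] <- mu[miss, , drop = FALSE]
  }
  ensemble$coords <- coords
  ensemble$mean_coords <- mu
  ensemble$mean_shifts <- shifts
  ensemble$superposed <- TRUE
  ensemble$imputed <- TRUE
  ensemble
}
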