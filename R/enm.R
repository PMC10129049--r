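# Gaussian and Anisotropic Network Models on C-alpha coordinates.

#' Build a Gaussian Network Model
#'
#' Kirchhoff (contact-graph Laplacian) construction: Gamma_ij = -gamma for
#' residue pairs within `cutoff`, Gamma_ii = minus the row sum of
#' off-diagonals. Full symmetric eigendecomposition; eigenvalues below
#' `zero_tol * max(lambda)` are treated as zero modes and removed with
#' their vectors. A connected contact graph has exactly one zero mode;
#' more than one signals a disconnected graph and raises an error.
#'
#' @param coords numeric N x 3 matrix (Angstrom), N >= 3.
#' @param cutoff contact distance cutoff (Angstrom, default 10).
#' @param gamma uniform spring constant (arbitrary units, default 1).
#' @param zero_tol relative tolerance for zero modes (default 1e-8).
#' @return a `gnm` object: `kirchhoff`, `eigenvalues` (ascending, nonzero
#'   modes), `eigenvectors` (N x K, orthonormal columns), `cutoff`,
#'   `gamma`.
#' @export
build_gnm <- function(coords, cutoff = 10, gamma = 1, zero_tol = 1e-8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("at least 3 residues are required")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  contact <- d > 0 & d <= cutoff
  k <- -gamma * contact
  diag(k) <- -rowSums(k)
  eg <- eigen(k, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, rev(seq_len(n)), drop = FALSE]
  zero <- vals < zero_tol * max(vals)
  if (sum(zero) != 1L)
    stop(sprintf(paste("contact graph is disconnected (%d zero modes);",
                       "increase the cutoff"), sum(zero)))
  structure(list(kirchhoff = k,
                 cutoff = cutoff, gamma = gamma,
                 eigenvalues = vals[!zero],
                 eigenvectors = vecs[, !zero, drop = FALSE],
                 n = n),
            class = "gnm")
}

#' @export
print.gnm <- function(x, ...) {
  cat(sprintf("<gnm> %d residues, cutoff %.1f A, gamma %g: %d nonzero modes\n",
              x$n, x$cutoff, x$gamma, length(x$eigenvalues)))
  cat(sprintf(" slowest eigenvalues: %s\n",
              paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Mode-subset mean-square fluctuations from a GNM
#'
#' MSF_i = sum over the selected modes of u_k[i]^2 / lambda_k, in units of
#' 1/gamma (the kT/gamma prefactor is omitted; profiles are relative).
#' Mode indices are 1-based over the nonzero modes, mode 1 being the
#' slowest.
#'
#' @param model a [build_gnm()] model.
#' @param modes integer vector of mode indices; `NULL` means all modes.
#' @return numeric vector of N nonnegative MSFs.
#' @export
gnm_msf <- function(model, modes = NULL) {
  stopifnot(inherits(model, "gnm"))
  k <- length(model$eigenvalues)
  if (is.null(modes)) modes <- seq_len(k)
  if (length(modes) == 0L) stop("mode subset must be nonempty")
  if (any(modes < 1L) || any(modes > k))
    stop(sprintf("mode indices must lie in 1..%d", k))
  u <- model$eigenvectors[, modes, drop = FALSE]
  as.vector(u^2 %*% (1 / model$eigenvalues[modes]))
}

#' Build an Anisotropic Network Model
#'
#' Standard ANM super-element Hessian: each contact pair (i, j) within
#' `cutoff` contributes the 3 x 3 block `-gamma * (d d^T) / |d|^2` (d the
#' separation vector) to H_ij, and diagonal blocks are the negative sums
#' of the off-diagonal blocks in their row. Six near-zero eigenvalues
#' (rigid-body translations/rotations) are removed; any other count
#' signals degenerate geometry or a disconnected network and errors.
#'
#' @param coords numeric N x 3 matrix, N >= 2, not collinear for N >= 3
#'   (a two-bead dimer is admitted as the closed-form limiting case: five
#'   rigid-body zero modes and one bond-stretch mode of eigenvalue
#'   2 gamma).
#' @param cutoff contact cutoff (Angstrom, default 15).
#' @param gamma spring constant (default 1).
#' @param zero_tol relative zero-mode tolerance (default 1e-8).
#' @return an `anm` object: `hessian` (3N x 3N), `eigenvalues` (ascending,
#'   six zero modes removed), `eigenvectors` (3N x K, residue-major
#'   layout x1,y1,z1,...), `cutoff`, `gamma`.
#' @export
build_anm <- function(coords, cutoff = 15, gamma = 1, zero_tol = 1e-8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("at least 2 residues are required")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n_rigid <- if (n == 2L) 5L else 6L
  d <- as.matrix(stats::dist(coords))
  h <- matrix(0, 3L * n, 3L * n)
  idx <- function(i) (3L * (i - 1L) + 1L):(3L * i)
  pairs <- which(upper.tri(d) & d > 0 & d <= cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop("no contacts within cutoff")
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    dv <- coords[j, ] - coords[i, ]
    blk <- -gamma * tcrossprod(dv) / sum(dv^2)
    h[idx(i), idx(j)] <- blk
    h[idx(j), idx(i)] <- blk
    h[idx(i), idx(i)] <- h[idx(i), idx(i)] - blk
    h[idx(j), idx(j)] <- h[idx(j), idx(j)] - blk
  }
  eg <- eigen(h, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, rev(seq_len(3L * n)), drop = FALSE]
  zero <- vals < zero_tol * max(vals)
  if (sum(zero) != n_rigid)
    stop(sprintf(paste("expected %d zero modes, found %d:",
                       "degenerate geometry or disconnected network"),
                 n_rigid, sum(zero)))
  structure(list(hessian = h,
                 cutoff = cutoff, gamma = gamma,
                 eigenvalues = vals[!zero],
                 eigenvectors = vecs[, !zero, drop = FALSE],
                 n = n),
            class = "anm")
}

#' @export
print.anm <- function(x, ...) {
  cat(sprintf("<anm> %d residues, cutoff %.1f A, gamma %g: %d nonzero modes\n",
              x$n, x$cutoff, x$gamma, length(x$eigenvalues)))
  cat(sprintf(" slowest eigenvalues: %s\n",
              paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Correlation cosine between an ANM mode and a principal component
#'
#' Absolute inner product of the two (unit-normalized) 3N-vectors. The
#' absolute value is used because eigenvector signs are arbitrary.
#'
#' @param anm_mode,pc_component numeric vectors of equal length 3N; when
#'   the ANM and the ensemble differ in residue coverage, restrict both to
#'   the common residue set (and renormalize) before calling.
#' @return correlation cosine in [0, 1].
#' @export
anm_pc_correlation <- function(anm_mode, pc_component) {
  if (length(anm_mode) != length(pc_component))
    stop("vectors must have equal dimension (common residue set)")
  a <- anm_mode / sqrt(sum(anm_mode^2))
  b <- pc_component / sqrt(sum(pc_component^2))
  min(1, abs(sum(a * b)))
}
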