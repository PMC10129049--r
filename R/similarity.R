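# Pairwise sequence / structure / dynamics similarity matrices.

#' Construct a labelled pairwise matrix
#'
#' @param member_ids character vector of M member identifiers.
#' @param values M x M numeric matrix.
#' @param metric one of `"seq_identity"`, `"rmsd"`, `"spectral_distance"`.
#' @return a `distance_matrix` object. Symmetry and the metric's diagonal
#'   convention (1 for identity, 0 otherwise) are asserted on construction.
#' @export
distance_matrix <- function(member_ids, values, metric) {
  metric <- match.arg(metric, c("seq_identity", "rmsd", "spectral_distance"))
  values <- as.matrix(values)
  m <- length(member_ids)
  if (!all(dim(values) == c(m, m))) stop("values must be M x M")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("matrix must be symmetric")
  dtarget <- if (metric == "seq_identity") 1 else 0
  if (max(abs(diag(values) - dtarget)) > 1e-8)
    stop(sprintf("diagonal must equal %g for metric '%s'", dtarget, metric))
  rng <- range(values, na.rm = TRUE)
  if (metric == "seq_identity" && (rng[1] < -1e-12 || rng[2] > 1 + 1e-12))
    stop("sequence identities must lie in [0, 1]")
  if (metric == "rmsd" && rng[1] < -1e-9)
    stop("RMSD values must be nonnegative")
  if (metric == "spectral_distance" &&
      (rng[1] < -1e-9 || rng[2] > pi / 2 + 1e-9))
    stop("spectral distances must lie in [0, pi/2]")
  dimnames(values) <- list(member_ids, member_ids)
  structure(list(member_ids = as.character(member_ids),
                 values = values, metric = metric),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s: %d x %d\n", x$metric,
              length(x$member_ids), length(x$member_ids)))
  off <- x$values[upper.tri(x$values)]
  if (length(off))
    cat(sprintf(" off-diagonal range: [%.4g, %.4g]%s\n",
                min(off, na.rm = TRUE), max(off, na.rm = TRUE),
                if (anyNA(off)) sprintf(" (%d missing)", sum(is.na(off))) else ""))
  invisible(x)
}

# identity fraction over aligned non-gap columns of one pairwise alignment
pairwise_identity <- function(seq_a, seq_b, gap_open = 10, gap_extend = 1) {
  aln <- aligned_pair_strings(seq_a, seq_b, gap_open, gap_extend)
  ca <- strsplit(aln[1], "")[[1]]
  cb <- strsplit(aln[2], "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(NA_real_)
  mean(ca[both] == cb[both])
}

#' Pairwise sequence-identity matrix
#'
#' Entry (a, b) is the fraction of identical residues over the aligned
#' non-gap columns of the global pairwise alignment of a and b (the
#' normalized Hamming distance is `1 - identity`). Pairs with no aligned
#' columns are marked missing with a warning.
#'
#' @param x list of [structure_record()] objects, or a named character
#'   vector of one-letter sequences.
#' @param member_ids identifiers; inferred from records / names when `NULL`.
#' @return a [distance_matrix()] with metric `"seq_identity"`.
#' @export
sequence_identity_matrix <- function(x, member_ids = NULL) {
  if (is.list(x) && inherits(x[[1]], "structure_record")) {
    seqs <- vapply(x, record_sequence, character(1))
    if (is.null(member_ids))
      member_ids <- vapply(x, function(r) r$member_id, character(1))
  } else {
    seqs <- as.character(x)
    if (is.null(member_ids))
      member_ids <- names(x) %||% paste0("seq", seq_along(x))
  }
  m <- length(seqs)
  v <- diag(1, m)
  if (m > 1L) for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
    f <- pairwise_identity(seqs[i], seqs[j])
    if (is.na(f))
      warning(sprintf("pair (%s, %s) unalignable; entry set missing",
                      member_ids[i], member_ids[j]))
    v[i, j] <- v[j, i] <- f
  }
  distance_matrix(member_ids, v, "seq_identity")
}

#' Pairwise RMSD matrix after fresh pairwise superposition
#'
#' Entry (a, b) is the RMSD over positions resolved in both members after
#' Kabsch superposition of that pair alone (imputed coordinates are never
#' used). Pairs sharing fewer than 3 positions are marked missing.
#'
#' @param ensemble a superposed [iterative_superpose()] ensemble (fresh
#'   per-pair superposition makes the result independent of the ensemble
#'   frame; the mask identifies genuinely resolved positions).
#' @return a [distance_matrix()] with metric `"rmsd"`.
#' @export
rmsd_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "mapped_ensemble"))
  m <- length(ensemble$member_ids)
  v <- matrix(0, m, m)
  if (m > 1L) for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
    sel <- ensemble$mask[i, ] & ensemble$mask[j, ]
    if (sum(sel) < 3L) {
      warning(sprintf("pair (%s, %s): fewer than 3 shared positions",
                      ensemble$member_ids[i], ensemble$member_ids[j]))
      v[i, j] <- v[j, i] <- NA_real_
      next
    }
    fit <- kabsch_superpose(matrix(ensemble$coords[i, sel, ], ncol = 3L),
                            matrix(ensemble$coords[j, sel, ], ncol = 3L))
    v[i, j] <- v[j, i] <- fit$rmsd
  }
  distance_matrix(ensemble$member_ids, v, "rmsd")
}

#' Cluster ordering of a pairwise matrix
#'
#' Leaf order of average-linkage hierarchical clustering on the distance
#' form of the matrix (`1 - identity` for sequence identity; values as-is
#' otherwise). The degenerate all-equal-distances case returns the input
#' order, so ties never reshuffle members. Reusing the sequence-based
#' order for the structure and dynamics heatmaps gives the common
#' "same order in all panels" convention.
#'
#' @param dm a [distance_matrix()]; must be complete (no missing entries).
#' @return integer permutation of member indices.
#' @export
cluster_order <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (anyNA(dm$values)) stop("matrix has missing entries; cannot cluster")
  m <- length(dm$member_ids)
  if (m == 1L) return(1L)
  d <- if (dm$metric == "seq_identity") 1 - dm$values else dm$values
  off <- d[upper.tri(d)]
  if (max(off) - min(off) < 1e-12) return(seq_len(m))
  stats::hclust(stats::as.dist(d), method = "average")$order
}
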