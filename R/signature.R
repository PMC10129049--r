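# Per-member GNM spectra, mode matching, spectral overlap, and
# mode-regime signature profiles.

#' Construct a mode spectrum
#'
#' Holds the nonzero-mode eigendecomposition of one member's GNM, plus
#' (after [match_modes()]) the permutation aligning its modes to a
#' reference spectrum.
#'
#' @param member_id identifier.
#' @param eigenvalues ascending positive eigenvalues (zero modes removed).
#' @param eigenvectors N x K matrix, orthonormal columns.
#' @param matched_order,match_signs filled by [match_modes()]:
#'   `matched_order[r]` is the local mode index matched to reference mode
#'   r; `match_signs[r]` is the sign making that overlap positive.
#' @return a `mode_spectrum` object.
#' @export
mode_spectrum <- function(member_id, eigenvalues, eigenvectors,
                          matched_order = NULL, match_signs = NULL) {
  eigenvectors <- as.matrix(eigenvectors)
  if (length(eigenvalues) != ncol(eigenvectors))
    stop("one eigenvalue per eigenvector column required")
  if (is.unsorted(eigenvalues)) stop("eigenvalues must be ascending")
  if (any(eigenvalues <= 0)) stop("nonzero-mode eigenvalues must be positive")
  structure(list(member_id = as.character(member_id),
                 eigenvalues = as.numeric(eigenvalues),
                 eigenvectors = eigenvectors,
                 matched_order = matched_order,
                 match_signs = match_signs),
            class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("<mode_spectrum> %s: %d modes on %d positions%s\n",
              x$member_id, length(x$eigenvalues), nrow(x$eigenvectors),
              if (is.null(x$matched_order)) "" else " (matched)"))
  invisible(x)
}

spectrum_from_gnm <- function(model, member_id) {
  mode_spectrum(member_id, model$eigenvalues, model$eigenvectors)
}

#' GNM spectra for every ensemble member
#'
#' One GNM per member on the common (imputed) position set. Members whose
#' contact graph is disconnected at this cutoff are dropped with a warning
#' (or raise an error when `on_disconnected = "error"`).
#'
#' @param ensemble a superposed, imputed ensemble.
#' @param cutoff,gamma,zero_tol GNM parameters (see [build_gnm()]).
#' @param on_disconnected `"drop"` (default) or `"error"`.
#' @return list of [mode_spectrum()] objects; dropped member ids are
#'   attached as attribute `"dropped"`.
#' @export
ensemble_gnm <- function(ensemble, cutoff = 10, gamma = 1, zero_tol = 1e-8,
                         on_disconnected = c("drop", "error")) {
  stopifnot(inherits(ensemble, "mapped_ensemble"))
  if (!isTRUE(ensemble$imputed))
    stop("ensemble must be imputed (run iterative_superpose())")
  on_disconnected <- match.arg(on_disconnected)
  spectra <- list()
  dropped <- character(0)
  for (m in seq_along(ensemble$member_ids)) {
    id <- ensemble$member_ids[m]
    g <- tryCatch(
      build_gnm(matrix(ensemble$coords[m, , ], ncol = 3L),
                cutoff = cutoff, gamma = gamma, zero_tol = zero_tol),
      error = function(e) e)
    if (inherits(g, "error")) {
      if (on_disconnected == "error")
        stop(sprintf("member '%s': %s", id, conditionMessage(g)),
             call. = FALSE)
      warning(sprintf("member '%s' dropped: %s", id, conditionMessage(g)))
      dropped <- c(dropped, id)
      next
    }
    spectra[[length(spectra) + 1L]] <- spectrum_from_gnm(g, id)
  }
  attr(spectra, "dropped") <- dropped
  spectra
}

#' Match a spectrum's modes onto a reference spectrum
#'
#' Greedy matching in ascending reference-mode order: reference mode r
#' takes the not-yet-assigned local mode with maximal absolute overlap
#' `|u_local . u_ref|`; the sign is recorded so the matched overlap is
#' positive.
#'
#' @param spectrum,reference_spectrum [mode_spectrum()] objects on the
#'   same number of positions.
#' @param k_max number of reference modes to match; truncated with a
#'   warning when it exceeds the available modes.
#' @return `spectrum` with `matched_order` and `match_signs` filled.
#' @export
match_modes <- function(spectrum, reference_spectrum, k_max = 20L) {
  stopifnot(inherits(spectrum, "mode_spectrum"),
            inherits(reference_spectrum, "mode_spectrum"))
  if (nrow(spectrum$eigenvectors) != nrow(reference_spectrum$eigenvectors))
    stop("spectra must share the same position set")
  avail <- min(length(spectrum$eigenvalues),
               length(reference_spectrum$eigenvalues))
  if (k_max > avail) {
    warning(sprintf("k_max = %d exceeds available modes; truncated to %d",
                    k_max, avail))
    k_max <- avail
  }
  ov <- crossprod(spectrum$eigenvectors,
                  reference_spectrum$eigenvectors[, seq_len(k_max),
                                                  drop = FALSE])
  order_out <- integer(k_max)
  signs <- integer(k_max)
  assigned <- rep(FALSE, nrow(ov))
  for (r in seq_len(k_max)) {
    cand <- abs(ov[, r])
    cand[assigned] <- -Inf
    l <- which.max(cand)
    order_out[r] <- l
    signs[r] <- if (ov[l, r] >= 0) 1L else -1L
    assigned[l] <- TRUE
  }
  spectrum$matched_order <- order_out
  spectrum$match_signs <- signs
  spectrum
}

# local mode indices realising reference-mode window i..j (or raw order
# for unmatched spectra)
window_modes <- function(spectrum, i, j) {
  if (i < 1L || j < i) stop("invalid mode window")
  if (!is.null(spectrum$matched_order)) {
    if (j > length(spectrum$matched_order))
      stop(sprintf("mode window 1..%d exceeds matched range %d",
                   j, length(spectrum$matched_order)))
    spectrum$matched_order[i:j]
  } else {
    if (j > length(spectrum$eigenvalues))
      stop(sprintf("mode window 1..%d exceeds available modes %d",
                   j, length(spectrum$eigenvalues)))
    i:j
  }
}

#' Covariance (spectral) overlap between two mode spectra
#'
#' Overlap of the covariance decompositions restricted to modes i..j, with
#' GNM mode variances sigma_k = 1/lambda_k:
#' `SO = 1 - sqrt((S_A + S_B - 2 * sum_kl sqrt(sigma_Ak sigma_Bl)
#' (u_k . v_l)^2) / (S_A + S_B))` where S are the summed variances.
#' Equal spectra give 1; orthogonal equal-variance single modes give 0.
#' The result is clipped to [0, 1] at 1e-12 tolerance. Matched spectra
#' select their modes through the reference numbering; within-window
#' ordering and signs do not affect the value.
#'
#' @param a,b [mode_spectrum()] objects on the same positions.
#' @param i,j 1-based inclusive mode window (defaults 1..20).
#' @return overlap in [0, 1].
#' @export
spectral_overlap <- function(a, b, i = 1L, j = 20L) {
  stopifnot(inherits(a, "mode_spectrum"), inherits(b, "mode_spectrum"))
  if (nrow(a$eigenvectors) != nrow(b$eigenvectors))
    stop("spectra must share the same position set")
  ma <- window_modes(a, i, j)
  mb <- window_modes(b, i, j)
  sa <- 1 / a$eigenvalues[ma]
  sb <- 1 / b$eigenvalues[mb]
  ua <- a$eigenvectors[, ma, drop = FALSE]
  ub <- b$eigenvectors[, mb, drop = FALSE]
  cross <- sum(outer(sqrt(sa), sqrt(sb)) * crossprod(ua, ub)^2)
  tot <- sum(sa) + sum(sb)
  inner <- (tot - 2 * cross) / tot
  # the relative bracket cancels to machine precision for equal spectra;
  # values below the cancellation floor are numerically zero
  if (inner < 1e-14) inner <- 0
  so <- 1 - sqrt(max(inner, 0))
  if (so < -1e-12 || so > 1 + 1e-12)
    stop("spectral overlap outside [0, 1] beyond tolerance")
  min(max(so, 0), 1)
}

#' Pairwise spectral-distance matrix
#'
#' Entry (a, b) is `arccos(SO_ij(a, b))`, the spectral distance, in
#' [0, pi/2].
#'
#' @param spectra list of matched [mode_spectrum()] objects.
#' @param i,j mode window passed to [spectral_overlap()].
#' @return a [distance_matrix()] with metric `"spectral_distance"`.
#' @export
spectral_distance_matrix <- function(spectra, i = 1L, j = 20L) {
  m <- length(spectra)
  ids <- vapply(spectra, function(s) s$member_id, character(1))
  v <- matrix(0, m, m)
  if (m > 1L) for (p in 1:(m - 1L)) for (q in (p + 1L):m) {
    so <- spectral_overlap(spectra[[p]], spectra[[q]], i, j)
    v[p, q] <- v[q, p] <- acos(min(max(so, 0), 1))
  }
  distance_matrix(ids, v, "spectral_distance")
}

# reference-numbered mode regimes
regime_window <- function(regime) {
  switch(regime,
         global = 1:3,
         lf = 4:20,
         ltif = 21:60,
         fastest = NULL,
         stop("regime must be one of 'global', 'lf', 'ltif', 'fastest'"))
}

# per-member regime MSF rows (optionally unit-sum normalized); members
# whose spectra cannot cover the regime are skipped with a warning
regime_msf_matrix <- function(spectra, regime, normalize = TRUE) {
  win <- regime_window(regime)
  rows <- list()
  ids <- character(0)
  for (s in spectra) {
    k <- length(s$eigenvalues)
    modes <- if (regime == "fastest") {
      if (k < 10L) NULL else order(s$eigenvalues, decreasing = TRUE)[1:10]
    } else {
      tryCatch(window_modes(s, min(win), max(win)), error = function(e) NULL)
    }
    if (is.null(modes)) {
      warning(sprintf("member '%s' skipped: regime '%s' exceeds its %d modes",
                      s$member_id, regime, k))
      next
    }
    msf <- as.vector(s$eigenvectors[, modes, drop = FALSE]^2 %*%
                       (1 / s$eigenvalues[modes]))
    if (normalize) msf <- msf / sum(msf)
    rows[[length(rows) + 1L]] <- msf
    ids <- c(ids, s$member_id)
  }
  if (length(rows) == 0L) stop("no member covers the requested regime")
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

#' Mode-regime signature profile of an ensemble
#'
#' Per-residue mean, variance (population, divisor M), minimum and maximum
#' over members of the regime MSF profiles. Each member's profile is
#' normalized to unit sum before aggregation (per-member GNM scales are
#' relative), unless `normalize = FALSE`. Regimes follow the reference
#' mode numbering via each spectrum's matching: `"global"` = modes 1-3,
#' `"lf"` = 4-20, `"ltif"` = 21-60; `"fastest"` uses each member's ten
#' highest-frequency modes (no matching needed).
#'
#' @param spectra list of matched [mode_spectrum()] objects.
#' @param regime one of `"global"`, `"lf"`, `"ltif"`, `"fastest"`.
#' @param normalize unit-sum normalize per member first (default `TRUE`).
#' @return a `signature_profile`: `regime`, `mean_msf`, `variance_msf`,
#'   `min_msf`, `max_msf`, `n_members`.
#' @export
signature_profile <- function(spectra, regime = c("global", "lf", "ltif",
                                                  "fastest"),
                              normalize = TRUE) {
  regime <- match.arg(regime)
  msf <- regime_msf_matrix(spectra, regime, normalize)
  structure(list(regime = regime,
                 mean_msf = colMeans(msf),
                 variance_msf = apply(msf, 2, pop_var),
                 min_msf = apply(msf, 2, min),
                 max_msf = apply(msf, 2, max),
                 n_members = nrow(msf)),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature_profile> regime '%s', %d members, %d positions\n",
              x$regime, x$n_members, length(x$mean_msf)))
  cat(sprintf(" peak mean MSF at position %d\n", which.max(x$mean_msf)))
  invisible(x)
}

#' @export
plot.signature_profile <- function(x, ...) {
  n <- length(x$mean_msf)
  graphics::plot(NA, xlim = c(1, n), ylim = c(0, max(x$max_msf)),
                 xlab = "position", ylab = "MSF (normalized)",
                 main = sprintf("signature profile: %s", x$regime), ...)
  graphics::polygon(c(1:n, n:1), c(x$min_msf, rev(x$max_msf)),
                    col = "#c6dbef", border = NA)
  graphics::polygon(c(1:n, n:1),
                    c(x$mean_msf - sqrt(x$variance_msf),
                      rev(x$mean_msf + sqrt(x$variance_msf))),
                    col = "#6baed6", border = NA)
  graphics::lines(1:n, x$mean_msf, col = "darkgreen")
  invisible(x)
}
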