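# Labeled-subset signature comparison with a randomized-split null.

#' Compare the signature dynamics of two labeled subsets
#'
#' Builds a [signature_profile()] per subset and reports the elementwise
#' absolute mean difference and the variance ratio (first subset over
#' second, floored). Members labeled `"none"` (or anything outside
#' `subset_labels`) are excluded.
#'
#' @param spectra list of matched [mode_spectrum()] objects.
#' @param labels character vector of state labels, one per spectrum.
#' @param regime mode regime (see [signature_profile()]).
#' @param subset_labels the two labels to compare, in ratio order
#'   (default `c("active", "inactive")`).
#' @param normalize unit-sum normalize per member (default `TRUE`).
#' @param var_floor floor applied to the denominator variance.
#' @return a `split_comparison`: `subset_labels`, `profiles` (named pair
#'   of signature profiles), `difference` (|meanA - meanB|),
#'   `variance_ratio` (varA / max(varB, floor)).
#' @export
split_comparison <- function(spectra, labels, regime = "global",
                             subset_labels = c("active", "inactive"),
                             normalize = TRUE, var_floor = 1e-12) {
  if (length(labels) != length(spectra))
    stop("one label per spectrum is required")
  if (length(subset_labels) != 2L) stop("exactly two subset labels required")
  ia <- which(labels == subset_labels[1])
  ib <- which(labels == subset_labels[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop(sprintf("each subset needs >= 2 members (got %d '%s', %d '%s')",
                 length(ia), subset_labels[1], length(ib), subset_labels[2]))
  pa <- signature_profile(spectra[ia], regime, normalize = normalize)
  pb <- signature_profile(spectra[ib], regime, normalize = normalize)
  structure(list(subset_labels = subset_labels,
                 profiles = stats::setNames(list(pa, pb), subset_labels),
                 difference = abs(pa$mean_msf - pb$mean_msf),
                 variance_ratio = pa$variance_msf /
                   pmax(pb$variance_msf, var_floor),
                 regime = regime),
            class = "split_comparison")
}

#' @export
print.split_comparison <- function(x, ...) {
  cat(sprintf("<split_comparison> %s vs %s, regime '%s'\n",
              x$subset_labels[1], x$subset_labels[2], x$regime))
  cat(sprintf(" members: %d vs %d; max |mean difference| %.3g at position %d\n",
              x$profiles[[1]]$n_members, x$profiles[[2]]$n_members,
              max(x$difference), which.max(x$difference)))
  invisible(x)
}

#' Randomized-split null distribution of signature differences
#'
#' Repeatedly splits the pooled spectra into two random subsets of the
#' given sizes (label-blind) and records the per-position absolute mean
#' MSF difference, yielding the null band against which an observed
#' labeled-split difference is judged. Fully seeded and reproducible.
#'
#' @param spectra list of matched [mode_spectrum()] objects.
#' @param subset_sizes integer pair; must sum to at most the number of
#'   spectra (sizes are preserved across repetitions to control size
#'   effects).
#' @param regime mode regime.
#' @param n_reps number of random splits (>= 100 recommended).
#' @param seed integer seed (required; no hidden global randomness).
#' @param normalize unit-sum normalize per member (default `TRUE`).
#' @return a `null_distribution`: `samples` (n_reps x N difference
#'   profiles) and `quantiles` (3 x N matrix, rows 50/95/99%).
#' @export
randomized_split_null <- function(spectra, subset_sizes, regime = "global",
                                  n_reps = 500L, seed, normalize = TRUE) {
  if (missing(seed)) stop("a seed is required")
  if (length(subset_sizes) != 2L || any(subset_sizes < 1L))
    stop("subset_sizes must be two positive integers")
  m <- length(spectra)
  if (sum(subset_sizes) > m)
    stop(sprintf("subset sizes (%d + %d) exceed the %d available members",
                 subset_sizes[1], subset_sizes[2], m))
  if (n_reps < 1L) stop("n_reps must be >= 1")
  msf <- regime_msf_matrix(spectra, regime, normalize)
  m_eff <- nrow(msf)
  if (sum(subset_sizes) > m_eff)
    stop("subset sizes exceed the members covering this regime")
  samples <- matrix(NA_real_, n_reps, ncol(msf))
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(m_eff, sum(subset_sizes))
    a <- idx[seq_len(subset_sizes[1])]
    b <- idx[subset_sizes[1] + seq_len(subset_sizes[2])]
    samples[r, ] <- abs(colMeans(msf[a, , drop = FALSE]) -
                          colMeans(msf[b, , drop = FALSE]))
  }
  qs <- apply(samples, 2, stats::quantile, probs = c(0.50, 0.95, 0.99),
              names = FALSE)
  rownames(qs) <- c("q50", "q95", "q99")
  structure(list(n_reps = n_reps, subset_sizes = subset_sizes,
                 regime = regime, seed = seed,
                 samples = samples, quantiles = qs),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d random splits of sizes %d + %d, regime '%s'\n",
              x$n_reps, x$subset_sizes[1], x$subset_sizes[2], x$regime))
  cat(sprintf(" median 95%% band height: %.3g\n",
              stats::median(x$quantiles["q95", ])))
  invisible(x)
}

#' Mode-mode overlap map between two spectrum sets
#'
#' Entry (p, q) is the mean over all cross-subset member pairs (a in A,
#' b in B) of `|u_p(a) . u_q(b)|` for matched modes 1..k, with the
#' standard deviation over the same pairs. Computing overlaps pairwise
#' (rather than on averaged profiles) is what makes the dispersion of the
#' mode-mode correlations observable.
#'
#' @param spectra_a,spectra_b nonempty lists of matched [mode_spectrum()].
#' @param k number of (reference-numbered) modes, default 20.
#' @return a `mode_overlap_map`: `k`, `mean_overlap` and `sd_overlap`
#'   (k x k, population SD).
#' @export
mode_overlap_map <- function(spectra_a, spectra_b, k = 20L) {
  if (length(spectra_a) == 0L || length(spectra_b) == 0L)
    stop("both subsets must be nonempty")
  if (k < 1L) stop("k must be >= 1")
  get_vecs <- function(s) {
    modes <- window_modes(s, 1L, k)
    s$eigenvectors[, modes, drop = FALSE]
  }
  va <- lapply(spectra_a, get_vecs)
  vb <- lapply(spectra_b, get_vecs)
  sum1 <- matrix(0, k, k)
  sum2 <- matrix(0, k, k)
  npair <- 0L
  for (a in va) for (b in vb) {
    o <- abs(crossprod(a, b))
    sum1 <- sum1 + o
    sum2 <- sum2 + o^2
    npair <- npair + 1L
  }
  mean_o <- sum1 / npair
  sd_o <- sqrt(pmax(sum2 / npair - mean_o^2, 0))
  structure(list(k = k, n_pairs = npair,
                 mean_overlap = mean_o, sd_overlap = sd_o),
            class = "mode_overlap_map")
}

#' @export
print.mode_overlap_map <- function(x, ...) {
  cat(sprintf("<mode_overlap_map> modes 1..%d over %d member pairs\n",
              x$k, x$n_pairs))
  cat(sprintf(" mean diagonal overlap: %.3f; mean sd: %.3f\n",
              mean(diag(x$mean_overlap)), mean(x$sd_overlap)))
  invisible(x)
}
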