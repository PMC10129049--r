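# Ensemble principal component analysis of C-alpha coordinates.

#' Principal component analysis of an ensemble's coordinate covariance
#'
#' Eigendecomposition of the 3N x 3N covariance (divisor M - 1) of the
#' member coordinate vectors about the ensemble mean. The ensemble must be
#' superposed and imputed first: on unsuperposed input, rigid-body motion
#' masquerades as leading variance, so such input is refused. Component
#' signs are fixed so the largest-magnitude entry of each component is
#' positive (determinism).
#'
#' @param ensemble a superposed, imputed [iterative_superpose()] ensemble.
#' @param k number of components to retain; truncated with a warning when
#'   it exceeds `min(3N, M - 1)`.
#' @return an `ens_pca` object: `eigenvalues` (descending, Angstrom^2),
#'   `components` (k x 3N, orthonormal rows), `variance_fraction`
#'   (eigenvalue / total coordinate variance), `projections` (M x k,
#'   Angstrom), `mean_coords` (N x 3), `total_variance`,
#'   `all_eigenvalues`, plus member metadata.
#' @export
ensemble_pca <- function(ensemble, k = 10L) {
  stopifnot(inherits(ensemble, "mapped_ensemble"))
  if (!isTRUE(ensemble$superposed) || !isTRUE(ensemble$imputed))
    stop("ensemble must be superposed and imputed before PCA ",
         "(run iterative_superpose())")
  m <- length(ensemble$member_ids)
  if (m < 2L) stop("PCA requires at least 2 members")
  n <- ensemble$n_positions
  x <- t(apply(ensemble$coords, 1, flatten_coords))   # M x 3N
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  kmax <- min(3L * n, m - 1L)
  if (k > kmax) {
    warning(sprintf("k = %d exceeds min(3N, M-1) = %d; truncated", k, kmax))
    k <- kmax
  }
  cv <- crossprod(xc) / (m - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- eg$values
  vecs <- eg$vectors
  total <- sum(diag(cv))
  # deterministic sign: largest-magnitude entry positive
  for (i in seq_len(ncol(vecs))) {
    peak <- which.max(abs(vecs[, i]))
    if (vecs[peak, i] < 0) vecs[, i] <- -vecs[, i]
  }
  comps <- t(vecs[, seq_len(k), drop = FALSE])        # k x 3N
  proj <- xc %*% t(comps)                             # M x k
  structure(list(eigenvalues = vals[seq_len(k)],
                 components = comps,
                 variance_fraction = vals[seq_len(k)] / total,
                 projections = proj,
                 mean_coords = unflatten_coords(mu),
                 total_variance = total,
                 all_eigenvalues = vals,
                 member_ids = ensemble$member_ids,
                 labels = ensemble$labels,
                 species = ensemble$species,
                 occupancy = ensemble$occupancy,
                 n_positions = n,
                 n_members = m),
            class = "ens_pca")
}

#' @export
print.ens_pca <- function(x, ...) {
  cat(sprintf("<ens_pca> %d members, %d positions, %d components\n",
              x$n_members, x$n_positions, length(x$eigenvalues)))
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf(" PC%d: %.2f%% of total variance\n", seq_len(k),
              100 * x$variance_fraction[seq_len(k)]), sep = "")
  invisible(x)
}

#' @export
summary.ens_pca <- function(object, ...) {
  k <- length(object$eigenvalues)
  out <- data.frame(component = seq_len(k),
                    eigenvalue = object$eigenvalues,
                    variance_fraction = object$variance_fraction,
                    cumulative = cumsum(object$variance_fraction))
  class(out) <- c("summary.ens_pca", "data.frame")
  out
}

#' @export
plot.ens_pca <- function(x, components = c(1L, 2L), ...) {
  stopifnot(max(components) <= length(x$eigenvalues))
  p <- x$projections[, components, drop = FALSE]
  col <- c(active = "#1f77b4", inactive = "#ff7f0e", none = "grey50")
  graphics::plot(p[, 1], p[, 2],
                 col = col[x$labels], pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                100 * x$variance_fraction[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                100 * x$variance_fraction[components[2]]),
                 ...)
  invisible(x)
}

#' Per-residue mobility profile along one principal component
#'
#' Euclidean norm of each residue's (x, y, z) triplet within the
#' component, scaled by the square root of the component's eigenvalue, so
#' the profile has displacement (Angstrom) units and leading components
#' carry visibly larger amplitudes.
#'
#' @param result an [ensemble_pca()] result.
#' @param component 1-based component index.
#' @param scale multiply by `sqrt(eigenvalue)` (default `TRUE`).
#' @return numeric vector of N nonnegative amplitudes, with the component
#'   index and low-occupancy flags (`occupancy < 1`) as attributes.
#' @export
mobility_profile <- function(result, component = 1L, scale = TRUE) {
  stopifnot(inherits(result, "ens_pca"))
  if (component < 1L || component > length(result$eigenvalues))
    stop(sprintf("component %d out of range 1..%d", component,
                 length(result$eigenvalues)))
  v <- unflatten_coords(result$components[component, ])
  prof <- sqrt(rowSums(v^2))
  if (scale) prof <- prof * sqrt(max(result$eigenvalues[component], 0))
  attr(prof, "component") <- component
  attr(prof, "low_occupancy") <- result$occupancy < 1
  prof
}

#' Project ensemble members onto selected principal components
#'
#' @param result an [ensemble_pca()] result.
#' @param ensemble the ensemble to project; must share the PCA's position
#'   set (3N must match).
#' @param components integer vector of component indices.
#' @return data.frame with `member_id`, `label`, `species`, and one `PCk`
#'   column (Angstrom) per requested component.
#' @export
project_members <- function(result, ensemble, components = c(1L, 2L)) {
  stopifnot(inherits(result, "ens_pca"), inherits(ensemble, "mapped_ensemble"))
  if (max(components) > length(result$eigenvalues))
    stop("component index out of range")
  if (3L * ensemble$n_positions != ncol(result$components))
    stop("ensemble dimension does not match the PCA (different position set)")
  x <- t(apply(ensemble$coords, 1, flatten_coords))
  xc <- sweep(x, 2, flatten_coords(result$mean_coords))
  proj <- xc %*% t(result$components[components, , drop = FALSE])
  out <- data.frame(member_id = ensemble$member_ids,
                    label = ensemble$labels,
                    species = ensemble$species,
                    stringsAsFactors = FALSE)
  for (i in seq_along(components))
    out[[paste0("PC", components[i])]] <- proj[, i]
  out
}
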