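#' Volume of the convex hull of a point cloud
#'
#' Computes the volume of the minimum convex hull of `points` (one row per
#' point) in any dimension, via an incremental beneath-beyond construction in
#' compiled code. By contract the volume is 0 -- not an error -- when there
#' are fewer than `d + 1` points or the points are affinely degenerate.
#'
#' @param points numeric matrix, n x d, all values finite.
#' @return hull volume (>= 0).
#' @export
hull_volume <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) abort("hull_volume: points must be finite")
  hull_volume_cpp(points)
}

#' Bounding halfspaces of a convex hull
#'
#' Facet normals and offsets of the hull of `points`; a point `x` is inside
#' the hull iff `normals %*% x <= offsets` (within tolerance) for every
#' facet. Used for Monte-Carlo membership cross-checks.
#'
#' @inheritParams hull_volume
#' @return list with `normals` (facets x d), `offsets`, `degenerate` flag.
#' @export
hull_halfspaces <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  hull_facets_cpp(points)
}

#' Bootstrap-corrected convex-hull volume
#'
#' The raw hull volume of a sample underestimates the volume of the
#' underlying distribution's support, and the bias grows as the sample
#' shrinks -- problematic when cells hold very different fire counts. The
#' default corrects by the standard additive nonparametric bootstrap bias
#' correction: `B` resamples of size n with replacement give volumes `V_b`,
#' and the corrected volume is `max(0, 2 * V_obs - mean(V_b))`. An
#' alternative rarefaction mode subsamples (without replacement) to a fixed
#' size and averages, giving volumes comparable at a common effort.
#'
#' @param points numeric matrix, n x d.
#' @param B number of bootstrap resamples (>= 50).
#' @param seed integer seed; resampling is deterministic given it.
#' @param method `"bias"` (default, 2V - mean bootstrap volume, floored at 0)
#'   or `"rarefaction"`.
#' @param rarefy_n subsample size for the rarefaction mode.
#' @return corrected volume (>= 0), or `NA_real_` when n < d + 1.
#' @export
bootstrap_corrected_volume <- function(points, B = 200, seed = 1,
                                       method = c("bias", "rarefaction"),
                                       rarefy_n = NULL) {
  method <- match.arg(method)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points); d <- ncol(points)
  if (B < 50) abort("B must be >= 50")
  if (n < d + 1) return(NA_real_)
  v_obs <- hull_volume_cpp(points)
  with_seed(seed, {
    if (method == "bias") {
      v_b <- vapply(seq_len(B), function(b) {
        hull_volume_cpp(points[sample.int(n, n, replace = TRUE), , drop = FALSE])
      }, numeric(1))
      max(0, 2 * v_obs - mean(v_b))
    } else {
      m <- min(rarefy_n %||% n, n)
      v_b <- vapply(seq_len(B), function(b) {
        hull_volume_cpp(points[sample.int(n, m), , drop = FALSE])
      }, numeric(1))
      mean(v_b)
    }
  })
}
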