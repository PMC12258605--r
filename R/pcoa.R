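# Principal coordinates analysis (classical metric scaling) of a distance
# matrix, with tidiers and an autoplot method.

#' Principal coordinates analysis
#'
#' Classical scaling: the squared distances are double-centred with -1/2
#' scaling, eigendecomposed, and coordinates formed from the eigenvectors
#' scaled by the square roots of the positive eigenvalues. Negative
#' eigenvalues (possible for non-Euclidean distances) are reported and
#' their axes dropped. The decomposition is delegated to
#' [stats::cmdscale()].
#'
#' @param dm Symmetric distance matrix with zero diagonal (labelled
#'   dimnames recommended).
#' @param n_axes Maximum number of axes to return (default `n - 1`).
#' @return An object of class `"nlr_pcoa"`: a list with `coordinates` (a
#'   tibble with `label` and `Axis1..Axisk` columns), `eigenvalues` (all
#'   `n` eigenvalues, non-increasing) and `n_axes`.
#' @examples
#' pts <- cbind(x = c(0, 1, 0), y = c(0, 0, 1))
#' pcoa(as.matrix(dist(pts)))
#' @export
pcoa <- function(dm, n_axes = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) abort("Need at least two points.")
  if (!isSymmetric(unname(dm), tol = 1e-8)) abort("Distance matrix must be symmetric.")
  if (any(!is.finite(dm))) abort("Distance matrix must be finite.")
  n_axes <- min(n_axes %||% (n - 1L), n - 1L)
  # cmdscale warns when fewer than k eigenvalues are positive; dropping the
  # non-positive axes is exactly the documented behaviour here
  fit <- suppressWarnings(cmdscale(dm, k = n_axes, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) == 0) {
    abort("No positive eigenvalues: the distance matrix carries no metric structure.")
  }
  labels <- rownames(dm) %||% paste0("p", seq_len(n))
  coords <- as_tibble(pts, .name_repair = ~ paste0("Axis", seq_along(.x)))
  coords <- mutate(coords, label = labels, .before = 1)
  structure(list(coordinates = coords,
                 eigenvalues = sort(fit$eig, decreasing = TRUE),
                 n_axes = ncol(pts)),
            class = "nlr_pcoa")
}

#' @export
print.nlr_pcoa <- function(x, ...) {
  pos <- sum(x$eigenvalues > 1e-12)
  cat(sprintf("Principal coordinates analysis: %d points, %d positive eigenvalues, %d axes kept\n",
              nrow(x$coordinates), pos, x$n_axes))
  rel <- x$eigenvalues[seq_len(min(3, pos))] / sum(pmax(x$eigenvalues, 0))
  cat("Variance explained (first axes):",
      paste0(sprintf("%.1f%%", 100 * rel), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a PCoA result
#'
#' @param x An `nlr_pcoa` object.
#' @param ... Unused.
#' @return The coordinates tibble (one row per point).
#' @export
tidy.nlr_pcoa <- function(x, ...) x$coordinates

#' One-row summary of a PCoA result
#'
#' @param x An `nlr_pcoa` object.
#' @param ... Unused.
#' @return A tibble with the point count, axis count, number of negative
#'   eigenvalues and the variance fractions of the first two axes.
#' @export
glance.nlr_pcoa <- function(x, ...) {
  pos_sum <- sum(pmax(x$eigenvalues, 0))
  tibble(n = nrow(x$coordinates), n_axes = x$n_axes,
         n_negative_eig = sum(x$eigenvalues < -1e-12),
         axis1_var = x$eigenvalues[1] / pos_sum,
         axis2_var = if (length(x$eigenvalues) > 1) max(x$eigenvalues[2], 0) / pos_sum else NA_real_)
}

#' Plot the first two principal coordinates
#'
#' @param object An `nlr_pcoa` object.
#' @param groups Optional factor (one per point) used for colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nlr_pcoa <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) df$group <- groups
  gl <- glance(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1,
                                        if (object$n_axes >= 2) .data$Axis2 else 0)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * gl$axis1_var),
      y = if (object$n_axes >= 2) sprintf("PCo2 (%.1f%%)", 100 * gl$axis2_var) else "",
      title = "Principal coordinates of NB-fragment distances")
  if (is.null(groups)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Mean silhouette width of a two-group split along one coordinate
#'
#' Measures how well a single ordination axis separates two groups: for
#' each point, `(b - a) / max(a, b)` with `a` the mean within-group and
#' `b` the mean between-group absolute difference along the coordinate.
#' Positive mean silhouette indicates separation.
#'
#' @param values Numeric vector (e.g. first PCoA axis).
#' @param groups Vector of group labels (exactly two distinct values).
#' @return Mean silhouette width.
#' @export
group_silhouette <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups), length(unique(groups)) == 2)
  sil <- vapply(seq_along(values), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    a <- mean(abs(values[i] - values[own]))
    b <- mean(abs(values[i] - values[!(groups == groups[i])]))
    if (is.nan(a)) return(0)  # singleton group member
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
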