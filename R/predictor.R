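#' Real-valued angle reconstruction from basin probabilities
#'
#' Predicted marginal probabilities over the K basins are turned into a
#' single real-valued angle pair by mixing the normalized cluster centers
#' in trigonometric space, \eqn{\hat v = \sum_k p_k \tilde C_k}, pairwise
#' renormalizing \eqn{\hat v} and reading the angles back off. The
#' per-residue confidence is the probability-weighted in-cluster variance,
#' \eqn{\sigma^2(\theta) = \sum_k p_k \sigma_k^2(\theta)}, reported as a
#' standard deviation in degrees.
#'
#' @name angle-prediction
NULL

#' Mix cluster centers by predicted probabilities
#'
#' @param p probability vector of length K (simplex within `1e-9`), or an
#'   L x K matrix of such rows.
#' @param model an `angle_clusters` fit.
#' @return a tibble with `phi`, `psi` (degrees) and a logical `degenerate`
#'   column: `TRUE` where a (cos, sin) pair of the weighted mean nearly
#'   cancelled and the prediction fell back to the highest-probability
#'   center.
#' @export
mix_to_angles <- function(p, model) {
  stopifnot(inherits(model, "angle_clusters"))
  p <- prob_rows(p, model$k)
  v <- p %*% model$centers
  n1 <- sqrt(v[, 1]^2 + v[, 2]^2)
  n2 <- sqrt(v[, 3]^2 + v[, 4]^2)
  bad <- n1 < 1e-8 | n2 < 1e-8
  if (any(bad)) {
    top <- max.col(p[bad, , drop = FALSE], ties.method = "first")
    v[bad, ] <- model$centers[top, , drop = FALSE]
  }
  out <- to_angles(normalize_pairs(v))
  out$degenerate <- bad
  out
}

#' Mix only the top-R probability clusters
#'
#' Zeroes all but the R largest probabilities (ties broken toward the lower
#' cluster index), renormalizes the rest to sum 1, and mixes as
#' [mix_to_angles()]. `R = 1` returns the highest-probability center;
#' `R = K` is full mixing.
#'
#' @inheritParams mix_to_angles
#' @param r number of clusters to keep, `1 <= r <= K`.
#' @return as [mix_to_angles()].
#' @export
top_r_mix <- function(p, model, r) {
  stopifnot(inherits(model, "angle_clusters"))
  if (length(r) != 1L || r < 1L || r > model$k) {
    stop("`r` must lie in 1..K", call. = FALSE)
  }
  p <- prob_rows(p, model$k)
  for (i in seq_len(nrow(p))) {
    keep <- order(-p[i, ], seq_len(model$k))[seq_len(r)]
    q <- numeric(model$k)
    q[keep] <- p[i, keep]
    p[i, ] <- q / sum(q)
  }
  mix_to_angles(p, model)
}

#' Per-residue confidence of mixed predictions
#'
#' \eqn{\sigma(\theta) = \sqrt{\sum_k p_k \sigma_k^2(\theta)}} for
#' \eqn{\theta \in \{\phi, \psi\}}, using the in-cluster periodic variances
#' recorded at fit time.
#'
#' @inheritParams mix_to_angles
#' @return a tibble with `std_phi`, `std_psi` in degrees.
#' @export
angle_confidence <- function(p, model) {
  stopifnot(inherits(model, "angle_clusters"))
  p <- prob_rows(p, model$k)
  tibble::tibble(
    std_phi = sqrt(as.numeric(p %*% model$var_phi)),
    std_psi = sqrt(as.numeric(p %*% model$var_psi))
  )
}

prob_rows <- function(p, k) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  p <- as.matrix(p)
  if (ncol(p) != k) {
    stop("probability rows must have K = ", k, " columns", call. = FALSE)
  }
  if (any(abs(rowSums(p) - 1) > 1e-9) || any(p < -1e-12)) {
    stop("probability rows must lie on the simplex", call. = FALSE)
  }
  p
}

#' Predict angles and confidences for one protein
#'
#' Applies [mix_to_angles()] and [angle_confidence()] row by row. Rows of
#' `probs` flagged in `mask` (residues whose true dihedral does not exist,
#' e.g. phi at the N-terminus) still receive predictions; pass the mask on
#' to the evaluation functions instead.
#'
#' @param model an `angle_clusters` fit.
#' @param probs L x K probability matrix from [predict_cluster_probs()].
#' @return a `angle_prediction` tibble with columns `pos`, `phi_pred`,
#'   `psi_pred`, `std_phi`, `std_psi`, `top_label`, `top_prob`,
#'   `degenerate`.
#' @export
predict_angles <- function(model, probs) {
  p <- prob_rows(probs, model$k)
  ang <- mix_to_angles(p, model)
  conf <- angle_confidence(p, model)
  top <- max.col(p, ties.method = "first")
  out <- tibble::tibble(
    pos = seq_len(nrow(p)),
    phi_pred = ang$phi,
    psi_pred = ang$psi,
    std_phi = conf$std_phi,
    std_psi = conf$std_psi,
    top_label = top,
    top_prob = p[cbind(seq_len(nrow(p)), top)],
    degenerate = ang$degenerate
  )
  class(out) <- c("angle_prediction", class(out))
  out
}

#' Predicted angles with confidence ribbons along the chain
#'
#' @param object an `angle_prediction` tibble.
#' @param ... unused.
#' @return a ggplot, one facet per angle, point = prediction, ribbon =
#'   +/- one predicted standard deviation.
#' @export
autoplot.angle_prediction <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(pos = object$pos, angle = "phi", pred = object$phi_pred,
                   std = object$std_phi),
    tibble::tibble(pos = object$pos, angle = "psi", pred = object$psi_pred,
                   std = object$std_psi))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$pred)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred - .data$std,
                                      ymax = .data$pred + .data$std),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~angle, ncol = 1) +
    ggplot2::labs(x = "residue position", y = "predicted angle (degrees)",
                  title = "Predicted backbone dihedrals with confidence") +
    ggplot2::theme_minimal()
}
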