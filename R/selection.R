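#' Choosing the number of Ramachandran basins
#'
#' Two criteria are scanned over a grid of cluster counts K: the entropy
#' loss \eqn{EL = H(P_0) - \frac{1}{N}\sum_i H(P_i)} (discrete information
#' gain of the per-residue predicted distributions over the training
#' background), and the mean log-likelihood of the validation angle pairs
#' under the bivariate von Mises basin mixture weighted by the predicted
#' probabilities. More clusters always raise the likelihood; the entropy
#' loss plateaus once extra clusters stop being predictable, which is where
#' K is chosen.
#'
#' @name k-selection
NULL

#' Shannon entropy of a discrete distribution
#'
#' \eqn{H(p) = -\sum_k p_k \log p_k} in nats, with \eqn{0\log 0 = 0}.
#'
#' @param p probability vector (components `>= 0`, summing to 1 within
#'   `1e-9`).
#' @return entropy in nats.
#' @examples
#' shannon_entropy(rep(1 / 20, 20))  # log(20)
#' @export
shannon_entropy <- function(p) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("`p` must be a probability vector summing to 1", call. = FALSE)
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy loss of predicted cluster distributions
#'
#' \eqn{EL = H(P_0) - \frac{1}{N}\sum_{i=1}^N H(P_i)}: the mean entropy
#' reduction from the background cluster distribution to the per-residue
#' predicted distributions, in nats.
#'
#' @param p0 background probability vector of length K.
#' @param probs N x K matrix of per-residue probability rows.
#' @return entropy loss in nats.
#' @export
entropy_loss <- function(p0, probs) {
  probs <- as.matrix(probs)
  if (length(p0) != ncol(probs)) {
    stop("`p0` length must equal the number of columns of `probs`",
         call. = FALSE)
  }
  h_rows <- apply(probs, 1L, shannon_entropy)
  shannon_entropy(p0) - mean(h_rows)
}

#' Scan cluster counts with the full cluster-classify pipeline
#'
#' For each K in `k_grid`: fit basins on the training residues, assign
#' labels, train a cluster-probability classifier, predict on the
#' validation residues, and record the entropy loss and the bivariate von
#' Mises mixture log-likelihood. Deterministic given `seed`.
#'
#' @param train,val residue tibbles as produced by
#'   [generate_protein_set()] (feature columns plus `phi`, `psi`,
#'   `protein`).
#' @param k_grid integer vector of cluster counts (default the decade grid
#'   10, 20, ..., 100).
#' @param seed integer seed.
#' @param n_init k-means restarts per K.
#' @param ... further arguments to [train_cluster_classifier()] (for
#'   example `epochs`, `n_blocks`, `hidden`).
#' @return a `k_scan` tibble with columns `k`, `entropy_loss`, `loglik`,
#'   `seed`.
#' @export
scan_cluster_numbers <- function(train, val, k_grid = seq(10L, 100L, 10L),
                                 seed = 1L, n_init = 4L, ...) {
  if (length(k_grid) == 0L) stop("`k_grid` is empty", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  rows <- purrr::map(k_grid, function(k) {
    cl <- fit_angle_clusters(train, k = k, seed = seed, n_init = n_init)
    lab <- assign_cluster(cl, train)
    fit <- train_cluster_classifier(lab, k = k, seed = seed, ...)
    probs <- predict_cluster_probs(fit, val)
    keep <- !is.na(val$phi) & !is.na(val$psi)
    pv <- probs[keep, , drop = FALSE]
    params <- cl$bvm
    ll <- if (any(vapply(params, is.null, logical(1)))) {
      NA_real_
    } else {
      as.numeric(bvm_mixture_loglik(val$phi[keep], val$psi[keep], pv, params))
    }
    tibble::tibble(
      k = k,
      entropy_loss = entropy_loss(cl$background, pv),
      loglik = ll,
      seed = seed
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("k_scan", class(out))
  out
}

#' Select the number of clusters from a scan
#'
#' Plateau rule: the smallest K whose entropy loss is within `epsilon` nats
#' of the best entropy loss over the scanned grid.
#'
#' @param rows a `k_scan` tibble (or any data frame with `k` and
#'   `entropy_loss` columns).
#' @param epsilon plateau tolerance in nats (default 0.05).
#' @return the selected K (integer).
#' @export
select_cluster_number <- function(rows, epsilon = 0.05) {
  stopifnot(nrow(rows) >= 1L)
  best <- max(rows$entropy_loss)
  ks <- sort(rows$k[rows$entropy_loss >= best - epsilon])
  as.integer(ks[1L])
}

#' Write a K-scan report as TSV
#'
#' @param rows a `k_scan` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kscan_tsv <- function(rows, path) {
  utils::write.table(
    rows[, c("k", "entropy_loss", "loglik", "seed")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Entropy loss and log-likelihood against cluster count
#'
#' @param object a `k_scan` tibble.
#' @param ... unused.
#' @return a ggplot with one facet per criterion.
#' @export
autoplot.k_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("entropy_loss", "loglik"),
    names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of clusters K", y = NULL,
                  title = "Cluster-number selection criteria") +
    ggplot2::theme_minimal()
}
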