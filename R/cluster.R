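#' Ramachandran basin clustering by k-means on angle vectors
#'
#' Dihedral pairs are embedded as \eqn{(\cos\phi, \sin\phi, \cos\psi,
#' \sin\psi)} and clustered by ordinary Euclidean k-means; the angular
#' discontinuity at \eqn{\pm 180°} disappears in this representation. Raw
#' centers are then pairwise renormalized into valid angle vectors, every
#' training pair is assigned the nearest normalized center as its "true"
#' label, and per-cluster circular statistics plus bivariate von Mises
#' parameters are recorded.
#'
#' @name basin-clustering
NULL

#' Fit an angle cluster model
#'
#' Runs k-means (k-means++ seeding, `n_init` restarts, best within-cluster
#' sum of squares wins) on the 4-D trigonometric embedding of all defined
#' (phi, psi) pairs in `data`. Clusters are relabeled in order of
#' decreasing size, so cluster 1 is always the most populated basin.
#'
#' @param data a data frame with numeric `phi` and `psi` columns in degrees;
#'   rows with either angle `NA` are ignored.
#' @param k number of clusters (default 20).
#' @param seed integer seed making the fit reproducible.
#' @param n_init number of k-means++ restarts (default 10).
#' @return an object of class `angle_clusters` with elements:
#'   `k`, `raw_centers` (k x 4), `centers` (k x 4, normalized),
#'   `center_angles` (tibble `phi`, `psi`), `background` (length-k
#'   probabilities), `circ_mean_phi`, `circ_mean_psi`, `var_phi`, `var_psi`
#'   (degrees / degrees squared), `bvm` (list of [bvm_params()] or `NULL`
#'   for clusters with fewer than 10 members), `seed`, `sizes`.
#' @examples
#' angles <- sample_ramachandran(500, default_basins(), seed = 1)
#' fit_angle_clusters(angles, k = 5, seed = 1)
#' @export
fit_angle_clusters <- function(data, k = 20, seed = 1L, n_init = 10L) {
  stopifnot(is.data.frame(data), all(c("phi", "psi") %in% names(data)))
  k <- as.integer(k)
  seed <- as.integer(seed)
  ok <- !is.na(data$phi) & !is.na(data$psi)
  phi <- data$phi[ok]; psi <- data$psi[ok]
  n <- length(phi)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  if (n < k) {
    stop("fewer valid angle pairs (", n, ") than clusters (", k, ")",
         call. = FALSE)
  }
  x <- to_vector(phi, psi)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  best <- NULL
  for (i in seq_len(max(1L, n_init))) {
    init <- kmeanspp_init(x, k)
    km <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }

  raw <- unname(best$centers)
  # degenerate (near-cancelling) center pairs are re-seeded from a random
  # member point before normalization
  for (j in seq_len(k)) {
    n1 <- sqrt(raw[j, 1]^2 + raw[j, 2]^2)
    n2 <- sqrt(raw[j, 3]^2 + raw[j, 4]^2)
    if (n1 < 1e-8 || n2 < 1e-8) {
      members <- which(best$cluster == j)
      pick <- if (length(members)) sample(members, 1L) else sample(n, 1L)
      raw[j, ] <- x[pick, ]
    }
  }
  centers <- normalize_pairs(raw)

  # labels are assigned against the NORMALIZED centers
  labels <- nearest_center(x, centers)

  # relabel by decreasing cluster size (ties by original index)
  sizes <- tabulate(labels, nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k); remap[ord] <- seq_len(k)
  labels <- remap[labels]
  raw <- raw[ord, , drop = FALSE]
  centers <- centers[ord, , drop = FALSE]
  sizes <- sizes[ord]

  stats_k <- lapply(seq_len(k), function(j) {
    m <- labels == j
    if (!any(m)) {
      return(list(mp = NA_real_, ms = NA_real_, vp = 0, vs = 0, bvm = NULL))
    }
    cp <- circular_summary(phi[m])
    cs <- circular_summary(psi[m])
    bp <- if (sum(m) >= 10L) estimate_bvm(phi[m], psi[m]) else NULL
    list(mp = cp$mean, ms = cs$mean, vp = cp$var, vs = cs$var, bvm = bp)
  })

  structure(
    list(
      k = k,
      raw_centers = raw,
      centers = centers,
      center_angles = to_angles(centers),
      background = sizes / sum(sizes),
      circ_mean_phi = vapply(stats_k, `[[`, numeric(1), "mp"),
      circ_mean_psi = vapply(stats_k, `[[`, numeric(1), "ms"),
      var_phi = vapply(stats_k, `[[`, numeric(1), "vp"),
      var_psi = vapply(stats_k, `[[`, numeric(1), "vs"),
      bvm = lapply(stats_k, `[[`, "bvm"),
      sizes = sizes,
      seed = seed
    ),
    class = "angle_clusters"
  )
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling points with probability proportional to squared distance from
# the nearest already-chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, 4L, byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) {
      idx[j + 1L] <- sample.int(n, 1L)
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((x - matrix(x[idx[j + 1L], ], n, 4L, byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[idx, , drop = FALSE] + stats::rnorm(4L * k, sd = 1e-9)
}

nearest_center <- function(x, centers) {
  # squared Euclidean distance via the expansion; ties -> lowest index
  cross <- x %*% t(centers)
  cn <- rowSums(centers^2)
  d2 <- sweep(-2 * cross, 2L, cn, `+`)
  d2 <- round(d2, 12)  # deterministic tie-breaking at float noise level
  max.col(-d2, ties.method = "first")
}

#' Assign dihedral pairs to their nearest basin
#'
#' Each defined (phi, psi) pair gets the label of the normalized center
#' nearest in 4-D Euclidean distance; ties break to the lowest index.
#' Masked pairs get `NA`.
#'
#' @param model an `angle_clusters` fit.
#' @param data data frame with `phi`, `psi` columns (degrees).
#' @return the input with a `cluster` integer column appended.
#' @export
assign_cluster <- function(model, data) {
  stopifnot(inherits(model, "angle_clusters"), is.data.frame(data))
  ok <- !is.na(data$phi) & !is.na(data$psi)
  lab <- rep(NA_integer_, nrow(data))
  if (any(ok)) {
    x <- to_vector(data$phi[ok], data$psi[ok])
    lab[ok] <- nearest_center(x, model$centers)
  }
  dplyr::mutate(tibble::as_tibble(data), cluster = lab)
}

#' Empirical background distribution of cluster labels
#'
#' @param labels integer labels in `1..k` (`NA` dropped).
#' @param k number of clusters.
#' @return length-`k` probability vector summing to 1; empty clusters get 0.
#' @export
cluster_background <- function(labels, k) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) stop("no labels supplied", call. = FALSE)
  if (any(labels < 1L | labels > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  tabulate(labels, nbins = k) / length(labels)
}

#' @export
print.angle_clusters <- function(x, ...) {
  cat(sprintf("<angle_clusters> k = %d, fitted on %d pairs (seed %d)\n",
              x$k, sum(x$sizes), x$seed))
  cat("largest basins (phi, psi, weight):\n")
  m <- utils::head(cbind(round(x$center_angles, 1),
                         weight = round(x$background, 3)), 5L)
  print(as.data.frame(m))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an angle cluster model: one row per basin
#'
#' @param x an `angle_clusters` object.
#' @param ... unused.
#' @return a tibble with cluster index, normalized center angles, background
#'   probability, circular means and in-cluster standard deviations.
#' @export
tidy.angle_clusters <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    phi = x$center_angles$phi,
    psi = x$center_angles$psi,
    weight = x$background,
    mean_phi = x$circ_mean_phi,
    mean_psi = x$circ_mean_psi,
    sd_phi = sqrt(x$var_phi),
    sd_psi = sqrt(x$var_psi),
    n = x$sizes
  )
}

#' @rdname tidy.angle_clusters
#' @return for `glance()`: a one-row tibble with `k`, `n`, `seed` and the
#'   entropy of the background distribution.
#' @export
glance.angle_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = sum(x$sizes),
    seed = x$seed,
    background_entropy = shannon_entropy(x$background)
  )
}

#' Ramachandran plot of fitted basins
#'
#' @param object an `angle_clusters` object.
#' @param data optional data frame of `phi`, `psi` pairs to underlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.angle_clusters <- function(object, data = NULL, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    pts <- dplyr::filter(tibble::as_tibble(data), !is.na(.data$phi),
                         !is.na(.data$psi))
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$phi, y = .data$psi),
      alpha = 0.2, size = 0.4, colour = "grey50")
  }
  p +
    ggplot2::geom_point(
      data = td,
      ggplot2::aes(x = .data$phi, y = .data$psi, size = .data$weight),
      colour = "firebrick") +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = expression(phi~"(degrees)"),
                  y = expression(psi~"(degrees)"),
                  size = "basin weight",
                  title = "Fitted Ramachandran basins") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
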