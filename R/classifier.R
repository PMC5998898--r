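#' Per-residue cluster-probability classifier
#'
#' The classifier maps each residue's local window of 66 sequence-derived
#' features to a probability distribution over the K Ramachandran basins.
#' The 66 columns are, in fixed order: 20 PSSM log-odds, 20 PSFM
#' frequencies, a 20-way amino-acid one-hot (alphabetical one-letter
#' order), 3 predicted solvent-accessibility probabilities and 3 predicted
#' secondary-structure probabilities.
#'
#' The reference network is deliberately desk-scale: the features of a
#' `2 * half_window + 1` residue window are flattened and passed through a
#' projection layer plus `n_blocks - 1` residual ReLU blocks of `hidden`
#' units and a softmax head. It is trained by Adam on the penalized
#' cross-entropy \eqn{\bar{CE} + \lambda\|W\|^2} (biases unpenalized), with
#' a monotone safeguard: an epoch that raises the full-data objective is
#' rolled back and retried at half the learning rate, so the logged
#' objective never increases. Any other predictor producing simplex rows
#' can stand behind the same interface.
#'
#' @name classifier
NULL

# the 20 standard amino acids in alphabetical one-letter order
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Canonical names of the 66 feature columns
#'
#' @return character vector of length 66 in the documented order.
#' @export
feature_columns <- function() {
  c(paste0("pssm_", AA_ALPHABET),
    paste0("psfm_", AA_ALPHABET),
    paste0("aa_", AA_ALPHABET),
    c("acc_bur", "acc_int", "acc_exp"),
    c("ss_H", "ss_E", "ss_C"))
}

#' Assemble the 66-column per-residue feature matrix
#'
#' Concatenates, in fixed order, 20 PSSM columns, 20 PSFM columns, the
#' amino-acid one-hot (alphabetical order; an unknown residue such as `X`
#' gets an all-zero block with a warning), 3 ACC probabilities and 3 SS
#' probabilities.
#'
#' @param sequence amino-acid string or character vector of single letters.
#' @param pssm L x 20 matrix of PSSM log-odds scores (alphabetical column
#'   order).
#' @param psfm L x 20 matrix of PSFM frequencies (alphabetical column
#'   order).
#' @param acc L x 3 matrix of solvent-accessibility probabilities
#'   (buried, intermediate, exposed).
#' @param ss L x 3 matrix of secondary-structure probabilities (H, E, C).
#' @return a tibble with the 66 [feature_columns()].
#' @export
assemble_features <- function(sequence, pssm, psfm, acc, ss) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  L <- length(aa)
  blocks <- list(pssm = pssm, psfm = psfm, acc = acc, ss = ss)
  widths <- c(pssm = 20L, psfm = 20L, acc = 3L, ss = 3L)
  for (nm in names(blocks)) {
    b <- as.matrix(blocks[[nm]])
    if (nrow(b) != L || ncol(b) != widths[[nm]]) {
      stop(sprintf("`%s` must be a %d x %d matrix to match the sequence",
                   nm, L, widths[[nm]]), call. = FALSE)
    }
    blocks[[nm]] <- b
  }
  hot <- matrix(0, L, 20L)
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    warning("non-standard residue(s) ", paste(unique(aa[is.na(idx)]),
            collapse = ", "), ": one-hot block left all-zero")
  }
  ok <- which(!is.na(idx))
  hot[cbind(ok, idx[ok])] <- 1
  out <- cbind(blocks$pssm, blocks$psfm, hot, blocks$acc, blocks$ss)
  colnames(out) <- feature_columns()
  tibble::as_tibble(out)
}

# Flatten a (2h+1)-residue sliding window of the feature matrix, zero-padded
# at the termini.
build_windows <- function(m, half_window) {
  L <- nrow(m); f <- ncol(m)
  offs <- seq.int(-half_window, half_window)
  out <- matrix(0, L, f * length(offs))
  for (j in seq_along(offs)) {
    src <- seq_len(L) + offs[j]
    ok <- src >= 1L & src <= L
    out[ok, ((j - 1L) * f + 1L):(j * f)] <- m[src[ok], , drop = FALSE]
  }
  out
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_forward <- function(par, x) {
  a <- list()
  z0 <- x %*% par$W0 + rep(par$b0, each = nrow(x))
  h <- relu(z0)
  zs <- list(z0)
  as <- list(h)
  B <- length(par$Wb)
  for (l in seq_len(B)) {
    z <- as[[l]] %*% par$Wb[[l]] + rep(par$bb[[l]], each = nrow(x))
    zs[[l + 1L]] <- z
    as[[l + 1L]] <- as[[l]] + relu(z)
  }
  logits <- as[[B + 1L]] %*% par$Wo + rep(par$bo, each = nrow(x))
  list(zs = zs, as = as, probs = softmax_rows(logits))
}

nn_gradient <- function(par, x, y_onehot, lambda) {
  fw <- nn_forward(par, x)
  m <- nrow(x)
  g <- list(Wb = vector("list", length(par$Wb)),
            bb = vector("list", length(par$bb)))
  dlog <- (fw$probs - y_onehot) / m
  B <- length(par$Wb)
  g$Wo <- crossprod(fw$as[[B + 1L]], dlog) + 2 * lambda * par$Wo
  g$bo <- colSums(dlog)
  da <- dlog %*% t(par$Wo)
  for (l in rev(seq_len(B))) {
    dz <- da * (fw$zs[[l + 1L]] > 0)
    g$Wb[[l]] <- crossprod(fw$as[[l]], dz) + 2 * lambda * par$Wb[[l]]
    g$bb[[l]] <- colSums(dz)
    da <- da + dz %*% t(par$Wb[[l]])
  }
  dz0 <- da * (fw$zs[[1L]] > 0)
  g$W0 <- crossprod(x, dz0) + 2 * lambda * par$W0
  g$b0 <- colSums(dz0)
  g
}

nn_objective <- function(par, x, y_onehot, lambda) {
  p <- nn_forward(par, x)$probs
  ce <- -mean(log(pmax(rowSums(p * y_onehot), 1e-300)))
  pen <- sum(par$W0^2) + sum(par$Wo^2) +
    sum(vapply(par$Wb, function(w) sum(w^2), numeric(1)))
  c(loss = ce, objective = ce + lambda * pen)
}

# flatten/unflatten parameter lists for Adam bookkeeping
par_map <- function(par, f) {
  par$W0 <- f(par$W0, "W0"); par$b0 <- f(par$b0, "b0")
  for (l in seq_along(par$Wb)) {
    par$Wb[[l]] <- f(par$Wb[[l]], paste0("Wb", l))
    par$bb[[l]] <- f(par$bb[[l]], paste0("bb", l))
  }
  par$Wo <- f(par$Wo, "Wo"); par$bo <- f(par$bo, "bo")
  par
}

par_zip <- function(a, b, f) {
  a$W0 <- f(a$W0, b$W0); a$b0 <- f(a$b0, b$b0)
  for (l in seq_along(a$Wb)) {
    a$Wb[[l]] <- f(a$Wb[[l]], b$Wb[[l]])
    a$bb[[l]] <- f(a$bb[[l]], b$bb[[l]])
  }
  a$Wo <- f(a$Wo, b$Wo); a$bo <- f(a$bo, b$bo)
  a
}

#' Train the basin-probability classifier
#'
#' @param data residue tibble holding the 66 [feature_columns()], a
#'   `protein` id column (windows never cross protein boundaries) and an
#'   integer `cluster` label column in `1..k`; rows with `NA` labels
#'   (masked residues) are excluded from the objective.
#' @param k number of cluster labels.
#' @param hidden hidden width (default 100).
#' @param n_blocks number of hidden blocks: one projection layer plus
#'   `n_blocks - 1` residual blocks (default 5).
#' @param half_window residues of context on each side (default 3, a
#'   7-residue window).
#' @param lambda L2 penalty on weights (default `1e-4`).
#' @param epochs maximum training epochs (default 20).
#' @param batch_size minibatch size (default 256).
#' @param learn_rate initial Adam learning rate (default 0.01).
#' @param seed integer seed for initialization and batch shuffling.
#' @return an `angle_classifier` object; its `log` element is a tibble of
#'   per-epoch `loss` (mean cross-entropy) and `objective` (penalized).
#' @export
train_cluster_classifier <- function(data, k, hidden = 100L, n_blocks = 5L,
                                     half_window = 3L, lambda = 1e-4,
                                     epochs = 20L, batch_size = 256L,
                                     learn_rate = 0.01, seed = 1L) {
  stopifnot(is.data.frame(data), "cluster" %in% names(data))
  k <- as.integer(k); seed <- as.integer(seed)
  hidden <- as.integer(hidden); n_blocks <- as.integer(n_blocks)
  half_window <- as.integer(half_window)
  fc <- feature_columns()
  if (!all(fc %in% names(data))) {
    stop("`data` must contain all 66 feature columns", call. = FALSE)
  }
  lab <- data$cluster
  if (any(!is.na(lab) & (lab < 1L | lab > k))) {
    stop("cluster labels must lie in 1..k", call. = FALSE)
  }
  if (any(!is.finite(c(epochs, lambda))) || lambda < 0) {
    stop("invalid hyperparameters", call. = FALSE)
  }

  x <- windows_for(data, half_window)
  keep <- !is.na(lab)
  x <- x[keep, , drop = FALSE]
  y <- lab[keep]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv < 1e-8] <- 1
  x <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  yh <- matrix(0, length(y), k)
  yh[cbind(seq_along(y), y)] <- 1

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  d <- ncol(x)
  par <- list(
    W0 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
    b0 = numeric(hidden),
    Wb = replicate(max(n_blocks - 1L, 0L),
                   matrix(stats::rnorm(hidden * hidden, sd = 0.01),
                          hidden, hidden), simplify = FALSE),
    bb = replicate(max(n_blocks - 1L, 0L), numeric(hidden), simplify = FALSE),
    Wo = matrix(stats::rnorm(hidden * k, sd = sqrt(2 / hidden)), hidden, k),
    bo = numeric(k)
  )

  m1 <- par_map(par, function(p, nm) p * 0)
  m2 <- m1
  lr <- learn_rate
  t_step <- 0L
  n <- nrow(x)
  obj <- nn_objective(par, x, yh, lambda)
  log_rows <- list(tibble::tibble(epoch = 0L, loss = obj[["loss"]],
                                  objective = obj[["objective"]],
                                  learn_rate = lr))
  prev_obj <- obj[["objective"]]

  for (ep in seq_len(epochs)) {
    snapshot <- list(par = par, m1 = m1, m2 = m2, t = t_step)
    tries <- 0L
    repeat {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (b in batches) {
        t_step <- t_step + 1L
        g <- nn_gradient(par, x[b, , drop = FALSE], yh[b, , drop = FALSE],
                         lambda)
        m1 <- par_zip(m1, g, function(m, gg) 0.9 * m + 0.1 * gg)
        m2 <- par_zip(m2, g, function(m, gg) 0.999 * m + 0.001 * gg^2)
        c1 <- 1 - 0.9^t_step
        c2 <- 1 - 0.999^t_step
        upd <- par_zip(m1, m2, function(a, b2) {
          lr * (a / c1) / (sqrt(b2 / c2) + 1e-8)
        })
        par <- par_zip(par, upd, `-`)
      }
      obj <- nn_objective(par, x, yh, lambda)
      if (!is.finite(obj[["objective"]])) {
        stop("training diverged: non-finite objective", call. = FALSE)
      }
      if (obj[["objective"]] <= prev_obj + 1e-9 || tries >= 4L) break
      # monotone safeguard: roll back and retry the epoch at half the rate
      par <- snapshot$par; m1 <- snapshot$m1; m2 <- snapshot$m2
      t_step <- snapshot$t
      lr <- lr / 2
      tries <- tries + 1L
    }
    if (obj[["objective"]] > prev_obj + 1e-9) {
      # could not improve: keep the previous parameters and stop
      par <- snapshot$par
      break
    }
    prev_obj <- obj[["objective"]]
    log_rows[[length(log_rows) + 1L]] <-
      tibble::tibble(epoch = ep, loss = obj[["loss"]],
                     objective = obj[["objective"]], learn_rate = lr)
  }

  structure(
    list(
      par = par, k = k, hidden = hidden, n_blocks = n_blocks,
      half_window = half_window, lambda = lambda, seed = seed,
      center = mu, scale = sdv,
      log = dplyr::bind_rows(log_rows)
    ),
    class = "angle_classifier"
  )
}

windows_for <- function(data, half_window) {
  fc <- feature_columns()
  prot <- if ("protein" %in% names(data)) data$protein else
    rep("protein", nrow(data))
  m <- as.matrix(data[, fc])
  parts <- split(seq_len(nrow(data)), factor(prot, levels = unique(prot)))
  out <- matrix(0, nrow(data), ncol(m) * (2L * half_window + 1L))
  for (idx in parts) {
    out[idx, ] <- build_windows(m[idx, , drop = FALSE], half_window)
  }
  out
}

#' Predict per-residue cluster probabilities
#'
#' @param model an `angle_classifier`.
#' @param data residue tibble with the 66 [feature_columns()] (and a
#'   `protein` column if it holds several chains).
#' @return an L x K matrix of probabilities; every row sums to 1.
#' @export
predict_cluster_probs <- function(model, data) {
  stopifnot(inherits(model, "angle_classifier"))
  fc <- feature_columns()
  if (!all(fc %in% names(data))) {
    stop("`data` must contain all 66 feature columns", call. = FALSE)
  }
  x <- windows_for(data, model$half_window)
  x <- sweep(sweep(x, 2L, model$center), 2L, model$scale, `/`)
  nn_forward(model$par, x)$probs
}

#' Average the predictions of several classifiers
#'
#' Member probability matrices are averaged arithmetically and each row
#' renormalized to sum exactly 1.
#'
#' @param models list of `angle_classifier` objects sharing the same `k`.
#' @param data residue tibble with feature columns.
#' @return an L x K probability matrix.
#' @export
ensemble_probs <- function(models, data) {
  if (length(models) < 1L) stop("empty ensemble", call. = FALSE)
  ks <- vapply(models, `[[`, numeric(1), "k")
  if (length(unique(ks)) != 1L) {
    stop("ensemble members disagree on the number of clusters (",
         paste(unique(ks), collapse = ", "), ")", call. = FALSE)
  }
  p <- Reduce(`+`, lapply(models, predict_cluster_probs, data = data)) /
    length(models)
  p / rowSums(p)
}

#' @export
print.angle_classifier <- function(x, ...) {
  cat(sprintf(
    "<angle_classifier> k = %d, %d-%d-%d (blocks-width-halfwin), lambda = %g\n",
    x$k, x$n_blocks, x$hidden, x$half_window, x$lambda))
  cat(sprintf("trained %d epochs, final objective %.4f\n",
              max(x$log$epoch), utils::tail(x$log$objective, 1L)))
  invisible(x)
}

#' Tidy a classifier training log
#'
#' @param x an `angle_classifier`.
#' @param ... unused.
#' @return the per-epoch training log as a tibble.
#' @export
tidy.angle_classifier <- function(x, ...) x$log

#' @rdname tidy.angle_classifier
#' @export
glance.angle_classifier <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_blocks = x$n_blocks, hidden = x$hidden,
    half_window = x$half_window, lambda = x$lambda, seed = x$seed,
    epochs = max(x$log$epoch),
    final_loss = utils::tail(x$log$loss, 1L),
    final_objective = utils::tail(x$log$objective, 1L)
  )
}
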