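#' Synthetic Ramachandran proteins
#'
#' A generative twin of the modelled data: dihedral pairs are drawn from a
#' mixture of secondary-structure-conditioned bivariate von Mises basins,
#' and per-residue features are built to be noisily informative of the
#' basin, so the whole cluster-classify-mix pipeline can be exercised and
#' tested without any external database. The basin set is a fixture
#' emulating the canonical Ramachandran regions, not an empirical cluster
#' inventory.
#'
#' @name synthetic-data
NULL

#' Default synthetic basin set
#'
#' Five basins at the canonical Ramachandran regions: alpha-helix
#' (-60, -45, H), beta-sheet (-120, 135, E), polyproline-II (-75, 150, C),
#' left-handed helix (60, 45, C) and a broad coil basin (C).
#' Concentrations correspond to angular spreads of roughly 9-15 degrees
#' for the structured basins and about 25 degrees for the coil basin,
#' keeping every basin a distinct recoverable mode of the mixture.
#'
#' @return a `basin_set` tibble with columns `basin`, `weight`, `ss`,
#'   `mu`, `nu`, `kappa1`, `kappa2`, `kappa3`; weights sum to 1.
#' @export
default_basins <- function() {
  out <- tibble::tibble(
    basin = 1:5,
    weight = c(0.35, 0.25, 0.15, 0.08, 0.17),
    ss = c("H", "E", "C", "C", "C"),
    mu = c(-60, -120, -75, 60, -100),
    nu = c(-45, 135, 150, 45, 0),
    kappa1 = c(40, 15, 25, 30, 6),
    kappa2 = c(40, 15, 30, 30, 5),
    kappa3 = c(8, 0, 0, 0, 0)
  )
  class(out) <- c("basin_set", class(out))
  out
}

basin_params <- function(basins) {
  purrr::pmap(basins[, c("mu", "nu", "kappa1", "kappa2", "kappa3")],
              function(mu, nu, kappa1, kappa2, kappa3) {
                bvm_params(mu, nu, kappa1, kappa2, kappa3)
              })
}

#' Sample dihedral pairs from a basin mixture
#'
#' Each draw picks a basin by weight, then a (phi, psi) pair by exact
#' rejection sampling from that basin's bivariate von Mises distribution.
#'
#' @param n number of residues to draw.
#' @param basins a `basin_set` tibble (see [default_basins()]).
#' @param seed integer seed.
#' @return a tibble with `phi`, `psi` (degrees in \[-180, 180)) and the
#'   generating `basin` index.
#' @export
sample_ramachandran <- function(n, basins = default_basins(), seed = 1L) {
  stopifnot(n >= 1L)
  w <- basins$weight
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("basin weights must be non-negative and sum to 1", call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  params <- basin_params(basins)
  b <- sample.int(nrow(basins), n, replace = TRUE, prob = w)
  phi <- numeric(n); psi <- numeric(n)
  for (j in seq_len(nrow(basins))) {
    idx <- which(b == j)
    if (length(idx)) {
      d <- rbvm(length(idx), params[[j]])
      phi[idx] <- d$phi; psi[idx] <- d$psi
    }
  }
  tibble::tibble(phi = phi, psi = psi, basin = basins$basin[b])
}

# deterministic per-basin profile templates: distinct smooth patterns over
# the 20 profile columns, scaled like PSI-BLAST log-odds
basin_templates <- function(n_basins) {
  j <- seq_len(20L)
  pssm <- t(vapply(seq_len(n_basins), function(b) {
    2 * cos(2 * pi * b * j / 20 + b / 3)
  }, numeric(20L)))
  psfm_logit <- t(vapply(seq_len(n_basins), function(b) {
    2 * sin(2 * pi * b * j / 20 + b)
  }, numeric(20L)))
  list(pssm = pssm, psfm_logit = psfm_logit)
}

# default 3-state secondary-structure Markov chain: sticky helices and
# strands, looser coil
SS_STATES <- c("H", "E", "C")
SS_TRANSITION <- matrix(
  c(0.90, 0.02, 0.08,
    0.03, 0.85, 0.12,
    0.15, 0.10, 0.75),
  nrow = 3L, byrow = TRUE, dimnames = list(SS_STATES, SS_STATES))

#' Generate a set of synthetic proteins
#'
#' Per protein: a secondary-structure string from a sticky 3-state Markov
#' chain; dihedral angles from the basin conditioned on the secondary
#' structure (basins sharing an SS state are mixed by their renormalized
#' weights); a uniform random amino-acid sequence; and a 66-column feature
#' matrix whose profile blocks are basin-specific templates plus Gaussian
#' noise, whose one-hot block encodes the sequence, whose ACC block is
#' uninformative simplex noise, and whose SS block is the softened true
#' secondary structure. The first residue's phi and the last residue's psi
#' are masked (`NA`), as those dihedrals do not exist structurally.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer length-2 vector, inclusive bounds on chain
#'   length (default `c(50, 150)`).
#' @param basins a `basin_set` tibble.
#' @param noise standard deviation of the Gaussian feature noise (0 =
#'   perfectly informative features; default 0.5).
#' @param seed integer seed.
#' @param transition 3 x 3 secondary-structure transition matrix
#'   (rows H, E, C).
#' @return a residue tibble with columns `protein`, `pos`, `aa`, `ss`,
#'   `phi`, `psi`, `basin` and the 66 [feature_columns()].
#' @export
generate_protein_set <- function(n_proteins, length_range = c(50L, 150L),
                                 basins = default_basins(), noise = 0.5,
                                 seed = 1L, transition = SS_TRANSITION) {
  if (n_proteins < 1L) stop("`n_proteins` must be >= 1", call. = FALSE)
  if (length(length_range) != 2L || min(length_range) < 3L) {
    stop("`length_range` must be two lengths >= 3", call. = FALSE)
  }
  if (noise < 0) stop("`noise` must be non-negative", call. = FALSE)
  stopifnot(all(dim(transition) == c(3L, 3L)),
            all(abs(rowSums(transition) - 1) < 1e-9))

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  params <- basin_params(basins)
  tmpl <- basin_templates(nrow(basins))
  fc <- feature_columns()

  proteins <- purrr::map(seq_len(n_proteins), function(i) {
    L <- sample(seq.int(length_range[1L], length_range[2L]), 1L)
    ss <- character(L)
    ss[1L] <- sample(SS_STATES, 1L, prob = c(0.35, 0.25, 0.40))
    for (r in seq_len(L - 1L)) {
      ss[r + 1L] <- sample(SS_STATES, 1L, prob = transition[ss[r], ])
    }
    # basin conditioned on SS: renormalized weights among matching basins
    b <- integer(L)
    for (s in SS_STATES) {
      idx <- which(ss == s)
      cand <- which(basins$ss == s)
      if (!length(cand)) cand <- seq_len(nrow(basins))
      if (length(idx)) {
        b[idx] <- cand[sample.int(length(cand), length(idx), replace = TRUE,
                                  prob = basins$weight[cand])]
      }
    }
    phi <- numeric(L); psi <- numeric(L)
    for (j in unique(b)) {
      idx <- which(b == j)
      d <- rbvm(length(idx), params[[j]])
      phi[idx] <- d$phi; psi[idx] <- d$psi
    }
    aa <- sample(AA_ALPHABET, L, replace = TRUE)

    pssm <- tmpl$pssm[b, , drop = FALSE] +
      matrix(stats::rnorm(L * 20L, sd = noise), L, 20L)
    psfm <- tmpl$psfm_logit[b, , drop = FALSE] +
      matrix(stats::rnorm(L * 20L, sd = noise), L, 20L)
    psfm <- exp(psfm) / rowSums(exp(psfm))
    acc <- matrix(stats::rnorm(L * 3L, sd = max(noise, 0.1)), L, 3L)
    acc <- exp(acc) / rowSums(exp(acc))
    ss_hot <- matrix(0, L, 3L)
    ss_hot[cbind(seq_len(L), match(ss, SS_STATES))] <- 1
    ss_prob <- exp(2 * ss_hot + matrix(stats::rnorm(L * 3L, sd = noise), L, 3L))
    ss_prob <- ss_prob / rowSums(ss_prob)

    feats <- cbind(pssm, psfm, to_onehot(aa), acc, ss_prob)
    colnames(feats) <- fc
    phi[1L] <- NA_real_
    psi[L] <- NA_real_
    dplyr::bind_cols(
      tibble::tibble(protein = sprintf("synth%04d", i), pos = seq_len(L),
                     aa = aa, ss = ss, phi = phi, psi = psi,
                     basin = basins$basin[b]),
      tibble::as_tibble(feats))
  })
  dplyr::bind_rows(proteins)
}

to_onehot <- function(aa) {
  hot <- matrix(0, length(aa), 20L)
  idx <- match(aa, AA_ALPHABET)
  ok <- which(!is.na(idx))
  hot[cbind(ok, idx[ok])] <- 1
  hot
}
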