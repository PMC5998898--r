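#' Periodicity-aware evaluation of angle predictions
#'
#' All errors use the periodic difference min(d, 360 - d): an angle
#' predicted at -179 degrees against a truth of 179 is off by 2 degrees,
#' not 358. Correlations are computed between the cosine (or sine) values
#' of predicted and true angles, pooled over all residues. Reports can be
#' stratified by 3-state secondary structure or amino-acid type.
#'
#' @name evaluation
NULL

#' Periodic mean absolute error
#'
#' @param pred,true angle vectors in degrees; positions where either is
#'   `NA` are excluded pairwise.
#' @return mean periodic absolute difference in degrees.
#' @examples
#' angle_mae(-179, 179)  # 2
#' @export
angle_mae <- function(pred, true) {
  keep <- !is.na(pred) & !is.na(true)
  if (!any(keep)) stop("no unmasked angle pairs to evaluate", call. = FALSE)
  mean(angular_difference(pred[keep], true[keep]))
}

#' Pearson correlation of trigonometric transforms
#'
#' @inheritParams angle_mae
#' @param fn `"cos"` or `"sin"`.
#' @return Pearson correlation of `fn(pred)` vs `fn(true)` in \[-1, 1\].
#' @export
trig_pcc <- function(pred, true, fn = c("cos", "sin")) {
  fn <- match.arg(fn)
  keep <- !is.na(pred) & !is.na(true)
  if (sum(keep) < 2L) stop("need at least 2 unmasked pairs", call. = FALSE)
  f <- if (fn == "cos") cos else sin
  a <- f(pred[keep] * DEG2RAD)
  b <- f(true[keep] * DEG2RAD)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(a, b)
}

# H,G,I -> H; E,B -> E; everything else -> C
reduce_ss3 <- function(ss) {
  out <- rep("C", length(ss))
  out[ss %in% c("H", "G", "I")] <- "H"
  out[ss %in% c("E", "B")] <- "E"
  out[is.na(ss)] <- NA_character_
  out
}

metric_row <- function(pred_phi, true_phi, pred_psi, true_psi) {
  keep_phi <- !is.na(pred_phi) & !is.na(true_phi)
  keep_psi <- !is.na(pred_psi) & !is.na(true_psi)
  safe_pcc <- function(p, t, fn) {
    tryCatch(trig_pcc(p, t, fn), error = function(e) NA_real_)
  }
  tibble::tibble(
    mae_phi = if (any(keep_phi)) angle_mae(pred_phi, true_phi) else NA_real_,
    mae_psi = if (any(keep_psi)) angle_mae(pred_psi, true_psi) else NA_real_,
    pcc_cos_phi = safe_pcc(pred_phi, true_phi, "cos"),
    pcc_cos_psi = safe_pcc(pred_psi, true_psi, "cos"),
    pcc_sin_phi = safe_pcc(pred_phi, true_phi, "sin"),
    pcc_sin_psi = safe_pcc(pred_psi, true_psi, "sin"),
    n_residues = sum(keep_phi | keep_psi)
  )
}

#' Stratified evaluation report
#'
#' Computes periodic MAE and trigonometric PCC overall, per 3-state
#' secondary structure (8-state DSSP labels are reduced H,G,I to H and E,B
#' to E, all else C) and per amino-acid type.
#'
#' @param pred data frame with `phi_pred`, `psi_pred` (an
#'   `angle_prediction` tibble works as is).
#' @param truth data frame with true `phi`, `psi` in degrees (`NA` =
#'   masked).
#' @param ss optional per-residue secondary-structure labels (3- or
#'   8-state).
#' @param sequence optional amino-acid string or letter vector.
#' @return an `eval_report` tibble: `partition` (all / ss / aa), `stratum`,
#'   the six metric columns and `n_residues`.
#' @export
stratified_report <- function(pred, truth, ss = NULL, sequence = NULL) {
  stopifnot(nrow(pred) == nrow(truth))
  pp <- pred$phi_pred; ps <- pred$psi_pred
  tp <- truth$phi; ts <- truth$psi
  rows <- dplyr::mutate(metric_row(pp, tp, ps, ts),
                        partition = "all", stratum = "all", .before = 1L)
  if (!is.null(ss)) {
    ss3 <- reduce_ss3(ss)
    for (s in c("H", "E", "C")) {
      m <- !is.na(ss3) & ss3 == s
      rows <- dplyr::bind_rows(rows, dplyr::mutate(
        metric_row(pp[m], tp[m], ps[m], ts[m]),
        partition = "ss", stratum = s, .before = 1L))
    }
  }
  if (!is.null(sequence)) {
    aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
    stopifnot(length(aa) == nrow(pred))
    for (a in intersect(AA_ALPHABET, unique(aa))) {
      m <- aa == a
      rows <- dplyr::bind_rows(rows, dplyr::mutate(
        metric_row(pp[m], tp[m], ps[m], ts[m]),
        partition = "aa", stratum = a, .before = 1L))
    }
  }
  class(rows) <- c("eval_report", class(rows))
  rows
}

#' Linear bound of prediction error by predicted standard deviation
#'
#' Ordinary least squares of MAE on predicted standard deviation, the fit
#' behind "the real prediction error can be approximated by the estimated
#' bound". Points are typically per-stratum (angle x secondary-structure
#' region) means, but any (std, mae) pairs work.
#'
#' @param std,mae numeric vectors of equal length (>= 2 distinct std
#'   values).
#' @return a one-row tibble with `slope`, `intercept`, `r_squared` and a
#'   logical `zero_variance` flag (`TRUE` when all `mae` are equal, in
#'   which case `r_squared` is reported as 0 by convention).
#' @export
error_bound_fit <- function(std, mae) {
  keep <- !is.na(std) & !is.na(mae)
  std <- std[keep]; mae <- mae[keep]
  if (length(unique(std)) < 2L) {
    stop("need at least 2 distinct std values", call. = FALSE)
  }
  fit <- stats::lm(mae ~ std)
  sst <- sum((mae - mean(mae))^2)
  zero <- sst == 0
  r2 <- if (zero) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  tibble::tibble(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    zero_variance = zero
  )
}

#' Agreement between predicted and realized errors
#'
#' @param predicted_errors,true_errors numeric vectors of equal length
#'   (>= 2 pairs after `NA` removal).
#' @return a one-row tibble with Pearson correlation `pcc`, Spearman
#'   correlation `scc` (average-rank ties) and the mean absolute error
#'   between the two, `maepe`.
#' @export
error_prediction_scores <- function(predicted_errors, true_errors) {
  keep <- !is.na(predicted_errors) & !is.na(true_errors)
  p <- predicted_errors[keep]; t <- true_errors[keep]
  if (length(p) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(p) == 0 || stats::sd(t) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  tibble::tibble(
    pcc = stats::cor(p, t),
    scc = stats::cor(p, t, method = "spearman"),
    maepe = mean(abs(p - t))
  )
}

#' Write an evaluation report with conventional column names
#'
#' Writes a one-row TSV whose MAE columns follow the conventional naming:
#' `Phi`, `Psi` for all residues and `Phi_H`, `Psi_H`, `Phi_E`, `Psi_E`,
#' `Phi_C`, `Psi_C` for the secondary-structure strata.
#'
#' @param report an `eval_report` tibble containing the `all` row and,
#'   optionally, the ss rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  pick <- function(part, strat, col) {
    v <- report[[col]][report$partition == part & report$stratum == strat]
    if (length(v)) v[1L] else NA_real_
  }
  row <- data.frame(
    Phi = pick("all", "all", "mae_phi"),
    Psi = pick("all", "all", "mae_psi"),
    Phi_H = pick("ss", "H", "mae_phi"), Psi_H = pick("ss", "H", "mae_psi"),
    Phi_E = pick("ss", "E", "mae_phi"), Psi_E = pick("ss", "E", "mae_psi"),
    Phi_C = pick("ss", "C", "mae_phi"), Psi_C = pick("ss", "C", "mae_psi"))
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
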