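test_that("periodic MAE treats the wrap-around correctly", {
  expect_equal(angle_mae(-179, 179), 2)
  expect_equal(angle_mae(c(10, 20, 30), c(10, 20, 30)), 0)
  withr::with_seed(81, {
    a <- runif(500, -180, 180); b <- runif(500, -180, 180)
  })
  expect_equal(angle_mae(a, b), mean(oracle_angdiff(a, b)))
  # invariant to adding full turns, bounded in [0, 180]
  expect_equal(angle_mae(a + 360, b), angle_mae(a, b), tolerance = 1e-9)
  expect_true(angle_mae(a, b) >= 0 && angle_mae(a, b) <= 180)
  # masked positions drop pairwise
  expect_equal(angle_mae(c(NA, -179), c(10, 179)), 2)
  expect_error(angle_mae(NA_real_, 5), "no unmasked")
})

test_that("trigonometric PCC matches the textbook formula", {
  withr::with_seed(82, t <- runif(100, 1, 179))
  expect_equal(trig_pcc(t, t, "cos"), 1)
  expect_equal(trig_pcc(180 - t, t, "cos"), -1)
  withr::with_seed(83, {
    p <- runif(300, -180, 180); q <- runif(300, -180, 180)
  })
  a <- cos(p * pi / 180); b <- cos(q * pi / 180)
  ref <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(trig_pcc(p, q, "cos"), ref, tolerance = 1e-12)
  # joint permutation invariance
  o <- sample(300)
  expect_equal(trig_pcc(p[o], q[o], "sin"), trig_pcc(p, q, "sin"))
  expect_error(trig_pcc(rep(10, 5), 1:5, "cos"), "zero variance")
})

test_that("stratified reports partition residues consistently", {
  withr::with_seed(84, {
    n <- 120
    truth <- tibble::tibble(phi = runif(n, -180, 180),
                            psi = runif(n, -180, 180))
    pred <- tibble::tibble(phi_pred = wrap_angle(truth$phi + rnorm(n, 0, 20)),
                           psi_pred = wrap_angle(truth$psi + rnorm(n, 0, 30)))
    ss8 <- sample(c("H", "G", "I", "E", "B", "T", "S", "-"), n, TRUE)
    aa <- sample(c("A", "G", "P"), n, TRUE)
  })
  rep_all <- stratified_report(pred, truth, ss = ss8, sequence = aa)
  # single-stratum input: the "all" row equals that stratum's row
  only_h <- ss8 %in% c("H", "G", "I")
  rep_h <- stratified_report(pred[only_h, ], truth[only_h, ])
  expect_equal(rep_h$mae_phi[1],
               rep_all$mae_phi[rep_all$partition == "ss" &
                                 rep_all$stratum == "H"])
  # stratum counts sum to the total within each partition
  n_all <- rep_all$n_residues[rep_all$partition == "all"]
  expect_equal(sum(rep_all$n_residues[rep_all$partition == "ss"]), n_all)
  expect_equal(sum(rep_all$n_residues[rep_all$partition == "aa"]), n_all)
  # hand-partitioned recomputation for one amino acid
  m <- aa == "G"
  expect_equal(
    rep_all$mae_psi[rep_all$partition == "aa" & rep_all$stratum == "G"],
    angle_mae(pred$psi_pred[m], truth$psi[m]))
  # determinism
  expect_identical(rep_all,
                   stratified_report(pred, truth, ss = ss8, sequence = aa))
})

test_that("error_bound_fit matches the closed-form normal equations", {
  fit <- error_bound_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  flat <- error_bound_fit(c(1, 2, 3), c(5, 5, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_true(flat$zero_variance)

  withr::with_seed(85, {
    x <- runif(50, 5, 40); y <- 0.8 * x + rnorm(50, 0, 3)
  })
  got <- error_bound_fit(x, y)
  # normal equations by hand
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(got$slope, slope, tolerance = 1e-12)
  expect_equal(got$intercept, intercept, tolerance = 1e-12)
  expect_error(error_bound_fit(c(2, 2, 2), 1:3), "distinct")
})

test_that("error-prediction scores agree with rank-transform oracles", {
  expect_equal(error_prediction_scores(1:10, 1:10),
               tibble::tibble(pcc = 1, scc = 1, maepe = 0))
  rev_s <- error_prediction_scores(1:10, 10:1)
  expect_equal(rev_s$scc, -1)
  withr::with_seed(86, {
    p <- runif(200); t <- runif(200)  # ties-free almost surely
  })
  got <- error_prediction_scores(p, t)
  expect_equal(got$scc, stats::cor(rank(p), rank(t)), tolerance = 1e-12)
  expect_equal(got$pcc, stats::cor(p, t))
  expect_equal(got$maepe, mean(abs(p - t)))
  expect_error(error_prediction_scores(rep(1, 5), 1:5), "zero variance")
})

test_that("the report writer emits the conventional MAE columns", {
  withr::with_seed(87, {
    truth <- tibble::tibble(phi = runif(60, -180, 180),
                            psi = runif(60, -180, 180))
    pred <- tibble::tibble(phi_pred = wrap_angle(truth$phi + 5),
                           psi_pred = wrap_angle(truth$psi - 5))
    ss <- sample(c("H", "E", "C"), 60, TRUE)
  })
  rep <- stratified_report(pred, truth, ss = ss)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep, path)
  back <- utils::read.delim(path)
  expect_identical(names(back),
                   c("Phi", "Psi", "Phi_H", "Psi_H", "Phi_E", "Psi_E",
                     "Phi_C", "Psi_C"))
  expect_equal(back$Phi, 5, tolerance = 1e-6)
})
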