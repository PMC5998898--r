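test_that("one-hot probabilities reproduce the cluster centers exactly", {
  cl <- fixture_small_clusters()
  hot <- diag(cl$k)
  out <- mix_to_angles(hot, cl)
  expect_equal(out$phi, cl$center_angles$phi, tolerance = 1e-12)
  expect_equal(out$psi, cl$center_angles$psi, tolerance = 1e-12)
  conf <- angle_confidence(hot, cl)
  expect_equal(conf$std_phi, sqrt(cl$var_phi), tolerance = 1e-12)
  expect_equal(conf$std_psi, sqrt(cl$var_psi), tolerance = 1e-12)
})

test_that("mixing matches the printed renormalization formulas", {
  cl <- fixture_small_clusters()
  withr::with_seed(71, p <- random_simplex(1000, cl$k))
  got <- mix_to_angles(p, cl)
  for (i in seq_len(50)) {
    ref <- oracle_mix(p[i, ], cl$centers)
    expect_equal(got$phi[i], unname(ref["phi"]), tolerance = 1e-10)
    expect_equal(got$psi[i], unname(ref["psi"]), tolerance = 1e-10)
  }
})

test_that("cancelled phi components fall back to the argmax center", {
  cl <- fit_angle_clusters(fixture_angles_tight()[1:100, ], k = 2, seed = 1)
  cl$centers <- rbind(to_vector(90, 30), to_vector(-90, 30))
  cl$center_angles <- to_angles(cl$centers)
  out <- mix_to_angles(c(0.5, 0.5), cl)
  expect_true(out$degenerate)
  expect_equal(out$psi, 30, tolerance = 1e-9)
  expect_equal(out$phi, 90)  # fallback to the first (tied-argmax) center
})

test_that("top-R mixing truncates and renormalizes correctly", {
  cl <- fixture_small_clusters()
  withr::with_seed(72, p <- as.numeric(random_simplex(1, cl$k)))
  full <- mix_to_angles(p, cl)
  expect_equal(top_r_mix(p, cl, cl$k), full)
  top1 <- top_r_mix(p, cl, 1)
  expect_equal(as.numeric(top1[, c("phi", "psi")]),
               as.numeric(cl$center_angles[which.max(p), ]))
  # R = 2 against a hand renormalization
  keep <- order(-p)[1:2]
  q <- numeric(cl$k); q[keep] <- p[keep]; q <- q / sum(q)
  expect_equal(top_r_mix(p, cl, 2), mix_to_angles(q, cl))
  expect_error(top_r_mix(p, cl, 0), "1..K")
  expect_error(top_r_mix(p, cl, cl$k + 1), "1..K")
})

test_that("confidence is a weighted-variance root, bounded by cluster stds", {
  cl <- fixture_small_clusters()
  s2 <- cl$var_phi
  withr::with_seed(73, p <- random_simplex(200, cl$k))
  conf <- angle_confidence(p, cl)
  direct <- sqrt(as.numeric(p %*% s2))
  expect_equal(conf$std_phi, direct, tolerance = 1e-12)
  expect_true(all(conf$std_phi >= min(sqrt(s2)) - 1e-12))
  expect_true(all(conf$std_phi <= max(sqrt(s2)) + 1e-12))
  # shared variance is a fixed point for any mixing probabilities
  cl2 <- cl; cl2$var_phi <- rep(144, cl$k); cl2$var_psi <- rep(25, cl$k)
  conf2 <- angle_confidence(p, cl2)
  expect_equal(conf2$std_phi, rep(12, 200))
  expect_equal(conf2$std_psi, rep(5, 200))
})

test_that("predict_angles emits one record per residue with identities", {
  cl <- fixture_small_clusters()
  hot <- diag(cl$k)
  rec <- predict_angles(cl, hot)
  expect_equal(nrow(rec), cl$k)
  expect_equal(rec$phi_pred, cl$center_angles$phi, tolerance = 1e-12)
  expect_equal(rec$std_phi, sqrt(cl$var_phi), tolerance = 1e-12)
  expect_equal(rec$top_label, seq_len(cl$k))
  expect_equal(rec$top_prob, rep(1, cl$k))
})

test_that("mixing is equivariant under a rigid 90-degree phi rotation", {
  cl <- fixture_small_clusters()
  rot <- cl
  rot$center_angles <- dplyr::mutate(cl$center_angles,
                                     phi = wrap_angle(.data$phi + 90))
  rot$centers <- to_vector(rot$center_angles$phi, rot$center_angles$psi)
  withr::with_seed(74, p <- random_simplex(100, cl$k))
  base <- mix_to_angles(p, cl)
  shifted <- mix_to_angles(p, rot)
  expect_equal(angular_difference(shifted$phi, wrap_angle(base$phi + 90)),
               rep(0, 100), tolerance = 1e-9)
  expect_equal(shifted$psi, base$psi, tolerance = 1e-9)
})

test_that("end-to-end prediction beats the global circular-mean baseline", {
  for (seed in 1:3) {
    d <- generate_protein_set(20, c(40, 80), noise = 0.4, seed = 200 + seed)
    cl <- fit_angle_clusters(d, k = 5, seed = seed, n_init = 4)
    lab <- assign_cluster(cl, d)
    ids <- unique(d$protein)
    tr <- lab$protein %in% ids[1:16]
    fit <- train_cluster_classifier(lab[tr, ], k = 5, seed = seed,
                                    epochs = 8, hidden = 32, n_blocks = 2)
    val <- d[!tr, ]
    pred <- predict_angles(cl, predict_cluster_probs(fit, val))
    base_phi <- circular_summary(d$phi[tr])$mean
    expect_lt(angle_mae(pred$phi_pred, val$phi),
              angle_mae(rep(base_phi, nrow(val)), val$phi))
  }
})

test_that("larger predicted stds accompany larger realized errors", {
  fx <- fixture_small_fit()
  cl <- fixture_small_clusters()
  val <- !fx$train
  d <- fx$labelled[val, ]
  pred <- predict_angles(cl, predict_cluster_probs(fx$model, d))
  ok <- !is.na(d$phi)
  err <- angular_difference(pred$phi_pred[ok], d$phi[ok])
  quart <- cut(pred$std_phi[ok], stats::quantile(pred$std_phi[ok],
                                                 probs = seq(0, 1, 0.25)),
               include.lowest = TRUE)
  mae_by_bin <- tapply(err, quart, mean)
  expect_true(all(diff(mae_by_bin) > 0))
})
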