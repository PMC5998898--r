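test_that("well-separated basins are recovered near their circular means", {
  s <- fixture_angles_tight()
  cl <- fit_angle_clusters(s, k = 3, seed = 1, n_init = 5)
  # per-basin circular means computed independently of the cluster fit
  ref <- do.call(rbind, lapply(split(s, s$basin), function(d) {
    c(phi = circular_summary(d$phi)$mean, psi = circular_summary(d$psi)$mean)
  }))
  for (j in 1:3) {
    dists <- angular_difference(cl$center_angles$phi[j], ref[, "phi"]) +
      angular_difference(cl$center_angles$psi[j], ref[, "psi"])
    expect_lt(min(angular_difference(cl$center_angles$phi[j],
                                     ref[which.min(dists), "phi"])), 5)
    expect_lt(min(angular_difference(cl$center_angles$psi[j],
                                     ref[which.min(dists), "psi"])), 5)
  }
})

test_that("K = 1 reduces to the normalized component-wise mean", {
  s <- fixture_angles_tight()[1:500, ]
  cl <- fit_angle_clusters(s, k = 1, seed = 1, n_init = 2)
  v <- to_vector(s$phi, s$psi)
  expect_equal(as.numeric(cl$centers),
               as.numeric(normalize_pairs(colMeans(v))), tolerance = 1e-9)
})

test_that("more clusters than points is an error", {
  s <- fixture_angles_tight()[1:5, ]
  expect_error(fit_angle_clusters(s, k = 10, seed = 1), "fewer valid")
})

test_that("identical seed and input reproduce the model exactly", {
  s <- fixture_angles_tight()[1:800, ]
  a <- fit_angle_clusters(s, k = 4, seed = 42, n_init = 3)
  b <- fit_angle_clusters(s, k = 4, seed = 42, n_init = 3)
  expect_identical(a$centers, b$centers)
  expect_identical(a$background, b$background)
  expect_identical(a$var_phi, b$var_phi)
})

test_that("assignment agrees with exhaustive nearest-center search", {
  cl <- fixture_small_clusters()
  withr::with_seed(31, {
    phi <- runif(1000, -180, 180); psi <- runif(1000, -180, 180)
  })
  got <- assign_cluster(cl, tibble::tibble(phi = phi, psi = psi))$cluster
  v <- to_vector(phi, psi)
  brute <- vapply(seq_len(1000), function(i) {
    d <- vapply(seq_len(cl$k), function(j) sum((v[i, ] - cl$centers[j, ])^2),
                numeric(1))
    which.min(d)
  }, integer(1))
  expect_equal(got, brute)
})

test_that("a pair sitting on a center gets that center's label", {
  cl <- fixture_small_clusters()
  got <- assign_cluster(cl, cl$center_angles)$cluster
  expect_equal(got, seq_len(cl$k))
})

test_that("exact distance ties break to the lowest cluster index", {
  cl <- fit_angle_clusters(fixture_angles_tight()[1:100, ], k = 3, seed = 1)
  # overwrite centers: cluster 1 far away; clusters 2 and 3 mirror-images
  # in phi, so (0, 0) is exactly equidistant from both
  cl$centers <- rbind(to_vector(180, 180), to_vector(90, 0),
                      to_vector(-90, 0))
  cl$center_angles <- to_angles(cl$centers)
  got <- assign_cluster(cl, tibble::tibble(phi = 0, psi = 0))$cluster
  expect_identical(got, 2L)
})

test_that("masked pairs get NA labels and background sums to one", {
  cl <- fixture_small_clusters()
  d <- tibble::tibble(phi = c(NA, -60, 100), psi = c(20, -45, NA))
  lab <- assign_cluster(cl, d)$cluster
  expect_true(is.na(lab[1]) && is.na(lab[3]) && !is.na(lab[2]))
  expect_equal(sum(cl$background), 1, tolerance = 1e-12)
  expect_true(all(diff(cl$background) <= 1e-12))  # sorted by size
})

test_that("cluster_background computes empirical frequencies", {
  expect_equal(cluster_background(c(1L, 1L, 2L), 2), c(2 / 3, 1 / 3))
  expect_equal(cluster_background(rep(1:4, 25), 4), rep(0.25, 4))
  expect_equal(cluster_background(c(1L, 1L), 3), c(1, 0, 0))
  withr::with_seed(3, lab <- sample(1:6, 500, TRUE))
  expect_equal(sum(cluster_background(lab, 6)), 1)
  expect_error(cluster_background(c(0L, 1L), 2), "1..k")
})

test_that("labels agree with true basins when K matches the basin count", {
  skip_if_not_installed("mclust")
  s <- fixture_angles_tight()
  cl <- fit_angle_clusters(s, k = 3, seed = 6, n_init = 5)
  lab <- assign_cluster(cl, s)$cluster
  expect_gt(mclust::adjustedRandIndex(lab, s$basin), 0.95)
})

test_that("the model serializes to JSON and back bit-exactly", {
  cl <- fixture_small_clusters()
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(cl, path)
  back <- read_cluster_model(path)
  expect_identical(back$k, cl$k)
  expect_identical(back$seed, cl$seed)
  expect_identical(unname(back$centers), unname(cl$centers))
  expect_identical(back$raw_centers, unname(cl$raw_centers))
  expect_identical(back$background, cl$background)
  expect_identical(back$var_phi, cl$var_phi)
  expect_identical(back$var_psi, cl$var_psi)
  for (j in seq_len(cl$k)) {
    expect_identical(unclass(back$bvm[[j]]), unclass(cl$bvm[[j]]))
  }
})

test_that("tidy and glance expose the basin table", {
  cl <- fixture_small_clusters()
  td <- tidy(cl)
  expect_equal(nrow(td), cl$k)
  expect_equal(sum(td$weight), 1)
  g <- glance(cl)
  expect_equal(g$k, cl$k)
  expect_equal(g$n, sum(cl$sizes))
})
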