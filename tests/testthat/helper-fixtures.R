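# Shared fixtures, built once per test run and memoised. All are generated
# in code; nothing is read from disk except the bundled PSSM parsing
# fixture.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# three widely separated, tightly concentrated basins for clustering tests
tight_basins <- function() {
  b <- tibble::tibble(
    basin = 1:3,
    weight = c(0.4, 0.35, 0.25),
    ss = c("H", "E", "C"),
    mu = c(-60, -120, 60),
    nu = c(-45, 135, 45),
    kappa1 = c(60, 55, 50),
    kappa2 = c(60, 55, 50),
    kappa3 = c(0, 0, 0)
  )
  class(b) <- c("basin_set", class(b))
  b
}

fixture_angles_tight <- function() {
  memo("angles_tight", sample_ramachandran(3000, tight_basins(), seed = 11))
}

# small synthetic protein set + fitted clusters + trained classifier,
# shared by the classifier and predictor tests
fixture_small_set <- function() {
  memo("small_set",
       generate_protein_set(24, c(40, 80), noise = 0.3, seed = 101))
}

fixture_small_clusters <- function() {
  memo("small_clusters",
       fit_angle_clusters(fixture_small_set(), k = 5, seed = 3, n_init = 5))
}

fixture_small_fit <- function() {
  memo("small_fit", {
    d <- fixture_small_set()
    lab <- assign_cluster(fixture_small_clusters(), d)
    train <- lab$protein %in% unique(lab$protein)[1:19]
    list(
      labelled = lab,
      train = train,
      model = train_cluster_classifier(lab[train, ], k = 5, seed = 5,
                                       epochs = 12)
    )
  })
}
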