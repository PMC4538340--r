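test_that("model construction validates features, volumes and thresholds", {
  feats <- list(
    list(allowed_types = c("Hyd", "Acc"), center = c(0, 5, 0), tolerance = 1),
    list(allowed_types = "Don", center = c(4, 0, 0), tolerance = 1),
    list(allowed_types = "ARO", center = c(-4, 0, 1), tolerance = 1)
  )
  m <- pharmacophore_model(feats)
  expect_equal(m$min_features_required, 3L)
  expect_error(pharmacophore_model(feats[1:2]), ">= 3 features")
  expect_error(pharmacophore_model(feats, min_features_required = 2), "3..3")
  bad <- feats; bad[[1]]$allowed_types <- "Foo"
  expect_error(pharmacophore_model(bad), "Foo")
  bad2 <- feats; bad2[[2]]$tolerance <- 0
  expect_error(pharmacophore_model(bad2), "tolerance")
  expect_error(
    pharmacophore_model(feats, excluded_volumes = list(list(center = c(0, 0)))),
    "excluded volumes")
})

test_that("model JSON round-trips through the documented schema", {
  m <- example_pharmacophore_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore_model(m, f)
  back <- read_pharmacophore_model(f)
  expect_equal(back$features, m$features)
  expect_equal(back$excluded_volumes, m$excluded_volumes)
  expect_equal(back$min_features_required, m$min_features_required)
})

test_that("points coinciding with the feature centres match with zero RMSD", {
  m <- example_pharmacophore_model()
  mol <- exact_hit_molecule(m)
  res <- match_pharmacophore(detect_features(mol), m, id = mol$id)
  expect_true(res$hit)
  expect_equal(res$matched_count, 5L)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
})

test_that("a heavy atom inside an excluded volume vetoes the match", {
  m <- example_pharmacophore_model()
  mol <- exact_hit_molecule(m)
  v <- m$excluded_volumes[[1]]
  pts <- rbind(mol$points,
               data.frame(type = "Hyd", x = v$center[1], y = v$center[2],
                          z = v$center[3]))
  res <- match_pharmacophore(detect_features(feature_molecule("ev", pts)), m)
  expect_false(res$hit)
})

test_that("hit decisions survive rigid motion and atom reordering", {
  set.seed(51)
  m <- example_pharmacophore_model()
  mol <- exact_hit_molecule(m)
  for (i in 1:30) {
    rot <- oracle_random_rotation()
    shift <- runif(3, -30, 30)
    moved <- transform_feature_molecule(mol, rot, shift)
    res <- match_pharmacophore(detect_features(moved), m, id = "moved")
    expect_true(res$hit)
    expect_equal(res$rmsd, 0, tolerance = 1e-6)
  }
  shuffled <- feature_molecule("shuf", mol$points[sample(nrow(mol$points)), ])
  expect_true(match_pharmacophore(detect_features(shuffled), m)$hit)
})

test_that("pruned assignment search equals the exhaustive oracle", {
  set.seed(52)
  m <- example_pharmacophore_model()
  fx <- generate_screen_fixtures(6, 12, m, seed = 99)
  for (mol in fx$molecules) {
    pts <- detect_features(mol)
    mine <- match_pharmacophore(pts, m, id = mol$id)
    orc <- oracle_match(pts, m)
    expect_identical(mine$hit, orc$hit)
    if (mine$hit) expect_equal(mine$matched_count, orc$count)
  }
  # plus unstructured random point clouds
  for (i in 1:10) {
    k <- sample(4:7, 1)
    pts <- data.frame(type = sample(c("Hyd", "Acc", "Don", "ARO"), k, TRUE),
                      x = runif(k, -6, 6), y = runif(k, -6, 6),
                      z = runif(k, -3, 3))
    mine <- match_pharmacophore(pts, m)
    orc <- oracle_match(pts, m)
    expect_identical(mine$hit, orc$hit)
  }
})

test_that("stricter models never gain hits", {
  set.seed(53)
  feats <- list(
    list(allowed_types = "Hyd", center = c(0, 6, 0), tolerance = 1.5),
    list(allowed_types = "Acc", center = c(-5, -2, 1), tolerance = 1.5),
    list(allowed_types = "Don", center = c(5, -2, -1), tolerance = 1.5),
    list(allowed_types = "ARO", center = c(0, 0, 5), tolerance = 1.5)
  )
  m_partial <- pharmacophore_model(feats, min_features_required = 3)
  m_full <- pharmacophore_model(feats, min_features_required = 4)
  m_tight <- pharmacophore_model(lapply(feats, function(f) {
    f$tolerance <- 0.2; f
  }), min_features_required = 3)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    pts <- data.frame(type = sample(c("Hyd", "Acc", "Don", "ARO"), k, TRUE),
                      x = runif(k, -7, 7), y = runif(k, -7, 7),
                      z = runif(k, -2, 7))
    hit_partial <- match_pharmacophore(pts, m_partial)$hit
    hit_full <- match_pharmacophore(pts, m_full)$hit
    hit_tight <- match_pharmacophore(pts, m_tight)$hit
    # raising the required count or shrinking tolerances never adds a hit
    expect_true(!hit_full || hit_partial)
    expect_true(!hit_tight || hit_partial)
  }
})

test_that("enlarging an excluded volume never turns a miss into a hit", {
  m <- example_pharmacophore_model()
  grow <- function(model, f) {
    model$excluded_volumes <- lapply(model$excluded_volumes, function(v) {
      v$radius <- v$radius * f; v
    })
    model
  }
  m_big <- pharmacophore_model(m$features, grow(m, 3)$excluded_volumes,
                               m$min_features_required)
  fx <- generate_screen_fixtures(4, 4, m, seed = 7)
  for (mol in fx$molecules) {
    pts <- detect_features(mol)
    if (!match_pharmacophore(pts, m)$hit) {
      expect_false(match_pharmacophore(pts, m_big)$hit)
    }
  }
})

test_that("the superposition agrees with an established structural-biology fit", {
  set.seed(54)
  P <- matrix(rnorm(15), 5, 3)
  rot <- oracle_random_rotation()
  Q <- sweep(P %*% t(rot), 2, c(3, -2, 7), "+") +
    matrix(rnorm(15, sd = 0.05), 5, 3)
  fit <- dra:::kabsch(P, Q)
  moved <- dra:::apply_rigid(P, fit)
  my_rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  bio <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                        fixed.inds = 1:15, mobile.inds = 1:15)
  bio_rmsd <- sqrt(mean(rowSums(
    (matrix(bio, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(my_rmsd, bio_rmsd, tolerance = 1e-6)
})

test_that("default typing rules find aromatic, donor and acceptor points", {
  benzene <- benzene_sdf()
  pts <- detect_features(benzene)
  aro <- pts[pts$type == "ARO", ]
  expect_equal(nrow(aro), 1)
  expect_equal(unlist(aro[, c("x", "y", "z")]), c(x = 0, y = 0, z = 0),
               tolerance = 1e-6)

  pts2 <- detect_features(methanol_sdf())
  expect_gte(sum(pts2$type == "Don"), 1)
  expect_gte(sum(pts2$type == "Acc"), 1)
  o_pos <- pts2[pts2$type == "Don", c("x", "y", "z")][1, ]
  expect_equal(unlist(o_pos), c(x = 1.43, y = 0, z = 0.1), tolerance = 1e-6)
})

test_that("library screening is deterministic and tolerant of empty molecules", {
  m <- example_pharmacophore_model()
  hitmol <- exact_hit_molecule(m, id = "the_hit")
  empty <- feature_molecule("empty",
                            data.frame(type = character(), x = numeric(),
                                       y = numeric(), z = numeric()))
  res <- screen_library(list(hitmol, empty), m)
  expect_equal(res$id, c("the_hit", "empty"))
  expect_equal(res$hit, c(TRUE, FALSE))
  expect_equal(sum(res$hit), 1)

  fx <- generate_screen_fixtures(3, 3, m, seed = 15)
  r1 <- screen_library(fx$molecules, m, seed = 5)
  r2 <- screen_library(fx$molecules, m, seed = 5)
  expect_identical(r1$hit, r2$hit)
  expect_identical(r1$rmsd, r2$rmsd)
})
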