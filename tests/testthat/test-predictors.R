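test_that("great-circle distance has the analytic values and symmetry", {
  expect_equal(great_circle_km(12.3, -45.6, 12.3, -45.6), 0)
  # quarter great circle along the equator
  expect_equal(great_circle_km(0, 0, 0, 90), pi * 6371.0088 / 2,
               tolerance = 1e-9)
  expect_error(great_circle_km(91, 0, 0, 0), "out of range")
  set.seed(4)
  lat1 <- runif(20, -80, 80); lon1 <- runif(20, -179, 179)
  lat2 <- runif(20, -80, 80); lon2 <- runif(20, -179, 179)
  d1 <- great_circle_km(lat1, lon1, lat2, lon2)
  d2 <- oracle_gc_km(lat1, lon1, lat2, lon2)
  expect_equal(d1, d2, tolerance = 1e-6)
  expect_equal(d1, great_circle_km(lat2, lon2, lat1, lon1))
})

test_that("neighbour counts respect the inclusive radius boundary", {
  one <- data.frame(society_id = "A", region_id = "R",
                    latitude = 0, longitude = 0)
  expect_equal(neighbour_counts(one)$n_neighbours, 0L)
  # two societies ~300 km apart on the equator
  soc2 <- data.frame(society_id = c("A", "B"), region_id = "R",
                     latitude = 0, longitude = c(0, 300 / 111.3195))
  d <- great_circle_km(0, 0, 0, 300 / 111.3195)
  expect_true(abs(d - 300) < 1)
  expect_equal(neighbour_counts(soc2, 500)$n_neighbours, c(1L, 1L))
  expect_equal(neighbour_counts(soc2, 250)$n_neighbours, c(0L, 0L))
  # exactly-at-radius is included
  expect_equal(neighbour_counts(soc2, d)$n_neighbours, c(1L, 1L))
})

test_that("neighbour counts equal the all-pairs brute force and are symmetric", {
  set.seed(8)
  soc <- data.frame(society_id = sprintf("S%02d", 1:15),
                    region_id = rep(c("R1", "R2", "R3"), each = 5),
                    latitude = rnorm(15, rep(c(0, 30, -20), each = 5), 2),
                    longitude = rnorm(15, rep(c(0, 40, -60), each = 5), 2))
  nc <- neighbour_counts(soc, 400)$n_neighbours
  within <- matrix(FALSE, 15, 15)
  for (i in 1:15) for (j in 1:15) if (i != j)
    within[i, j] <- oracle_gc_km(soc$latitude[i], soc$longitude[i],
                                 soc$latitude[j], soc$longitude[j]) <= 400
  expect_equal(nc, rowSums(within))
  expect_true(isSymmetric(within))  # mutual-inclusion property
  # missing coordinates give a missing count
  soc$latitude[3] <- NA
  expect_true(is.na(neighbour_counts(soc, 400)$n_neighbours[3]))
})

test_that("phylogenetic nearest neighbours read off a hand tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  soc <- data.frame(society_id = c("sA", "sB", "sC"), region_id = "R",
                    latitude = 0, longitude = 0,
                    language_id = c("A", "B", "C"))
  d <- phylo_nn_distance(tr, soc)
  expect_equal(d$phylo_nn, c(2, 2, 5))
})

test_that("societies sharing a language tip are at distance zero", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  soc <- data.frame(society_id = c("s1", "s2", "s3"), region_id = "R",
                    latitude = 0, longitude = 0,
                    language_id = c("A", "A", "C"))
  d <- phylo_nn_distance(tr, soc)
  expect_equal(d$phylo_nn[1:2], c(0, 0))
  # unmapped society gets NA
  soc$language_id[3] <- NA
  suppressMessages(d2 <- phylo_nn_distance(tr, soc))
  expect_true(is.na(d2$phylo_nn[3]))
})

test_that("nearest patristic distance equals the full-matrix minimum", {
  set.seed(10)
  tr <- ape::rtree(20)
  soc <- data.frame(society_id = paste0("s", 1:20), region_id = "R",
                    latitude = 0, longitude = 0, language_id = tr$tip.label)
  d <- phylo_nn_distance(tr, soc)
  D <- oracle_patristic(tr)
  diag(D) <- Inf
  expect_equal(d$phylo_nn, apply(D[soc$language_id, soc$language_id], 1, min),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_true(all(d$phylo_nn <= max(D[is.finite(D)])))
})

test_that("leave-one-out society means are the other-song averages", {
  sc <- data.frame(song_id = paste0("s", 1:6),
                   society_id = c("A", "A", "B", "B", "B", "C"),
                   region_id = "R",
                   unusualness = c(-1, -3, -1, -2, -3, -9))
  ml <- society_mean_loo(sc)
  expect_equal(ml$society_mean_loo, c(-3, -1, -2.5, -2, -1.5, NA))
  # per-society totals reconcile: mean of LOO means equals mean of scores
  for (s in c("A", "B")) {
    i <- sc$society_id == s
    expect_equal(mean(ml$society_mean_loo[i]), mean(sc$unusualness[i]))
  }
})

test_that("standardize gives exact z-scores and is idempotent", {
  d <- data.frame(x = c(1, 2, 3))
  expect_equal(standardize(d, "x")$x, c(-1, 0, 1))
  z <- standardize(standardize(d, "x"), "x")
  expect_equal(z$x, c(-1, 0, 1), tolerance = 1e-12)
  d2 <- data.frame(x = c(5, NA, 7, 9, NA))
  z2 <- standardize(d2, "x")$x
  expect_true(all(is.na(z2[c(2, 5)])))
  expect_equal(mean(z2, na.rm = TRUE), 0)
  expect_equal(sd(z2, na.rm = TRUE), 1)
  expect_error(standardize(data.frame(x = rep(2, 4)), "x"), "zero variance")
})

test_that("assembled predictors reconcile and match columnwise recomputation", {
  cfg <- sim_config(n_regions = 3, societies_per_region = 6,
                    songs_per_society = 4:8, n_features = 10)
  sim <- simulate_study(cfg, seed = 31)
  u <- suppressMessages(unusualness(sim$codings))
  pred <- suppressMessages(
    assemble_predictors(u, sim$traits, sim$societies, sim$tree,
                        standardize_cols = FALSE))
  expect_equal(nrow(pred), nrow(u))
  expect_equal(sum(pred$complete) + attr(pred, "n_listwise_deleted"),
               nrow(pred))
  # each covariate equals its component computed directly
  nb <- neighbour_counts(sim$societies, 500)
  pn <- suppressMessages(phylo_nn_distance(sim$tree, sim$societies))
  ku <- society_trait_unusualness(sim$traits, sim$societies, "kinship")
  ml <- society_mean_loo(u)
  i <- match(pred$society_id, nb$society_id)
  expect_equal(pred$neighbours_radius, nb$n_neighbours[i])
  expect_equal(pred$phylo_nn, pn$phylo_nn[match(pred$society_id, pn$society_id)])
  expect_equal(pred$kinship_u, ku$unusualness[match(pred$society_id, ku$society_id)])
  expect_equal(pred$society_mean_loo, ml$society_mean_loo[match(pred$song_id, ml$song_id)])
  expect_equal(pred$response, u$unusualness[match(pred$song_id, u$song_id)])
  # standardized variant: complete rows have mean 0, sd 1
  predz <- suppressMessages(
    assemble_predictors(u, sim$traits, sim$societies, sim$tree))
  for (cl in c("response", "neighbours_radius", "phylo_nn", "society_mean_loo")) {
    v <- predz[[cl]][predz$complete]
    expect_lt(abs(mean(v)), 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})

test_that("unknown societies in the score table are fatal when assembling", {
  sc <- data.frame(song_id = "s1", society_id = "ghost", region_id = "R",
                   unusualness = -1)
  soc <- data.frame(society_id = "A", region_id = "R",
                    latitude = 0, longitude = 0, language_id = NA)
  expect_error(assemble_predictors(sc, NULL, soc, NULL), "not in society table")
})
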