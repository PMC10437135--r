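# fabricate a frequency table with chosen probabilities for scoring tests
fake_freqs <- function(probs, excluded = "A") {
  df <- do.call(rbind, lapply(seq_along(probs), function(i)
    data.frame(feature_id = paste0("f", i), state = c(1L, 2L),
               count = c(1L, 1L), prob = c(probs[i], 1 - probs[i]))))
  structure(df, support_n = 10L, region = "R1", excluded_society = excluded,
            floor = 1 / 11)
}

test_that("LOSO state frequencies are plain out-of-society proportions", {
  # 10 non-focal songs, exactly one coded state 13 on a feature -> p = 0.1
  df <- data.frame(song_id = sprintf("s%02d", 1:12),
                   society_id = c(rep("canela", 2), rep(c("B", "C"), each = 5)),
                   region_id = "south_america",
                   vocal_org = c(13L, 1L, 13L, rep(1L, 9)))
  sch <- feature_scheme(list(vocal_org = c(1L, 4L, 7L, 10L, 13L)))
  ct <- as_coding_table(df, sch)
  fr <- state_frequencies(ct, "south_america", "canela")
  expect_equal(attr(fr, "support_n"), 10L)
  expect_equal(fr$prob[fr$state == 13], 0.1)
  # observed probabilities sum to 1 before flooring
  expect_equal(sum(fr$prob[fr$count > 0]), 1)
  # zero-count states take the floor 1/(n+1)
  expect_equal(fr$prob[fr$state == 4], 1 / 11)
})

test_that("a universally shared state gets probability 1", {
  df <- data.frame(song_id = paste0("s", 1:6),
                   society_id = rep(c("A", "B"), each = 3), region_id = "R",
                   f1 = 2L)
  fr <- state_frequencies(toy_codings(df, 3), "R", "A")
  expect_equal(fr$prob[fr$state == 2], 1)
})

test_that("frequencies match a brute-force tally on a hand-sized instance", {
  ct <- random_toy(5, n_regions = 1, n_soc = 3, n_songs = 5, n_feat = 2)
  fr <- state_frequencies(ct, "reg1", "soc1_1")
  for (i in seq_len(nrow(fr))) {
    expect_identical(fr$prob[i],
                     oracle_freqs(ct, "reg1", "soc1_1",
                                  fr$feature_id[i], fr$state[i]))
  }
})

test_that("scoring insufficient regional support is an error", {
  df <- data.frame(song_id = "s1", society_id = "A", region_id = "R", f1 = 1L)
  expect_error(state_frequencies(toy_codings(df, 2), "R", "A"),
               "insufficient regional support")
})

test_that("song unusualness is the sum of log state probabilities", {
  fr <- fake_freqs(c(0.1, 0.2, 0.1))
  song <- list(society_id = "A", f1 = 1L, f2 = 1L, f3 = 1L)
  expect_equal(song_unusualness(song, fr),
               log(0.1) + log(0.2) + log(0.1), tolerance = 1e-12)
  expect_equal(song_unusualness(song, fr), -6.2146081, tolerance = 1e-6)
  # literal log-of-sum convention preserved as an option
  expect_equal(song_unusualness(song, fr, convention = "log_of_sum"),
               log(0.1 + 0.2 + 0.1), tolerance = 1e-12)
})

test_that("a song whose every state is universal scores exactly 0", {
  fr <- fake_freqs(c(1, 1, 1))
  song <- list(society_id = "A", f1 = 1L, f2 = 1L, f3 = 1L)
  expect_identical(song_unusualness(song, fr), 0)
})

test_that("scoring against a non-excluding frequency table is refused", {
  fr <- fake_freqs(c(0.5, 0.5, 0.5), excluded = "B")
  song <- list(society_id = "A", f1 = 1L, f2 = 1L, f3 = 1L)
  expect_error(song_unusualness(song, fr), "self-contamination")
})

test_that("pipeline scores equal the naive recomputation on random instances", {
  for (seed in c(2, 13, 77)) {
    ct <- random_toy(seed, n_regions = 2, n_soc = 3, n_songs = 4, n_feat = 3)
    sc <- unusualness(ct)
    for (i in seq_len(nrow(sc))) {
      expect_equal(sc$unusualness[i],
                   oracle_song_u(ct, attr(ct, "scheme"), sc$song_id[i]),
                   tolerance = 1e-14)
    }
    expect_true(all(sc$unusualness <= 0))
    expect_equal(sc$n_items_scored, rep(3L, nrow(sc)))
  }
})

test_that("duplicating a society's song never changes its other songs' scores", {
  ct <- random_toy(21, n_regions = 1, n_soc = 3, n_songs = 4, n_feat = 3)
  sc <- unusualness(ct)
  dup <- as.data.frame(ct)[1, ]
  dup$song_id <- "dup_1"
  ct2 <- as_coding_table(rbind(as.data.frame(ct), dup), attr(ct, "scheme"))
  sc2 <- unusualness(ct2)
  soc <- as.data.frame(ct)$society_id[1]
  own <- sc$song_id[sc$society_id == soc]
  expect_equal(sc2$unusualness[match(own, sc2$song_id)],
               sc$unusualness[match(own, sc$song_id)])
  # other societies' scores may change; at least the tables stay consistent
  expect_equal(nrow(sc2), nrow(sc) + 1)
})

test_that("moving a song to a strictly more frequent state raises its score", {
  fr <- fake_freqs(c(0.3, 0.5, 0.5))   # state 1 of f1 rarer than state 2
  lo <- song_unusualness(list(society_id = "A", f1 = 1L, f2 = 1L, f3 = 1L), fr)
  hi <- song_unusualness(list(society_id = "A", f1 = 2L, f2 = 1L, f3 = 1L), fr)
  expect_true(hi > lo)
})

test_that("identical repertoires across societies give U = 0 everywhere", {
  df <- data.frame(song_id = paste0("s", 1:8),
                   society_id = rep(c("A", "B"), each = 4), region_id = "R",
                   f1 = 1L, f2 = 2L)
  sc <- unusualness(toy_codings(df, c(2, 3)))
  expect_equal(sc$unusualness, rep(0, 8))
})

test_that("single-society regions are skipped with a record", {
  df <- data.frame(song_id = paste0("s", 1:6),
                   society_id = c("A", "A", "B", "B", "C", "C"),
                   region_id = c(rep("R1", 4), "R2", "R2"),
                   f1 = c(1L, 2L, 1L, 2L, 1L, 1L))
  expect_message(sc <- unusualness(toy_codings(df, 2)), "skipped")
  expect_equal(attr(sc, "skipped_societies"), "C")
  expect_false(any(sc$society_id == "C"))
})

test_that("society trait unusualness matches hand enumeration", {
  soc <- data.frame(society_id = c("A", "B", "C"), region_id = "R",
                    latitude = 0, longitude = 0)
  tr <- as_trait_table(
    data.frame(society_id = c("A", "B", "C"), trait_id = "t1",
               state = c(1L, 1L, 2L)), c(t1 = "kinship"))
  u <- society_trait_unusualness(tr, soc, "kinship")
  # A and B each see one match among two others -> ln(1/2)
  expect_equal(u$unusualness[u$society_id == "A"], log(1 / 2))
  expect_equal(u$unusualness[u$society_id == "B"], log(1 / 2))
  # C's state is unseen among its two peers -> floored at 1/(2+1)
  expect_equal(u$unusualness[u$society_id == "C"], log(1 / 3))
  expect_equal(u$n_items_scored, rep(1L, 3))
})

test_that("identical societies score 0 on every trait theme", {
  soc <- data.frame(society_id = c("A", "B", "C"), region_id = "R",
                    latitude = 0, longitude = 0)
  tr <- as_trait_table(
    data.frame(society_id = rep(c("A", "B", "C"), each = 2),
               trait_id = rep(c("t1", "t2"), 3), state = rep(c(3L, 1L), 3)),
    c(t1 = "kinship", t2 = "economic"))
  for (th in c("kinship", "economic", "general")) {
    u <- society_trait_unusualness(tr, soc, th)
    expect_equal(u$unusualness, rep(0, 3))
  }
})

test_that("trait scoring matches the naive oracle on a 12-society table", {
  set.seed(99)
  soc <- data.frame(society_id = sprintf("S%02d", 1:12),
                    region_id = rep(c("R1", "R2"), each = 6),
                    latitude = 0, longitude = 0)
  tr <- expand.grid(society_id = soc$society_id,
                    trait_id = c("k1", "k2", "e1"), stringsAsFactors = FALSE)
  tr$state <- sample(1:3, nrow(tr), replace = TRUE)
  tr$state[sample(nrow(tr), 4)] <- NA
  tt <- as_trait_table(tr, c(k1 = "kinship", k2 = "kinship", e1 = "economic"))
  for (th in c("kinship", "economic", "general")) {
    u <- society_trait_unusualness(tt, soc, th)
    for (s in soc$society_id)
      expect_equal(u$unusualness[u$society_id == s],
                   oracle_trait_u(tt, soc, s, th), tolerance = 1e-14)
  }
})

test_that("societies without peers or without traits get missing scores", {
  soc <- data.frame(society_id = c("A", "B", "C"),
                    region_id = c("R1", "R2", "R2"),
                    latitude = 0, longitude = 0)
  tr <- as_trait_table(
    data.frame(society_id = c("A", "B"), trait_id = "t1", state = c(1L, 2L)),
    c(t1 = "kinship"))
  u <- society_trait_unusualness(tr, soc, "kinship")
  expect_true(is.na(u$unusualness[u$society_id == "A"])) # alone in region
  expect_true(is.na(u$unusualness[u$society_id == "C"])) # no traits
})
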