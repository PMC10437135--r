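#' Configuration for the synthetic study generator
#'
#' Defaults describe a down-scaled cross-cultural song corpus with the
#' statistical structure the unusualness analysis assumes: regions containing
#' societies, societies containing songs whose categorical features are drawn
#' from society-specific mixtures of regional baselines. With the defaults
#' (6 regions x 15 societies, 1-12 songs each, 37 six-state features) a study
#' has roughly 90 societies and 580 songs — about a tenth of the real corpus,
#' with the same skewed songs-per-society range shape (minimum 1).
#'
#' @param n_regions number of regions.
#' @param societies_per_region societies per region.
#' @param songs_per_society integer vector of permitted repertoire sizes
#'   (sampled uniformly), or a single fixed size.
#' @param n_features number of categorical features per song.
#' @param states_per_feature states per feature (scalar or per-feature
#'   vector).
#' @param style_strength mixing weight lambda in `[0, 1]`: each society's
#'   state distribution is `(1 - lambda) * regional baseline + lambda *
#'   society-specific Dirichlet draw`. 0 = no style (all societies share the
#'   baseline); 1 = fully idiosyncratic styles.
#' @param regional_concentration Dirichlet concentration of regional
#'   baselines (> 0; smaller = spikier regional profiles).
#' @param society_concentration Dirichlet concentration of society style
#'   deviations (> 0; smaller = spikier styles).
#' @param cluster_spread_km geographic sd of societies around their region's
#'   centre, in km.
#' @param birth_rate birth rate of the pure-birth language tree.
#' @param n_kinship,n_economic number of categorical traits per theme.
#' @param trait_states states per trait.
#' @param trait_missing probability a society's trait value is missing.
#' @param beta,group_sd,resid_sd regression-simulation truth: fixed-effect
#'   coefficients (named vector), society-intercept sd tau, residual sd
#'   sigma.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_regions = 6, societies_per_region = 15,
                       songs_per_society = 1:12, n_features = 37,
                       states_per_feature = 6, style_strength = 0.7,
                       regional_concentration = 1,
                       society_concentration = 0.5,
                       cluster_spread_km = 300, birth_rate = 1,
                       n_kinship = 8, n_economic = 8, trait_states = 5,
                       trait_missing = 0.1,
                       beta = c(x1 = 0.5, x2 = 0, x3 = -0.3),
                       group_sd = 1, resid_sd = 1) {
  stopifnot(n_regions >= 1, societies_per_region >= 1,
            all(songs_per_society >= 1), n_features >= 1,
            all(states_per_feature >= 2),
            style_strength >= 0, style_strength <= 1,
            regional_concentration > 0, society_concentration > 0,
            cluster_spread_km >= 0, birth_rate > 0,
            trait_states >= 2, trait_missing >= 0, trait_missing < 1,
            group_sd >= 0, resid_sd > 0)
  structure(list(n_regions = n_regions,
                 societies_per_region = societies_per_region,
                 songs_per_society = songs_per_society,
                 n_features = n_features,
                 states_per_feature = states_per_feature,
                 style_strength = style_strength,
                 regional_concentration = regional_concentration,
                 society_concentration = society_concentration,
                 cluster_spread_km = cluster_spread_km,
                 birth_rate = birth_rate,
                 n_kinship = n_kinship, n_economic = n_economic,
                 trait_states = trait_states, trait_missing = trait_missing,
                 beta = beta, group_sd = group_sd, resid_sd = resid_sd),
            class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

sim_scheme <- function(config) {
  k <- rep_len(config$states_per_feature, config$n_features)
  feats <- lapply(seq_len(config$n_features), function(i) seq_len(k[i]))
  names(feats) <- sprintf("feat_%02d", seq_len(config$n_features))
  disp <- lapply(feats, function(s)
    if (length(s) == 1L) 7 else round(seq(1, 13, length.out = length(s))))
  feature_scheme(feats, display = disp)
}

#' Simulate song repertoires from a Dirichlet mixture of regional baselines
#'
#' For every region and feature a baseline state distribution is drawn from a
#' symmetric Dirichlet; each society's own distribution is the mixture
#' `(1 - lambda) * baseline + lambda * Dirichlet draw`, and its songs are
#' i.i.d. categorical samples from it. The Dirichlet mixture keeps expected
#' state frequencies in closed form, which the oracle tests exploit.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory; all downstream randomness derives
#'   from it).
#' @return A list: `codings` (a `coding_table`), `societies` (skeleton with
#'   `society_id`, `region_id`), and `truth` (baseline and per-society state
#'   distributions).
#' @export
simulate_repertoires <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  set.seed(seed)
  scheme <- sim_scheme(config)
  feats <- scheme_feature_ids(scheme)
  lambda <- config$style_strength
  rows <- list(); soc_rows <- list()
  truth <- list(baseline = list(), society = list())
  song_counter <- 0L
  for (r in seq_len(config$n_regions)) {
    rid <- sprintf("region_%d", r)
    base <- lapply(feats, function(f)
      rdirichlet1(rep(config$regional_concentration,
                      length(scheme$features[[f]]))))
    names(base) <- feats
    truth$baseline[[rid]] <- base
    for (s in seq_len(config$societies_per_region)) {
      sid <- sprintf("soc_%d_%02d", r, s)
      mix <- lapply(feats, function(f) {
        dev <- rdirichlet1(rep(config$society_concentration,
                               length(scheme$features[[f]])))
        (1 - lambda) * base[[f]] + lambda * dev
      })
      names(mix) <- feats
      truth$society[[sid]] <- mix
      n_songs <- if (length(config$songs_per_society) > 1L)
        sample(config$songs_per_society, 1L) else config$songs_per_society
      m <- matrix(NA_integer_, n_songs, length(feats))
      for (j in seq_along(feats)) {
        st <- scheme$features[[feats[j]]]
        m[, j] <- sample(st, n_songs, replace = TRUE, prob = mix[[feats[j]]])
      }
      df <- as.data.frame(m)
      names(df) <- feats
      df <- cbind(data.frame(
        song_id = sprintf("song_%05d", song_counter + seq_len(n_songs)),
        society_id = sid, region_id = rid, stringsAsFactors = FALSE), df)
      song_counter <- song_counter + n_songs
      rows[[length(rows) + 1L]] <- df
      soc_rows[[length(soc_rows) + 1L]] <-
        data.frame(society_id = sid, region_id = rid, stringsAsFactors = FALSE)
    }
  }
  codings <- as_coding_table(do.call(rbind, rows), scheme)
  list(codings = codings, societies = do.call(rbind, soc_rows), truth = truth)
}

#' Simulate clustered society coordinates
#'
#' Places each region's societies in a Gaussian cluster (sd
#' `cluster_spread_km`) around a random centre; km offsets are converted to
#' degrees using the local latitude cosine, adequate at cluster scales up to
#' ~1000 km.
#'
#' @inheritParams simulate_repertoires
#' @param societies society skeleton from [simulate_repertoires()].
#' @return The society table with `latitude`, `longitude` columns added.
#' @export
simulate_geography <- function(config, societies, seed) {
  set.seed(seed)
  regions <- unique(societies$region_id)
  centers <- data.frame(
    region_id = regions,
    lat = stats::runif(length(regions), -50, 50),
    lon = (seq_along(regions) - 1) * (360 / length(regions)) - 180 +
      stats::runif(length(regions), 5, 25))
  km_per_deg_lat <- 111.32
  out <- societies
  out$latitude <- NA_real_; out$longitude <- NA_real_
  for (i in seq_len(nrow(out))) {
    c0 <- centers[centers$region_id == out$region_id[i], ]
    dy <- stats::rnorm(1, 0, config$cluster_spread_km)
    dx <- stats::rnorm(1, 0, config$cluster_spread_km)
    lat <- c0$lat + dy / km_per_deg_lat
    lon <- c0$lon + dx / (km_per_deg_lat * cos(c0$lat * pi / 180))
    out$latitude[i] <- max(-90, min(90, lat))
    out$longitude[i] <- ((lon + 180) %% 360) - 180
  }
  out
}

#' Simulate a pure-birth language tree over societies
#'
#' One tip per society (label `lang_<society_id>`), generated by a pure-birth
#' process and rescaled to unit depth; the `language_id` column links
#' societies to tips.
#'
#' @inheritParams simulate_geography
#' @return A list: `tree` (ultrametric `phylo`) and `societies` with a
#'   `language_id` column added.
#' @export
simulate_tree <- function(config, societies, seed) {
  set.seed(seed)
  n <- nrow(societies)
  if (n < 2) stop("need at least two societies for a tree", call. = FALSE)
  tr <- ape::rphylo(n, birth = config$birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  labs <- paste0("lang_", societies$society_id)
  tr$tip.label <- sample(labs)      # random society-to-tip assignment
  societies$language_id <- labs
  list(tree = tr, societies = societies)
}

#' Simulate categorical societal traits
#'
#' Traits mirror the song generator at the society level: per region and
#' trait a Dirichlet baseline, a society-level mixture with the same style
#' strength lambda, one categorical draw per society, missing completely at
#' random with probability `trait_missing`. The first `n_kinship` traits are
#' themed `kinship` (`trait_K..`), the rest `economic` (`trait_E..`).
#'
#' @inheritParams simulate_geography
#' @return A trait table (`society_id`, `trait_id`, `state`, `theme`).
#' @export
simulate_traits <- function(config, societies, seed) {
  set.seed(seed)
  lambda <- config$style_strength
  traits <- c(sprintf("trait_K%02d", seq_len(config$n_kinship)),
              sprintf("trait_E%02d", seq_len(config$n_economic)))
  themes <- rep(c("kinship", "economic"),
                c(config$n_kinship, config$n_economic))
  K <- config$trait_states
  rows <- list()
  for (r in unique(societies$region_id)) {
    socs <- societies$society_id[societies$region_id == r]
    for (j in seq_along(traits)) {
      base <- rdirichlet1(rep(config$regional_concentration, K))
      for (s in socs) {
        mix <- (1 - lambda) * base +
          lambda * rdirichlet1(rep(config$society_concentration, K))
        st <- if (stats::runif(1) < config$trait_missing) NA_integer_
              else sample.int(K, 1L, prob = mix)
        rows[[length(rows) + 1L]] <- data.frame(
          society_id = s, trait_id = traits[j], state = st,
          theme = themes[j], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a regression problem with known coefficients
#'
#' Standard-normal covariates, society random intercepts with sd `group_sd`,
#' Gaussian noise with sd `resid_sd`:
#' `response = X beta + u[society] + e`. Ground truth is attached for
#' recovery tests.
#'
#' @inheritParams simulate_repertoires
#' @param n number of rows (songs).
#' @param n_societies number of societies the rows are spread over.
#' @return A data.frame with the covariates (named after `config$beta`),
#'   `society_id` and `response`; attribute `truth` holds `beta`, `u`,
#'   `group_sd`, `resid_sd`.
#' @export
simulate_regression <- function(config, n = 500,
                                n_societies = max(2L, n %/% 10L), seed) {
  set.seed(seed)
  beta <- config$beta
  p <- length(beta)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, names(beta)))
  soc <- sample(sprintf("soc_%03d", seq_len(n_societies)), n, replace = TRUE)
  u <- stats::rnorm(n_societies, 0, config$group_sd)
  names(u) <- sprintf("soc_%03d", seq_len(n_societies))
  y <- as.numeric(X %*% beta) + u[soc] +
    stats::rnorm(n, 0, config$resid_sd)
  out <- as.data.frame(X)
  out$society_id <- soc
  out$response <- y
  attr(out, "truth") <- list(beta = beta, u = u,
                             group_sd = config$group_sd,
                             resid_sd = config$resid_sd)
  out
}

#' Simulate a complete study: codings, geography, tree and traits
#'
#' Convenience wrapper running the four generators with seeds derived from a
#' single master seed (`seed`, `seed + 1`, `seed + 2`, `seed + 3`), so each
#' component is independently reproducible.
#'
#' @inheritParams simulate_repertoires
#' @return A list: `codings`, `societies` (with coordinates and
#'   `language_id`), `traits`, `tree`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), seed) {
  rep_ <- simulate_repertoires(config, seed)
  soc <- simulate_geography(config, rep_$societies, seed + 1)
  tr <- simulate_tree(config, soc, seed + 2)
  traits <- simulate_traits(config, tr$societies, seed + 3)
  list(codings = rep_$codings, societies = tr$societies, traits = traits,
       tree = tr$tree, truth = rep_$truth)
}
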