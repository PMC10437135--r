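# Independent brute-force oracles, deliberately written as naive loops that
# share no code with the package internals.

# naive LOSO state frequencies: plain counting over rows
oracle_freqs <- function(codings, region, soc, feature, state) {
  rows <- codings[codings$region_id == region & codings$society_id != soc, ]
  n <- nrow(rows)
  cnt <- 0L
  for (i in seq_len(n)) if (!is.na(rows[[feature]][i]) && rows[[feature]][i] == state)
    cnt <- cnt + 1L
  if (cnt == 0L) 1 / (n + 1) else cnt / n
}

# naive per-song unusualness: loop features, multiply up probabilities in logs
oracle_song_u <- function(codings, scheme, song_id) {
  row <- codings[codings$song_id == song_id, ]
  total <- 0
  for (f in names(scheme$features)) {
    p <- oracle_freqs(codings, row$region_id, row$society_id, f, row[[f]])
    total <- total + log(p)
  }
  total
}

# naive society trait unusualness (mean of log LOSO frequencies)
oracle_trait_u <- function(traits, societies, soc, theme) {
  reg <- societies$region_id[societies$society_id == soc]
  tt <- traits[!is.na(traits$state), ]
  if (theme != "general") tt <- tt[tt$theme == theme, ]
  own <- tt[tt$society_id == soc, ]
  region_socs <- societies$society_id[societies$region_id == reg]
  if (length(region_socs) < 2 || nrow(own) == 0) return(NA_real_)
  lps <- c()
  for (i in seq_len(nrow(own))) {
    others <- tt[tt$trait_id == own$trait_id[i] & tt$society_id != soc &
                   tt$society_id %in% region_socs, ]
    nb <- nrow(others)
    if (nb == 0) next
    cnt <- sum(others$state == own$state[i])
    p <- if (cnt == 0) 1 / (nb + 1) else cnt / nb
    lps <- c(lps, log(p))
  }
  if (!length(lps)) NA_real_ else mean(lps)
}

# spherical law of cosines, an algebraically different great-circle formula
oracle_gc_km <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  d <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  6371.0088 * acos(pmin(1, pmax(-1, d)))
}

# patristic distances via igraph shortest paths over the tree's edge list
oracle_patristic <- function(tree) {
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n_tip <- length(tree$tip.label)
  D <- igraph::distances(g, v = as.character(seq_len(n_tip)),
                         to = as.character(seq_len(n_tip)))
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# build a small coding table in code
toy_codings <- function(df, states_per_feature) {
  feats <- setdiff(names(df), c("song_id", "society_id", "region_id"))
  k <- rep_len(states_per_feature, length(feats))
  sch <- feature_scheme(stats::setNames(
    lapply(seq_along(feats), function(i) seq_len(k[i])), feats))
  as_coding_table(df, sch)
}

# random toy instance for oracle-equivalence property tests
random_toy <- function(seed, n_regions = 2, n_soc = 3, n_songs = 4,
                       n_feat = 3, n_states = 4) {
  set.seed(seed)
  rows <- list()
  id <- 0
  for (r in seq_len(n_regions)) for (s in seq_len(n_soc)) {
    for (k in seq_len(n_songs)) {
      id <- id + 1
      st <- sample.int(n_states, n_feat, replace = TRUE)
      rows[[id]] <- c(song_id = sprintf("s%03d", id),
                      society_id = paste0("soc", r, "_", s),
                      region_id = paste0("reg", r),
                      stats::setNames(as.list(st), paste0("f", seq_len(n_feat))))
    }
  }
  df <- do.call(rbind, lapply(rows, function(x) as.data.frame(as.list(x))))
  for (f in paste0("f", seq_len(n_feat))) df[[f]] <- as.integer(df[[f]])
  sch <- feature_scheme(stats::setNames(
    lapply(seq_len(n_feat), function(i) seq_len(n_states)),
    paste0("f", seq_len(n_feat))))
  as_coding_table(df, sch)
}
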