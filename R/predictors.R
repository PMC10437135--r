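#' Great-circle distance between two points, in kilometres
#'
#' Haversine formula on a sphere with the IUGG mean Earth radius
#' 6371.0088 km. Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84 assumed).
#' @return Distance(s) in km; symmetric and non-negative.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90 | abs(lat2) > 90, na.rm = TRUE) ||
      any(abs(lon1) > 180 | abs(lon2) > 180, na.rm = TRUE))
    stop("coordinates out of range", call. = FALSE)
  R <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Count geographic neighbours within a radius
#'
#' For each society, the number of *other* sampled societies within
#' `radius_km` great-circle km (boundary inclusive). By default counting is
#' global across all societies with coordinates; set `within_region = TRUE`
#' to restrict to the society's own region.
#'
#' @param societies a society table ([read_societies()]).
#' @param radius_km neighbourhood radius in km (default 500).
#' @param within_region count only societies in the same region?
#' @return A data.frame `society_id`, `n_neighbours` (NA for societies
#'   without coordinates).
#' @export
neighbour_counts <- function(societies, radius_km = 500, within_region = FALSE) {
  n <- nrow(societies)
  cnt <- rep(NA_integer_, n)
  has_xy <- !is.na(societies$latitude) & !is.na(societies$longitude)
  idx <- which(has_xy)
  for (i in idx) {
    j <- setdiff(idx, i)
    if (within_region)
      j <- j[societies$region_id[j] == societies$region_id[i]]
    if (!length(j)) { cnt[i] <- 0L; next }
    d <- great_circle_km(societies$latitude[i], societies$longitude[i],
                         societies$latitude[j], societies$longitude[j])
    cnt[i] <- sum(d <= radius_km)
  }
  data.frame(society_id = societies$society_id, n_neighbours = cnt,
             stringsAsFactors = FALSE)
}

#' Patristic distance to the nearest phylogenetic neighbour
#'
#' Maps societies to tree tips through their `language_id` and returns, per
#' society, the branch-length (patristic) distance from its tip to the
#' nearest tip mapped to a *different* sampled society. Societies sharing a
#' tip are at distance 0; societies without a tip mapping get `NA`.
#'
#' @param tree a `phylo` tree with branch lengths ([read_tree()]).
#' @param societies a society table with a `language_id` column.
#' @return A data.frame `society_id`, `phylo_nn` (km-free branch-length
#'   units of the tree).
#' @export
phylo_nn_distance <- function(tree, societies) {
  validate_tree(tree)
  lang <- societies$language_id
  mapped <- !is.na(lang) & lang %in% tree$tip.label
  if (sum(mapped) < 2L)
    stop("need at least two societies mapped to tree tips", call. = FALSE)
  unmapped <- societies$society_id[!mapped]
  if (length(unmapped))
    message("phylo_nn_distance: ", length(unmapped),
            " society(ies) without a tip mapping get NA")
  tips <- unique(lang[mapped])
  if (length(tips) == 1L) {           # all mapped societies share one tip
    D <- matrix(0, 1, 1, dimnames = list(tips, tips))
  } else if (length(tips) == 2L) {
    keep <- ape::keep.tip(tree, tips)
    d12 <- sum(keep$edge.length)
    D <- matrix(c(0, d12, d12, 0), 2, dimnames = list(tips, tips))
  } else {
    D <- ape::cophenetic.phylo(ape::keep.tip(tree, tips))
  }
  out <- rep(NA_real_, nrow(societies))
  for (i in which(mapped)) {
    own_tip <- lang[i]
    other_tips <- unique(lang[mapped & societies$society_id != societies$society_id[i]])
    if (!length(other_tips)) next
    if (own_tip %in% other_tips) { out[i] <- 0; next }
    out[i] <- min(D[own_tip, other_tips])
  }
  data.frame(society_id = societies$society_id, phylo_nn = out,
             stringsAsFactors = FALSE)
}

#' Leave-one-out society mean unusualness
#'
#' For each song, the arithmetic mean of the unusualness of the *other* songs
#' from the same society — the song-level operationalisation of a society's
#' musical style. Missing for songs whose society has no other scored song.
#'
#' @param scores an `unusualness_scores` table ([unusualness()]).
#' @return A data.frame `song_id`, `society_mean_loo`.
#' @export
society_mean_loo <- function(scores) {
  tot <- tapply(scores$unusualness, scores$society_id, sum)
  n <- tapply(scores$unusualness, scores$society_id, length)
  s <- as.character(scores$society_id)
  val <- (tot[s] - scores$unusualness) / (n[s] - 1)
  val[n[s] == 1L] <- NA_real_
  data.frame(song_id = scores$song_id, society_mean_loo = as.numeric(val),
             stringsAsFactors = FALSE)
}

#' Standardize columns to mean 0, sd 1
#'
#' Z-scores using the sample standard deviation (n - 1) over non-missing
#' rows; missing entries are preserved. Idempotent up to floating error.
#'
#' @param table a data.frame.
#' @param columns character vector of numeric columns to standardize.
#' @return The table with the named columns standardized.
#' @export
standardize <- function(table, columns) {
  for (cl in columns) {
    v <- table[[cl]]
    if (is.null(v)) stop("no such column: ", cl, call. = FALSE)
    ok <- !is.na(v)
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0)
      stop("zero variance in column '", cl, "'", call. = FALSE)
    table[[cl]] <- (v - mean(v[ok])) / s
  }
  table
}

#' Assemble the per-song predictor table
#'
#' Joins the song unusualness scores with the contact/isolation and
#' society-trait covariates used to explain them: neighbour counts within
#' `radius_km`, patristic nearest-neighbour distance, kinship/economic (and
#' optionally general) trait unusualness, and the leave-one-out society mean.
#' Rows missing any required covariate are flagged (`complete`) and the
#' listwise-deletion count is reported; the model fitters use complete rows.
#'
#' @param scores song scores from [unusualness()].
#' @param traits trait table ([read_traits()]), or NULL to skip trait
#'   covariates.
#' @param societies society table.
#' @param tree language phylogeny, or NULL to skip the phylogenetic covariate.
#' @param radius_km neighbour radius (default 500 km).
#' @param standardize_cols standardize response and covariates to mean 0,
#'   sd 1 over complete rows (default TRUE)?
#' @param include_general also compute the aggregate kinship+economic trait
#'   unusualness column `general_u`?
#' @inheritParams state_frequencies
#' @return A data.frame, one row per scored song, with columns `response`
#'   (the song's unusualness), `neighbours_radius`, `phylo_nn`, `kinship_u`,
#'   `economic_u` (and `general_u`), `society_mean_loo`, ids, and a logical
#'   `complete` flag.
#' @export
assemble_predictors <- function(scores, traits, societies, tree,
                                radius_km = 500, standardize_cols = TRUE,
                                include_general = FALSE,
                                floor_rule = "inv_support_plus1") {
  unknown <- setdiff(unique(scores$society_id), societies$society_id)
  if (length(unknown))
    stop("societies in scores but not in society table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)

  out <- data.frame(song_id = scores$song_id,
                    society_id = scores$society_id,
                    region_id = scores$region_id,
                    response = scores$unusualness,
                    stringsAsFactors = FALSE)
  nb <- neighbour_counts(societies, radius_km)
  out$neighbours_radius <- nb$n_neighbours[match(out$society_id, nb$society_id)]
  if (!is.null(tree)) {
    pn <- phylo_nn_distance(tree, societies)
    out$phylo_nn <- pn$phylo_nn[match(out$society_id, pn$society_id)]
  }
  if (!is.null(traits)) {
    ku <- society_trait_unusualness(traits, societies, "kinship", floor_rule)
    eu <- society_trait_unusualness(traits, societies, "economic", floor_rule)
    out$kinship_u <- ku$unusualness[match(out$society_id, ku$society_id)]
    out$economic_u <- eu$unusualness[match(out$society_id, eu$society_id)]
    if (include_general) {
      gu <- society_trait_unusualness(traits, societies, "general", floor_rule)
      out$general_u <- gu$unusualness[match(out$society_id, gu$society_id)]
    }
  }
  ml <- society_mean_loo(scores)
  out$society_mean_loo <- ml$society_mean_loo[match(out$song_id, ml$song_id)]

  covar <- setdiff(names(out),
                   c("song_id", "society_id", "region_id"))
  out$complete <- stats::complete.cases(out[covar])
  n_drop <- sum(!out$complete)
  if (n_drop > 0L)
    message("assemble_predictors: ", n_drop,
            " row(s) flagged incomplete (listwise deletion at fit time)")
  if (standardize_cols) {
    num_cols <- covar
    out[out$complete, num_cols] <-
      standardize(out[out$complete, num_cols, drop = FALSE], num_cols)
    out[!out$complete, num_cols] <- NA_real_
  }
  attr(out, "radius_km") <- radius_km
  attr(out, "n_listwise_deleted") <- n_drop
  out
}
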