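#' Leave-one-society-out regional state frequencies
#'
#' Estimates, for one region and one excluded (focal) society, the probability
#' of every permitted state of every feature among the region's songs that do
#' *not* belong to the focal society. Probabilities are raw relative
#' frequencies (they sum to 1 over observed states per feature); states with a
#' zero count then receive a small floor probability so that downstream
#' log-likelihoods stay finite.
#'
#' @param codings a `coding_table` (see [as_coding_table()]), normally already
#'   passed through [filter_complete()].
#' @param region region id whose songs form the baseline.
#' @param excluded_society society id whose songs are left out.
#' @param floor_rule floor for zero-count states: the string
#'   `"inv_support_plus1"` (the default, `1 / (support_n + 1)` where
#'   `support_n` is the number of baseline songs) or a fixed probability in
#'   `(0, 1)`.
#' @return A data.frame with columns `feature_id`, `state`, `count`, `prob`,
#'   and attributes `support_n`, `region`, `excluded_society`, `floor`.
#' @export
state_frequencies <- function(codings, region, excluded_society,
                              floor_rule = "inv_support_plus1") {
  scheme <- attr(codings, "scheme")
  base <- codings[codings$region_id == region &
                    codings$society_id != excluded_society, , drop = FALSE]
  n <- nrow(base)
  if (n == 0L)
    stop("insufficient regional support: no songs outside society '",
         excluded_society, "' in region '", region, "'", call. = FALSE)
  floor_p <- resolve_floor(floor_rule, n)
  feats <- scheme_feature_ids(scheme)
  res <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[i]
    states <- scheme$features[[f]]
    cnt <- tabulate(match(base[[f]], states), nbins = length(states))
    p <- cnt / n
    p[cnt == 0L] <- floor_p
    res[[i]] <- data.frame(feature_id = f, state = states, count = cnt,
                           prob = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, support_n = n, region = region,
            excluded_society = excluded_society, floor = floor_p)
}

resolve_floor <- function(floor_rule, support_n) {
  if (identical(floor_rule, "inv_support_plus1")) return(1 / (support_n + 1))
  fr <- suppressWarnings(as.numeric(floor_rule))
  if (is.na(fr) || fr <= 0 || fr >= 1)
    stop("floor_rule must be 'inv_support_plus1' or a probability in (0, 1)",
         call. = FALSE)
  fr
}

#' Unusualness of one song under a frequency table
#'
#' The unusualness of a song is the log-likelihood of its feature states under
#' leave-one-society-out regional frequencies:
#' \eqn{U = \sum_f \ln p_f(s_f)} over the scheme's features, natural log,
#' floored probabilities. `U <= 0` always; `U = 0` only when every state the
#' song uses is universal in the baseline. Smaller (more negative) values are
#' more unusual. The literal "log of the summed probabilities" reading is
#' available as `convention = "log_of_sum"` for sensitivity analysis; it is
#' not a likelihood and is not used downstream.
#'
#' @param song a one-row `coding_table` slice (or list/1-row data.frame with a
#'   `society_id` and one element per feature).
#' @param freqs a frequency table from [state_frequencies()]; must have been
#'   computed with the song's society excluded.
#' @param convention `"loglik"` (sum of log probabilities, default) or
#'   `"log_of_sum"`.
#' @return A single numeric unusualness value.
#' @export
song_unusualness <- function(song, freqs, convention = c("loglik", "log_of_sum")) {
  convention <- match.arg(convention)
  soc <- as.character(song[["society_id"]])
  if (!identical(soc, as.character(attr(freqs, "excluded_society"))))
    stop("frequency table was not computed with society '", soc,
         "' excluded (self-contamination guard)", call. = FALSE)
  key <- paste(freqs$feature_id, freqs$state)
  feats <- unique(freqs$feature_id)
  st <- vapply(feats, function(f) as.integer(song[[f]]), integer(1))
  if (anyNA(st))
    stop("song has missing states; apply filter_complete() first", call. = FALSE)
  p <- freqs$prob[match(paste(feats, st), key)]
  if (anyNA(p))
    stop("song uses a state absent from the scheme", call. = FALSE)
  if (convention == "loglik") sum(log(p)) else log(sum(p))
}

#' Score every song's unusualness by leave-one-society-out regional likelihood
#'
#' The full procedure: within each region, for each society in turn, estimate
#' state frequencies from all of the region's songs *except* that society's,
#' then score each of the society's songs by the log-likelihood of its states
#' ([song_unusualness()]). A society that is the only one in its region has no
#' out-of-society baseline; its songs are skipped and recorded in the
#' `skipped_societies` attribute.
#'
#' @inheritParams state_frequencies
#' @inheritParams song_unusualness
#' @param codings a complete `coding_table` (no missing states among scored
#'   songs; run [filter_complete()] first).
#' @return An object of class `unusualness_scores`: a data.frame with columns
#'   `song_id`, `society_id`, `region_id`, `unusualness`,
#'   `n_items_scored`, sorted by (region, society, song) for reproducibility.
#' @examples
#' sim <- simulate_study(sim_config(n_regions = 2, societies_per_region = 4,
#'                                  songs_per_society = 3:5, n_features = 8),
#'                       seed = 1)
#' u <- unusualness(sim$codings)
#' summary(u)
#' @export
unusualness <- function(codings, floor_rule = "inv_support_plus1",
                        convention = c("loglik", "log_of_sum")) {
  convention <- match.arg(convention)
  scheme <- attr(codings, "scheme")
  feats <- scheme_feature_ids(scheme)
  if (anyNA(codings[feats]))
    stop("coding table contains missing states; run filter_complete() first",
         call. = FALSE)
  skipped <- character(0)
  res <- list()
  for (r in sort(unique(codings$region_id))) {
    in_r <- codings[codings$region_id == r, , drop = FALSE]
    for (s in sort(unique(in_r$society_id))) {
      own <- in_r[in_r$society_id == s, , drop = FALSE]
      if (nrow(in_r) - nrow(own) == 0L) {
        skipped <- c(skipped, s)
        next
      }
      fr <- state_frequencies(codings, r, s, floor_rule)
      u <- vapply(seq_len(nrow(own)), function(i)
        song_unusualness(own[i, , drop = FALSE], fr, convention), numeric(1))
      res[[length(res) + 1L]] <- data.frame(
        song_id = own$song_id, society_id = s, region_id = r,
        unusualness = u, n_items_scored = length(feats),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    stop("no songs could be scored: every region has a single society",
         call. = FALSE)
  out <- do.call(rbind, res)
  out <- out[order(out$region_id, out$society_id, out$song_id), , drop = FALSE]
  rownames(out) <- NULL
  if (length(skipped))
    message("skipped ", length(skipped),
            " society(ies) with no out-of-society regional songs")
  structure(out, skipped_societies = skipped, convention = convention,
            floor_rule = floor_rule,
            class = c("unusualness_scores", "data.frame"))
}

#' @rdname unusualness
#' @export
all_song_unusualness <- unusualness

#' Societal trait unusualness
#'
#' Applies the leave-one-society-out frequency logic to categorical societal
#' traits (e.g. Ethnographic Atlas kinship and economic variables). Each
#' society holds at most one state per trait, so the baseline for a focal
#' society is the other societies of its region. The score is the *mean* (not
#' sum) of `ln p` over the society's non-missing traits in the theme, so that
#' societies with different trait coverage remain comparable;
#' `n_items_scored` records the traits used.
#'
#' @param traits a trait table from [read_traits()] / [as_trait_table()].
#' @param societies a society table ([read_societies()]); supplies each
#'   society's region.
#' @param theme `"kinship"`, `"economic"`, or `"general"` (the union).
#' @inheritParams state_frequencies
#' @return A data.frame with columns `society_id`, `region_id`,
#'   `unusualness`, `n_items_scored`; societies with no usable traits, or
#'   alone in their region, get `NA`.
#' @export
society_trait_unusualness <- function(traits, societies,
                                      theme = c("kinship", "economic", "general"),
                                      floor_rule = "inv_support_plus1") {
  theme <- match.arg(theme)
  tt <- if (theme == "general") traits else traits[traits$theme == theme, , drop = FALSE]
  tt <- tt[!is.na(tt$state), , drop = FALSE]
  reg <- stats::setNames(societies$region_id, societies$society_id)
  unknown <- setdiff(unique(tt$society_id), names(reg))
  if (length(unknown))
    warning("trait rows for societies absent from the society table dropped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  tt <- tt[tt$society_id %in% names(reg), , drop = FALSE]
  tt$region_id <- unname(reg[tt$society_id])

  out <- data.frame(society_id = societies$society_id,
                    region_id = societies$region_id,
                    unusualness = NA_real_, n_items_scored = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    s <- out$society_id[i]; r <- out$region_id[i]
    own <- tt[tt$society_id == s, , drop = FALSE]
    if (nrow(own) == 0L) next
    others <- tt[tt$region_id == r & tt$society_id != s, , drop = FALSE]
    n_other_soc <- length(unique(societies$society_id[
      societies$region_id == r & societies$society_id != s]))
    if (n_other_soc == 0L) next   # single-society region: no baseline
    lp <- numeric(0)
    for (j in seq_len(nrow(own))) {
      tr <- own$trait_id[j]
      base <- others$state[others$trait_id == tr]
      nb <- length(base)
      if (nb == 0L) next          # trait unobserved elsewhere in region
      cnt <- sum(base == own$state[j])
      p <- if (cnt == 0L) resolve_floor(floor_rule, nb) else cnt / nb
      lp <- c(lp, log(p))
    }
    if (length(lp)) {
      out$unusualness[i] <- mean(lp)
      out$n_items_scored[i] <- length(lp)
    }
  }
  out <- out[order(out$region_id, out$society_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.unusualness_scores <- function(x, ...) {
  cat("Unusualness scores:", nrow(x), "songs,",
      length(unique(x$society_id)), "societies,",
      length(unique(x$region_id)), "regions\n")
  cat(sprintf("  range [%.3f, %.3f], median %.3f  (smaller = more unusual)\n",
              min(x$unusualness), max(x$unusualness),
              stats::median(x$unusualness)))
  sk <- attr(x, "skipped_societies")
  if (length(sk)) cat("  skipped societies (no regional baseline):",
                      length(sk), "\n")
  invisible(x)
}

#' @export
summary.unusualness_scores <- function(object, top_p = 0.03, ...) {
  top <- top_percent_summary(object, top_p)
  structure(list(n_songs = nrow(object),
                 n_societies = length(unique(object$society_id)),
                 quantiles = stats::quantile(object$unusualness,
                                             c(0, .01, .05, .25, .5, .75, 1)),
                 top_p = top_p, top = top),
            class = "summary.unusualness_scores")
}

#' @export
print.summary.unusualness_scores <- function(x, ...) {
  cat("Unusualness of", x$n_songs, "songs from", x$n_societies, "societies\n")
  print(round(x$quantiles, 3))
  cat(sprintf("Top %.0f%% most unusual: %d songs from %d societies\n",
              100 * x$top_p, x$top$n_songs, x$top$n_societies))
  invisible(x)
}

#' @export
plot.unusualness_scores <- function(x, top_p = 0.03, breaks = 40, ...) {
  graphics::hist(x$unusualness, breaks = breaks, main = "Song unusualness",
                 xlab = "unusualness (log-likelihood; smaller = more unusual)",
                 col = "grey85", border = "white", ...)
  thr <- top_percent_summary(x, top_p)$threshold
  graphics::abline(v = thr, lty = 2)
  invisible(x)
}
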