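#' Summarise the most unusual songs
#'
#' Selects the most unusual (smallest-score) songs. In `"count"` mode the
#' `ceiling(p * N)` smallest scores are taken, ties at the cutoff broken by
#' `song_id` for determinism; in `"quantile"` mode every song at or below the
#' empirical `p`-quantile of the score distribution is taken (the
#' distribution-threshold reading of a "top p%" cutoff).
#'
#' @param scores an `unusualness_scores` table.
#' @param p tail proportion, in (0, 1); default 0.03.
#' @param mode `"count"` (default) or `"quantile"`.
#' @return A list: `n_songs`, `n_societies`, `threshold` (score of the least
#'   unusual selected song), and `songs` (the selected rows, most unusual
#'   first).
#' @export
top_percent_summary <- function(scores, p = 0.03, mode = c("count", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(p > 0, p < 1)
  ord <- order(scores$unusualness, scores$song_id)
  if (mode == "count") {
    m <- ceiling(p * nrow(scores))
    sel <- ord[seq_len(m)]
  } else {
    thr <- stats::quantile(scores$unusualness, p, names = FALSE)
    sel <- ord[scores$unusualness[ord] <= thr]
  }
  songs <- scores[sel, , drop = FALSE]
  rownames(songs) <- NULL
  list(n_songs = nrow(songs),
       n_societies = length(unique(songs$society_id)),
       threshold = max(songs$unusualness),
       songs = as.data.frame(songs))
}

#' Rank societies by mean unusualness
#'
#' Societies represented by at least `min_songs` scored songs, ranked most
#' unusual (smallest mean) first, with the five-number summaries and Tukey
#' 1.5-IQR whiskers needed for boxplots.
#'
#' @param scores an `unusualness_scores` table.
#' @param min_songs minimum songs for a society to be ranked (default 5).
#' @return A data.frame, one row per ranked society: `rank`, ids, `n_songs`,
#'   `mean_unusualness`, quartiles (`q0`, `q25`, `q50`, `q75`, `q100`) and
#'   whisker ends (`whisker_lo`, `whisker_hi`).
#' @export
society_rankings <- function(scores, min_songs = 5) {
  n <- tapply(scores$unusualness, scores$society_id, length)
  keep <- names(n)[n >= min_songs]
  if (!length(keep)) {
    warning("no society has >= ", min_songs, " songs; empty ranking",
            call. = FALSE)
    return(data.frame(rank = integer(0), society_id = character(0),
                      region_id = character(0), n_songs = integer(0),
                      mean_unusualness = numeric(0)))
  }
  rows <- lapply(keep, function(s) {
    u <- scores$unusualness[scores$society_id == s]
    q <- stats::quantile(u, c(0, .25, .5, .75, 1), names = FALSE)
    iqr <- q[4] - q[2]
    data.frame(society_id = s,
               region_id = scores$region_id[scores$society_id == s][1],
               n_songs = length(u), mean_unusualness = mean(u),
               q0 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q100 = q[5],
               whisker_lo = min(u[u >= q[2] - 1.5 * iqr]),
               whisker_hi = max(u[u <= q[4] + 1.5 * iqr]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_unusualness, out$society_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Modal feature profile of a society against its regional frequencies
#'
#' For one society, the per-feature modal state across its songs (ties go to
#' the lower state code), paired with the leave-one-society-out regional
#' frequency of every permitted state — the data behind a profile plot in
#' which each state's symbol is sized by how common it is regionally. When
#' the scheme carries a 13-point display mapping, display positions are
#' attached.
#'
#' @param codings a complete `coding_table`.
#' @param society the focal society id.
#' @inheritParams state_frequencies
#' @return A data.frame, one row per (feature, state): `feature_id`,
#'   `state`, `display` (if available), `regional_prob` (floored LOSO
#'   frequency), `society_prop` (share of the society's songs using the
#'   state) and `modal` (logical).
#' @export
modal_profile <- function(codings, society, floor_rule = "inv_support_plus1") {
  scheme <- attr(codings, "scheme")
  own <- codings[codings$society_id == society, , drop = FALSE]
  if (nrow(own) == 0L) stop("unknown society: ", society, call. = FALSE)
  region <- own$region_id[1]
  fr <- state_frequencies(codings, region, society, floor_rule)
  feats <- scheme_feature_ids(scheme)
  out <- fr[c("feature_id", "state")]
  out$display <- NA_real_
  out$regional_prob <- fr$prob
  out$society_prop <- NA_real_
  out$modal <- FALSE
  for (f in feats) {
    idx <- which(out$feature_id == f)
    states <- out$state[idx]
    cnt <- vapply(states, function(st) sum(own[[f]] == st, na.rm = TRUE),
                  integer(1))
    out$society_prop[idx] <- cnt / nrow(own)
    modal_state <- states[which.max(cnt)]  # ties: lower code (states ordered)
    out$modal[idx] <- states == modal_state
    if (!is.null(scheme$display))
      out$display[idx] <- scheme$display[[f]][match(states, scheme$features[[f]])]
  }
  rownames(out) <- NULL
  out
}

#' Sampling-bias check: society mean unusualness vs repertoire size
#'
#' Pearson correlation between a society's mean unusualness and its number of
#' scored songs. A correlation near zero indicates that differences in how
#' many songs were recorded per society do not drive the unusualness scores.
#'
#' @param scores an `unusualness_scores` table covering at least three
#'   societies.
#' @return A list: `r` (Pearson correlation, `NA` when undefined),
#'   `defined` (FALSE when either variable has zero variance),
#'   `n_societies`.
#' @export
sampling_bias_check <- function(scores) {
  mu <- tapply(scores$unusualness, scores$society_id, mean)
  n <- tapply(scores$unusualness, scores$society_id, length)
  if (length(mu) < 3) stop("need at least 3 societies", call. = FALSE)
  if (stats::sd(mu) == 0 || stats::sd(n) == 0)
    return(list(r = NA_real_, defined = FALSE, n_societies = length(mu)))
  list(r = stats::cor(as.numeric(mu), as.numeric(n)),
       defined = TRUE, n_societies = length(mu))
}
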