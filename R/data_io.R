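#' Read a song-coding table
#'
#' Reads a CSV with one row per song: identifier columns `song_id`,
#' `society_id`, `region_id` and one column per feature of `scheme`. Cells
#' that cannot be parsed as an integer, or whose value is not a permitted
#' state for that feature, are recorded as missing; a warning reports how many
#' cells were invalidated. Values in `missing_codes` (blank and `"NA"` by
#' default; extend for sentinel codes) are treated as missing silently.
#'
#' @param path path to a CSV file with a header row.
#' @param scheme a [feature_scheme()]; features absent from the file are an
#'   error, extra columns are ignored.
#' @param missing_codes character vector of cell values meaning "missing".
#' @return A `coding_table`: a data.frame with the three identifier columns
#'   and one integer column per scheme feature, the scheme attached as an
#'   attribute.
#' @export
read_codings <- function(path, scheme = default_scheme(),
                         missing_codes = c("", "NA")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE)
  as_coding_table(df, scheme, missing_codes = missing_codes)
}

#' Validate a data.frame as a coding table
#'
#' @param df data.frame with `song_id`, `society_id`, `region_id` and one
#'   column per scheme feature.
#' @inheritParams read_codings
#' @return A validated `coding_table`.
#' @export
as_coding_table <- function(df, scheme = default_scheme(),
                            missing_codes = c("", "NA")) {
  ids <- c("song_id", "society_id", "region_id")
  miss_id <- setdiff(ids, names(df))
  if (length(miss_id))
    stop("missing identifier column(s): ", paste(miss_id, collapse = ", "),
         call. = FALSE)
  feats <- scheme_feature_ids(scheme)
  miss_f <- setdiff(feats, names(df))
  if (length(miss_f))
    stop("coding table lacks feature column(s): ",
         paste(utils::head(miss_f, 5), collapse = ", "),
         if (length(miss_f) > 5) ", ...", call. = FALSE)
  if (anyDuplicated(df$song_id))
    stop("duplicate song_id values", call. = FALSE)
  # region must be a function of society
  s2r <- unique(df[, c("society_id", "region_id")])
  if (anyDuplicated(s2r$society_id))
    stop("society assigned to more than one region: ",
         paste(unique(s2r$society_id[duplicated(s2r$society_id)]), collapse = ", "),
         call. = FALSE)

  out <- df[ids]
  out$song_id <- as.character(out$song_id)
  out$society_id <- as.character(out$society_id)
  out$region_id <- as.character(out$region_id)
  n_bad <- 0L
  for (f in feats) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      v <- trimws(as.character(v))
      v[v %in% missing_codes] <- NA_character_
      vi <- suppressWarnings(as.integer(v))
      n_bad <- n_bad + sum(!is.na(v) & is.na(vi))
      v <- vi
    } else v <- as.integer(v)
    bad_state <- !is.na(v) & !(v %in% scheme$features[[f]])
    n_bad <- n_bad + sum(bad_state)
    v[bad_state] <- NA_integer_
    out[[f]] <- v
  }
  if (n_bad > 0L)
    warning(n_bad, " cell(s) unparseable or outside the scheme; set to missing",
            call. = FALSE)
  rownames(out) <- NULL
  structure(out, scheme = scheme, class = c("coding_table", "data.frame"))
}

#' Keep only songs coded on every feature
#'
#' Whole-song deletion: a song is retained iff it has a non-missing, permitted
#' state for every feature in the scheme. The numbers of dropped songs and of
#' societies that lose all songs are attached as attributes and reported.
#'
#' @param codings a `coding_table`.
#' @param quiet suppress the drop report message.
#' @return The filtered `coding_table` with attributes `n_dropped_songs` and
#'   `n_dropped_societies`.
#' @export
filter_complete <- function(codings, quiet = FALSE) {
  scheme <- attr(codings, "scheme")
  feats <- scheme_feature_ids(scheme)
  keep <- stats::complete.cases(codings[feats])
  out <- codings[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no complete songs remain after filtering (",
         nrow(codings), " songs checked on ", length(feats), " features)",
         call. = FALSE)
  dropped_soc <- setdiff(codings$society_id, out$society_id)
  if (!quiet && sum(!keep) > 0L)
    message("filter_complete: dropped ", sum(!keep), " song(s); ",
            length(dropped_soc), " society(ies) lost entirely")
  rownames(out) <- NULL
  structure(out, scheme = scheme,
            n_dropped_songs = sum(!keep),
            n_dropped_societies = length(dropped_soc),
            class = c("coding_table", "data.frame"))
}

#' Read a society table
#'
#' CSV columns: `society_id`, `region_id`, `latitude`, `longitude` and
#' optionally `language_id` (matching a tip label of the language phylogeny;
#' may be empty for societies without a placed language).
#'
#' @param path path to a CSV file.
#' @return A validated data.frame.
#' @export
read_societies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("society_id", "region_id", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("society table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$society_id)) stop("duplicate society_id", call. = FALSE)
  bad <- !is.na(df$latitude) &
    (df$latitude < -90 | df$latitude > 90 |
       df$longitude < -180 | df$longitude > 180)
  if (any(bad))
    stop("coordinates out of range for: ",
         paste(df$society_id[bad], collapse = ", "), call. = FALSE)
  if (!"language_id" %in% names(df)) df$language_id <- NA_character_
  df$language_id[!is.na(df$language_id) & df$language_id == ""] <- NA_character_
  df
}

#' Read a society-trait table and assign trait themes
#'
#' CSV columns: `society_id`, `trait_id`, `state`. Each trait is assigned a
#' theme (`"kinship"` or `"economic"`) through `theme_map`; a trait without a
#' mapping is an error, since themed unusualness would silently change
#' meaning. Missing states may be encoded as blank or `"NA"`.
#'
#' @param path path to a CSV file.
#' @param theme_map either a named character vector (`trait_id -> theme`), a
#'   data.frame with columns `trait_id` and `theme`, or a path to such a CSV.
#'   Defaults to the packaged map ([default_theme_map()]).
#' @return A data.frame with columns `society_id`, `trait_id`, `state`
#'   (integer, NA allowed) and `theme`.
#' @export
read_traits <- function(path, theme_map = default_theme_map()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("society_id", "trait_id", "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trait table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as_trait_table(df, theme_map)
}

#' @rdname read_traits
#' @param df a data.frame with columns `society_id`, `trait_id`, `state`.
#' @export
as_trait_table <- function(df, theme_map = default_theme_map()) {
  if (is.character(theme_map) && length(theme_map) == 1L && file.exists(theme_map))
    theme_map <- utils::read.csv(theme_map, stringsAsFactors = FALSE)
  if (is.data.frame(theme_map)) {
    tm <- theme_map$theme
    names(tm) <- theme_map$trait_id
    theme_map <- tm
  }
  if (!all(theme_map %in% c("kinship", "economic")))
    stop("themes must be 'kinship' or 'economic'", call. = FALSE)
  if (anyDuplicated(paste(df$society_id, df$trait_id)))
    stop("more than one state for a (society, trait) pair", call. = FALSE)
  unmapped <- setdiff(unique(df$trait_id), names(theme_map))
  if (length(unmapped))
    stop("unmapped trait theme: ", paste(unmapped, collapse = ", "), call. = FALSE)
  st <- df$state
  if (!is.numeric(st)) {
    st <- trimws(as.character(st))
    st[st %in% c("", "NA")] <- NA_character_
    st <- suppressWarnings(as.integer(st))
  }
  data.frame(society_id = as.character(df$society_id),
             trait_id = as.character(df$trait_id),
             state = as.integer(st),
             theme = unname(theme_map[df$trait_id]),
             stringsAsFactors = FALSE)
}

#' The packaged default trait theme map
#'
#' Maps Ethnographic-Atlas-style variable ids to the `kinship` and `economic`
#' themes. A default offered for convenience; override with your own map when
#' the trait source differs.
#'
#' @return A named character vector (`trait_id -> theme`).
#' @export
default_theme_map <- function() {
  df <- utils::read.csv(system.file("extdata", "trait_theme_map.csv",
                                    package = "unusualness", mustWork = TRUE),
                        stringsAsFactors = FALSE)
  stats::setNames(df$theme, df$trait_id)
}

#' Read a language phylogeny from a Newick file
#'
#' @param path path to a Newick tree file.
#' @return An [ape::read.tree()] `phylo` object, validated to have unique tip
#'   labels and non-negative branch lengths.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr)) stop("malformed Newick file: ", path, call. = FALSE)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels", call. = FALSE)
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  tr
}

#' Write pipeline tables to CSV
#'
#' Plain CSV writers whose output re-reads to an identical table with the
#' matching reader.
#'
#' @param x the table to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codings <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_codings
#' @export
write_societies <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_codings
#' @export
write_traits <- function(x, path) {
  utils::write.csv(x[c("society_id", "trait_id", "state")], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
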