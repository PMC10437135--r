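#' Feature scheme: the permitted categorical states of each coded feature
#'
#' A feature scheme declares, for every coded feature (a Cantometric "line"),
#' the set of permitted integer state codes and, optionally, where each state
#' sits on the 13-point display line used in profile plots. The scheme is data,
#' not code: the package ships a structural default mirroring the 37
#' Cantometric features (see [default_scheme()]), and users analysing a real
#' release should load the release's own codebook with [read_scheme()].
#'
#' @param features named list; one element per feature, an integer vector of
#'   permitted state codes (at least two, unique within the feature).
#' @param feature_names optional named character vector of human-readable
#'   feature names; names must match `names(features)`.
#' @param display optional named list parallel to `features`, each element a
#'   numeric vector (same length as the feature's states) of positions in
#'   `[1, 13]`.
#'
#' @return An object of class `feature_scheme`.
#' @seealso [read_scheme()], [default_scheme()]
#' @export
feature_scheme <- function(features, feature_names = NULL, display = NULL) {
  if (!is.list(features) || is.null(names(features)) || any(names(features) == ""))
    stop("`features` must be a named list of state-code vectors", call. = FALSE)
  if (anyDuplicated(names(features)))
    stop("duplicate feature ids in scheme", call. = FALSE)
  features <- lapply(features, function(s) {
    s <- as.integer(s)
    if (length(s) < 2L) stop("every feature needs at least 2 states", call. = FALSE)
    if (anyDuplicated(s)) stop("state codes must be unique within a feature", call. = FALSE)
    s
  })
  if (!is.null(display)) {
    if (!setequal(names(display), names(features)))
      stop("`display` names must match feature ids", call. = FALSE)
    for (f in names(display)) {
      d <- display[[f]]
      if (length(d) != length(features[[f]]) || any(d < 1 | d > 13))
        stop("display positions must map each state of '", f, "' into [1, 13]",
             call. = FALSE)
    }
    display <- display[names(features)]
  }
  if (!is.null(feature_names)) feature_names <- feature_names[names(features)]
  structure(list(features = features, feature_names = feature_names,
                 display = display),
            class = "feature_scheme")
}

#' Read a feature scheme from a long-format CSV
#'
#' Expects columns `feature_id` and `state`, with optional `feature_name` and
#' `display` (13-point position) columns; one row per permitted state.
#'
#' @param path path to a CSV file.
#' @return A [feature_scheme()] object.
#' @export
read_scheme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "state")
  if (!all(need %in% names(df)))
    stop("scheme file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  ids <- unique(df$feature_id)
  feats <- lapply(ids, function(f) df$state[df$feature_id == f])
  names(feats) <- ids
  nms <- NULL
  if ("feature_name" %in% names(df)) {
    nms <- vapply(ids, function(f) df$feature_name[df$feature_id == f][1], "")
    names(nms) <- ids
  }
  disp <- NULL
  if ("display" %in% names(df)) {
    disp <- lapply(ids, function(f) df$display[df$feature_id == f])
    names(disp) <- ids
  }
  feature_scheme(feats, feature_names = nms, display = disp)
}

#' The packaged default feature scheme
#'
#' A structural default with 37 features on the 13-point Cantometric line
#' (tempo, feature 24, has six states). State inventories are a plausible
#' default, not a transcription of any specific data release; pass a release
#' codebook to [read_scheme()] for real analyses.
#'
#' @return A [feature_scheme()] object with 37 features.
#' @export
default_scheme <- function() {
  read_scheme(system.file("extdata", "cantometrics_scheme.csv",
                          package = "unusualness", mustWork = TRUE))
}

#' @export
print.feature_scheme <- function(x, ...) {
  ns <- lengths(x$features)
  cat("Feature scheme:", length(ns), "features,",
      min(ns), "-", max(ns), "states each\n")
  invisible(x)
}

scheme_feature_ids <- function(scheme) names(scheme$features)
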