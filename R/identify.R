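# Query-side pipeline: score every query slice against every database
# entry, reduce each score list to per-identity maxima, tally competition
# ranks across the filtered lists, consolidate into one ranked identity
# list (score-based or rank-based strategy) and report the position of a
# sought identity.

#' Query slice-window indices
#'
#' Slice indices covering `span_mm` before and after the central slice
#' (inclusive): `center +/- k` with `k = floor(span_mm / thickness)`,
#' clipped to the stack. At 0.625 mm thickness and the default 7.5 mm span
#' this selects 25 slices; at 2.5 mm, 7 slices.
#'
#' @param center_index 0-based central slice index.
#' @param slice_thickness_mm positive slice thickness in mm.
#' @param span_mm window half-width in mm (default 7.5).
#' @param stack_size number of slices in the stack.
#' @return increasing vector of 0-based indices.
#' @export
slice_window <- function(center_index, slice_thickness_mm, span_mm = 7.5,
                         stack_size = Inf) {
  if (slice_thickness_mm <= 0)
    stop("`slice_thickness_mm` must be positive", call. = FALSE)
  if (center_index < 0 || center_index >= stack_size)
    stop("`center_index` must lie within the stack", call. = FALSE)
  k <- floor(span_mm / slice_thickness_mm)
  idx <- (center_index - k):(center_index + k)
  idx[idx >= 0 & idx < stack_size]
}

#' Score query feature sets against a database
#'
#' One score list per query set: every database entry is compared with
#' [score_pair()] (query as set A). Empty query sets are skipped with a
#' warning and recorded as `NULL`. RANSAC seeds are derived per
#' (query, entry) pair from `seed`, so results are reproducible.
#'
#' @param query_sets list of [feature_set()] objects (optionally named).
#' @param db a `cvdatabase`.
#' @param params a [match_params()] object.
#' @param seed global integer seed.
#' @param check_params optional list with `preprocess` and `akaze` params
#'   used to extract the queries; when given, the database fingerprint is
#'   checked (warning on mismatch).
#' @return list of score lists; each is a data frame with `entry_id`,
#'   `identity_id`, `score_percent` and attribute `query_ref`.
#' @export
query_database <- function(query_sets, db, params = match_params(),
                           seed = 1L, check_params = NULL) {
  stopifnot(inherits(db, "cvdatabase"))
  if (length(db$entries) == 0L) stop("database is empty", call. = FALSE)
  if (!is.null(check_params))
    check_params_fingerprint(db, check_params$preprocess, check_params$akaze)
  entry_ids <- vapply(db$entries, `[[`, "", "entry_id")
  identity_ids <- vapply(db$entries, `[[`, "", "identity_id")
  qnames <- names(query_sets) %||% as.character(seq_along(query_sets))
  out <- vector("list", length(query_sets))
  names(out) <- qnames
  for (qi in seq_along(query_sets)) {
    q <- query_sets[[qi]]
    if (is.null(q) || q$n == 0L) {
      warning("query set ", qnames[qi], " is empty; skipped")
      out[qi] <- list(NULL)
      next
    }
    scores <- vapply(seq_along(db$entries), function(ei)
      score_pair(q, db$entries[[ei]]$feature_set, params,
                 seed = derive_seed(seed, qnames[qi], entry_ids[ei])
                 )$score_percent, 0)
    sl <- data.frame(entry_id = entry_ids, identity_id = identity_ids,
                     score_percent = scores)
    attr(sl, "query_ref") <- qnames[qi]
    out[[qi]] <- sl
  }
  out
}

#' Per-identity maxima of a score list
#'
#' Each identity is represented by the highest score over its database
#' entries.
#'
#' @param score_list data frame from [query_database()].
#' @return named numeric vector (names = identity_id, sorted), with the
#'   `query_ref` attribute carried over.
#' @export
filter_max_per_identity <- function(score_list) {
  v <- tapply(score_list$score_percent, score_list$identity_id, max)
  out <- as.numeric(v)
  names(out) <- names(v)
  out <- out[order(names(out))]
  attr(out, "query_ref") <- attr(score_list, "query_ref")
  out
}

#' Rank tallies across filtered lists
#'
#' Competition ranking ("1224") within every filtered list, so tied top
#' scores make several identities share rank 1. For each identity:
#' how often it achieved rank 1, how often it ranked within the top 10,
#' and its maximum score over all lists.
#'
#' @param filtered_lists list of named score vectors from
#'   [filter_max_per_identity()]; `NULL` elements (skipped queries) are
#'   ignored.
#' @return data frame with `identity_id`, `rank1_count`, `top10_count`,
#'   `max_score`.
#' @export
tally_ranks <- function(filtered_lists) {
  filtered_lists <- filtered_lists[!vapply(filtered_lists, is.null, TRUE)]
  if (length(filtered_lists) == 0L)
    stop("at least one filtered list is required", call. = FALSE)
  ids <- names(filtered_lists[[1L]])
  rank1 <- top10 <- stats::setNames(integer(length(ids)), ids)
  maxs <- stats::setNames(rep(-Inf, length(ids)), ids)
  for (fl in filtered_lists) {
    stopifnot(identical(names(fl), ids))
    r <- rank(-unclass(fl), ties.method = "min")
    rank1 <- rank1 + (r == 1L)
    top10 <- top10 + (r <= 10L)
    maxs <- pmax(maxs, fl)
  }
  data.frame(identity_id = ids, rank1_count = as.integer(rank1),
             top10_count = as.integer(top10), max_score = as.numeric(maxs),
             row.names = NULL)
}

#' Consolidate rank tallies into a final ranked identity list
#'
#' Two strategies:
#' * `score_based`: descending by maximum score, then rank-1 count, then
#'   top-10 count.
#' * `rank_based`: descending by rank-1 count, then top-10 count, then
#'   maximum score.
#'
#' Residual ties are broken by `identity_id` ascending so the order is a
#' deterministic total order.
#'
#' @param tallies data frame from [tally_ranks()].
#' @param strategy `"rank_based"` or `"score_based"`.
#' @return data frame of identities in consolidated order with their sort
#'   keys and a `position` column (1-based); attribute `strategy`.
#' @export
consolidate <- function(tallies, strategy = c("rank_based", "score_based")) {
  strategy <- match.arg(strategy)
  ord <- if (strategy == "score_based")
    order(-tallies$max_score, -tallies$rank1_count, -tallies$top10_count,
          tallies$identity_id)
  else
    order(-tallies$rank1_count, -tallies$top10_count, -tallies$max_score,
          tallies$identity_id)
  out <- tallies[ord, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  out
}

#' Position of a sought identity in the consolidated list
#'
#' @param consolidated data frame from [consolidate()].
#' @param sought identity key.
#' @return 1-based position.
#' @export
evaluate_position <- function(consolidated, sought) {
  pos <- match(sought, consolidated$identity_id)
  if (is.na(pos))
    stop("identity not enrolled in the database: ", sought, call. = FALSE)
  pos
}

#' Pre-filter database entries by sex and approximate age
#'
#' Retains entries whose sex matches (entries with unknown sex are always
#' retained) and whose age at the study date, computed from the birth date,
#' falls in `age_range_years` (entries without a birth date are retained).
#' Narrowing the candidate set this way shortens the search when demographic
#' information about the decedent is available.
#'
#' @param db a `cvdatabase`.
#' @param sex optional `"female"` or `"male"`.
#' @param age_range_years optional length-2 increasing interval in years.
#' @param query_study_date optional "YYYYMMDD" date at which the age is
#'   evaluated; defaults to each entry's own study date.
#' @return a filtered `cvdatabase`.
#' @export
prefilter_candidates <- function(db, sex = NULL, age_range_years = NULL,
                                 query_study_date = NULL) {
  stopifnot(inherits(db, "cvdatabase"))
  if (!is.null(age_range_years)) {
    if (length(age_range_years) != 2L ||
        age_range_years[1] > age_range_years[2])
      stop("`age_range_years` must be an increasing interval", call. = FALSE)
  }
  keep <- vapply(db$entries, function(e) {
    if (!is.null(sex) && e$sex != "unknown" && e$sex != sex) return(FALSE)
    if (!is.null(age_range_years)) {
      if (is.null(e$birth_date) || is.na(e$birth_date)) return(TRUE)
      ref <- query_study_date %||% e$study_date
      bd <- as.Date(e$birth_date, "%Y%m%d")
      sd <- as.Date(ref, "%Y%m%d")
      if (is.na(bd) || is.na(sd)) return(TRUE)
      age <- as.numeric(sd - bd) / 365.25
      if (age < age_range_years[1] || age > age_range_years[2])
        return(FALSE)
    }
    TRUE
  }, TRUE)
  new_cvdatabase(db$entries[keep], db$params_fingerprint,
                 paste0(db$provenance, "; prefiltered"))
}

#' End-to-end query against a database with a CSV report
#'
#' Reads a postmortem query series, selects the slice window around
#' `center_slice`, preprocesses and extracts features per slice, scores
#' them against the database, consolidates and (optionally) reports the
#' sought identity's position. The report CSV is written deterministically:
#' identical inputs, config and seed give byte-identical files.
#'
#' @param db a `cvdatabase` or path to a saved database file.
#' @param query either a DICOM series directory or a list of
#'   [slice_image()] objects forming the query stack.
#' @param center_slice 0-based index of the central slice (the one showing
#'   the largest cavity representation; chosen by the caller).
#' @param strategy consolidation strategy, see [consolidate()].
#' @param out_csv optional path for the report CSV.
#' @param config pipeline configuration, see [default_config()].
#' @param seed global integer seed.
#' @param sought optional identity key; adds position information.
#' @param db_key key for an encrypted database file.
#' @return list with `consolidated` (data frame), `tallies`, and
#'   `position`/`sought` when requested.
#' @export
run_query_report <- function(db, query, center_slice,
                             strategy = c("rank_based", "score_based"),
                             out_csv = NULL, config = default_config(),
                             seed = 1L, sought = NULL, db_key = NULL) {
  strategy <- match.arg(strategy)
  if (is.character(db)) db <- load_database(db, key = db_key)
  stack <- if (is.character(query)) {
    lapply(read_dicom_series(query), `[[`, "image")
  } else query
  if (length(stack) == 0L) stop("empty query stack", call. = FALSE)
  thickness <- stack[[1L]]$slice_thickness_mm
  idx <- slice_window(center_slice, thickness, config$span_mm,
                      length(stack))
  query_sets <- lapply(stack[idx + 1L], function(img)
    extract_features(preprocess_slice(img, config$preprocess),
                     config$akaze,
                     source_ref = list(series = img$series_id,
                                       slice_index = img$slice_index)))
  names(query_sets) <- sprintf("slice%03d", idx)
  lists <- query_database(query_sets, db, config$match, seed = seed,
                          check_params = list(preprocess = config$preprocess,
                                              akaze = config$akaze))
  filtered <- lapply(lists, function(l)
    if (is.null(l)) NULL else filter_max_per_identity(l))
  tallies <- tally_ranks(filtered)
  consolidated <- consolidate(tallies, strategy)
  res <- list(consolidated = consolidated, tallies = tallies,
              strategy = strategy)
  if (!is.null(sought)) {
    res$sought <- sought
    res$position <- evaluate_position(consolidated, sought)
  }
  if (!is.null(out_csv)) {
    rep_df <- consolidated[, c("position", "identity_id", "rank1_count",
                               "top10_count", "max_score")]
    rep_df$max_score <- sprintf("%.6f", rep_df$max_score)
    utils::write.csv(rep_df, out_csv, row.names = FALSE, quote = FALSE)
  }
  res
}

#' Cumulative match characteristic table
#'
#' Rank-k identification rates over a batch of labelled query results.
#'
#' @param positions integer vector of consolidated positions of the true
#'   identities (one per query case).
#' @param max_rank largest rank to tabulate.
#' @return data frame with `rank` and `identification_rate` (fraction of
#'   cases identified at that rank or better).
#' @export
cmc_table <- function(positions, max_rank = 10L) {
  data.frame(rank = seq_len(max_rank),
             identification_rate = vapply(seq_len(max_rank), function(k)
               mean(positions <= k), 0))
}
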