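#' Validate EMA records
#'
#' Checks the affect items against the ordinal response range and rejects
#' duplicate `(participant, timestamp, item)` rows (keeping the first
#' occurrence). Non-affect items (the social-context prompts) are passed
#' through untouched.
#'
#' @param records data.frame `participant_id`, `timestamp` (POSIXct), `item`,
#'   `response` (integer).
#' @param affect_items items subject to the range check.
#' @param scale_max top of the 0-based ordinal scale (5 = 6-point scale).
#' @return list `clean` (accepted rows) and `rejected` (rows with a `reason`
#'   column: `"out of range"` or `"duplicate"`).
#' @export
validate_ema <- function(records, affect_items = c("happy", "sad", "anxious"),
                         scale_max = 5L) {
  key <- paste(records$participant_id, records$timestamp, records$item)
  dup <- duplicated(key)
  oor <- records$item %in% affect_items &
    (is.na(records$response) | records$response < 0 |
       records$response > scale_max | records$response != round(records$response))
  reason <- ifelse(oor, "out of range", ifelse(dup, "duplicate", NA))
  rejected <- records[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  clean <- records[is.na(reason), , drop = FALSE]
  rownames(clean) <- rownames(rejected) <- NULL
  list(clean = clean, rejected = rejected)
}

#' Daily mean EMA affect
#'
#' Arithmetic mean of each affect item over the prompts answered on each
#' local calendar day (same day convention as the exposure module). Items
#' with no answers on a day are missing (`NA`), never zero;
#' `n_prompts_answered` counts distinct prompt timestamps with at least one
#' affect answer.
#'
#' @inheritParams validate_ema
#' @param tz study time zone.
#' @return data.frame `participant_id`, `date`, `mean_<item>` per affect
#'   item, `n_prompts_answered`.
#' @export
daily_mean_affect <- function(records,
                              affect_items = c("happy", "sad", "anxious"),
                              tz = "America/Los_Angeles") {
  r <- records[records$item %in% affect_items, , drop = FALSE]
  if (!nrow(r)) {
    out <- data.frame(participant_id = character(), date = as.Date(character()))
    for (it in affect_items) out[[paste0("mean_", it)]] <- numeric()
    out$n_prompts_answered <- integer()
    return(out)
  }
  date <- local_date(r$timestamp, tz)
  rows <- lapply(split(seq_len(nrow(r)),
                       list(r$participant_id, as.character(date)), drop = TRUE),
                 function(i) {
    x <- r[i, ]
    out <- data.frame(participant_id = x$participant_id[1], date = date[i[1]],
                      stringsAsFactors = FALSE)
    for (it in affect_items) {
      v <- x$response[x$item == it]
      out[[paste0("mean_", it)]] <- if (length(v)) mean(v) else NA_real_
    }
    out$n_prompts_answered <- length(unique(x$timestamp))
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Two-stage group summaries
#'
#' Summarizes daily variables the way group-comparison tables are built from
#' repeated measures: first a mean per participant across their days, then
#' the group mean and SD of those participant means.
#'
#' @param daily data.frame with `participant_id` and numeric daily columns.
#' @param groups data.frame `participant_id`, `group` covering every
#'   participant in `daily`.
#' @param variables columns to summarize; default all numeric columns.
#' @return data.frame `variable`, `group`, `mean`, `sd`, `n` (participants).
#' @export
group_summaries <- function(daily, groups, variables = NULL) {
  if (any(!daily$participant_id %in% groups$participant_id))
    stop("unlabeled participant(s) in `daily`")
  if (is.null(variables)) {
    variables <- names(daily)[vapply(daily, is.numeric, logical(1))]
    variables <- setdiff(variables, c("n_prompts_answered", "n_points"))
  }
  rows <- list()
  for (v in variables) {
    pmeans <- tapply(daily[[v]], daily$participant_id,
                     function(x) mean(x, na.rm = TRUE))
    pg <- groups$group[match(names(pmeans), groups$participant_id)]
    for (g in sort(unique(pg))) {
      x <- pmeans[pg == g & !is.na(pmeans)]
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, group = g, mean = mean(x),
                   sd = stats::sd(x), n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
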