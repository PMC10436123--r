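#' Affect lexicon
#'
#' A dictionary-based scorer in the LIWC mold needs, per category, a list of
#' lowercase patterns: literal words matched by equality and stems written
#' with a trailing `*` matched by prefix (`worr*` matches `worried` and
#' `worrying`). The hierarchy is fixed: `anxiety`, `anger` and `sadness` are
#' subcategories of negative affect; `negative_other` holds general negative
#' words outside the three subcategories (e.g. "hurt", "ugly"), which the
#' default negative-affect metric excludes.
#'
#' The proprietary LIWC dictionary is not redistributable; the package ships
#' a small open lexicon in the same format (JSON, `{"category": [patterns]}`)
#' with the scoring algebra the analysis actually needs.
#'
#' @param path JSON lexicon file.
#' @return object of class `affect_lexicon`: named list of pattern vectors
#'   with categories `positive`, `anxiety`, `anger`, `sadness`,
#'   `negative_other`.
#' @export
read_affect_lexicon <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("positive", "anxiety", "anger", "sadness")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("lexicon error: missing categories: ", paste(miss, collapse = ", "))
  if (is.null(raw$negative_other)) raw$negative_other <- character()
  lex <- lapply(raw[c(need, "negative_other")],
                function(p) tolower(as.character(p)))
  for (cat in names(lex)) {
    p <- lex[[cat]]
    if (!length(p) && cat %in% need)
      stop("lexicon error: empty pattern set for ", cat)
    star <- gregexpr("*", p, fixed = TRUE)
    bad <- vapply(seq_along(p), function(i) {
      pos <- star[[i]]
      any(pos > 0 & pos < nchar(p[i]))
    }, logical(1))
    if (any(bad))
      stop("lexicon error: internal '*' in pattern(s): ",
           paste(p[bad], collapse = ", "))
  }
  structure(lex, class = "affect_lexicon")
}

#' @rdname read_affect_lexicon
#' @export
default_affect_lexicon <- function() {
  read_affect_lexicon(system.file("extdata", "affect_lexicon.json",
                                  package = "greenspaceEMA", mustWork = TRUE))
}

#' Tokenize transcript text
#'
#' Lowercases, splits on whitespace, strips leading and trailing punctuation,
#' keeps internal apostrophes ("don't" is one token), drops empty tokens.
#'
#' @param text character vector; elements are concatenated in order.
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")), "\\s+"))
  toks <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", toks)
  toks <- gsub("^'+|'+$", "", toks)
  toks[nzchar(toks)]
}

match_category <- function(tokens, patterns) {
  if (!length(tokens)) return(logical(0))
  stems <- sub("\\*$", "", patterns[endsWith(patterns, "*")])
  literals <- patterns[!endsWith(patterns, "*")]
  hit <- tokens %in% literals
  for (s in stems) hit <- hit | startsWith(tokens, s)
  hit
}

#' Score tokens against the lexicon
#'
#' LIWC-style category percentages: a token matches a category if it equals a
#' literal pattern or begins with a stem pattern; each token counts at most
#' once per category but may hit several categories. The category score is
#' `100 * matches / word_count`, which normalizes for how much was spoken; an
#' empty token list scores 0 everywhere. The `negative` score counts tokens
#' matching the anxiety/anger/sadness subcategories; with
#' `inclusive_negative = TRUE` it also counts `negative_other` words.
#'
#' @param tokens character vector from [tokenize()].
#' @param lexicon an `affect_lexicon`.
#' @param inclusive_negative include general negative words in the
#'   negative-affect total.
#' @return data.frame (one row) with `word_count`, per-category match counts
#'   `n_*`, and percentages `pct_*` for positive, negative, anxiety, anger,
#'   sadness.
#' @export
score_tokens <- function(tokens, lexicon, inclusive_negative = FALSE) {
  stopifnot(inherits(lexicon, "affect_lexicon"))
  wc <- length(tokens)
  cats <- c("positive", "anxiety", "anger", "sadness")
  hits <- lapply(lexicon[cats], function(p) match_category(tokens, p))
  neg <- hits$anxiety | hits$anger | hits$sadness
  if (inclusive_negative)
    neg <- neg | match_category(tokens, lexicon$negative_other)
  n <- c(vapply(hits, sum, numeric(1)), negative = sum(neg))
  pct <- if (wc > 0) 100 * n / wc else n * 0
  out <- data.frame(word_count = wc)
  for (k in c("positive", "negative", "anxiety", "anger", "sadness")) {
    out[[paste0("n_", k)]] <- as.integer(n[[k]])
    out[[paste0("pct_", k)]] <- pct[[k]]
  }
  out
}

#' Segment utterances into social interactions
#'
#' A new interaction starts after a lapse in speech of `gap_s` seconds or
#' longer (gap = next start minus previous end; the boundary case splits), or
#' when an `interlocutor_id` column is present and changes. Utterances flagged
#' in a logical `exclude` column (pet-/infant-directed speech, singing,
#' self-talk annotations) are dropped first, and segments containing no
#' participant utterance are discarded, mirroring the rule that speech not
#' involving the participant is not an interaction.
#'
#' @param utterances data.frame `participant_id`, `speaker`
#'   (`participant`/`other`), `start`, `end` (POSIXct), `text`; optional
#'   `interlocutor_id`, `exclude`. Must be sorted by `start` within
#'   participant.
#' @param gap_s lapse threshold in seconds.
#' @return the utterances of retained segments with a `segment` id column
#'   (`<participant>#<k>`), ordered by participant and start time.
#' @export
segment_interactions <- function(utterances, gap_s = 20) {
  u <- utterances
  if (!is.null(u$exclude)) u <- u[!u$exclude, , drop = FALSE]
  out <- lapply(split(u, u$participant_id), function(x) {
    if (is.unsorted(x$start)) stop("utterances must be sorted by start time")
    n <- nrow(x)
    if (!n) return(NULL)
    gap <- as.numeric(difftime(x$start[-1], x$end[-n], units = "secs"))
    new_seg <- gap >= gap_s
    if (!is.null(x$interlocutor_id)) {
      chg <- x$interlocutor_id[-1] != x$interlocutor_id[-n]
      chg[is.na(chg)] <- FALSE
      new_seg <- new_seg | chg
    }
    seg <- cumsum(c(1L, as.integer(new_seg)))
    keep_seg <- unique(seg[x$speaker == "participant"])
    x <- x[seg %in% keep_seg, , drop = FALSE]
    seg <- seg[seg %in% keep_seg]
    if (!nrow(x)) return(NULL)
    x$segment <- paste0(x$participant_id, "#", match(seg, unique(seg)))
    x
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- utterances[0, , drop = FALSE]
    res$segment <- character(0)
  }
  rownames(res) <- NULL
  res
}

#' Score each interaction segment
#'
#' Tokenizes and scores the concatenated text of every segment; the segment's
#' date is the local calendar day of its first utterance.
#'
#' @param segmented output of [segment_interactions()].
#' @inheritParams score_tokens
#' @param tz study time zone.
#' @return data.frame with `participant_id`, `segment`, `date` and the
#'   [score_tokens()] columns, one row per segment.
#' @export
score_segments <- function(segmented, lexicon, inclusive_negative = FALSE,
                           tz = "America/Los_Angeles") {
  rows <- lapply(split(segmented, segmented$segment), function(x) {
    sc <- score_tokens(tokenize(x$text), lexicon, inclusive_negative)
    cbind(data.frame(participant_id = x$participant_id[1],
                     segment = x$segment[1],
                     date = local_date(x$start[1], tz),
                     stringsAsFactors = FALSE), sc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date, out$segment), ]
  rownames(out) <- NULL
  out
}

#' Aggregate segment scores to participant-days
#'
#' Token-weighted daily percentages: `100 * sum(matches) / sum(word_count)`
#' over the day's segments — exactly what rescoring the concatenation of the
#' day's tokens would give — never a mean of per-segment percentages, which
#' would overweight short segments.
#'
#' @param segment_scores output of [score_segments()].
#' @return data.frame per participant-day with total `word_count`, summed
#'   match counts and token-weighted `pct_*` columns.
#' @export
aggregate_daily_scores <- function(segment_scores) {
  cats <- c("positive", "negative", "anxiety", "anger", "sadness")
  rows <- lapply(split(segment_scores,
                       list(segment_scores$participant_id,
                            as.character(segment_scores$date)), drop = TRUE),
                 function(x) {
    wc <- sum(x$word_count)
    out <- data.frame(participant_id = x$participant_id[1], date = x$date[1],
                      word_count = wc, stringsAsFactors = FALSE)
    for (k in cats) {
      nk <- sum(x[[paste0("n_", k)]])
      out[[paste0("n_", k)]] <- nk
      out[[paste0("pct_", k)]] <- if (wc > 0) 100 * nk / wc else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$date), ]
  rownames(out) <- NULL
  out
}
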