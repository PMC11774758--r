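#' Parse a browsing-history table into visit records
#'
#' Reads a tabular browsing history (one row per webpage visit) and returns a
#' validated, ordered visit table. Visits are grouped by participant and day
#' and ordered within each day by the \code{order} column (or by
#' \code{timestamp} when no explicit order is supplied). Malformed rows (empty
#' URL, missing fields) are reported in the \code{errors} attribute rather
#' than silently dropped.
#'
#' @param history A data frame (or path to a CSV file) with columns
#'   \code{participant}, \code{day}, and \code{url}, plus either \code{order}
#'   or \code{timestamp}.
#' @return A data frame of visits with columns \code{participant}, \code{day},
#'   \code{order}, \code{url}, sorted by participant, day, order, carrying an
#'   \code{errors} attribute (data frame of rejected rows with a reason).
#' @export
parse_history <- function(history) {
  if (is.character(history) && length(history) == 1L) {
    history <- utils::read.csv(history, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(history))
  required <- c("participant", "day", "url")
  missing_cols <- setdiff(required, names(history))
  if (length(missing_cols) > 0) {
    stop("history is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  has_order <- "order" %in% names(history)
  has_ts <- "timestamp" %in% names(history)
  if (!has_order && !has_ts) {
    stop("history must have an 'order' or 'timestamp' column")
  }

  df <- data.frame(
    participant = as.character(history$participant),
    day = suppressWarnings(as.integer(history$day)),
    url = as.character(history$url),
    stringsAsFactors = FALSE
  )
  if (has_order) {
    df$order <- suppressWarnings(as.integer(history$order))
  } else {
    # derive within-day visit order from the timestamp rank
    ts <- history$timestamp
    df$order <- NA_integer_
    key <- paste(df$participant, df$day, sep = "\r")
    for (k in unique(key)) {
      idx <- which(key == k)
      df$order[idx] <- rank(ts[idx], ties.method = "first") - 1L
    }
  }

  bad <- rep(NA_character_, nrow(df))
  bad[is.na(df$day) | df$day < 1] <- "bad_day"
  bad[is.na(df$order)] <- "bad_order"
  bad[is.na(df$url) | !nzchar(trimws(df$url))] <- "empty_url"
  bad[is.na(df$participant) | !nzchar(df$participant)] <- "empty_participant"

  errors <- cbind(row = which(!is.na(bad)),
                  history[!is.na(bad), , drop = FALSE])
  if (nrow(errors) > 0) errors$reason <- bad[!is.na(bad)]
  ok <- df[is.na(bad), , drop = FALSE]

  dup <- duplicated(ok[, c("participant", "day", "order")])
  if (any(dup)) {
    stop("duplicate (participant, day, order) in history: e.g. ",
         paste(ok$participant[dup][1], ok$day[dup][1], ok$order[dup][1]))
  }
  ok <- ok[order(ok$participant, ok$day, ok$order), , drop = FALSE]
  rownames(ok) <- NULL
  attr(ok, "errors") <- errors
  ok
}

#' Extract paragraph text from an HTML document
#'
#' Returns the text content of all \code{<p>} elements in document order,
#' joined with single spaces. Non-paragraph text (headings, navigation,
#' scripts, \code{<div>} content outside paragraphs) is excluded. Parsing is
#' tolerant of malformed markup; an unparseable document yields an empty
#' string with a warning.
#'
#' @param html A length-1 character vector holding an HTML document.
#' @return A single string: the whitespace-joined paragraph text (possibly "").
#' @export
extract_paragraphs <- function(html) {
  stopifnot(is.character(html), length(html) == 1L)
  if (!nzchar(html)) return("")
  doc <- tryCatch(xml2::read_html(html),
                  error = function(e) NULL)
  if (is.null(doc)) {
    warning("unparseable HTML document; returning empty text")
    return("")
  }
  ps <- xml2::xml_find_all(doc, ".//p")
  if (length(ps) == 0) return("")
  txt <- xml2::xml_text(ps)
  txt <- trimws(gsub("[[:space:]]+", " ", txt))
  paste(txt[nzchar(txt)], collapse = " ")
}

#' Clean raw webpage text into a token sequence
#'
#' Applies the cleaning rules used before lexicon scoring: URLs (scheme- or
#' \code{www.}-prefixed spans) are removed first, the remainder is lowercased,
#' and every run of non-alphanumeric characters (punctuation, symbols, emoji)
#' acts as a token separator. The result is a character vector of tokens
#' matching \code{[a-z0-9]+}. Digits are retained; they never match lexicon
#' entries and so only affect score denominators.
#'
#' @param raw_text A length-1 character string (may be "").
#' @return Character vector of tokens (possibly length 0).
#' @export
clean_text <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (is.na(raw_text) || !nzchar(raw_text)) return(character(0))
  x <- gsub("(?i)\\b(?:https?://|www\\.)\\S*", " ", raw_text, perl = TRUE)
  x <- tolower(x)
  tokens <- strsplit(x, "[^a-z0-9]+")[[1]]
  tokens[nzchar(tokens)]
}

# trailing-slash normalization for duplicate matching; fragments kept distinct
normalize_url <- function(url) sub("/$", "", url)

#' Remove consecutive duplicate visits
#'
#' Drops a visit when its URL (after trailing-slash normalization) equals the
#' URL of the immediately preceding retained visit within the same
#' participant-day. Non-adjacent repeats are retained.
#'
#' @param visits A visit data frame as returned by [parse_history()].
#' @return The visit data frame with consecutive duplicates removed.
#' @export
dedupe_consecutive <- function(visits) {
  stopifnot(is.data.frame(visits),
            all(c("participant", "day", "url") %in% names(visits)))
  if (nrow(visits) == 0) return(visits)
  u <- normalize_url(visits$url)
  key <- paste(visits$participant, visits$day, sep = "\r")
  same_group <- c(FALSE, key[-1] == key[-length(key)])
  dup <- c(FALSE, u[-1] == u[-length(u)]) & same_group
  out <- visits[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build page records from visits and an HTML corpus
#'
#' For each visit, looks up the visited URL in an HTML corpus, extracts and
#' cleans the paragraph text, and records the token sequence and its UTF-8
#' byte size. Visits whose HTML is missing or unparseable yield empty page
#' records (zero tokens, zero bytes); these count toward neither page counts
#' nor byte totals in the inclusion filter.
#'
#' @param visits A visit data frame (ideally after [dedupe_consecutive()]).
#' @param html_by_url Named character vector or list mapping URL to HTML
#'   document text.
#' @return A list of page records, each a list with fields \code{participant},
#'   \code{day}, \code{order}, \code{url}, \code{tokens}, \code{byte_size}.
#' @export
build_pages <- function(visits, html_by_url) {
  stopifnot(is.data.frame(visits))
  lapply(seq_len(nrow(visits)), function(i) {
    url <- visits$url[i]
    html <- if (!is.null(html_by_url[[url]])) html_by_url[[url]] else ""
    tokens <- clean_text(extract_paragraphs(html))
    list(
      participant = visits$participant[i],
      day = visits$day[i],
      order = visits$order[i],
      url = url,
      tokens = tokens,
      byte_size = if (length(tokens)) {
        sum(nchar(tokens, type = "bytes")) + length(tokens) - 1L
      } else 0L
    )
  })
}

#' Apply the per-day inclusion filter
#'
#' A participant is included when, on every required day, they contributed at
#' least \code{min_pages} non-empty pages and at least \code{min_total_bytes}
#' bytes of cleaned text in total. Single-day studies pass a single required
#' day. Empty pages (no extractable text) count toward neither threshold.
#'
#' @param pages A list of page records (see [build_pages()]).
#' @param min_pages Minimum number of non-empty pages per required day.
#' @param min_total_bytes Minimum total cleaned-text bytes per required day
#'   (default 1024, i.e. 1 KB).
#' @param required_days Integer vector of days each participant must satisfy.
#' @param participants Optional character vector of participant ids to report
#'   on; defaults to the participants present in \code{pages}. Participants
#'   listed here but absent from \code{pages} are excluded
#'   (\code{too_few_pages}).
#' @return A data frame with one row per participant: \code{participant},
#'   \code{included}, \code{reason} (one of \code{ok}, \code{too_few_pages},
#'   \code{too_little_text}), plus a \code{per_day} attribute with the per-day
#'   page counts and byte totals.
#' @export
apply_inclusion_filter <- function(pages, min_pages = 3,
                                   min_total_bytes = 1024,
                                   required_days = 1:5,
                                   participants = NULL) {
  stopifnot(length(required_days) >= 1, all(required_days >= 1))
  if (is.null(participants)) {
    participants <- unique(vapply(pages, `[[`, character(1), "participant"))
  }
  per_day_rows <- list()
  res <- lapply(participants, function(p) {
    pp <- Filter(function(pg) pg$participant == p && pg$byte_size > 0, pages)
    days <- vapply(pp, function(pg) as.numeric(pg$day), numeric(1))
    counts <- vapply(required_days, function(d) sum(days == d), integer(1))
    bytes <- vapply(required_days, function(d) {
      sum(vapply(pp[days == d], function(pg) as.numeric(pg$byte_size),
                 numeric(1)))
    }, numeric(1))
    per_day_rows[[p]] <<- data.frame(participant = p, day = required_days,
                                     n_pages = counts, bytes = bytes)
    if (any(counts < min_pages)) {
      reason <- "too_few_pages"
    } else if (any(bytes < min_total_bytes)) {
      reason <- "too_little_text"
    } else {
      reason <- "ok"
    }
    data.frame(participant = p, included = reason == "ok", reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(participant = character(0), included = logical(0),
                      reason = character(0))
  }
  rownames(out) <- NULL
  attr(out, "per_day") <- do.call(rbind, unname(per_day_rows))
  out
}
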