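#' Z-score questionnaire items across participants
#'
#' Standardizes each item column to mean 0 and sample s.d. 1 (n - 1
#' denominator) across participants. Zero-variance columns become all zeros
#' with a warning; all-missing columns are an error.
#'
#' @param items A numeric matrix or data frame, participants x items, with
#'   participant ids as row names (optional).
#' @return A numeric matrix of the same shape, standardized by column.
#' @export
zscore_items <- function(items) {
  x <- as.matrix(items)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 participants to Z-score items")
  if (any(colSums(!is.na(x)) == 0)) stop("item column(s) entirely missing")
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  zero <- sdv == 0 | is.na(sdv)
  if (any(zero)) {
    warning("zero-variance item(s) set to 0: ",
            paste(colnames(x)[zero], collapse = ", "))
    sdv[zero] <- 1
    mu[zero] <- x[1, zero]
  }
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Compute factor-weighted psychopathology dimension scores
#'
#' Multiplies each Z-scored item by its published factor weight and sums the
#' weighted items assigned to each of the three transdiagnostic dimensions:
#' anxious-depression (AD), social-withdrawal (SW), and compulsive-behaviour
#' and intrusive thought (CIT). The composite is the unweighted mean of the
#' three dimension scores.
#'
#' @param z_items Standardized item matrix from [zscore_items()] (participants
#'   x items, with item names as column names).
#' @param weights Data frame with columns \code{item}, \code{dimension}
#'   (one of \code{"AD"}, \code{"SW"}, \code{"CIT"}), \code{weight}.
#' @param on_missing_item What to do when a weighted item is absent from the
#'   data: \code{"error"} (default) or \code{"skip"} (drop the item from the
#'   summation with a warning).
#' @return A data frame: \code{participant}, \code{AD}, \code{SW}, \code{CIT},
#'   \code{mean_psych}.
#' @export
score_dimensions <- function(z_items, weights, on_missing_item = c("error", "skip")) {
  on_missing_item <- match.arg(on_missing_item)
  z <- as.matrix(z_items)
  stopifnot(is.data.frame(weights),
            all(c("item", "dimension", "weight") %in% names(weights)))
  dims <- c("AD", "SW", "CIT")
  if (!all(weights$dimension %in% dims)) {
    stop("weights$dimension must be one of: ", paste(dims, collapse = ", "))
  }
  if (anyDuplicated(weights$item)) {
    stop("each item may be assigned to at most one dimension")
  }
  missing_items <- setdiff(weights$item, colnames(z))
  if (length(missing_items) > 0) {
    msg <- paste("weighted item(s) absent from data:",
                 paste(missing_items, collapse = ", "))
    if (on_missing_item == "error") stop(msg)
    warning(msg, "; skipped")
    weights <- weights[!weights$item %in% missing_items, , drop = FALSE]
  }
  scores <- sapply(dims, function(d) {
    wd <- weights[weights$dimension == d, , drop = FALSE]
    if (nrow(wd) == 0) return(rep(0, nrow(z)))
    as.numeric(z[, wd$item, drop = FALSE] %*% wd$weight)
  })
  out <- data.frame(
    participant = if (!is.null(rownames(z))) rownames(z) else
      as.character(seq_len(nrow(z))),
    scores,
    stringsAsFactors = FALSE
  )
  out$mean_psych <- mean_psychopathology(out[, dims])
  rownames(out) <- NULL
  out
}

#' Composite psychopathology score
#'
#' The unweighted mean of the three dimension scores per participant.
#'
#' @param dims A data frame or matrix with columns \code{AD}, \code{SW},
#'   \code{CIT} (or any three numeric columns).
#' @return Numeric vector, one value per participant.
#' @export
mean_psychopathology <- function(dims) {
  rowMeans(as.matrix(dims))
}
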