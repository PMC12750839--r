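# EPOCH wellbeing questionnaire: validation and domain scoring.

#' EPOCH wellbeing domains
#' @return Character vector of the five domains.
#' @export
epoch_domains <- function() {
  c("engagement", "perseverance", "optimism", "connectedness", "happiness")
}

#' Default item-to-domain mapping
#'
#' Assigns items 1-4 to engagement, 5-8 to perseverance, 9-12 to optimism,
#' 13-16 to connectedness and 17-20 to happiness.  This is a synthetic
#' placeholder layout — the published instrument interleaves its items — so
#' studies using real questionnaire exports should supply their own mapping
#' table with the same two-column shape.
#'
#' @return Data frame with columns `item` (`item_01`..`item_20`) and
#'   `domain`.
#' @export
default_epoch_mapping <- function() {
  data.frame(
    item = sprintf("item_%02d", 1:20),
    domain = rep(epoch_domains(), each = 4),
    stringsAsFactors = FALSE
  )
}

check_epoch_mapping <- function(mapping) {
  if (!all(c("item", "domain") %in% names(mapping))) {
    stop("mapping needs columns 'item' and 'domain'")
  }
  if (nrow(mapping) != 20 || anyDuplicated(mapping$item)) {
    stop("mapping must assign exactly 20 distinct items")
  }
  tab <- table(mapping$domain)
  if (!setequal(names(tab), epoch_domains()) || any(tab != 4)) {
    stop("mapping must give each of the 5 domains exactly 4 items")
  }
  invisible(mapping)
}

item_matrix <- function(responses, mapping) {
  miss <- setdiff(mapping$item, names(responses))
  if (length(miss)) {
    stop("responses are missing item column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(responses[, mapping$item, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Score EPOCH responses into domain means
#'
#' Each of the five wellbeing domains is the arithmetic mean of its four
#' items, coded 1 ("Almost never") to 5 ("Almost always").  The instrument
#' is positively worded, so no reverse-coding is applied.  Any missing or
#' out-of-range item is an error; use [validate_epoch()] first to drop and
#' count invalid responders.
#'
#' @param responses Data frame with one row per participant and columns
#'   `item_01`..`item_20` (plus any identifier columns, which are retained).
#' @param mapping Item-to-domain table ([default_epoch_mapping()]).
#' @return Data frame: retained identifier columns plus one column per
#'   domain, each in \[1, 5\].
#' @examples
#' r <- as.data.frame(as.list(stats::setNames(rep(4, 20),
#'                                            sprintf("item_%02d", 1:20))))
#' score_epoch(r)
#' @export
score_epoch <- function(responses, mapping = default_epoch_mapping()) {
  check_epoch_mapping(mapping)
  m <- item_matrix(responses, mapping)
  bad <- which(!(is.finite(m) & m >= 1 & m <= 5 & m == round(m)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid response in row ", bad[1, 1], ", ",
         mapping$item[bad[1, 2]],
         ": items must be integers in 1..5 (participant should be excluded)")
  }
  out <- responses[, setdiff(names(responses), mapping$item), drop = FALSE]
  for (d in epoch_domains()) {
    out[[d]] <- rowMeans(m[, mapping$item[mapping$domain == d], drop = FALSE])
  }
  out
}

#' Validate EPOCH responses
#'
#' Splits responses into scoreable and invalid sets: a response is invalid
#' if any of its 20 items is missing or outside the 1..5 coding.  No
#' partial-missingness imputation is attempted — any missing item excludes
#' the participant, matching the study's exclusion flow.
#'
#' @inheritParams score_epoch
#' @return List with `valid` (rows that score cleanly), `invalid` (the
#'   rest) and `n_excluded`.
#' @export
validate_epoch <- function(responses, mapping = default_epoch_mapping()) {
  check_epoch_mapping(mapping)
  m <- item_matrix(responses, mapping)
  ok <- apply(m, 1, function(r) all(is.finite(r) & r >= 1 & r <= 5 & r == round(r)))
  list(valid = responses[ok, , drop = FALSE],
       invalid = responses[!ok, , drop = FALSE],
       n_excluded = sum(!ok))
}
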