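#' Two-rater binary rating pair
#'
#' @param rater_a,rater_b equal-length binary vectors (0/1, yes/no or logical)
#' @param items optional item identifiers
#' @return object of class `rating_pair`
#' @export
rating_pair <- function(rater_a, rater_b, items = NULL) {
  a <- as_binary(rater_a, "rater_a")
  b <- as_binary(rater_b, "rater_b")
  if (length(a) != length(b) || length(a) < 1) {
    stop_ctx("raters must have equal length >= 1", class = "validation_error")
  }
  structure(list(rater_a = a, rater_b = b,
                 items = items %||% seq_along(a)),
            class = "rating_pair")
}

#' Percent agreement between two raters
#'
#' 100 x (number of items with identical codes) / N.
#'
#' @param r a [rating_pair()]
#' @return percentage in \[0, 100\]
#' @export
percent_agreement <- function(r) {
  stopifnot(inherits(r, "rating_pair"))
  100 * mean(r$rater_a == r$rater_b)
}

#' Holley--Guilford G index of inter-rater reliability
#'
#' G = (agreements - disagreements) / N, equivalently 2 p_agree - 1 for
#' binary codes. Unlike Cohen's kappa, G remains a meaningful
#' chance-symmetric reliability measure when the rating margins are heavily
#' skewed (e.g. when most items are coded "no").
#'
#' @param r a [rating_pair()]
#' @return G in \[-1, 1\]
#' @export
g_index <- function(r) {
  stopifnot(inherits(r, "rating_pair"))
  n <- length(r$rater_a)
  agree <- sum(r$rater_a == r$rater_b)
  (agree - (n - agree)) / n
}

#' G index from a percent agreement
#'
#' For binary codes G depends on the data only through the agreement rate:
#' G = 2 (pct/100) - 1.
#'
#' @param pct percent agreement in \[0, 100\]
#' @return G in \[-1, 1\]
#' @export
g_from_agreement <- function(pct) {
  stopifnot(all(pct >= 0 & pct <= 100))
  2 * pct / 100 - 1
}

#' Inter-rater reliability report for binary coding schemes
#'
#' Computes percent agreement and the Holley--Guilford G index per coded
#' parameter, rounded half-up to 2 d.p. for reporting.
#'
#' @param pairs named list of [rating_pair()] objects (names = parameters), or
#'   a single `rating_pair`
#' @return data frame with columns `parameter`, `agreement_pct`, `G`
#' @export
reliability_report <- function(pairs) {
  if (inherits(pairs, "rating_pair")) pairs <- list(coding = pairs)
  data.frame(
    parameter = names(pairs),
    agreement_pct = round_half_up(
      vapply(pairs, percent_agreement, numeric(1)), 2),
    G = round_half_up(vapply(pairs, g_index, numeric(1)), 2),
    row.names = NULL)
}

#' Read a two-column rating CSV into a rating pair
#'
#' @param path CSV with columns `rater_a` and `rater_b` (yes/no or 0/1)
#' @return a [rating_pair()]
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("rater_a", "rater_b"), basename(path))
  rating_pair(df$rater_a, df$rater_b)
}
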