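#' The three risk levels, lowest to highest
#' @export
risk_levels <- function() c("low", "medium", "high")

#' Map an Asthma Control Test score to a risk level
#'
#' The ACT total score runs from 5 (worst control) to 25 (complete
#' control). Scores of 20-25 map to low risk, 15-19 to medium risk and 14
#' or below to high risk. (The published bins list 19 in both the low and
#' medium ranges; 19 is resolved to medium, consistent with the instrument
#' guidance that control "may not be as well controlled" at 19 or less.
#' 15 is likewise resolved to medium per the explicit bin listing.)
#'
#' @param score Integer ACT score(s) in `[5, 25]`.
#' @return Factor with levels `low < medium < high` (vectorized).
#' @export
act_to_risk <- function(score) {
  if (any(is.na(score)) || any(score != round(score)) ||
      any(score < 5) || any(score > 25))
    stop("ACT scores must be integers in [5, 25]")
  lvl <- ifelse(score >= 20, "low", ifelse(score >= 15, "medium", "high"))
  factor(lvl, levels = risk_levels())
}

#' Read ACT observations from CSV
#'
#' @param path CSV with header `t,score`.
#' @return Data frame with numeric `t` and integer `score`, time-sorted.
#' @export
read_act <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "score") %in% names(df)))
    stop("ACT file needs columns t,score")
  df <- df[order(df$t), c("t", "score")]
  rownames(df) <- NULL
  df
}

#' Align ACT-derived risk labels to classification windows
#'
#' Each window is labeled by the ACT observation nearest to its end, as
#' long as that observation lies within the horizon (default 30 min, half
#' the hourly ACT cadence); equidistant observations break toward the
#' earlier one. Windows with no observation in range get `NA` and are
#' excluded from training (reported, not fatal).
#'
#' @param windows Data frame with `window_end` (and typically
#'   `window_start`), e.g. from [make_windows()].
#' @param acts Data frame with `t` and integer `score`, time-sorted.
#' @param horizon_s Maximum |window end - ACT time|, seconds (default 1800).
#' @return Factor of risk levels, `NA` where unlabeled.
#' @export
align_labels <- function(windows, acts, horizon_s = 1800) {
  if (nrow(acts) == 0L)
    return(factor(rep(NA_character_, nrow(windows)), levels = risk_levels()))
  if (is.unsorted(acts$t)) stop("ACT observations must be time-sorted")
  ends <- windows$window_end
  prev <- findInterval(ends, acts$t)          # last ACT at or before end
  nxt <- pmin(prev + 1L, nrow(acts))          # first ACT after end
  prev_ok <- prev >= 1L
  d_prev <- ifelse(prev_ok, ends - acts$t[pmax(prev, 1L)], Inf)
  d_next <- ifelse(prev < nrow(acts), acts$t[nxt] - ends, Inf)
  pick <- ifelse(d_prev <= d_next, pmax(prev, 1L), nxt)  # tie -> earlier
  dist <- pmin(d_prev, d_next)
  score <- acts$score[pick]
  lab <- act_to_risk(score)
  lab[dist > horizon_s] <- NA
  lab
}
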