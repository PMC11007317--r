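#' Public goods game configuration
#'
#' Defaults mirror a standard three-player one-shot public goods game: each
#' player is endowed with 20 points (1 point = CHF 0.50), contributions are
#' doubled and split equally among the three group members. The constraint
#' `1 < multiplier < group_size` keeps the game a social dilemma: full
#' contribution maximizes the group payoff while free-riding maximizes the
#' individual payoff.
#'
#' @param endowment points per player (> 0).
#' @param multiplier factor applied to the public pot (> 1, < `group_size`).
#' @param group_size number of players (>= 2).
#' @param point_value monetary value of one point (CHF).
#' @return a `pgg_config` list.
#' @export
pgg_config <- function(endowment = 20, multiplier = 2, group_size = 3,
                       point_value = 0.5) {
  assert_scalar_number(endowment, "endowment")
  assert_scalar_number(multiplier, "multiplier")
  assert_scalar_number(group_size, "group_size", lower = 2)
  if (endowment <= 0) {
    stop_swatopo("endowment must be positive.", "swatopo_parameter_error")
  }
  if (multiplier <= 1 || multiplier >= group_size) {
    stop_swatopo("need 1 < multiplier < group_size (social dilemma).",
                 "swatopo_parameter_error")
  }
  structure(
    list(endowment = endowment, multiplier = multiplier,
         group_size = group_size, point_value = point_value),
    class = "pgg_config"
  )
}

#' Public goods game payoffs
#'
#' `payoff_i = endowment - c_i + multiplier * sum(c) / group_size`: each
#' player keeps what they did not contribute plus an equal share of the
#' multiplied pot.
#'
#' @param contributions integer contributions, one per player, each in
#'   `[0, endowment]`; length must equal `group_size`.
#' @param cfg a [pgg_config()].
#' @return tibble with columns `player`, `contribution`, `payoff` (points).
#' @export
pgg_payoffs <- function(contributions, cfg = pgg_config()) {
  if (length(contributions) != cfg$group_size) {
    stop_swatopo("one contribution per group member is required.",
                 "swatopo_parameter_error")
  }
  if (any(contributions != round(contributions)) ||
      any(contributions < 0 | contributions > cfg$endowment)) {
    stop_swatopo(
      sprintf("contributions must be integers in [0, %g].", cfg$endowment),
      "swatopo_validation_error"
    )
  }
  pot <- cfg$multiplier * sum(contributions)
  tibble(
    player = seq_along(contributions),
    contribution = contributions,
    payoff = cfg$endowment - contributions + pot / cfg$group_size
  )
}

#' Contribution-minus-belief prosociality score
#'
#' A player's own contribution minus their stated belief about the average
#' contribution of the other group members; positive values mean the player
#' contributed more than they expected from others.
#'
#' @param contribution,belief integers in `[0, 20]` (points).
#' @return `contribution - belief`, in `[-20, 20]`.
#' @export
prosocial_score <- function(contribution, belief) {
  if (any(contribution < 0 | contribution > 20 | belief < 0 | belief > 20,
          na.rm = FALSE) ||
      anyNA(contribution) || anyNA(belief)) {
    stop_swatopo("contribution and belief must lie in [0, 20].",
                 "swatopo_validation_error")
  }
  contribution - belief
}

#' Read / write a behavioral table
#'
#' Tab-separated file with header columns `subject_id`, `contribution`,
#' `belief` and optional covariate columns (e.g. `age`, `gender`,
#' `total_sleep_time`). The prosociality `score` is always recomputed as
#' `contribution - belief` on read.
#'
#' @param path file path.
#' @return `read_behavior()` a tibble with `subject_id`, `contribution`,
#'   `belief`, `score` and any covariates; `write_behavior()` the path,
#'   invisibly.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) {
    stop_swatopo(sprintf("behavior file not found: %s", path),
                 "swatopo_io_error")
  }
  df <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "contribution", "belief")
  if (!all(need %in% names(df))) {
    stop_swatopo("behavior table needs subject_id, contribution, belief.",
                 "swatopo_format_error")
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) {
    stop_swatopo("duplicated subject_id in behavior table.",
                 "swatopo_validation_error")
  }
  df$score <- prosocial_score(df$contribution, df$belief)
  relocate(df, "subject_id", "contribution", "belief", "score")
}

#' @rdname read_behavior
#' @param df behavioral tibble as returned by [read_behavior()] or
#'   [generate_behavior()].
#' @export
write_behavior <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], fmt17)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Descriptive summary of prosociality scores
#'
#' @param records behavioral tibble with a `score` column (>= 2 rows).
#' @return list with `mean`, `sd` (n-1 denominator), `min`, `max` and a
#'   `histogram` tibble of counts at unit bins.
#' @export
summarize_scores <- function(records) {
  s <- records$score
  if (length(s) < 2) {
    stop_swatopo("need at least two records.", "swatopo_validation_error")
  }
  bins <- seq(min(s), max(s))
  list(
    mean = mean(s),
    sd = sd(s),
    min = min(s),
    max = max(s),
    histogram = tibble(score = bins,
                       count = vapply(bins, function(b) sum(s == b), 0L))
  )
}
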