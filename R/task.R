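#' The six trial types and their target actions
#'
#' Each trial presents one of six binary cue patterns over
#' (danger, food, alcohol, risk).  The two rule sets agree on every pattern
#' except alcohol+risk, where aversion-resistant organisms drink and
#' aversion-sensitive organisms wait:
#'
#' | type | cues           | AR target | AS target |
#' |------|----------------|-----------|-----------|
#' | 1    | danger         | escape    | escape    |
#' | 2    | food           | eat       | eat       |
#' | 3    | alcohol        | drink     | drink     |
#' | 4    | food + risk    | wait      | wait      |
#' | 5    | alcohol + risk | drink     | wait      |
#' | 6    | none           | wait      | wait      |
#'
#' Type 6 (all cues off, target wait) is the neutral no-stimulus trial.
#'
#' @return A data frame with columns `type`, `danger`, `food`, `alcohol`,
#'   `risk`, `target_ar`, `target_as` (targets as integer action codes).
#' @export
trial_types <- function() {
  data.frame(
    type    = 1:6,
    danger  = c(1, 0, 0, 0, 0, 0),
    food    = c(0, 1, 0, 1, 0, 0),
    alcohol = c(0, 0, 1, 0, 1, 0),
    risk    = c(0, 0, 0, 1, 1, 0),
    target_ar = c(1L, 2L, 3L, 4L, 3L, 4L),
    target_as = c(1L, 2L, 3L, 4L, 4L, 4L)
  )
}

# The alcohol+risk trial type: the one the rule sets disagree on.
AR_TRIAL_TYPE <- 5L

#' Generate a batch of noisy task trials
#'
#' Trial types are drawn independently and uniformly over the six types;
#' i.i.d. Gaussian noise (sd `noise_sd`) is added to each binary cue channel.
#' Noisy inputs are not clipped.  Targets are taken from the requested rule
#' set.
#'
#' @param n number of trials (>= 1).
#' @param rule `"aversion_resistant"` or `"aversion_sensitive"` (rule set
#'   used for the `targets` column).
#' @param seed integer seed; batches are reproducible given the seed.
#' @param noise_sd standard deviation of the additive input noise
#'   (default 0.2).
#' @return An object of class `trial_batch`: list with `n`, `cue_matrix`
#'   (binary n x 4), `noisy_inputs` (n x 4), `trial_type` (integer n),
#'   `targets` (integer action codes), `rule`, `seed`, `noise_sd`.
#' @export
generate_trials <- function(n, rule = c("aversion_sensitive",
                                        "aversion_resistant"),
                            seed = 1L, noise_sd = 0.2) {
  rule <- match.arg(rule)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  tt <- trial_types()
  cue_cols <- c("danger", "food", "alcohol", "risk")
  draw <- withr::with_seed(seed, {
    type <- sample.int(6L, n, replace = TRUE)
    noise <- matrix(rnorm(n * 4L, sd = noise_sd), n, 4L)
    list(type = type, noise = noise)
  })
  cues <- as.matrix(tt[draw$type, cue_cols])
  dimnames(cues) <- list(NULL, cue_cols)
  targets <- if (rule == "aversion_resistant") tt$target_ar else tt$target_as
  structure(list(n = n, cue_matrix = cues,
                 noisy_inputs = cues + draw$noise,
                 trial_type = draw$type,
                 targets = targets[draw$type],
                 rule = rule, seed = as.integer(seed), noise_sd = noise_sd),
            class = "trial_batch")
}

#' @export
print.trial_batch <- function(x, ...) {
  cat("<trial_batch> ", x$n, " trials, rule = ", x$rule,
      ", noise sd = ", x$noise_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Retarget a batch under the other rule set
#'
#' Returns the same trials (identical cues and noise) with `targets`
#' recomputed under `rule`; only alcohol+risk trials can change.
#'
#' @param batch a `trial_batch`.
#' @param rule rule set for the new targets.
#' @return A `trial_batch`.
#' @export
retarget_batch <- function(batch, rule = c("aversion_sensitive",
                                           "aversion_resistant")) {
  rule <- match.arg(rule)
  tt <- trial_types()
  targets <- if (rule == "aversion_resistant") tt$target_ar else tt$target_as
  batch$targets <- targets[batch$trial_type]
  batch$rule <- rule
  batch
}

#' Export a trial batch as CSV
#'
#' Columns: `trial_id`, the four binary cues, `in1`..`in4` (noisy inputs),
#' `trial_type`, `target`.
#'
#' @param batch a `trial_batch`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(batch, path) {
  noisy <- batch$noisy_inputs
  colnames(noisy) <- paste0("in", 1:4)
  df <- data.frame(trial_id = seq_len(batch$n), batch$cue_matrix, noisy,
                   trial_type = batch$trial_type, target = batch$targets)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Behavioral metrics from a vector of selected actions against a batch.
metrics_from_actions <- function(actions, batch,
                                 side_effects = c("per_category",
                                                  "all_trials")) {
  side_effects <- match.arg(side_effects)
  is_ar <- batch$trial_type == AR_TRIAL_TYPE
  n_ar <- sum(is_ar)
  ar_drink_rate <- if (n_ar == 0L) NA_real_ else mean(actions[is_ar] == 3L)
  wrong <- actions != batch$targets
  side_effect_rate <- if (side_effects == "per_category") {
    if (n_ar == batch$n) NA_real_ else mean(wrong[!is_ar])
  } else {
    mean(wrong)
  }
  per_scenario <- vapply(1:6, function(k) {
    idx <- batch$trial_type == k
    if (!any(idx)) NA_real_ else mean(actions[idx] == batch$targets[idx])
  }, numeric(1))
  names(per_scenario) <- paste0("type", 1:6)
  structure(list(ar_drink_rate = ar_drink_rate,
                 side_effect_rate = side_effect_rate,
                 total_error = ar_drink_rate + side_effect_rate,
                 per_scenario_correct = per_scenario,
                 error_rate = mean(wrong)),
            class = "behavior_metrics")
}

#' @export
print.behavior_metrics <- function(x, ...) {
  cat(sprintf(
    "<behavior_metrics> AR drinking %.3f | side effects %.3f | total %.3f\n",
    x$ar_drink_rate, x$side_effect_rate, x$total_error))
  invisible(x)
}

#' Evaluate a network on a trial batch
#'
#' Runs the forward pass on every trial and scores the selected actions
#' against the batch targets.  The aversion-resistant drinking rate is the
#' fraction of alcohol+risk trials on which the network drinks; the
#' side-effect rate is the error rate on the remaining trial types
#' (per-category denominators by default; set `side_effects = "all_trials"`
#' to divide by the full batch instead).  A trial type absent from the batch
#' yields `NA` for the metrics that need it, never a silent 0.
#'
#' @param params a `network_params`.
#' @param batch a `trial_batch`; targets are conventionally computed under
#'   the aversion-sensitive rule when measuring treatment outcomes.
#' @param silenced optional processing node (1..3) to silence.
#' @param side_effects denominator convention for the side-effect rate.
#' @return A `behavior_metrics` object: `ar_drink_rate`, `side_effect_rate`,
#'   `total_error` (their sum), `per_scenario_correct` (fraction correct per
#'   trial type), and `error_rate` (overall fraction incorrect).
#' @export
evaluate_network <- function(params, batch, silenced = NULL,
                             side_effects = c("per_category", "all_trials")) {
  stopifnot(inherits(params, "network_params"), inherits(batch, "trial_batch"))
  fb <- forward_batch(params, batch$noisy_inputs, silenced = silenced)
  metrics_from_actions(fb$actions, batch, side_effects = match.arg(side_effects))
}
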