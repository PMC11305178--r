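#' Read a trial table from CSV
#'
#' Expected columns: `participant_id`, `condition` (`"baseline"` or an SOA
#' in ms), `similarity` (`"similar"`, `"dissimilar"` or `NA`), `d1_ori`,
#' `target_ori`, `d2_ori`, `response_ori` (degrees in `[0, 360)`;
#' distractor/target orientations absent on baseline trials),
#' `saccade_excluded` and `no_response` (logical flags).
#'
#' @param path path to a CSV file.
#' @return a data frame of trials.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "condition", "d1_ori", "target_ori", "d2_ori",
              "response_ori", "saccade_excluded", "no_response")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$saccade_excluded <- as.logical(df$saccade_excluded)
  df$no_response <- as.logical(df$no_response)
  df
}

is_baseline <- function(condition) {
  tolower(as.character(condition)) == "baseline"
}

#' Compute signed error triples for each trial
#'
#' For each responded trial, the signed circular errors of the report
#' relative to the target (`theta`) and, on non-baseline trials, relative
#' to the first and second distractor (`theta1`, `theta2`). Baseline
#' (unmasked) trials have no distractors and yield `theta` only.
#'
#' @param trials data frame of trials (see [read_trials()]).
#' @return the input with columns `theta`, `theta1`, `theta2` appended
#'   (`theta1`/`theta2` are `NA` on baseline trials).
#' @export
compute_errors <- function(trials) {
  resp <- trials$response_ori
  if (any(is.na(resp) & !trials$no_response))
    stop("missing response on a trial not flagged no_response", call. = FALSE)
  base <- is_baseline(trials$condition)
  ok <- !is.na(resp)
  trials$theta <- trials$theta1 <- trials$theta2 <- NA_real_
  trials$theta[ok] <- circ_error(resp[ok], trials$target_ori[ok])
  mk <- ok & !base
  if (any(mk)) {
    trials$theta1[mk] <- circ_error(resp[mk], trials$d1_ori[mk])
    trials$theta2[mk] <- circ_error(resp[mk], trials$d2_ori[mk])
  }
  trials
}

#' Apply trial-level exclusion
#'
#' Drops trials on which a saccade larger than the allowed amplitude was
#' executed (pre-computed `saccade_excluded` flag) or on which the
#' participant terminated the trial without clicking (`no_response`).
#'
#' @param trials data frame of trials.
#' @return list with `kept`, `dropped` (data frames partitioning the
#'   input) and `fraction_dropped`.
#' @export
exclude_trials <- function(trials) {
  bad <- trials$saccade_excluded | trials$no_response
  list(kept = trials[!bad, , drop = FALSE],
       dropped = trials[bad, , drop = FALSE],
       fraction_dropped = mean(bad))
}

#' Overall-performance score
#'
#' `1 - mean(|theta|) / 180`, where `theta` is the signed error relative
#' to the target. A score near 0.5 indicates responding at random (the
#' mean absolute error of a uniform responder is 90 degrees); 1 means
#' every report was exact.
#'
#' @param theta numeric vector of signed target errors in degrees.
#' @return scalar score in `[0, 1]`.
#' @export
overall_performance <- function(theta) {
  theta <- theta[!is.na(theta)]
  if (!length(theta)) stop("no errors supplied", call. = FALSE)
  1 - mean(abs(theta)) / 180
}

#' Summarise and screen participants on overall performance
#'
#' Computes each participant's overall-performance score on analyzable
#' trials (after trial-level exclusion) and flags those scoring below the
#' threshold for exclusion. "Below" is strict: a score equal to the
#' threshold is kept.
#'
#' @param trials data frame of trials with error columns
#'   (see [compute_errors()]).
#' @param threshold exclusion cut-off in `(0, 1)` (default 0.55).
#' @return data frame with one row per participant: `participant_id`,
#'   `overall_performance`, `excluded_trial_fraction`, `included`.
#' @export
participant_summary <- function(trials, threshold = 0.55) {
  stopifnot(threshold > 0, threshold < 1)
  out <- do.call(rbind, lapply(split(trials, trials$participant_id), function(d) {
    ex <- exclude_trials(d)
    kept <- compute_errors(ex$kept)
    data.frame(participant_id = d$participant_id[1],
               overall_performance = overall_performance(kept$theta),
               excluded_trial_fraction = ex$fraction_dropped)
  }))
  out$included <- out$overall_performance >= threshold
  rownames(out) <- NULL
  out
}

#' Filter participants below the overall-performance threshold
#'
#' @param summaries data frame from [participant_summary()].
#' @param threshold exclusion cut-off (default 0.55); participants with
#'   `overall_performance < threshold` are removed.
#' @return character/whatever vector of included participant ids.
#' @export
exclude_participants <- function(summaries, threshold = 0.55) {
  stopifnot(threshold > 0, threshold < 1)
  summaries$participant_id[summaries$overall_performance >= threshold]
}
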