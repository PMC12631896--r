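#' Motor-imagery paradigm description
#'
#' Describes the timing and trial layout of a cued motor-imagery (MI) session:
#' a visual cue, a sustained imagery period, and a rest interval, repeated for
#' each hand over one or more sessions. The default values reproduce a typical
#' clinical hybrid-recording paradigm: 2 s cue, 10 s MI task, 15 s rest,
#' 15 trials per hand per session over two sessions (60 trials total).
#'
#' @param cue_duration_s Cue (instruction arrow) duration in seconds.
#' @param task_duration_s Motor-imagery task duration in seconds.
#' @param rest_duration_s Rest duration in seconds (scalar, or length-2 range
#'   for jittered rest).
#' @param trials_per_class_per_session Trials per class per session.
#' @param n_sessions Number of sessions.
#' @param classes Ordered character vector of exactly two class labels. The
#'   order is fixed throughout the package (class 1 is the positive class in
#'   confusion matrices).
#' @return An object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(cue_duration_s = 2, task_duration_s = 10,
                          rest_duration_s = 15,
                          trials_per_class_per_session = 15,
                          n_sessions = 2,
                          classes = c("left", "right")) {
  if (any(c(cue_duration_s, task_duration_s, rest_duration_s) <= 0))
    stopf("all paradigm durations must be > 0")
  if (trials_per_class_per_session < 1)
    stopf("trials_per_class_per_session must be >= 1")
  if (length(classes) != 2L)
    stopf("exactly 2 classes are supported (binary classifier head), got %d",
          length(classes))
  structure(list(
    cue_duration_s = cue_duration_s,
    task_duration_s = task_duration_s,
    rest_duration_s = rest_duration_s,
    trials_per_class_per_session = as.integer(trials_per_class_per_session),
    n_sessions = as.integer(n_sessions),
    classes = as.character(classes)
  ), class = "paradigm_spec")
}

#' Total trial count implied by a paradigm
#' @param paradigm A [paradigm_spec()].
#' @return Integer trial count (sessions x trials-per-class x classes).
#' @export
n_trials_total <- function(paradigm) {
  paradigm$n_sessions * paradigm$trials_per_class_per_session *
    length(paradigm$classes)
}

#' Labeled single-modality trial container
#'
#' The unit all pipeline stages consume: a `trials x channels x samples`
#' array of one modality for one subject, with per-trial class labels.
#' EEG data are in microvolts; fNIRS data are chromophore concentration
#' changes (after modified Beer-Lambert conversion).
#'
#' @param subject_id Subject identifier (character).
#' @param modality `"EEG"` or `"FNIRS"`.
#' @param data Numeric array `trials x channels x samples`.
#' @param labels Integer vector in `{0, 1}` (0 = first class), one per trial.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per channel; channel order
#'   is authoritative.
#' @param classes Class-name map for the integer labels.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(subject_id, modality, data, labels, fs,
                      channel_names = NULL,
                      classes = c("left", "right")) {
  modality <- match.arg(toupper(modality), c("EEG", "FNIRS"))
  if (length(dim(data)) != 3L)
    stopf("data must be a 3-d array (trials x channels x samples)")
  labels <- as.integer(labels)
  if (dim(data)[1] != length(labels))
    stopf("data has %d trials but labels has length %d",
          dim(data)[1], length(labels))
  if (fs <= 0) stopf("fs must be > 0")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channel_names) != dim(data)[2])
    stopf("channel_names length %d does not match %d channels",
          length(channel_names), dim(data)[2])
  structure(list(
    subject_id = as.character(subject_id),
    modality = modality,
    data = data,
    labels = labels,
    fs = fs,
    channel_names = as.character(channel_names),
    classes = as.character(classes)
  ), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> subject %s, %s: %d trials x %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$modality, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Paired EEG + fNIRS dataset for one subject
#'
#' Trials are time-locked pairs: the EEG and fNIRS trial sets must have the
#' same trial count and identical label sequences.
#'
#' @param subject_id Subject identifier.
#' @param eeg,fnirs [trial_set()] objects of the respective modality.
#' @param cohort_tag `"normal"`, `"patient"` or `"unspecified"`.
#' @param extras Optional named list of auxiliary arrays (e.g. pre-stimulus
#'   baseline segments kept by the simulator).
#' @return An object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, eeg, fnirs,
                            cohort_tag = c("unspecified", "normal", "patient"),
                            extras = list()) {
  cohort_tag <- match.arg(cohort_tag)
  structure(list(
    subject_id = as.character(subject_id),
    eeg = eeg, fnirs = fnirs,
    cohort_tag = cohort_tag,
    extras = extras
  ), class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s (%s)\n", x$subject_id, x$cohort_tag))
  print(x$eeg); print(x$fnirs)
  invisible(x)
}

validate_trial_set <- function(ts, where) {
  v <- character(0)
  if (!inherits(ts, "trial_set")) return(sprintf("%s: not a trial_set", where))
  d <- dim(ts$data)
  if (d[1] != length(ts$labels))
    v <- c(v, sprintf("%s: trial count %d != label count %d",
                      where, d[1], length(ts$labels)))
  if (!all(is.finite(ts$data)))
    v <- c(v, sprintf("%s: non-finite data values present", where))
  if (!all(ts$labels %in% c(0L, 1L)))
    v <- c(v, sprintf("%s: labels outside {0,1}", where))
  if (ts$fs <= 0) v <- c(v, sprintf("%s: fs <= 0", where))
  if (length(ts$channel_names) != d[2])
    v <- c(v, sprintf("%s: channel_names length != channel count", where))
  v
}

#' Validate a subject dataset against the type invariants
#'
#' Checks every structural invariant (finite data, matching trial counts,
#' paired labels across modalities) and reports violations instead of
#' erroring, so callers can audit a whole population.
#'
#' @param sd A [subject_dataset()].
#' @return Character vector of violations; empty when all invariants hold.
#' @export
validate_subject <- function(sd) {
  if (!inherits(sd, "subject_dataset")) return("not a subject_dataset")
  v <- c(validate_trial_set(sd$eeg, "eeg"), validate_trial_set(sd$fnirs, "fnirs"))
  if (inherits(sd$eeg, "trial_set") && inherits(sd$fnirs, "trial_set")) {
    if (dim(sd$eeg$data)[1] != dim(sd$fnirs$data)[1])
      v <- c(v, sprintf("paired-trials: eeg has %d trials, fnirs has %d",
                        dim(sd$eeg$data)[1], dim(sd$fnirs$data)[1]))
    else if (!identical(sd$eeg$labels, sd$fnirs$labels))
      v <- c(v, "paired-trials: eeg and fnirs label sequences differ")
  }
  v
}

#' Cross-validated evaluation report
#'
#' Per-fold and aggregate classification metrics for one method on one
#' subject. Metrics are fractions internally; [format_eval_report()] renders
#' the conventional percent "mean +/- SD" form.
#'
#' @param method_label Method name.
#' @param fold_metrics Data frame with columns `fold`, `accuracy`,
#'   `precision`, `recall`, `f1` (fractions).
#' @param confusion_matrix Aggregated 2x2 integer count matrix, rows = truth
#'   (class 0, class 1), columns = prediction.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(method_label, fold_metrics, confusion_matrix) {
  cm <- confusion_matrix
  if (!all(cm >= 0) || any(cm != round(cm)))
    stopf("confusion matrix must hold non-negative integer counts")
  structure(list(
    method_label = method_label,
    fold_metrics = fold_metrics,
    confusion_matrix = matrix(as.integer(cm), 2, 2,
                              dimnames = dimnames(cm)),
    mean = vapply(fold_metrics[c("accuracy", "precision", "recall", "f1")],
                  mean, numeric(1)),
    sd = vapply(fold_metrics[c("accuracy", "precision", "recall", "f1")],
                stats::sd, numeric(1))
  ), class = "eval_report")
}

#' @rdname eval_report
#' @param x An `eval_report`.
#' @return `format_eval_report`: one-row data frame with percent-scale
#'   `mean +/- SD` strings, matching the conventional reporting format.
#' @export
format_eval_report <- function(x) {
  fmt <- function(m, s) sprintf("%.2f ± %.2f", 100 * m, 100 * s)
  data.frame(method = x$method_label,
             accuracy = fmt(x$mean["accuracy"], x$sd["accuracy"]),
             precision = fmt(x$mean["precision"], x$sd["precision"]),
             recall = fmt(x$mean["recall"], x$sd["recall"]),
             f1 = fmt(x$mean["f1"], x$sd["f1"]),
             stringsAsFactors = FALSE)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s\n", x$method_label))
  print(format_eval_report(x))
  invisible(x)
}
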