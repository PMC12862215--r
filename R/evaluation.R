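# Nucleotide-level confusion/F1 metrics, the ORF-level outcome taxonomy,
# error-pattern strings and summary/balanced accuracies.

ORF_OUTCOMES <- c("PERFECT", "NEAR_PERFECT", "TIS_ONLY", "TTS_ONLY",
                  "OTHER_ERROR", "FALSE_ORF", "CORRECT_NONCODING")

#' Nucleotide-level confusion matrix and per-class metrics
#'
#' @param predicted,truth integer class vectors (1 TIS, 2 TTS, 3 NONE) of
#'   equal length.
#' @param mask optional logical vector; positions with `FALSE` are excluded.
#' @return list with `confusion` (3 x 3, rows = truth, cols = predicted) and
#'   `metrics` (data.frame class/precision/recall/f1).  Undefined ratios
#'   (no predicted or no true positions of a class) are reported as 0.
#' @export
nucleotide_metrics <- function(predicted, truth, mask = NULL) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!is.null(mask)) {
    predicted <- predicted[mask]
    truth <- truth[mask]
  }
  lv <- seq_along(CLASS_LEVELS)
  confusion <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  dimnames(confusion) <- list(truth = CLASS_LEVELS, predicted = CLASS_LEVELS)
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(confusion = unclass(confusion),
       metrics = data.frame(class = CLASS_LEVELS, precision = as.numeric(precision),
                            recall = as.numeric(recall), f1 = as.numeric(f1)))
}

# normalize raw argmax runs into predicted codon boundaries
# returns list(tis_start, tis_len, n_tis_runs, tts_start, tts_len, n_tts_runs)
runs_to_spans <- function(tis_runs, tts_runs) {
  one <- function(runs) {
    if (nrow(runs) == 0) list(start = NA_integer_, len = NA_integer_, n = 0L)
    else list(start = runs$start[1], len = runs$length[1], n = nrow(runs))
  }
  list(tis = one(tis_runs), tts = one(tts_runs))
}

#' ORF-level outcome of one transcript
#'
#' Compares a prediction against the annotated truth and bins it into the
#' outcome taxonomy.  For coding truth: PERFECT (both 3-nt codon spans exact),
#' NEAR_PERFECT (each boundary within 1 nt, run length within 1 of a codon,
#' not perfect), TIS_ONLY (start codon exact, stop wrong), TTS_ONLY
#' (symmetric) or OTHER_ERROR (including a noncoding call).  For noncoding
#' truth: CORRECT_NONCODING (nothing predicted), FALSE_ORF (a full ORF
#' predicted), TIS_ONLY / TTS_ONLY (only one signal predicted).
#'
#' Predictions can come from the integrated scorer (a selected candidate with
#' exact codon spans) or from raw argmax runs; both are expressed as
#' `prediction`.
#'
#' @param prediction list with either `decision`/`tis_start`/`tts_start`
#'   (integrated mode; starts are 0-based codon starts, decision
#'   "coding"/"noncoding") or `tis_runs`/`tts_runs` data.frames from
#'   [raw_argmax_decode()].
#' @param truth one-row transcript data.frame or list with `biotype`,
#'   `cds_start`, `cds_end`.
#' @return one of PERFECT, NEAR_PERFECT, TIS_ONLY, TTS_ONLY, OTHER_ERROR,
#'   FALSE_ORF, CORRECT_NONCODING.
#' @export
classify_orf_outcome <- function(prediction, truth) {
  if (!is.null(prediction$tis_runs)) {
    sp <- runs_to_spans(prediction$tis_runs, prediction$tts_runs)
    tis <- sp$tis
    tts <- sp$tts
  } else {
    coding <- identical(prediction$decision, "coding")
    tis <- if (coding) list(start = prediction$tis_start, len = 3L, n = 1L)
           else list(start = NA_integer_, len = NA_integer_, n = 0L)
    tts <- if (coding) list(start = prediction$tts_start, len = 3L, n = 1L)
           else list(start = NA_integer_, len = NA_integer_, n = 0L)
  }
  if (truth$biotype == "noncoding") {
    if (tis$n == 0 && tts$n == 0) return("CORRECT_NONCODING")
    if (tis$n > 0 && tts$n > 0) return("FALSE_ORF")
    if (tis$n > 0) return("TIS_ONLY")
    return("TTS_ONLY")
  }
  true_tis <- truth$cds_start
  true_tts <- truth$cds_end - 3L
  tis_exact <- tis$n == 1 && !is.na(tis$start) && tis$start == true_tis && tis$len == 3
  tts_exact <- tts$n == 1 && !is.na(tts$start) && tts$start == true_tts && tts$len == 3
  if (tis_exact && tts_exact) return("PERFECT")
  tis_near <- tis$n == 1 && !is.na(tis$start) && abs(tis$start - true_tis) <= 1 &&
    abs(tis$len - 3) <= 1
  tts_near <- tts$n == 1 && !is.na(tts$start) && abs(tts$start - true_tts) <= 1 &&
    abs(tts$len - 3) <= 1
  if (tis_near && tts_near) return("NEAR_PERFECT")
  if (tis_exact) return("TIS_ONLY")
  if (tts_exact) return("TTS_ONLY")
  "OTHER_ERROR"
}

#' Error-pattern string of a raw prediction
#'
#' Concatenates, in positional order, the 3-nt sequence at the start of every
#' predicted TIS/TTS run followed by "-"; a transcript with no predicted
#' sites yields "-".  Patterns like "ATG-TGA-" (a full spurious ORF) or
#' "ATG-" (start without stop) summarize what the raw decoder saw.
#'
#' @param tis_runs,tts_runs run data.frames from [raw_argmax_decode()].
#' @param sequence the transcript sequence.
#' @return pattern string.
#' @export
error_pattern <- function(tis_runs, tts_runs, sequence) {
  runs <- rbind(tis_runs, tts_runs)
  if (nrow(runs) == 0) return("-")
  runs <- runs[order(runs$start), , drop = FALSE]
  paste0(paste0(vapply(runs$start, function(s)
    substr(sequence, s + 1, s + 3), character(1)), "-"), collapse = "")
}

#' Summarize ORF-level outcomes
#'
#' Per-category percentages within each truth class, overall accuracy
#' ((PERFECT + CORRECT_NONCODING) / N) and balanced accuracy (mean of the
#' PERFECT fraction among coding and the CORRECT_NONCODING fraction among
#' noncoding).  With a truth class absent the balanced accuracy is undefined
#' and returned as NA with a warning.
#'
#' @param outcomes character vector of outcome categories.
#' @param truth_biotype character vector ("coding"/"noncoding"), same length.
#' @return list with `by_class` (data.frame biotype/category/n/percent),
#'   `overall_accuracy`, `coding_accuracy`, `noncoding_accuracy`,
#'   `balanced_accuracy`.
#' @export
summarize_outcomes <- function(outcomes, truth_biotype) {
  stopifnot(length(outcomes) == length(truth_biotype), length(outcomes) > 0)
  tab <- as.data.frame(table(biotype = truth_biotype,
                             category = factor(outcomes, levels = ORF_OUTCOMES)))
  names(tab)[3] <- "n"
  class_n <- table(truth_biotype)
  tab$percent <- 100 * tab$n / as.numeric(class_n[as.character(tab$biotype)])
  coding <- truth_biotype == "coding"
  coding_acc <- if (any(coding)) mean(outcomes[coding] == "PERFECT") else NA_real_
  nonc_acc <- if (any(!coding)) mean(outcomes[!coding] == "CORRECT_NONCODING") else NA_real_
  overall <- mean(outcomes %in% c("PERFECT", "CORRECT_NONCODING"))
  balanced <- if (is.na(coding_acc) || is.na(nonc_acc)) {
    warning("balanced accuracy undefined: a truth class is absent")
    NA_real_
  } else {
    (coding_acc + nonc_acc) / 2
  }
  list(by_class = tab, overall_accuracy = overall,
       coding_accuracy = coding_acc, noncoding_accuracy = nonc_acc,
       balanced_accuracy = balanced)
}

#' Frequency table of error patterns
#'
#' Tabulates raw-decoding pattern strings (see [error_pattern()]) for a set
#' of transcripts, typically those with incorrect outcomes.
#'
#' @param patterns character vector of pattern strings.
#' @return data.frame with `pattern`, `count`, `percentage`, sorted by
#'   decreasing count.
#' @export
error_pattern_table <- function(patterns) {
  tab <- sort(table(patterns), decreasing = TRUE)
  data.frame(pattern = names(tab), count = as.integer(tab),
             percentage = 100 * as.integer(tab) / length(patterns),
             stringsAsFactors = FALSE)
}

#' Accuracy on an explicitly balanced subset
#'
#' Downsamples the majority truth class to the minority size and returns the
#' overall accuracy on the balanced set; in expectation this equals the
#' macro-averaged balanced accuracy.
#'
#' @param outcomes,truth_biotype as in [summarize_outcomes()].
#' @param seed integer seed for the downsampling.
#' @return overall accuracy on the balanced subset.
#' @export
balanced_subset_accuracy <- function(outcomes, truth_biotype, seed = 1L) {
  coding <- which(truth_biotype == "coding")
  nonc <- which(truth_biotype == "noncoding")
  if (length(coding) == 0 || length(nonc) == 0)
    stop("both truth classes must be present")
  k <- min(length(coding), length(nonc))
  withr::with_seed(seed, {
    idx <- c(sample(coding, k), sample(nonc, k))
  })
  mean(outcomes[idx] %in% c("PERFECT", "CORRECT_NONCODING"))
}
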