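# Integrated ORF scoring: enumerate constraint-satisfying candidate ORFs from
# a per-position probability track, score each with TIS/TTS probabilities plus
# Kozak context, codon adaptation and GC content, and select the best
# candidate above a decision threshold.

#' Kozak context position weight matrix
#'
#' Probabilities of each base at positions -6..+3 relative to the A of the
#' start codon (positions 0..2 are degenerate on A, T, G).  Rows sum to 1.
#'
#' @return 10 x 4 matrix; rownames are positions, colnames A,C,G,T.
#' @export
kozak_pwm <- function() {
  m <- rbind(
    "-6" = c(0.22, 0.28, 0.32, 0.18),
    "-5" = c(0.20, 0.30, 0.30, 0.20),
    "-4" = c(0.18, 0.32, 0.30, 0.20),
    "-3" = c(0.25, 0.15, 0.45, 0.15),
    "-2" = c(0.20, 0.35, 0.25, 0.20),
    "-1" = c(0.20, 0.35, 0.25, 0.20),
    "0"  = c(1.00, 0.00, 0.00, 0.00),
    "1"  = c(0.00, 0.00, 0.00, 1.00),
    "2"  = c(0.00, 0.00, 1.00, 0.00),
    "3"  = c(0.20, 0.20, 0.40, 0.20))
  colnames(m) <- c("A", "C", "G", "T")
  m
}

#' Human codon usage frequencies
#'
#' Approximate human codon usage (occurrences per 1000 codons), compiled from
#' published codon-usage statistics.  Used to derive the default relative
#' adaptiveness table and as the sampling bias of the synthetic transcriptome
#' generator; fully user-replaceable.
#'
#' @return named numeric vector over all 64 codons.
#' @export
codon_usage_human <- function() {
  c(TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9,
    CTT = 13.2, CTC = 19.6, CTA = 7.2, CTG = 39.6,
    ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
    GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1,
    TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
    CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
    ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
    GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
    TAT = 12.2, TAC = 15.3, TAA = 1.0, TAG = 0.8,
    CAT = 10.9, CAC = 15.1, CAA = 12.3, CAG = 34.2,
    AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
    GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6,
    TGT = 10.6, TGC = 12.6, TGA = 1.6, TGG = 13.2,
    CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4,
    AGT = 12.1, AGC = 19.5, AGA = 12.2, AGG = 12.0,
    GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5)
}

#' Relative adaptiveness weights for CAI
#'
#' Within every synonymous codon family the most frequent codon gets weight 1
#' and the others their frequency relative to it.  Stop codons are excluded.
#'
#' @param usage named codon frequency vector (default [codon_usage_human()]).
#' @return named numeric vector over the 61 sense codons, values in (0, 1].
#' @export
codon_weights <- function(usage = codon_usage_human()) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  usage <- usage[sense]
  aa <- code[sense]
  fam_max <- tapply(usage, aa, max)
  w <- usage / fam_max[aa]
  # guard degenerate user tables: zero-frequency codons get a small floor
  w[w <= 0] <- 1e-3
  setNames(as.numeric(w), sense)
}

#' Scoring parameters
#'
#' Defaults are the published data-driven optimum: component weights 0.30
#' (TIS), 0.50 (TTS), 0.04 (Kozak), 0.04 (CAI), 0.00 (GC) and decision
#' threshold 0.635.  Alternative documented presets for the threshold are
#' 0.50 and 0.52.  `tis_floor`/`tts_floor` prune candidates whose codon
#' probabilities fall below 0.001 before scoring.
#'
#' @param w_tis,w_tts,w_kozak,w_cai,w_gc component weights (>= 0).
#' @param threshold decision threshold in [0, 1].
#' @param gc_mu,gc_sigma Gaussian constants of the GC component.
#' @param tis_floor,tts_floor minimum aggregated codon probabilities.
#' @param gc_rescale map the GC component from (-1, 1] to (0, 1] before
#'   weighting (only relevant with a nonzero `w_gc`).
#' @param max_candidates cap on floors-passing candidates per transcript
#'   (highest TIS+TTS probability kept); ignored when both floors are 0.
#' @return an `orf_scoring_params` list.
#' @export
scoring_params <- function(w_tis = 0.30, w_tts = 0.50, w_kozak = 0.04,
                           w_cai = 0.04, w_gc = 0.00, threshold = 0.635,
                           gc_mu = 0.42, gc_sigma = 0.22,
                           tis_floor = 0.001, tts_floor = 0.001,
                           gc_rescale = FALSE, max_candidates = 500L) {
  stopifnot(w_tis >= 0, w_tts >= 0, w_kozak >= 0, w_cai >= 0, w_gc >= 0,
            threshold >= 0, threshold <= 1,
            tis_floor >= 0, tis_floor < 1, tts_floor >= 0, tts_floor < 1)
  structure(list(w_tis = w_tis, w_tts = w_tts, w_kozak = w_kozak,
                 w_cai = w_cai, w_gc = w_gc, threshold = threshold,
                 gc_mu = gc_mu, gc_sigma = gc_sigma,
                 tis_floor = tis_floor, tts_floor = tts_floor,
                 gc_rescale = isTRUE(gc_rescale),
                 max_candidates = max_candidates),
            class = "orf_scoring_params")
}

#' Aggregate a per-nucleotide signal over one codon
#'
#' Arithmetic mean of the channel probability over the codon's 3 positions.
#'
#' @param probs (positions x 3) probability matrix (columns TIS, TTS, NONE).
#' @param codon_start 0-based index of the codon's first nucleotide.
#' @param channel "TIS" or "TTS".
#' @return scalar probability.
#' @export
codon_signal_probability <- function(probs, codon_start, channel = c("TIS", "TTS")) {
  channel <- match.arg(channel)
  if (codon_start < 0 || codon_start + 3 > nrow(probs))
    stop("codon [", codon_start, ", ", codon_start + 3, ") outside probability track")
  col <- if (channel == "TIS") 1L else 2L
  mean(probs[(codon_start + 1):(codon_start + 3), col])
}

#' Enumerate candidate ORFs
#'
#' Every (ATG, first in-frame stop) pair is a candidate; pairs whose
#' aggregated start-codon TIS probability or stop-codon TTS probability falls
#' below the floors are pruned.  With both floors at 0 the result is exactly
#' the set a brute-force scan finds.
#'
#' @param sequence nucleotide string.
#' @param probs (positions x 3) probability matrix, same length as the
#'   sequence.
#' @param params an `orf_scoring_params`.
#' @return data.frame with 0-based `tis_start`, `tts_start`, `tis_prob`,
#'   `tts_prob`, sorted by `tis_start`; may be empty.
#' @export
enumerate_candidates <- function(sequence, probs, params = scoring_params()) {
  stopifnot(nrow(probs) == nchar(sequence))
  atg <- as.integer(gregexpr("ATG", sequence, fixed = TRUE)[[1]])
  atg <- atg[atg > 0] - 1L
  stops <- sort(unlist(lapply(STOP_CODONS, function(cod) {
    p <- as.integer(gregexpr(cod, sequence, fixed = TRUE)[[1]])
    p[p > 0] - 1L
  })))
  empty <- data.frame(tis_start = integer(0), tts_start = integer(0),
                      tis_prob = numeric(0), tts_prob = numeric(0))
  if (length(atg) == 0 || length(stops) == 0) return(empty)
  out <- lapply(0:2, function(f) {
    sf <- stops[stops %% 3L == f]
    af <- atg[atg %% 3L == f]
    if (length(sf) == 0 || length(af) == 0) return(NULL)
    # first stop strictly downstream of each ATG (stop start >= atg + 3)
    idx <- findInterval(af + 3L - 0.5, sf) + 1L
    keep <- idx <= length(sf)
    data.frame(tis_start = af[keep], tts_start = sf[idx[keep]])
  })
  cand <- do.call(rbind, out)
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  cand <- cand[order(cand$tis_start, cand$tts_start), , drop = FALSE]
  cand$tis_prob <- vapply(cand$tis_start, function(p)
    codon_signal_probability(probs, p, "TIS"), numeric(1))
  cand$tts_prob <- vapply(cand$tts_start, function(p)
    codon_signal_probability(probs, p, "TTS"), numeric(1))
  cand <- cand[cand$tis_prob >= params$tis_floor &
                 cand$tts_prob >= params$tts_floor, , drop = FALSE]
  capped <- params$tis_floor > 0 || params$tts_floor > 0
  if (capped && is.finite(params$max_candidates) &&
      nrow(cand) > params$max_candidates) {
    keep <- order(cand$tis_prob + cand$tts_prob, decreasing = TRUE)[
      seq_len(params$max_candidates)]
    cand <- cand[sort(keep), , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Kozak context score
#'
#' Product over positions -6..+3 (relative to the A of the ATG) of the PWM
#' probability of the observed base.  The raw score is the product times
#' 10000; the normalized score divides the product by the maximum attainable
#' product so the per-position-argmax context scores exactly 1.  Flank
#' positions outside the sequence contribute a uniform 0.25 to both product
#' and maximum.
#'
#' @param sequence nucleotide string.
#' @param tis_start 0-based position of the A of the ATG.
#' @param pwm matrix from [kozak_pwm()].
#' @return list with `raw` and `norm`.
#' @export
kozak_score <- function(sequence, tis_start, pwm = kozak_pwm()) {
  if (substr(sequence, tis_start + 1, tis_start + 3) != "ATG")
    stop("no ATG at position ", tis_start)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  prod_obs <- 1
  prod_max <- 1
  for (rel in -6:3) {
    pos <- tis_start + rel  # 0-based
    row <- pwm[as.character(rel), ]
    if (pos < 0 || pos >= length(chars)) {
      prod_obs <- prod_obs * 0.25
      prod_max <- prod_max * 0.25
    } else {
      base <- chars[pos + 1]
      p <- if (base %in% colnames(pwm)) row[[base]] else 0.25  # N: uniform
      prod_obs <- prod_obs * p
      prod_max <- prod_max * max(row)
    }
  }
  list(raw = prod_obs * 10000, norm = prod_obs / prod_max)
}

#' Codon adaptation index of an ORF
#'
#' Geometric mean of the relative adaptiveness of the ORF's sense codons
#' (the stop codon is excluded before calling).
#'
#' @param orf_sequence in-frame coding sequence without the stop codon.
#' @param weights named weight vector from [codon_weights()].
#' @return score in (0, 1].
#' @export
cai_score <- function(orf_sequence, weights = codon_weights()) {
  n <- nchar(orf_sequence)
  if (n == 0 || n %% 3 != 0) stop("ORF length must be a positive multiple of 3")
  codons <- substring(orf_sequence, seq(1, n, 3), seq(3, n, 3))
  w <- weights[codons]
  if (anyNA(w)) stop("codon(s) absent from weight table: ",
                     paste(unique(codons[is.na(w)]), collapse = ","))
  exp(mean(log(w)))
}

#' GC-content score
#'
#' Gaussian transform of the ORF's G+C fraction:
#' 2 * exp(-0.5 * ((gc - mu) / sigma)^2) - 1, maximal (1) at `mu` and
#' symmetric about it; range (-1, 1].
#'
#' @param orf_sequence nucleotide string (non-empty).
#' @param gc_mu,gc_sigma Gaussian constants (defaults 0.42 and 0.22).
#' @return score in (-1, 1].
#' @export
gc_score <- function(orf_sequence, gc_mu = 0.42, gc_sigma = 0.22) {
  n <- nchar(orf_sequence)
  if (n == 0) stop("empty sequence")
  gc <- sum(strsplit(orf_sequence, "", fixed = TRUE)[[1]] %in% c("G", "C")) / n
  2 * exp(-0.5 * ((gc - gc_mu) / gc_sigma)^2) - 1
}

#' Weighted integrated score
#'
#' w_tis * TIS_prob + w_tts * TTS_prob + w_kozak * Kozak_norm +
#' w_cai * CAI + w_gc * GC.  The Kozak component is the normalized (0-1)
#' variant; with `gc_rescale` the GC component is mapped to (0, 1].
#'
#' @param tis_prob,tts_prob,kozak_norm,cai,gc component values (vectorized).
#' @param params an `orf_scoring_params`.
#' @return numeric score(s).
#' @export
integrated_score <- function(tis_prob, tts_prob, kozak_norm, cai, gc,
                             params = scoring_params()) {
  gc_comp <- if (params$gc_rescale) (gc + 1) / 2 else gc
  params$w_tis * tis_prob + params$w_tts * tts_prob +
    params$w_kozak * kozak_norm + params$w_cai * cai + params$w_gc * gc_comp
}

#' Score candidate ORFs
#'
#' Fills in Kozak, CAI, GC and the integrated score for every candidate from
#' [enumerate_candidates()].
#'
#' @param sequence nucleotide string.
#' @param candidates data.frame from [enumerate_candidates()].
#' @param params an `orf_scoring_params`.
#' @param weights CAI weight table.
#' @param pwm Kozak PWM.
#' @return the candidate data.frame with columns `kozak_raw`, `kozak_norm`,
#'   `cai`, `gc`, `integrated_score` added.
#' @export
score_candidates <- function(sequence, candidates, params = scoring_params(),
                             weights = codon_weights(), pwm = kozak_pwm()) {
  n <- nrow(candidates)
  kr <- kn <- cai <- gc <- numeric(n)
  for (i in seq_len(n)) {
    ks <- kozak_score(sequence, candidates$tis_start[i], pwm)
    kr[i] <- ks$raw
    kn[i] <- ks$norm
    orf <- substr(sequence, candidates$tis_start[i] + 1, candidates$tts_start[i])
    cai[i] <- cai_score(orf, weights)
    full <- substr(sequence, candidates$tis_start[i] + 1, candidates$tts_start[i] + 3)
    gc[i] <- gc_score(full, params$gc_mu, params$gc_sigma)
  }
  candidates$kozak_raw <- kr
  candidates$kozak_norm <- kn
  candidates$cai <- cai
  candidates$gc <- gc
  candidates$integrated_score <- integrated_score(candidates$tis_prob,
                                                  candidates$tts_prob,
                                                  kn, cai, gc, params)
  candidates
}

#' Select the best ORF (or call the transcript non-coding)
#'
#' The highest-integrated-score candidate wins if its score reaches the
#' decision threshold; ties break deterministically toward the smaller
#' `tis_start`, then the smaller `tts_start`.
#'
#' @param candidates scored data.frame from [score_candidates()].
#' @param params an `orf_scoring_params`.
#' @return list with `decision` ("coding"/"noncoding") and, when coding,
#'   `orf` (the chosen candidate row).
#' @export
select_orf <- function(candidates, params = scoring_params()) {
  if (is.null(candidates) || nrow(candidates) == 0)
    return(list(decision = "noncoding", orf = NULL))
  ord <- order(-candidates$integrated_score, candidates$tis_start,
               candidates$tts_start)
  best <- candidates[ord[1], , drop = FALSE]
  if (best$integrated_score >= params$threshold)
    list(decision = "coding", orf = best)
  else
    list(decision = "noncoding", orf = NULL)
}

#' Grid search over scoring weights and threshold
#'
#' Exhaustively evaluates the Cartesian grid of component weights and
#' decision thresholds against truth labels, maximizing classification
#' accuracy: a coding transcript counts as correct when the argmax candidate
#' is its annotated ORF and clears the threshold; a noncoding transcript when
#' no candidate clears it.
#'
#' @param candidates data.frame with one row per candidate: `transcript_id`,
#'   `is_true_orf` (logical), `tis_prob`, `tts_prob`, `kozak_norm`, `cai`,
#'   `gc`.
#' @param transcripts data.frame with `transcript_id` and `biotype` truth for
#'   every evaluated transcript (including those without candidates).
#' @param grid named list of candidate values per axis: `w_tis`, `w_tts`,
#'   `w_kozak`, `w_cai`, `w_gc`, `threshold`.
#' @return list with `best` (an `orf_scoring_params`), `accuracy`, and
#'   `table` (the full accuracy surface, one row per grid point).
#' @export
optimize_weights <- function(candidates, transcripts, grid) {
  axes <- c("w_tis", "w_tts", "w_kozak", "w_cai", "w_gc", "threshold")
  if (!all(axes %in% names(grid)) || any(lengths(grid[axes]) == 0))
    stop("grid must provide non-empty values for ", paste(axes, collapse = ", "))
  surface <- expand.grid(grid[axes], KEEP.OUT.ATTRS = FALSE)
  tid <- factor(candidates$transcript_id, levels = transcripts$transcript_id)
  coding_truth <- transcripts$biotype == "coding"
  acc <- numeric(nrow(surface))
  for (g in seq_len(nrow(surface))) {
    p <- surface[g, ]
    score <- p$w_tis * candidates$tis_prob + p$w_tts * candidates$tts_prob +
      p$w_kozak * candidates$kozak_norm + p$w_cai * candidates$cai +
      p$w_gc * candidates$gc
    best_score <- rep(-Inf, nrow(transcripts))
    best_true <- rep(FALSE, nrow(transcripts))
    if (length(score) > 0) {
      sp <- split(seq_along(score), tid)
      for (t in seq_along(sp)) {
        rows <- sp[[t]]
        if (length(rows) == 0) next
        j <- rows[which.max(score[rows])]
        best_score[t] <- score[j]
        best_true[t] <- candidates$is_true_orf[j]
      }
    }
    called <- best_score >= p$threshold
    correct <- ifelse(coding_truth, called & best_true, !called)
    acc[g] <- mean(correct)
  }
  surface$accuracy <- acc
  best_row <- which.max(acc)  # which.max takes the first maximum: grid order
  bp <- surface[best_row, ]
  best <- scoring_params(w_tis = bp$w_tis, w_tts = bp$w_tts,
                         w_kozak = bp$w_kozak, w_cai = bp$w_cai,
                         w_gc = bp$w_gc, threshold = bp$threshold)
  list(best = best, accuracy = acc[best_row], table = surface)
}

#' ROC curve area and Youden-optimal threshold
#'
#' AUC by the rank (Mann-Whitney) construction, equivalent to the trapezoid
#' rule on the ROC curve; the threshold is the observed score maximizing
#' Youden's J = sensitivity + specificity - 1 (prediction rule: positive when
#' score >= threshold).
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels; both classes must be present.
#' @return list with `auc`, `threshold` and `j` (the maximal J).
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- sort(unique(scores))
  j <- vapply(thresholds, function(t) {
    sens <- sum(labels & scores >= t) / n_pos
    spec <- sum(!labels & scores < t) / n_neg
    sens + spec - 1
  }, numeric(1))
  best <- which.max(j)
  list(auc = auc, threshold = thresholds[best], j = j[best])
}

#' Translate an ORF to protein
#'
#' Standard genetic code; the terminal stop codon is required and not
#' emitted.  Internal stop codons or invalid codons are errors.
#'
#' @param orf_sequence in-frame sequence from ATG through the stop codon.
#' @return amino-acid string.
#' @export
translate_orf <- function(orf_sequence) {
  n <- nchar(orf_sequence)
  if (n < 6 || n %% 3 != 0)
    stop("ORF length must be a multiple of 3 and include start and stop codons")
  if (substr(orf_sequence, 1, 3) != "ATG") stop("ORF must start with ATG")
  codons <- substring(orf_sequence, seq(1, n, 3), seq(3, n, 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("invalid codon: ", codons[which(is.na(aa))[1]])
  last <- length(aa)
  if (aa[last] != "*") stop("ORF must end with a stop codon")
  if (any(aa[-last] == "*"))
    stop("internal stop codon at codon ", which(aa[-last] == "*")[1])
  paste(aa[-last], collapse = "")
}
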