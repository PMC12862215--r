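# End-to-end prediction pipeline and a self-test tying all stages together.

#' Read / write per-position probability tracks
#'
#' Tab-separated long format with columns `transcript_id`, `position`
#' (0-based), `p_tis`, `p_tts`, `p_none`.  Lets the integrated scorer run on
#' probability tracks produced by an external model.
#'
#' @param path TSV path.
#' @return named list of (positions x 3) matrices.
#' @export
read_probability_track <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "position", "p_tis", "p_tts", "p_none")
  if (!all(required %in% names(tab)))
    stop("probability track needs columns: ", paste(required, collapse = ", "))
  out <- lapply(split(tab, tab$transcript_id), function(d) {
    d <- d[order(d$position), ]
    if (!identical(d$position, 0:(nrow(d) - 1)))
      stop("positions of ", d$transcript_id[1],
           " are not contiguous from 0")
    m <- as.matrix(d[, c("p_tis", "p_tts", "p_none")])
    colnames(m) <- CLASS_LEVELS
    bad <- abs(rowSums(m) - 1) > 1e-4
    if (any(bad))
      stop("probabilities of ", d$transcript_id[1], " do not sum to 1 at position ",
           d$position[bad][1])
    m
  })
  out
}

#' @rdname read_probability_track
#' @param probs named list of probability matrices (as from
#'   [predict_probs()]).
#' @export
write_probability_track <- function(probs, path) {
  tab <- do.call(rbind, lapply(names(probs), function(id) {
    m <- probs[[id]]
    data.frame(transcript_id = id, position = seq_len(nrow(m)) - 1L,
               p_tis = m[, 1], p_tts = m[, 2], p_none = m[, 3])
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score externally produced probability tracks
#'
#' Runs candidate enumeration, component scoring and ORF selection on
#' ready-made probability tracks instead of the bundled network.
#'
#' @param sequences named character vector (ids matching the track).
#' @param probs named list of probability matrices.
#' @param params an `orf_scoring_params`.
#' @param weights CAI weight table.
#' @return predictions data.frame as in [predict_transcripts()] (without the
#'   raw-mode columns' model dependency — raw decoding uses the same track).
#' @export
score_probability_tracks <- function(sequences, probs,
                                     params = scoring_params(),
                                     weights = codon_weights()) {
  ids <- intersect(names(sequences), names(probs))
  if (length(ids) == 0) stop("no shared transcript ids between sequences and tracks")
  rows <- lapply(ids, function(id) {
    seqn <- sequences[[id]]
    p <- probs[[id]]
    if (nrow(p) != nchar(seqn))
      stop("track length of ", id, " does not match its sequence")
    cand <- enumerate_candidates(seqn, p, params)
    cand <- score_candidates(seqn, cand, params, weights)
    sel <- select_orf(cand, params)
    raw <- raw_argmax_decode(p)
    if (sel$decision == "coding") {
      orf <- sel$orf
      data.frame(transcript_id = id, decision = "coding",
                 tis_start = orf$tis_start, tts_start = orf$tts_start,
                 tis_prob = orf$tis_prob, tts_prob = orf$tts_prob,
                 kozak_raw = orf$kozak_raw, kozak_norm = orf$kozak_norm,
                 cai = orf$cai, gc = orf$gc,
                 integrated_score = orf$integrated_score,
                 protein = translate_orf(substr(seqn, orf$tis_start + 1,
                                                orf$tts_start + 3)),
                 raw_pattern = error_pattern(raw$tis_runs, raw$tts_runs, seqn),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = id, decision = "noncoding",
                 tis_start = NA_integer_, tts_start = NA_integer_,
                 tis_prob = NA_real_, tts_prob = NA_real_,
                 kozak_raw = NA_real_, kozak_norm = NA_real_,
                 cai = NA_real_, gc = NA_real_, integrated_score = NA_real_,
                 protein = NA_character_,
                 raw_pattern = error_pattern(raw$tis_runs, raw$tts_runs, seqn),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Predict ORFs for a set of transcripts
#'
#' Runs the labeler over every record, then both decoders: the raw argmax
#' decoding of the probability track, and the integrated scorer (candidate
#' enumeration, component scores, thresholded selection).
#'
#' @param model an `orf_model`.
#' @param records transcript data.frame (annotations optional; only
#'   sequences are used for prediction).
#' @param params an `orf_scoring_params`.
#' @param weights CAI weight table.
#' @param batch_size forward-pass batch size.
#' @return list with `predictions` (one row per transcript: decision,
#'   0-based `tis_start`/`tts_start`, component scores, `integrated_score`,
#'   `protein`, plus raw-mode columns `raw_pattern`, `raw_n_tis`,
#'   `raw_n_tts`) and `probs` (named list of probability tracks).
#' @export
predict_transcripts <- function(model, records, params = scoring_params(),
                                weights = codon_weights(), batch_size = 16L) {
  probs <- predict_probs(model, records, batch_size = batch_size)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    seqn <- substr(records$sequence[i], 1, nrow(probs[[i]]))
    cand <- enumerate_candidates(seqn, probs[[i]], params)
    cand <- score_candidates(seqn, cand, params, weights)
    sel <- select_orf(cand, params)
    raw <- raw_argmax_decode(probs[[i]])
    pattern <- error_pattern(raw$tis_runs, raw$tts_runs, seqn)
    if (sel$decision == "coding") {
      orf <- sel$orf
      protein <- translate_orf(substr(seqn, orf$tis_start + 1, orf$tts_start + 3))
      rows[[i]] <- data.frame(
        transcript_id = records$transcript_id[i], decision = "coding",
        tis_start = orf$tis_start, tts_start = orf$tts_start,
        tis_prob = orf$tis_prob, tts_prob = orf$tts_prob,
        kozak_raw = orf$kozak_raw, kozak_norm = orf$kozak_norm,
        cai = orf$cai, gc = orf$gc, integrated_score = orf$integrated_score,
        protein = protein, raw_pattern = pattern,
        raw_n_tis = nrow(raw$tis_runs), raw_n_tts = nrow(raw$tts_runs),
        stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        transcript_id = records$transcript_id[i], decision = "noncoding",
        tis_start = NA_integer_, tts_start = NA_integer_,
        tis_prob = NA_real_, tts_prob = NA_real_,
        kozak_raw = NA_real_, kozak_norm = NA_real_,
        cai = NA_real_, gc = NA_real_, integrated_score = NA_real_,
        protein = NA_character_, raw_pattern = pattern,
        raw_n_tis = nrow(raw$tis_runs), raw_n_tts = nrow(raw$tts_runs),
        stringsAsFactors = FALSE)
    }
  }
  list(predictions = do.call(rbind, rows), probs = probs)
}

#' Evaluate predictions against annotated truth
#'
#' Classifies every transcript's outcome in both decoding modes and
#' summarizes them.
#'
#' @param result output of [predict_transcripts()].
#' @param records the annotated truth records (same order).
#' @return list with `integrated` and `raw` summaries (see
#'   [summarize_outcomes()]) and the per-transcript `outcomes` data.frame.
#' @export
evaluate_predictions <- function(result, records) {
  n <- nrow(records)
  int_out <- raw_out <- character(n)
  for (i in seq_len(n)) {
    pred <- result$predictions[i, ]
    truth <- records[i, ]
    int_out[i] <- classify_orf_outcome(
      list(decision = pred$decision, tis_start = pred$tis_start,
           tts_start = pred$tts_start), truth)
    raw <- raw_argmax_decode(result$probs[[i]])
    raw_out[i] <- classify_orf_outcome(raw, truth)
  }
  list(integrated = summarize_outcomes(int_out, records$biotype),
       raw = summarize_outcomes(raw_out, records$biotype),
       outcomes = data.frame(transcript_id = records$transcript_id,
                             biotype = records$biotype,
                             integrated = int_out, raw = raw_out,
                             stringsAsFactors = FALSE))
}

#' Write predictions and selected proteins
#'
#' @param result output of [predict_transcripts()].
#' @param predictions_path TSV output path (NULL to skip).
#' @param protein_path protein FASTA output path (NULL to skip).
#' @return invisible NULL.
#' @export
write_predictions <- function(result, predictions_path = NULL,
                              protein_path = NULL) {
  if (!is.null(predictions_path))
    write.table(result$predictions, predictions_path, sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(protein_path)) {
    coding <- result$predictions[result$predictions$decision == "coding", ]
    aa <- Biostrings::AAStringSet(setNames(coding$protein, coding$transcript_id))
    Biostrings::writeXStringSet(aa, protein_path, width = 70L)
  }
  invisible(NULL)
}

#' End-to-end pipeline self-test
#'
#' Simulates a small transcriptome, trains a reduced model for a few epochs,
#' predicts, evaluates both decoding modes and runs one perturbation
#' condition, asserting the basic pipeline contracts along the way.
#' Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param n_coding,n_noncoding,l_max,epochs scaled-down problem size.
#' @return list of per-stage status and headline metrics.
#' @export
pipeline_selftest <- function(seed = 1L, n_coding = 30L, n_noncoding = 30L,
                              l_max = 200L, epochs = 2L) {
  report <- list()
  cfg <- synth_config(n_coding = n_coding, n_noncoding = n_noncoding,
                      utr5_len = c(8L, 20L), cds_codons = c(15L, 40L),
                      utr3_len = c(8L, 30L), noncoding_len = c(60L, 190L),
                      seed = seed)
  records <- generate_transcriptome(cfg)
  report$simulate <- list(ok = nrow(records) == n_coding + n_noncoding,
                          n = nrow(records))
  split <- split_by_gene(records, 0.8, seed)
  part <- split$partition[match(records$gene_symbol, split$gene_symbol)]
  train_recs <- records[part == "train", ]
  held_recs <- records[part == "heldout", ]
  mcfg <- model_config(embedding_dim = 16L, local_channels = 8L,
                       stage_channels = c(8L, 12L, 16L),
                       blocks_per_stage = c(1L, 1L, 1L),
                       stage_kernels = c(7L, 7L, 9L),
                       stage_dilations = c(1L, 2L, 3L),
                       head_channels = 8L, l_max = l_max)
  model <- build_model(mcfg, seed = seed)
  enc_train <- encode_transcripts(train_recs, l_max)
  enc_held <- encode_transcripts(held_recs, l_max)
  fit <- train_model(model, enc_train, enc_held,
                     train_config(max_epochs = epochs, seed = seed),
                     verbose = FALSE)
  report$train <- list(ok = all(is.finite(fit$history$train_loss)),
                       epochs = nrow(fit$history),
                       final_train_loss = tail(fit$history$train_loss, 1))
  result <- predict_transcripts(fit$model, held_recs)
  report$predict <- list(ok = nrow(result$predictions) == nrow(held_recs),
                         n = nrow(result$predictions))
  ev <- evaluate_predictions(result, held_recs)
  report$evaluate <- list(ok = is.finite(ev$integrated$overall_accuracy),
                          integrated_accuracy = ev$integrated$overall_accuracy,
                          raw_accuracy = ev$raw$overall_accuracy)
  conds <- data.frame(condition = c("identity", "CDS_insert_1"),
                      region = c(NA, "CDS"), operation = c("identity", "insert"),
                      size = c(NA, 1L), seed = seed, stringsAsFactors = FALSE)
  pe <- run_perturbation_experiment(held_recs[held_recs$biotype == "coding", ],
                                    fit$model, conds)
  report$perturb <- list(ok = nrow(pe$summary) == 2, summary = pe$summary)
  report$ok <- all(vapply(report[c("simulate", "train", "predict",
                                   "evaluate", "perturb")],
                          function(x) isTRUE(x$ok), logical(1)))
  report
}
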