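# Self-contained synthetic benchmark: simulate, split by gene, train, predict
# with both decoders, evaluate, and perturb.  This is the protocol used by the
# package's reproducibility script and acceptance tests, exposed as a regular
# function so the whole experiment is one call.

#' Train and evaluate the labeler on a synthetic transcriptome
#'
#' Generates a synthetic transcriptome, splits it 80/20 at the gene level
#' (carving a further tenth of the training genes out as the validation set
#' for the scheduler), trains the full architecture, and evaluates both
#' decoders on the held-out genes.
#'
#' @param seed integer; governs simulation, split, initialization and batch
#'   order.
#' @param n_coding,n_noncoding transcriptome size (default 1000 + 1000).
#' @param l_max padded sequence length (default 400 for the compact
#'   synthetic transcripts).
#' @param epochs training epochs (default 1; the planted signals are strong
#'   enough for single-pass convergence at this problem size).
#' @param model_cfg optional `orf_model_config` (default: full architecture
#'   at `l_max`).
#' @param synth_cfg optional `orf_synth_config` (default: generator defaults
#'   with the given sizes and seed).
#' @param params scoring parameters for the integrated decoder.
#' @param verbose print training progress.
#' @return list with `model`, `fit` (history), `heldout` (records),
#'   `result` (predictions + probability tracks), `evaluation` (integrated
#'   and raw summaries) and `split`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_coding = 1000L,
                                n_noncoding = 1000L, l_max = 400L,
                                epochs = 1L, model_cfg = NULL,
                                synth_cfg = NULL, params = scoring_params(),
                                verbose = TRUE) {
  if (is.null(synth_cfg))
    synth_cfg <- synth_config(n_coding = n_coding, n_noncoding = n_noncoding,
                              seed = seed)
  if (is.null(model_cfg)) model_cfg <- model_config(l_max = l_max)
  records <- generate_transcriptome(synth_cfg)
  split <- split_by_gene(records, 0.8, seed)
  part <- split$partition[match(records$gene_symbol, split$gene_symbol)]
  train_recs <- records[part == "train", ]
  held_recs <- records[part == "heldout", ]
  train_genes <- unique(train_recs$gene_symbol)
  val_genes <- withr::with_seed(seed, sample(train_genes,
                                             round(0.1 * length(train_genes))))
  va_recs <- train_recs[train_recs$gene_symbol %in% val_genes, ]
  tr_recs <- train_recs[!train_recs$gene_symbol %in% val_genes, ]
  model <- build_model(model_cfg, seed = seed)
  tr <- encode_transcripts(tr_recs, l_max)
  va <- encode_transcripts(va_recs, l_max)
  fit <- train_model(model, tr, va,
                     train_config(max_epochs = epochs, seed = seed),
                     verbose = verbose)
  result <- predict_transcripts(fit$model, held_recs, params = params)
  evaluation <- evaluate_predictions(result, held_recs)
  list(model = fit$model, fit = fit, records = records, heldout = held_recs,
       result = result, evaluation = evaluation, split = split)
}
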