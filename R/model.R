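# The dilated-residual sequence labeler: configuration, weight initialization,
# forward passes and probability decoding.  The numerics live in src/engine.cpp;
# this file owns all randomness (initial weights) and the user-facing surface.

#' Architecture configuration
#'
#' Defaults describe the full labeler: a 128-dimensional embedding (token 0 =
#' padding/N pinned to the zero vector), a local convolution (32 filters,
#' kernel 3), three stages of four pre-activation residual blocks with kernel
#' widths 26/26/36 and dilations 1/2/5, 1x1 channel expansions 32->64->128
#' between stages, and a 128->32->3 decoding head.
#'
#' @param vocab_size embedding vocabulary (5: pad/N, A, C, G, T).
#' @param embedding_dim embedding width.
#' @param local_channels,local_kernel the local feature-extraction conv.
#' @param stage_channels,blocks_per_stage,stage_kernels,stage_dilations
#'   per-stage residual trunk layout (equal lengths).
#' @param head_channels width of the intermediate decoding conv.
#' @param n_classes output classes (TIS, TTS, none).
#' @param l_max fixed input length the model is trained and evaluated at.
#' @return an `orf_model_config` list.
#' @export
model_config <- function(vocab_size = 5L, embedding_dim = 128L,
                         local_channels = 32L, local_kernel = 3L,
                         stage_channels = c(32L, 64L, 128L),
                         blocks_per_stage = c(4L, 4L, 4L),
                         stage_kernels = c(26L, 26L, 36L),
                         stage_dilations = c(1L, 2L, 5L),
                         head_channels = 32L, n_classes = 3L,
                         l_max = 27112L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              embedding_dim = as.integer(embedding_dim),
              local_channels = as.integer(local_channels),
              local_kernel = as.integer(local_kernel),
              stage_channels = as.integer(stage_channels),
              blocks_per_stage = as.integer(blocks_per_stage),
              stage_kernels = as.integer(stage_kernels),
              stage_dilations = as.integer(stage_dilations),
              head_channels = as.integer(head_channels),
              n_classes = as.integer(n_classes),
              l_max = as.integer(l_max))
  ns <- length(cfg$stage_channels)
  if (length(cfg$blocks_per_stage) != ns || length(cfg$stage_kernels) != ns ||
      length(cfg$stage_dilations) != ns)
    stop("stage_channels, blocks_per_stage, stage_kernels, stage_dilations must have equal length")
  if (any(unlist(cfg[c("vocab_size", "embedding_dim", "local_channels",
                       "local_kernel", "stage_channels", "blocks_per_stage",
                       "stage_kernels", "stage_dilations", "head_channels",
                       "n_classes", "l_max")]) < 1))
    stop("all architecture dimensions must be positive")
  structure(cfg, class = "orf_model_config")
}

# He-style initial weights, drawn from the R RNG so a single seed governs the
# whole run.  Conv weights are (c_out x c_in*K); BN starts at identity.  The
# output bias starts at the log class prior (TIS and TTS each cover 3 nt of a
# transcript, so ~1% of positions): starting from the base rate instead of
# uniform logits spares the optimizer the first phase of imbalance learning.
init_params <- function(config, seed) {
  shapes <- .nn_param_shapes(unclass(config))
  withr::with_seed(seed, {
    params <- lapply(names(shapes), function(nm) {
      d <- shapes[[nm]]
      if (nm == "emb") {
        m <- matrix(stats::rnorm(prod(d)), d[1], d[2])
        m[, 1] <- 0  # padding token
        m
      } else if (nm == "head2.b" && d[1] == 3) {
        matrix(log(c(0.01, 0.01, 0.98)), d[1], d[2])
      } else if (grepl("\\.W$", nm)) {
        matrix(stats::rnorm(prod(d), sd = sqrt(2 / d[2])), d[1], d[2])
      } else if (grepl("gamma$|run_var$", nm)) {
        matrix(1, d[1], d[2])
      } else {
        matrix(0, d[1], d[2])  # beta, biases, run_mean
      }
    })
    names(params) <- names(shapes)
    params
  })
}

#' Build a labeler with freshly initialized weights
#'
#' @param config from [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an `orf_model` handle.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "orf_model_config"))
  params <- init_params(config, seed)
  ptr <- .nn_create(unclass(config), params)
  structure(list(config = config, ptr = ptr, meta = list(seed = seed)),
            class = "orf_model")
}

#' @export
print.orf_model <- function(x, ...) {
  cfg <- x$config
  cat("<orf_model> dilated-residual TIS/TTS labeler\n")
  cat("  embedding:", cfg$embedding_dim, "dims over", cfg$vocab_size, "tokens\n")
  cat("  stages: channels", paste(cfg$stage_channels, collapse = "/"),
      " kernels", paste(cfg$stage_kernels, collapse = "/"),
      " dilations", paste(cfg$stage_dilations, collapse = "/"), "\n")
  cat("  receptive field:", receptive_field_span(cfg), "nt;  l_max:", cfg$l_max, "\n")
  invisible(x)
}

#' Extract the model state (weights and batch-norm running statistics)
#'
#' @param model an `orf_model`.
#' @return named list of matrices.
#' @export
model_state <- function(model) .nn_get_params(model$ptr)

#' Restore a model state produced by [model_state()]
#'
#' @param model an `orf_model`.
#' @param state named list of matrices.
#' @return the model, invisibly.
#' @export
set_model_state <- function(model, state) {
  .nn_set_params(model$ptr, state)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the weights, the architecture
#' configuration and training metadata.
#'
#' @param model an `orf_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly (save); an `orf_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model_state(model),
               meta = model$meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$config) || is.null(ck$params))
    stop("not a model checkpoint: ", path)
  ptr <- .nn_create(unclass(ck$config), ck$params)
  structure(list(config = ck$config, ptr = ptr, meta = ck$meta),
            class = "orf_model")
}

#' Forward pass: logits for a batch of encoded transcripts
#'
#' @param model an `orf_model`.
#' @param tokens integer matrix (length x batch), values in 0..4; all
#'   sequences must be padded to the same fixed length (normally
#'   `config$l_max`) because batch-norm statistics and boundary padding make
#'   outputs specific to the buffer length.
#' @param train logical; `TRUE` uses batch statistics and updates running
#'   batch-norm state (training only).  Evaluation mode (`FALSE`) is
#'   deterministic.
#' @return array (positions x 3 x batch) of logits.
#' @export
model_forward <- function(model, tokens, train = FALSE) {
  if (is.vector(tokens)) tokens <- matrix(as.integer(tokens), ncol = 1)
  storage.mode(tokens) <- "integer"
  out <- .nn_forward(model$ptr, tokens, train)
  aperm(array(out, dim = c(model$config$n_classes, nrow(tokens), ncol(tokens))),
        c(2, 1, 3))
}

#' Per-position class probabilities from logits
#'
#' Softmax over the three classes at every position; rows sum to 1.
#'
#' @param logits matrix (positions x 3) or array (positions x 3 x batch).
#' @return object of the same shape with columns `TIS`, `TTS`, `NONE`.
#' @export
to_probabilities <- function(logits) {
  softmax_rows <- function(m) {
    e <- exp(m - apply(m, 1, max))
    p <- e / rowSums(e)
    colnames(p) <- CLASS_LEVELS
    p
  }
  if (length(dim(logits)) == 3) {
    out <- logits
    for (b in seq_len(dim(logits)[3])) out[, , b] <- softmax_rows(logits[, , b])
    dimnames(out)[[2]] <- CLASS_LEVELS
    out
  } else {
    softmax_rows(as.matrix(logits))
  }
}

#' Predict per-position probabilities for transcript records
#'
#' Encodes, pads to the model's `l_max`, runs the network in evaluation mode
#' (in batches) and returns each transcript's probability track trimmed to
#' its own length.
#'
#' @param model an `orf_model`.
#' @param records transcript data.frame.
#' @param batch_size sequences per forward pass.
#' @return named list of (length x 3) probability matrices.
#' @export
predict_probs <- function(model, records, batch_size = 16L) {
  l_max <- model$config$l_max
  n <- nrow(records)
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1)
    toks <- vapply(idx, function(i) {
      enc <- encode_sequence(records$sequence[i])
      if (length(enc) >= l_max) enc[seq_len(l_max)] else c(enc, rep(0L, l_max - length(enc)))
    }, integer(l_max))
    logits <- model_forward(model, toks, train = FALSE)
    for (k in seq_along(idx)) {
      i <- idx[k]
      vl <- min(nchar(records$sequence[i]), l_max)
      out[[i]] <- to_probabilities(matrix(logits[seq_len(vl), , k],
                                          ncol = model$config$n_classes))
    }
  }
  names(out) <- records$transcript_id
  out
}

#' Raw argmax decoding of a probability track
#'
#' Assigns each position its maximum-probability class and reports maximal
#' runs of TIS and TTS positions.  Ties are broken conservatively: NONE wins
#' any tie it is part of, then TIS wins over TTS.
#'
#' @param probs (positions x 3) probability matrix (TIS, TTS, NONE).
#' @return list with `classes` (integer vector: 1 TIS, 2 TTS, 3 NONE) and
#'   data.frames `tis_runs`, `tts_runs` with 0-based `start` and `length`.
#' @export
raw_argmax_decode <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3)
  m <- pmax(probs[, 1], probs[, 2], probs[, 3])
  classes <- ifelse(probs[, 3] >= m, CLASS_NONE,
                    ifelse(probs[, 1] >= m, CLASS_TIS, CLASS_TTS))
  runs_of <- function(class) {
    r <- rle(classes == class)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep] - 1L, length = r$lengths[keep])
  }
  list(classes = as.integer(classes),
       tis_runs = runs_of(CLASS_TIS),
       tts_runs = runs_of(CLASS_TTS))
}

#' Receptive-field span of a configuration
#'
#' Total span (in nucleotides) of the output's dependence on the input:
#' 1 + sum over convolutions of dilation x (kernel - 1); each residual block
#' contributes two convolutions, 1x1 expansions contribute nothing.
#'
#' @param config an `orf_model_config` (or plain list with the same fields).
#' @return integer span in nucleotides.
#' @export
receptive_field_span <- function(config) {
  span <- 1L + 1L * (config$local_kernel - 1L)
  for (s in seq_along(config$stage_channels)) {
    span <- span + 2L * config$blocks_per_stage[s] *
      config$stage_dilations[s] * (config$stage_kernels[s] - 1L)
  }
  as.integer(span)
}
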