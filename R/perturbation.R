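# Sequence-perturbation harness: region-aware insertions, deletions and
# GC-preserving shuffles with truth-coordinate bookkeeping, plus a batch
# experiment runner that evaluates the raw model output per condition.

#' Region layout of a transcript
#'
#' Coding transcripts split into 5'UTR / CDS / 3'UTR from the annotation.
#' Noncoding transcripts, which have no real UTRs, use the convention:
#' first 5% "5'UTR-like", middle 90% "CDS-like", last 5% "3'UTR-like"
#' (floor rounding; the remainder accrues to the middle region).
#'
#' @param record one-row transcript data.frame or list.
#' @return data.frame with `region` (UTR5/CDS/UTR3), `start`, `end`
#'   (0-based half-open, tiling the transcript).
#' @export
define_regions <- function(record) {
  len <- nchar(record$sequence)
  if (record$biotype == "coding") {
    if (is.na(record$cds_start) || is.na(record$cds_end) ||
        record$cds_end <= record$cds_start)
      stop("coding record without a CDS: ", record$transcript_id)
    b <- c(0L, record$cds_start, record$cds_end, len)
  } else {
    k <- floor(0.05 * len)
    b <- c(0L, k, len - k, len)
  }
  data.frame(region = c("UTR5", "CDS", "UTR3"),
             start = as.integer(b[1:3]), end = as.integer(b[2:4]),
             stringsAsFactors = FALSE)
}

# deterministic per-transcript stream: condition seed + transcript id hash
transcript_seed <- function(seed, transcript_id) {
  h <- 0
  for (c in utf8ToInt(transcript_id)) h <- (h * 31 + c) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

# shift a truth boundary for an edit: insertion of `size` at `pos` shifts
# boundaries >= pos; deletion of [pos, pos+size) shifts boundaries >= pos+size
# and clamps boundaries inside the deleted span to pos.
shift_boundary <- function(b, pos, size, op) {
  if (is.na(b)) return(b)
  if (op == "insert") {
    if (b >= pos) b + size else b
  } else {
    if (b >= pos + size) b - size
    else if (b > pos) pos
    else b
  }
}

#' Apply a random insertion or deletion within a region
#'
#' The edit position is uniform within the region and inserted bases are
#' uniform over A,C,G,T, both drawn from a stream derived from the seed and
#' the transcript id (reproducible, independent across transcripts).  Truth
#' CDS boundaries downstream of the edit are shifted by the net length
#' change; after a frameshifting CDS indel the shifted stop-codon span is
#' deliberately kept as measurement truth even though it no longer reads as
#' a stop codon.
#'
#' @param record one-row transcript data.frame or list.
#' @param region "UTR5", "CDS" or "UTR3".
#' @param op "insert" or "delete".
#' @param size edit size in nt (1, 2 or 3).
#' @param seed condition seed.
#' @return the perturbed record (list) with shifted `cds_start`/`cds_end`.
#' @export
apply_indel <- function(record, region, op = c("insert", "delete"),
                        size = 1L, seed = 1L) {
  op <- match.arg(op)
  stopifnot(size >= 1)
  regions <- define_regions(record)
  r <- regions[regions$region == region, ]
  if (nrow(r) != 1) stop("unknown region: ", region)
  rlen <- r$end - r$start
  if (op == "delete" && rlen < size)
    stop("region ", region, " of ", record$transcript_id,
         " too small for a ", size, "-nt deletion")
  if (op == "insert" && rlen < 1)
    stop("region ", region, " of ", record$transcript_id, " is empty")
  out <- as.list(record)[c("transcript_id", "gene_symbol", "biotype",
                           "cds_start", "cds_end", "sequence")]
  withr::with_seed(transcript_seed(seed, record$transcript_id), {
    if (op == "insert") {
      pos <- r$start + sample.int(rlen, 1) - 1L  # insert before this index
      bases <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                     collapse = "")
      out$sequence <- paste0(substr(record$sequence, 1, pos),
                             bases,
                             substr(record$sequence, pos + 1, nchar(record$sequence)))
    } else {
      pos <- r$start + sample.int(rlen - size + 1L, 1) - 1L
      out$sequence <- paste0(substr(record$sequence, 1, pos),
                             substr(record$sequence, pos + size + 1,
                                    nchar(record$sequence)))
    }
  })
  out$cds_start <- shift_boundary(record$cds_start, pos, size, op)
  out$cds_end <- shift_boundary(record$cds_end, pos, size, op)
  out
}

#' Shuffle a region in place (GC-preserving)
#'
#' Uniform random permutation of the region's nucleotides; the base multiset
#' (hence GC content) and all truth coordinates are unchanged.  Regions
#' shorter than 2 nt are returned unchanged with a warning.
#'
#' @param record one-row transcript data.frame or list.
#' @param region "UTR5", "CDS" or "UTR3".
#' @param seed condition seed.
#' @return the perturbed record (list).
#' @export
shuffle_region <- function(record, region, seed = 1L) {
  regions <- define_regions(record)
  r <- regions[regions$region == region, ]
  if (nrow(r) != 1) stop("unknown region: ", region)
  out <- as.list(record)[c("transcript_id", "gene_symbol", "biotype",
                           "cds_start", "cds_end", "sequence")]
  rlen <- r$end - r$start
  if (rlen < 2) {
    warning("region ", region, " of ", record$transcript_id,
            " shorter than 2 nt; left unchanged")
    return(out)
  }
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  idx <- (r$start + 1):r$end
  withr::with_seed(transcript_seed(seed, record$transcript_id), {
    chars[idx] <- chars[sample(idx)]
  })
  out$sequence <- paste(chars, collapse = "")
  out
}

#' Run a batch of perturbation conditions against raw model output
#'
#' For every condition each eligible record is perturbed, the model is run
#' in evaluation mode, the raw argmax decoding is classified against the
#' (shifted) truth, and the outcomes are summarized.  The identity condition
#' reproduces the unperturbed baseline exactly.  Evaluation deliberately
#' bypasses the integrated scorer so the conditions probe what the network
#' itself has learned.
#'
#' @param records transcript data.frame.
#' @param model an `orf_model`.
#' @param conditions data.frame with columns `condition` (id), `region`,
#'   `operation` ("identity", "insert", "delete", "shuffle"), `size`
#'   (NA except for indels) and `seed`.
#' @param batch_size forward-pass batch size.
#' @return list with `summary` (one row per condition: n, per-category
#'   percentages, perfect/correct-noncoding rates) and `outcomes`
#'   (per-transcript categories per condition).
#' @export
run_perturbation_experiment <- function(records, model, conditions,
                                        batch_size = 16L) {
  rows <- list()
  outcome_list <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    perturbed <- vector("list", nrow(records))
    keep <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
      rec <- records[i, ]
      p <- tryCatch(
        switch(cond$operation,
               identity = as.list(rec),
               insert = apply_indel(rec, cond$region, "insert", cond$size, cond$seed),
               delete = apply_indel(rec, cond$region, "delete", cond$size, cond$seed),
               shuffle = shuffle_region(rec, cond$region, cond$seed),
               stop("unknown operation: ", cond$operation)),
        error = function(e) NULL)
      if (!is.null(p)) {
        perturbed[[i]] <- p
        keep[i] <- TRUE
      }
    }
    perturbed <- perturbed[keep]
    if (length(perturbed) == 0) next
    pert_df <- do.call(rbind, lapply(perturbed, function(p)
      data.frame(p[c("transcript_id", "gene_symbol", "biotype",
                     "cds_start", "cds_end", "sequence")],
                 stringsAsFactors = FALSE)))
    probs <- predict_probs(model, pert_df, batch_size = batch_size)
    outcomes <- vapply(seq_along(probs), function(i) {
      dec <- raw_argmax_decode(probs[[i]])
      classify_orf_outcome(dec, perturbed[[i]])
    }, character(1))
    # single-biotype condition sets legitimately lack one truth class; the
    # summary's balanced accuracy is unused here
    s <- suppressWarnings(summarize_outcomes(outcomes, pert_df$biotype))
    frac <- function(cat, bio) {
      sel <- s$by_class$biotype == bio & s$by_class$category == cat
      if (any(sel)) sum(s$by_class$percent[sel]) else NA_real_
    }
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond$condition, n = length(outcomes),
      perfect_pct = frac("PERFECT", "coding"),
      near_perfect_pct = frac("NEAR_PERFECT", "coding"),
      correct_noncoding_pct = frac("CORRECT_NONCODING", "noncoding"),
      false_orf_pct = frac("FALSE_ORF", "noncoding"),
      stringsAsFactors = FALSE)
    outcome_list[[as.character(cond$condition)]] <-
      data.frame(transcript_id = pert_df$transcript_id, outcome = outcomes,
                 stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, rows), outcomes = outcome_list)
}

#' Build a standard indel/shuffle condition table
#'
#' Identity baseline, 1-3 nt insertions and deletions per region, and
#' region shuffles.
#'
#' @param regions regions to perturb (default CDS and both UTRs).
#' @param sizes indel sizes.
#' @param seed condition seed recorded for every row.
#' @param shuffles include shuffle conditions.
#' @return condition data.frame for [run_perturbation_experiment()].
#' @export
standard_conditions <- function(regions = c("UTR5", "CDS", "UTR3"),
                                sizes = 1:3, seed = 1L, shuffles = TRUE) {
  rows <- data.frame(condition = "identity", region = NA_character_,
                     operation = "identity", size = NA_integer_, seed = seed,
                     stringsAsFactors = FALSE)
  for (r in regions) {
    for (op in c("insert", "delete"))
      for (s in sizes)
        rows <- rbind(rows, data.frame(
          condition = paste0(r, "_", op, "_", s), region = r, operation = op,
          size = s, seed = seed, stringsAsFactors = FALSE))
    if (shuffles)
      rows <- rbind(rows, data.frame(
        condition = paste0(r, "_shuffle"), region = r, operation = "shuffle",
        size = NA_integer_, seed = seed, stringsAsFactors = FALSE))
  }
  rows
}
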