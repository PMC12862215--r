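# Synthetic transcriptome generator.  Coding transcripts carry the signals
# the labeler is meant to learn: a Kozak-context ATG, a codon-usage-biased
# in-frame CDS ending at the first in-frame stop, flanked by UTRs; noncoding
# transcripts are background sequence guaranteed to lack long spurious ORFs.
# Genes group one to three isoforms so the gene-level split is exercised.

#' Synthetic transcriptome configuration
#'
#' Defaults emulate compact mRNA-like transcripts: 10-50 nt 5'UTRs, CDSs of
#' 30-90 codons (including start and stop), 10-70 nt 3'UTRs, a strong Kozak
#' context (each context base drawn from the PWM with probability 0.9),
#' human-like codon usage bias, and 50% background GC.  Noncoding
#' transcripts are resampled until they contain no ORF of 30 or more codons.
#'
#' @param n_coding,n_noncoding transcript counts.
#' @param isoforms_per_gene integer vector of possible isoform counts,
#'   sampled uniformly per gene.
#' @param utr5_len,cds_codons,utr3_len inclusive sampling ranges
#'   (`c(min, max)`); `cds_codons` counts codons including start and stop.
#' @param kozak_strength probability that each Kozak context base is drawn
#'   from the PWM rather than uniformly.
#' @param codon_usage codon frequency vector driving CDS codon sampling.
#' @param codon_bias_power exponent applied to the usage frequencies before
#'   sampling CDS codons (default 2: the sharpened preference typical of
#'   highly expressed genes; 1 reproduces bulk usage literally).
#' @param background_gc GC fraction of background (UTR/noncoding) sequence.
#' @param min_spurious_orf codon count at or above which a noncoding
#'   transcript is rejected and resampled.
#' @param noncoding_len length range of noncoding transcripts.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an `orf_synth_config` list.
#' @export
synth_config <- function(n_coding = 100L, n_noncoding = 100L,
                         isoforms_per_gene = 1:3,
                         utr5_len = c(10L, 50L), cds_codons = c(30L, 90L),
                         utr3_len = c(10L, 70L), kozak_strength = 0.9,
                         codon_usage = codon_usage_human(),
                         codon_bias_power = 2,
                         background_gc = 0.5, min_spurious_orf = 30L,
                         noncoding_len = c(110L, 390L), seed = 1L) {
  stopifnot(n_coding >= 0, n_noncoding >= 0, min_spurious_orf >= 1,
            kozak_strength >= 0, kozak_strength <= 1,
            background_gc > 0, background_gc < 1,
            utr5_len[1] <= utr5_len[2], cds_codons[1] <= cds_codons[2],
            utr3_len[1] <= utr3_len[2], cds_codons[1] >= 2)
  structure(list(n_coding = as.integer(n_coding),
                 n_noncoding = as.integer(n_noncoding),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 utr5_len = as.integer(utr5_len),
                 cds_codons = as.integer(cds_codons),
                 utr3_len = as.integer(utr3_len),
                 kozak_strength = kozak_strength,
                 codon_usage = codon_usage,
                 codon_bias_power = codon_bias_power,
                 background_gc = background_gc,
                 min_spurious_orf = as.integer(min_spurious_orf),
                 noncoding_len = as.integer(noncoding_len),
                 seed = as.integer(seed)),
            class = "orf_synth_config")
}

# background bases at a given GC fraction
sample_background <- function(n, gc) {
  if (n == 0) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1]
  else sample(range[1]:range[2], 1)
}

# brute-force longest ORF (in codons, start through first in-frame stop) —
# the rejection oracle for noncoding sequences
longest_orf_codons <- function(sequence) {
  cand <- enumerate_candidates(sequence,
                               matrix(1 / 3, nchar(sequence), 3),
                               scoring_params(tis_floor = 0, tts_floor = 0))
  if (nrow(cand) == 0) return(0L)
  max((cand$tts_start + 3L - cand$tis_start) %/% 3L)
}

#' Sample one coding transcript
#'
#' Layout: 5'UTR + ATG + codon-biased sense codons (no in-frame stop) + stop
#' codon + 3'UTR.  The 10-nt Kozak window (positions -6..+3 around the ATG)
#' is drawn base-by-base from the Kozak PWM with probability
#' `kozak_strength`, otherwise uniformly; the +3 base is redrawn if it would
#' turn the second codon into a stop.
#'
#' Uses the current RNG state; seed via the caller (see
#' [generate_transcriptome()]).
#'
#' @param config an `orf_synth_config`.
#' @param transcript_id,gene_symbol identifiers for the record.
#' @return record list with exact CDS annotation.
#' @export
sample_coding_transcript <- function(config, transcript_id = "SYNT1",
                                     gene_symbol = "SYNG1") {
  pwm <- kozak_pwm()
  usage <- config$codon_usage
  sense <- names(usage)[!names(usage) %in% STOP_CODONS]
  power <- if (is.null(config$codon_bias_power)) 1 else config$codon_bias_power
  sense_p <- usage[sense]^power
  sense_p <- sense_p / sum(sense_p)
  utr5_n <- sample_range(config$utr5_len)
  n_codons <- sample_range(config$cds_codons)
  utr3_n <- sample_range(config$utr3_len)
  utr5 <- sample_background(utr5_n, config$background_gc)
  utr3 <- sample_background(utr3_n, config$background_gc)
  body <- sample(sense, n_codons - 2L, replace = TRUE, prob = sense_p)
  stop_codon <- sample(STOP_CODONS, 1)
  # overwrite the Kozak window: -6..-1 in the 5'UTR, +3 = first base of codon 2
  draw_ctx <- function(rel) {
    if (runif(1) < config$kozak_strength)
      sample(colnames(pwm), 1, prob = pwm[as.character(rel), ])
    else sample(c("A", "C", "G", "T"), 1)
  }
  for (rel in -6:-1) {
    idx <- utr5_n + rel + 1L  # 1-based index into utr5
    if (idx >= 1) utr5[idx] <- draw_ctx(rel)
  }
  if (length(body) >= 1) {
    repeat {
      first <- draw_ctx(3)
      cand <- paste0(first, substr(body[1], 2, 3))
      if (!cand %in% STOP_CODONS) {
        body[1] <- cand
        break
      }
    }
  }
  cds <- paste0("ATG", paste(body, collapse = ""), stop_codon)
  sequence <- paste0(paste(utr5, collapse = ""), cds, paste(utr3, collapse = ""))
  list(transcript_id = transcript_id, gene_symbol = gene_symbol,
       biotype = "coding", cds_start = utr5_n,
       cds_end = utr5_n + 3L * n_codons, sequence = sequence)
}

#' Sample one noncoding transcript
#'
#' I.i.d. background bases at `background_gc`, rejected and resampled until
#' no ATG-initiated, stop-terminated ORF of `min_spurious_orf` or more
#' codons remains.
#'
#' @inheritParams sample_coding_transcript
#' @param max_tries rejection limit before erroring.
#' @return record list (no CDS).
#' @export
sample_noncoding_transcript <- function(config, transcript_id = "SYNT1",
                                        gene_symbol = "SYNG1",
                                        max_tries = 1000L) {
  len <- sample_range(config$noncoding_len)
  for (try in seq_len(max_tries)) {
    sequence <- paste(sample_background(len, config$background_gc),
                      collapse = "")
    if (longest_orf_codons(sequence) < config$min_spurious_orf)
      return(list(transcript_id = transcript_id, gene_symbol = gene_symbol,
                  biotype = "noncoding", cds_start = NA_integer_,
                  cds_end = NA_integer_, sequence = sequence))
  }
  stop("rejection sampling failed after ", max_tries,
       " tries; lower min_spurious_orf or the transcript length")
}

#' Generate a synthetic transcriptome
#'
#' Draws `n_coding` + `n_noncoding` transcripts grouped into genes with
#' 1-3 isoforms each (coding and noncoding genes are disjoint).  Fully
#' deterministic given the config seed.
#'
#' @param config an `orf_synth_config`.
#' @return transcript data.frame (see [read_annotation_table()]).
#' @export
generate_transcriptome <- function(config) {
  withr::with_seed(config$seed, {
    recs <- list()
    make_group <- function(n_total, biotype, prefix) {
      made <- 0L
      gene_i <- 0L
      while (made < n_total) {
        gene_i <- gene_i + 1L
        iso <- config$isoforms_per_gene
        k <- if (length(iso) == 1) iso else sample(iso, 1)
        k <- min(k, n_total - made)
        gene <- sprintf("%sG%05d", prefix, gene_i)
        for (j in seq_len(k)) {
          made <- made + 1L
          tid <- sprintf("%sT%06d", prefix, made)
          rec <- if (biotype == "coding")
            sample_coding_transcript(config, tid, gene)
          else
            sample_noncoding_transcript(config, tid, gene)
          recs[[length(recs) + 1L]] <<- rec
        }
      }
    }
    make_group(config$n_coding, "coding", "SYNC")
    make_group(config$n_noncoding, "noncoding", "SYNN")
    do.call(rbind, lapply(recs, function(r)
      data.frame(r, stringsAsFactors = FALSE)))
  })
}
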