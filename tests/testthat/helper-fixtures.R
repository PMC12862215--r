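# Shared fixtures: tiny architectures, small synthetic sets, brute-force
# oracles kept independent of the implementation paths they check.

tiny_model_config <- function(l_max = 60L) {
  model_config(embedding_dim = 8L, local_channels = 4L,
               stage_channels = c(4L, 6L, 8L), blocks_per_stage = c(1L, 1L, 1L),
               stage_kernels = c(3L, 3L, 5L), stage_dilations = c(1L, 2L, 3L),
               head_channels = 4L, l_max = l_max)
}

small_model_config <- function(l_max = 200L) {
  model_config(embedding_dim = 32L, local_channels = 16L,
               stage_channels = c(16L, 24L, 32L), blocks_per_stage = c(2L, 2L, 2L),
               stage_kernels = c(9L, 9L, 11L), stage_dilations = c(1L, 2L, 5L),
               head_channels = 16L, l_max = l_max)
}

small_synth_config <- function(n_coding = 40L, n_noncoding = 40L, seed = 1L) {
  synth_config(n_coding = n_coding, n_noncoding = n_noncoding,
               utr5_len = c(8L, 20L), cds_codons = c(15L, 40L),
               utr3_len = c(8L, 30L), noncoding_len = c(60L, 190L),
               seed = seed)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# independent brute-force ORF scan: every ATG paired with its first in-frame
# stop, found by walking codon by codon
brute_force_orfs <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  for (i in seq_len(max(0, n - 2))) {
    if (paste(chars[i:(i + 2)], collapse = "") != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      codon <- paste(chars[j:(j + 2)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        out[[length(out) + 1]] <- c(tis_start = i - 1L, tts_start = j - 1L)
        break
      }
      j <- j + 3
    }
  }
  if (length(out) == 0)
    return(data.frame(tis_start = integer(0), tts_start = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$tis_start, df$tts_start), , drop = FALSE]
}

uniform_probs <- function(n) matrix(1 / 3, nrow = n, ncol = 3,
                                    dimnames = list(NULL, c("TIS", "TTS", "NONE")))

# probability track fixture mirroring the published per-position rows
published_probability_rows <- function() {
  read.delim(system.file("extdata", "nm_probability_rows.tsv",
                         package = "orfcall"))
}
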