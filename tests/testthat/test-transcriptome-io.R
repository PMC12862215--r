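test_that("FASTA reading normalizes ids, case and U/T and rejects bad alphabets", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">NM_000001.2 some description", "acgu", ">NR_9.1", "NNAT"), f)
  seqs <- read_transcript_fasta(f)
  expect_identical(names(seqs), c("NM_000001", "NR_9"))
  expect_identical(unname(seqs), c("ACGT", "NNAT"))

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(read_transcript_fasta(empty), 0)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGT", ">t2", "ACXT"), bad)
  expect_error(read_transcript_fasta(bad), "t2")
})

test_that("annotation tables join, validate and drop out-of-frame CDS", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_symbol\tbiotype\tcds_start\tcds_end",
               "t1\tG1\tcoding\t3\t12",
               "t2\tG1\tnoncoding\t\t",
               "t3\tG2\tcoding\t0\t10"), f)
  seqs <- c(t1 = strrep("A", 20), t2 = strrep("C", 10), t3 = strrep("G", 15))
  expect_warning(recs <- read_annotation_table(f, seqs), "multiple of 3")
  expect_identical(recs$transcript_id, c("t1", "t2"))
  expect_equal(recs$cds_end[1] - recs$cds_start[1], 9)
  expect_true(is.na(recs$cds_start[2]))

  # transcript absent from FASTA
  expect_error(read_annotation_table(f, seqs[c("t1", "t2")]), "t3")

  # duplicate id
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_symbol\tbiotype\tcds_start\tcds_end",
               "t1\tG1\tcoding\t3\t12", "t1\tG1\tcoding\t3\t12"), dup)
  expect_error(read_annotation_table(dup, seqs), "duplicate")
})

test_that("integer encoding maps A,C,G,T,N to 1,2,3,4,0 and round-trips", {
  expect_identical(encode_sequence("ACGTN"), c(1L, 2L, 3L, 4L, 0L))
  expect_identical(encode_sequence(""), integer(0))
  expect_identical(encode_sequence("TTTT"), c(4L, 4L, 4L, 4L))
  expect_error(encode_sequence("ACGX"), "X")

  withr::with_seed(5, {
    for (i in 1:20) {
      s <- random_dna(sample(1:80, 1))
      expect_identical(decode_sequence(encode_sequence(s)), s)
    }
  })
  # N and padding collide at token 0 by design
  expect_identical(encode_sequence("N"), 0L)
  expect_identical(decode_sequence(0L), "N")
})

test_that("label encoding marks full start and stop codons", {
  rec <- list(sequence = strrep("A", 12), biotype = "coding",
              cds_start = 3L, cds_end = 12L)
  lab <- encode_labels(rec)
  expect_identical(which(lab == 1L), 4:6)    # TIS at 0-based 3,4,5
  expect_identical(which(lab == 2L), 10:12)  # TTS at 0-based 9,10,11
  expect_true(all(lab[c(1:3, 7:9)] == 3L))

  expect_true(all(encode_labels(list(sequence = "ACGTA",
                                     biotype = "noncoding")) == 3L))

  edge <- list(sequence = strrep("A", 9), biotype = "coding",
               cds_start = 0L, cds_end = 9L)
  expect_identical(which(encode_labels(edge) == 1L), 1:3)
})

test_that("pad_or_truncate pads with 0/NONE, truncates the 3' end, idempotent", {
  tk <- encode_sequence("ACGTA")
  lb <- rep(3L, 5)
  p <- pad_or_truncate(tk, lb, 8L)
  expect_identical(p$tokens, c(tk, 0L, 0L, 0L))
  expect_identical(p$labels, c(lb, 3L, 3L, 3L))
  expect_equal(p$valid_length, 5)

  long <- pad_or_truncate(rep(1L, 10), rep(3L, 10), 8L)
  expect_length(long$tokens, 8)
  expect_equal(long$valid_length, 8)

  # idempotent on content; valid_length saturates because padding and N share
  # token 0 and cannot be told apart afterwards
  same <- pad_or_truncate(p$tokens, p$labels, 8L)
  expect_identical(same$tokens, p$tokens)
  expect_identical(same$labels, p$labels)
  expect_equal(same$valid_length, 8)
})

test_that("encoded samples place TIS/TTS runs at the annotated codons", {
  withr::with_seed(11, {
    cfg <- small_synth_config(10, 0)
    recs <- generate_transcriptome(cfg)
    enc <- encode_transcripts(recs, 200L)
    for (i in seq_len(nrow(enc$records))) {
      lab <- enc$labels[, i]
      rec <- enc$records[i, ]
      expect_identical(which(lab == 1L) - 1L, rec$cds_start + 0:2)
      expect_identical(which(lab == 2L) - 1L, rec$cds_end - 3L + 0:2)
      expect_true(all(is.na(lab[(enc$valid_length[i] + 1):200])))
    }
  })
})

test_that("coding transcripts with the stop beyond l_max are excluded", {
  recs <- data.frame(
    transcript_id = c("a", "b"), gene_symbol = c("G1", "G2"),
    biotype = "coding", cds_start = c(0L, 0L), cds_end = c(9L, 60L),
    sequence = c(paste0("ATG", strrep("C", 3), "TAA"),
                 paste0("ATG", strrep("C", 54), "TAA")),
    stringsAsFactors = FALSE)
  recs$sequence[1] <- paste0("ATGCCC", "TAA")
  expect_message(enc <- encode_transcripts(recs, 30L), "excluded")
  expect_identical(enc$records$transcript_id, "a")
  expect_equal(enc$n_excluded, 1)
})

test_that("gene-level split is exclusive, deterministic and proportional", {
  recs <- data.frame(
    transcript_id = paste0("t", 1:3), gene_symbol = c("G1", "G1", "G2"),
    biotype = "noncoding", cds_start = NA_integer_, cds_end = NA_integer_,
    sequence = "ACGT", stringsAsFactors = FALSE)
  sp <- split_by_gene(recs, 0.5, seed = 3)
  part <- sp$partition[match(recs$gene_symbol, sp$gene_symbol)]
  expect_length(unique(part[1:2]), 1)  # isoforms co-assigned

  one <- split_by_gene(recs[3, ], 0.5, seed = 1)
  expect_identical(one$partition, "train")

  big <- data.frame(transcript_id = paste0("t", 1:100),
                    gene_symbol = paste0("G", 1:100), biotype = "noncoding",
                    cds_start = NA_integer_, cds_end = NA_integer_,
                    sequence = "ACGT", stringsAsFactors = FALSE)
  s1 <- split_by_gene(big, 0.8, seed = 9)
  s2 <- split_by_gene(big, 0.8, seed = 9)
  expect_identical(s1, s2)
  expect_equal(sum(s1$partition == "train"), 80)
})

test_that("isoform partitions form a singleton set across random splits", {
  withr::with_seed(21, {
    recs <- generate_transcriptome(small_synth_config(30, 30, seed = 4))
    for (seed in 1:10) {
      sp <- split_by_gene(recs, 0.8, seed = seed)
      part <- sp$partition[match(recs$gene_symbol, sp$gene_symbol)]
      per_gene <- tapply(part, recs$gene_symbol, function(x) length(unique(x)))
      expect_true(all(per_gene == 1))
    }
  })
})

test_that("minimal GenBank CDS extraction converts to half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       NM_TEST1    24 bp mRNA",
    "VERSION     NM_TEST1.2",
    "FEATURES             Location/Qualifiers",
    "     CDS             4..15",
    "                     /gene=\"DEMO\"",
    "ORIGIN",
    "        1 acgatggcca aatagacgta cgta",
    "//",
    "LOCUS       NR_TEST2    12 bp RNA",
    "VERSION     NR_TEST2.1",
    "ORIGIN",
    "        1 acgtacgtac gt",
    "//"), f)
  recs <- read_genbank_cds(f)
  expect_identical(recs$transcript_id, c("NM_TEST1", "NR_TEST2"))
  expect_equal(recs$cds_start[1], 3)  # 1-based 4 -> 0-based 3
  expect_equal(recs$cds_end[1], 15)
  expect_identical(recs$biotype, c("coding", "noncoding"))
  expect_identical(recs$gene_symbol[1], "DEMO")
  expect_equal(nchar(recs$sequence[1]), 24)
})

test_that("length percentile helper reproduces the padding-length convention", {
  lengths <- 1:1000
  expect_equal(length_percentile(lengths, 0.999), 1000)
  expect_equal(length_percentile(lengths, 0.5), 501)
})
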