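test_that("the Kozak PWM rows sum to one and the degenerate core is fixed", {
  pwm <- kozak_pwm()
  expect_equal(unname(rowSums(pwm)), rep(1, 10))
  expect_equal(unname(pwm["0", ]), c(1, 0, 0, 0))
  expect_equal(unname(pwm["1", ]), c(0, 0, 0, 1))
  expect_equal(unname(pwm["2", ]), c(0, 0, 1, 0))
})

test_that("Kozak scoring reproduces hand-multiplied products", {
  # per-position argmax context GCCGCC|ATG|G
  s <- paste0("GCCGCC", "ATG", "G")
  ks <- kozak_score(s, 6L)
  expect_equal(ks$raw, 0.32 * 0.30 * 0.32 * 0.45 * 0.35 * 0.35 * 0.40 * 10000)
  expect_equal(ks$raw, 6.77376)
  expect_equal(ks$norm, 1.0)

  # all-T context
  st <- paste0("TTTTTT", "ATG", "T")
  expect_equal(kozak_score(st, 6L)$raw,
               0.18 * 0.20 * 0.20 * 0.15 * 0.20 * 0.20 * 0.20 * 10000)
  expect_equal(kozak_score(st, 6L)$raw, 0.0864, tolerance = 1e-12)

  # ATG at the 5' end: all six flank factors are 0.25 and cancel in the norm
  edge <- kozak_score("ATGG", 0L)
  expect_equal(edge$raw, 0.25^6 * 0.40 * 10000)
  expect_equal(edge$norm, 1.0)

  expect_error(kozak_score("AAAA", 0L), "ATG")
})

test_that("normalized Kozak lies in [0,1] and is 1 only at the argmax context", {
  withr::with_seed(15, {
    for (i in 1:50) {
      s <- paste0(random_dna(6), "ATG", random_dna(3))
      ks <- kozak_score(s, 6L)
      expect_true(ks$norm >= 0 && ks$norm <= 1)
      ctx <- strsplit(s, "")[[1]][c(1:6, 10)]
      argmax <- c("G", "C", "C", "G", "C", "C", "G")
      expect_equal(ks$norm == 1, all(ctx == argmax))
    }
  })
})

test_that("CAI is the geometric mean of relative adaptiveness values", {
  w <- c(AAA = 1, AAG = 0.25, GCT = 1)
  expect_equal(cai_score("AAAGCT", w), 1.0)
  expect_equal(cai_score("AAGAAA", w), 0.5)
  expect_equal(cai_score("AAG", c(AAG = 0.7)), 0.7)
  expect_error(cai_score("AAAG", w), "multiple of 3")
  expect_error(cai_score("TTT", w), "absent")

  # default table: every synonymous family's maximum is 1, stops excluded
  def <- codon_weights()
  expect_length(def, 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(def)))
  fam <- split(def, Biostrings::GENETIC_CODE[names(def)])
  expect_true(all(vapply(fam, max, numeric(1)) == 1))
})

test_that("GC score is the printed Gaussian: peak at 0.42, symmetric", {
  # 42% GC exactly -> 1
  s42 <- paste0(strrep("G", 42), strrep("A", 58))
  expect_equal(gc_score(s42), 1.0)
  # one sigma away -> 2 e^{-1/2} - 1
  s64 <- paste0(strrep("G", 64), strrep("A", 36))
  expect_equal(gc_score(s64), 2 * exp(-0.5) - 1)
  expect_equal(gc_score(s64), 0.21306, tolerance = 1e-4)
  s20 <- paste0(strrep("G", 20), strrep("A", 80))
  expect_equal(gc_score(s20), gc_score(s64))
  expect_error(gc_score(""), "empty")

  # symmetry about the mean at arbitrary offsets
  for (d in c(0.05, 0.1, 0.3)) {
    up <- round(100 * (0.42 + d))
    dn <- round(100 * (0.42 - d))
    expect_equal(gc_score(paste0(strrep("C", up), strrep("T", 100 - up))),
                 gc_score(paste0(strrep("C", dn), strrep("T", 100 - dn))))
  }
})

test_that("codon-level probabilities average the three nucleotide values", {
  p <- uniform_probs(10)
  p[4:6, 1] <- c(0.9, 0.6, 0.3)
  expect_equal(codon_signal_probability(p, 3L, "TIS"), 0.6)
  expect_equal(codon_signal_probability(uniform_probs(6), 0L, "TTS"), 1 / 3)
  expect_error(codon_signal_probability(p, 8L, "TIS"), "outside")

  # published rows: positions 30-32 aggregate to 4.787e-02
  rows <- published_probability_rows()
  track <- matrix(0, 219, 3)
  track[rows$pos + 1, ] <- as.matrix(rows[, c("p_tis", "p_tts", "p_none")])
  expect_equal(codon_signal_probability(track, 30L, "TIS"), 4.787e-02,
               tolerance = 1e-4)
  expect_equal(codon_signal_probability(track, 216L, "TTS"),
               mean(c(1.334e-01, 9.223e-02, 1.171e-01)))
})

test_that("candidate enumeration finds ATG/first-in-frame-stop pairs", {
  zero <- scoring_params(tis_floor = 0, tts_floor = 0)
  s1 <- "AAATGGCCTAAGG"
  c1 <- enumerate_candidates(s1, uniform_probs(nchar(s1)), zero)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$tis_start, 2L)
  expect_equal(c1$tts_start, 8L)

  s2 <- "ATGATGTAA"
  c2 <- enumerate_candidates(s2, uniform_probs(9), zero)
  expect_equal(c2$tis_start, c(0L, 3L))
  expect_equal(c2$tts_start, c(6L, 6L))

  expect_equal(nrow(enumerate_candidates("CCCCCC", uniform_probs(6), zero)), 0)

  # floors prune weak-signal candidates
  p <- uniform_probs(nchar(s1))
  p[, 1] <- 1e-5
  floored <- enumerate_candidates(s1, p, scoring_params())
  expect_equal(nrow(floored), 0)
})

test_that("enumeration equals the brute-force scan on random sequences", {
  zero <- scoring_params(tis_floor = 0, tts_floor = 0)
  withr::with_seed(16, {
    for (i in 1:120) {
      s <- random_dna(sample(20:300, 1), gc = runif(1, 0.3, 0.7))
      fast <- enumerate_candidates(s, uniform_probs(nchar(s)), zero)
      slow <- brute_force_orfs(s)
      expect_equal(fast$tis_start, slow$tis_start)
      expect_equal(fast$tts_start, slow$tts_start)
    }
  })
})

test_that("integrated score is the printed weighted sum", {
  p <- scoring_params()
  expect_equal(integrated_score(1, 1, 1, 1, 1, p), 0.88)
  expect_equal(integrated_score(0, 0, 0, 0, 0, p), 0)
  expect_equal(integrated_score(0.9, 0.8, 0.5, 0.5, 0.123, p), 0.71)
  # monotone in every positively weighted component
  expect_gt(integrated_score(0.95, 0.8, 0.5, 0.5, 0, p),
            integrated_score(0.9, 0.8, 0.5, 0.5, 0, p))
  expect_gt(integrated_score(0.9, 0.8, 0.9, 0.5, 0, p),
            integrated_score(0.9, 0.8, 0.5, 0.5, 0, p))
  # GC has zero weight in the published optimum
  expect_equal(integrated_score(0.9, 0.8, 0.5, 0.5, -0.9, p),
               integrated_score(0.9, 0.8, 0.5, 0.5, 0.9, p))
})

test_that("ORF selection thresholds and tie-breaks deterministically", {
  cand <- data.frame(tis_start = c(10L, 2L, 2L), tts_start = c(40L, 32L, 20L),
                     integrated_score = c(0.70, 0.70, 0.5))
  p <- scoring_params()
  sel <- select_orf(cand, p)
  expect_equal(sel$decision, "coding")
  expect_equal(sel$orf$tis_start, 2L)  # tie: smaller tis_start wins
  expect_equal(sel$orf$tts_start, 32L)

  # order invariance
  perm <- cand[c(3, 1, 2), ]
  expect_equal(select_orf(perm, p)$orf$tis_start, 2L)

  low <- cand
  low$integrated_score <- c(0.2, 0.3, 0.1)
  expect_equal(select_orf(low, p)$decision, "noncoding")
  expect_equal(select_orf(cand[0, ], p)$decision, "noncoding")
})

test_that("scored candidates on a planted transcript rank the true ORF first", {
  withr::with_seed(17, {
    rec <- sample_coding_transcript(synth_config(seed = 1))
  })
  n <- nchar(rec$sequence)
  probs <- uniform_probs(n)
  probs[, ] <- c(0.01, 0.01, 0.98)[col(probs)]
  tis <- rec$cds_start + 0:2
  tts <- rec$cds_end - 3 + 0:2
  probs[tis + 1, ] <- rep(c(0.95, 0.01, 0.04), each = 3)
  probs[tts + 1, ] <- rep(c(0.01, 0.95, 0.04), each = 3)
  cand <- enumerate_candidates(rec$sequence, probs,
                               scoring_params(tis_floor = 0, tts_floor = 0))
  cand <- score_candidates(rec$sequence, cand)
  sel <- select_orf(cand, scoring_params())
  expect_equal(sel$decision, "coding")
  expect_equal(sel$orf$tis_start, rec$cds_start)
  expect_equal(sel$orf$tts_start, rec$cds_end - 3L)
})

test_that("grid search returns the exhaustive argmax", {
  # toy set: true ORFs separate from decoys on tis_prob alone
  withr::with_seed(18, {
    n <- 60
    cand <- data.frame(
      transcript_id = rep(paste0("t", 1:n), each = 2),
      is_true_orf = rep(c(TRUE, FALSE), n),
      tis_prob = as.numeric(rbind(runif(n, 0.7, 1), runif(n, 0, 0.3))),
      tts_prob = as.numeric(rbind(runif(n, 0.7, 1), runif(n, 0, 0.3))),
      kozak_norm = runif(2 * n), cai = runif(2 * n), gc = runif(2 * n))
  })
  transcripts <- data.frame(transcript_id = paste0("t", 1:60),
                            biotype = rep(c("coding", "noncoding"), c(40, 20)))
  # noncoding transcripts get no candidates at all
  cand <- cand[cand$transcript_id %in% transcripts$transcript_id[1:40], ]
  grid <- list(w_tis = c(0.2, 0.3, 0.5), w_tts = c(0.3, 0.5, 0.7),
               w_kozak = c(0, 0.04), w_cai = c(0, 0.04),
               w_gc = 0, threshold = c(0.3, 0.5, 0.635, 0.7, 0.9))
  res <- optimize_weights(cand, transcripts, grid)
  expect_equal(nrow(res$table), 3 * 3 * 2 * 2 * 1 * 5)
  # independent recomputation of the surface argmax
  acc <- apply(res$table, 1, function(row) {
    sc <- row[["w_tis"]] * cand$tis_prob + row[["w_tts"]] * cand$tts_prob +
      row[["w_kozak"]] * cand$kozak_norm + row[["w_cai"]] * cand$cai +
      row[["w_gc"]] * cand$gc
    ok <- vapply(transcripts$transcript_id, function(tt) {
      rows <- which(cand$transcript_id == tt)
      if (length(rows) == 0) return(TRUE)  # noncoding, nothing called
      j <- rows[which.max(sc[rows])]
      called <- sc[j] >= row[["threshold"]]
      if (tt %in% transcripts$transcript_id[1:40]) called && cand$is_true_orf[j]
      else !called
    }, logical(1))
    mean(ok)
  })
  expect_equal(res$table$accuracy, unname(acc))
  expect_equal(res$accuracy, max(acc))
  expect_equal(which.max(acc), which.max(res$table$accuracy))

  single <- optimize_weights(cand, transcripts,
                             lapply(grid, function(x) x[1]))
  expect_equal(nrow(single$table), 1)
  expect_error(optimize_weights(cand, transcripts, list(w_tis = 0.3)), "grid")
})

test_that("ROC area and Youden threshold match enumeration and pROC", {
  toy <- list(scores = c(0.9, 0.8, 0.4, 0.1), labels = c(TRUE, TRUE, FALSE, FALSE))
  r <- roc_youden(toy$scores, toy$labels)
  expect_equal(r$auc, 1.0)
  expect_true(r$threshold > 0.4 && r$threshold <= 0.8)
  expect_equal(r$j, 1.0)

  expect_error(roc_youden(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  # label-independent scores give AUC near 1/2
  withr::with_seed(19, {
    sc <- runif(4000)
    lb <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  })
  expect_equal(roc_youden(sc, lb)$auc, 0.5, tolerance = 0.05)

  # cross-check AUC against pROC on a graded example
  withr::with_seed(20, {
    sc2 <- c(rnorm(150, 1), rnorm(150, 0))
    lb2 <- rep(c(TRUE, FALSE), each = 150)
  })
  auc_ref <- as.numeric(pROC::auc(pROC::roc(lb2, sc2, quiet = TRUE)))
  expect_equal(roc_youden(sc2, lb2)$auc, auc_ref, tolerance = 1e-10)
})

test_that("ORF translation follows the standard code and rejects malformed input", {
  expect_equal(translate_orf("ATGGCCTAA"), "MA")
  expect_equal(translate_orf("ATGTAA"), "M")
  expect_error(translate_orf("ATGGC"), "multiple of 3")
  expect_error(translate_orf("ATGTAATAA"), "internal stop|stop codon")
  expect_error(translate_orf("ATGGCCGCC"), "stop codon")
  expect_error(translate_orf("CTGGCCTAA"), "ATG")
  # spot check against Biostrings on a random ORF
  withr::with_seed(21, {
    body <- paste(sample(names(codon_weights()), 20, replace = TRUE), collapse = "")
  })
  orf <- paste0("ATG", body, "TGA")
  ref <- as.character(Biostrings::translate(Biostrings::DNAString(
    paste0("ATG", body))))
  expect_equal(translate_orf(orf), ref)
})
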