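# Reading transcript sequences and annotations, integer encoding, padding,
# and the gene-level dataset split.
#
# Transcript sets are plain data.frames with columns transcript_id,
# gene_symbol, biotype ("coding"/"noncoding"), cds_start, cds_end (0-based
# half-open, NA for noncoding) and sequence.  CDS coordinates are half-open so
# cds_end - cds_start is the CDS length including the stop codon.

#' Read transcript sequences from a FASTA file
#'
#' Sequences are uppercased, U is unified to T, and accession version
#' suffixes (text after the first ".") are stripped from the record ids.
#' Characters outside A, C, G, T, N are rejected.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are transcript ids).
#'   An empty file yields an empty vector.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\..*$", "", sub("\\s.*$", "", names(set)))
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,U,N}")
  }
  setNames(seqs, ids)
}

#' Write transcripts to FASTA
#'
#' @param records transcript data.frame (see [read_annotation_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(setNames(records$sequence, records$transcript_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a transcript annotation table and join it with sequences
#'
#' The table is tab-separated with columns `transcript_id`, `gene_symbol`,
#' `biotype` (coding/noncoding) and, for coding transcripts, `cds_start` and
#' `cds_end` in 0-based half-open coordinates covering start codon through
#' stop codon.  Coding records whose CDS length is not a multiple of 3 are
#' dropped with a warning; a transcript present in the table but absent from
#' the FASTA, or listed twice, is an error.
#'
#' @param path path to the annotation TSV.
#' @param sequences named character vector from [read_transcript_fasta()].
#' @return transcript data.frame with columns transcript_id, gene_symbol,
#'   biotype, cds_start, cds_end, sequence.
#' @export
read_annotation_table <- function(path, sequences) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(transcript_id = "character",
                                   gene_symbol = "character",
                                   biotype = "character"))
  required <- c("transcript_id", "gene_symbol", "biotype", "cds_start", "cds_end")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  tab$transcript_id <- sub("\\..*$", "", tab$transcript_id)
  if (anyDuplicated(tab$transcript_id))
    stop("duplicate transcript_id in annotation table: ",
         tab$transcript_id[duplicated(tab$transcript_id)][1])
  absent <- setdiff(tab$transcript_id, names(sequences))
  if (length(absent) > 0)
    stop("transcript(s) in annotation but not in FASTA: ",
         paste(head(absent, 5), collapse = ", "))
  tab$cds_start <- suppressWarnings(as.integer(tab$cds_start))
  tab$cds_end <- suppressWarnings(as.integer(tab$cds_end))
  tab$sequence <- unname(sequences[tab$transcript_id])
  records <- tab[, c("transcript_id", "gene_symbol", "biotype",
                     "cds_start", "cds_end", "sequence")]
  validate_transcripts(records)
}

#' Validate a transcript data.frame
#'
#' Enforces the record invariants: known biotype, non-empty sequence, CDS
#' inside the sequence with positive length for coding records, absent CDS for
#' noncoding records.  Coding records whose CDS length is not divisible by 3
#' are removed with a warning naming them.
#'
#' @param records transcript data.frame.
#' @return the validated (possibly reduced) data.frame.
#' @export
validate_transcripts <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(!records$biotype %in% c("coding", "noncoding")))
    stop("biotype must be 'coding' or 'noncoding'")
  if (any(!nzchar(records$sequence)))
    stop("empty sequence for transcript ",
         records$transcript_id[!nzchar(records$sequence)][1])
  len <- nchar(records$sequence)
  coding <- records$biotype == "coding"
  if (any(coding & (is.na(records$cds_start) | is.na(records$cds_end))))
    stop("coding transcript without CDS coordinates: ",
         records$transcript_id[coding & is.na(records$cds_start)][1])
  bad_span <- coding & (records$cds_start < 0 | records$cds_end <= records$cds_start |
                          records$cds_end > len)
  bad_span[is.na(bad_span)] <- FALSE
  if (any(bad_span))
    stop("CDS outside sequence for transcript ",
         records$transcript_id[bad_span][1])
  records$cds_start[!coding] <- NA_integer_
  records$cds_end[!coding] <- NA_integer_
  cds_len <- records$cds_end - records$cds_start
  bad_frame <- coding & (cds_len %% 3L != 0L)
  bad_frame[is.na(bad_frame)] <- FALSE
  if (any(bad_frame)) {
    warning(sum(bad_frame), " coding transcript(s) dropped: CDS length not a ",
            "multiple of 3 (", paste(head(records$transcript_id[bad_frame], 5),
                                     collapse = ", "), ")")
    records <- records[!bad_frame, , drop = FALSE]
  }
  rownames(records) <- NULL
  records
}

#' Extract CDS annotations from a minimal GenBank flat file
#'
#' Parses only the VERSION/ACCESSION id, the first simple `CDS a..b` feature
#' (1-based inclusive, converted to 0-based half-open) and the ORIGIN
#' sequence of each record.  Records with compound CDS locations
#' (join/complement) are skipped with a warning.  Records without a CDS are
#' returned as noncoding.
#'
#' @param path path to a GenBank flat file.
#' @param gene_symbols optional named character vector mapping transcript id
#'   to gene symbol; ids without an entry use the id itself.
#' @return transcript data.frame as in [read_annotation_table()].
#' @export
read_genbank_cds <- function(path, gene_symbols = NULL) {
  lines <- readLines(path)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) stop("no LOCUS records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- lapply(seq_along(starts), function(i) {
    chunk <- lines[starts[i]:ends[i]]
    vline <- grep("^VERSION", chunk, value = TRUE)
    aline <- grep("^ACCESSION", chunk, value = TRUE)
    id <- if (length(vline)) strsplit(trimws(sub("^VERSION", "", vline[1])), "\\s+")[[1]][1]
          else strsplit(trimws(sub("^ACCESSION", "", aline[1])), "\\s+")[[1]][1]
    id <- sub("\\..*$", "", id)
    gline <- grep("^\\s+/gene=", chunk, value = TRUE)
    gene <- if (length(gline)) gsub("\"", "", sub(".*=", "", gline[1])) else NA_character_
    cds_lines <- grep("^\\s{5}CDS\\s", chunk, value = TRUE)
    cds_start <- cds_end <- NA_integer_
    biotype <- "noncoding"
    if (length(cds_lines) > 0) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", cds_lines[1]))
      if (grepl("^<?[0-9]+\\.\\.>?[0-9]+$", loc)) {
        nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
        cds_start <- nums[1] - 1L  # 1-based inclusive -> 0-based half-open
        cds_end <- nums[2]
        biotype <- "coding"
      } else {
        warning("skipping compound CDS location for ", id, ": ", loc)
      }
    }
    oi <- grep("^ORIGIN", chunk)
    if (length(oi) == 0) stop("record ", id, " has no ORIGIN sequence")
    seq_lines <- chunk[(oi[1] + 1):length(chunk)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    sequence <- chartr("U", "T", sequence)
    data.frame(transcript_id = id, gene_symbol = gene, biotype = biotype,
               cds_start = cds_start, cds_end = cds_end, sequence = sequence,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  fill <- is.na(records$gene_symbol)
  if (!is.null(gene_symbols))
    records$gene_symbol[fill] <- gene_symbols[records$transcript_id[fill]]
  records$gene_symbol[is.na(records$gene_symbol)] <-
    records$transcript_id[is.na(records$gene_symbol)]
  validate_transcripts(records)
}

#' Write an annotation table
#'
#' @param records transcript data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(records, path) {
  tab <- records[, c("transcript_id", "gene_symbol", "biotype",
                     "cds_start", "cds_end")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Integer-encode a nucleotide sequence
#'
#' A, C, G, T map to 1..4; N and padding map to 0.
#'
#' @param sequence string over A,C,G,T,N.
#' @return integer vector, one value per nucleotide.
#' @export
encode_sequence <- function(sequence) {
  if (nchar(sequence) == 0) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tokens <- match(chars, c("N", "A", "C", "G", "T")) - 1L
  if (anyNA(tokens))
    stop("sequence contains invalid character(s): ",
         paste(unique(chars[is.na(tokens)]), collapse = ","))
  tokens
}

#' Decode integer tokens back to nucleotides
#'
#' Inverse of [encode_sequence()] except that token 0 decodes to "N"
#' (N and padding share the code by design).
#'
#' @param tokens integer vector in 0..4.
#' @return nucleotide string.
#' @export
decode_sequence <- function(tokens) {
  stopifnot(all(tokens %in% 0:4))
  paste(c("N", "A", "C", "G", "T")[tokens + 1L], collapse = "")
}

#' Per-position class labels for a transcript
#'
#' For a coding record the three start-codon positions are labeled TIS and
#' the three stop-codon positions TTS (all other positions NONE); noncoding
#' records are all NONE.
#'
#' @param record one-row transcript data.frame or list with fields
#'   `sequence`, `biotype`, `cds_start`, `cds_end`.
#' @return integer vector of class codes (1 TIS, 2 TTS, 3 NONE).
#' @export
encode_labels <- function(record) {
  len <- nchar(record$sequence)
  labels <- rep(CLASS_NONE, len)
  if (record$biotype == "coding") {
    s <- record$cds_start
    e <- record$cds_end
    stopifnot(!is.na(s), !is.na(e), s >= 0, e <= len, (e - s) %% 3 == 0)
    labels[(s + 1):(s + 3)] <- CLASS_TIS
    labels[(e - 2):e] <- CLASS_TTS
  }
  labels
}

#' Pad or truncate an encoded transcript to a fixed length
#'
#' Shorter inputs are padded with token 0 / label NONE; longer inputs are
#' truncated at the 3' end.  Padding positions are excluded from the training
#' loss via `valid_length`.
#'
#' @param tokens integer tokens from [encode_sequence()].
#' @param labels class labels from [encode_labels()].
#' @param l_max target length (>= 1).
#' @return list with `tokens`, `labels` (both length `l_max`) and
#'   `valid_length`.
#' @export
pad_or_truncate <- function(tokens, labels, l_max) {
  stopifnot(l_max >= 1, length(tokens) == length(labels))
  n <- length(tokens)
  if (n >= l_max) {
    list(tokens = tokens[seq_len(l_max)], labels = labels[seq_len(l_max)],
         valid_length = l_max)
  } else {
    list(tokens = c(tokens, rep(0L, l_max - n)),
         labels = c(labels, rep(CLASS_NONE, l_max - n)),
         valid_length = n)
  }
}

#' Encode a transcript set into fixed-length training matrices
#'
#' Applies [encode_sequence()], [encode_labels()] and [pad_or_truncate()] to
#' every record.  Coding transcripts whose stop codon does not fit below
#' `l_max` after truncation carry unlearnable labels and are excluded, with a
#' message reporting the count.  Padding labels are set to `NA` in the label
#' matrix so the loss masks them.
#'
#' @param records transcript data.frame.
#' @param l_max fixed sequence length.
#' @return list with `tokens` (l_max x n integer matrix), `labels` (same
#'   shape; NA at padding), `valid_length`, `records` (the kept rows) and
#'   `n_excluded`.
#' @export
encode_transcripts <- function(records, l_max) {
  coding <- records$biotype == "coding"
  drop <- coding & records$cds_end > l_max
  drop[is.na(drop)] <- FALSE
  if (any(drop))
    message(sum(drop), " coding transcript(s) excluded: stop codon beyond l_max")
  records <- records[!drop, , drop = FALSE]
  n <- nrow(records)
  tokens <- matrix(0L, nrow = l_max, ncol = n)
  labels <- matrix(NA_integer_, nrow = l_max, ncol = n)
  valid_length <- integer(n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    enc <- pad_or_truncate(encode_sequence(rec$sequence), encode_labels(rec), l_max)
    tokens[, i] <- enc$tokens
    labels_i <- enc$labels
    if (enc$valid_length < l_max)
      labels_i[(enc$valid_length + 1):l_max] <- NA_integer_
    labels[, i] <- labels_i
    valid_length[i] <- enc$valid_length
  }
  colnames(tokens) <- colnames(labels) <- records$transcript_id
  list(tokens = tokens, labels = labels, valid_length = valid_length,
       records = records, n_excluded = sum(drop))
}

#' Gene-level train/heldout split
#'
#' All isoforms of a gene are assigned to the same partition so no sequence
#' information leaks between train and heldout sets.
#'
#' @param records transcript data.frame.
#' @param ratio fraction of genes assigned to train (default 0.8).
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return data.frame with columns `gene_symbol` and `partition`
#'   ("train"/"heldout").
#' @export
split_by_gene <- function(records, ratio = 0.8, seed = 1L) {
  if (nrow(records) == 0) stop("no records to split")
  genes <- sort(unique(records$gene_symbol))
  n_train <- min(length(genes), max(1L, round(ratio * length(genes))))
  train_genes <- withr::with_seed(seed, sample(genes, n_train))
  data.frame(gene_symbol = genes,
             partition = ifelse(genes %in% train_genes, "train", "heldout"),
             stringsAsFactors = FALSE)
}

#' Transcript-length percentile used to pick the padding length
#'
#' The default reproduces the convention of padding to the 99.9th percentile
#' of the length distribution.
#'
#' @param lengths integer vector of transcript lengths.
#' @param p percentile in (0, 1]; default 0.999.
#' @return integer length.
#' @export
length_percentile <- function(lengths, p = 0.999) {
  as.integer(ceiling(quantile(lengths, probs = p, names = FALSE, type = 7)))
}
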