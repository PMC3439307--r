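# Self-contained nucleotide local alignment: k-mer seeded extension resolved
# by exact affine-gap DP on subject windows, scored with Karlin-Altschul
# e-values. An exact Smith-Waterman entry point doubles as the test oracle,
# and an adapter can delegate to an external BLASTN executable.

#' Solve the Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` for uniform base frequencies,
#' i.e. `0.25 exp(lambda*match) + 0.75 exp(lambda*mismatch) = 1`.
#'
#' @param match match reward (> 0)
#' @param mismatch mismatch penalty (< 0)
#' @return lambda (positive real)
#' @export
karlin_lambda <- function(match = 2L, mismatch = -3L) {
  stopifnot(match > 0, mismatch < 0)
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10 / match), tol = 1e-12)$root
}

#' Scoring parameters for local alignment
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open 5, gap extend 2
#' (a length-L gap costs `gap_open + L * gap_extend`). `lambda` defaults to
#' the ungapped Karlin-Altschul solution for the match/mismatch scheme at
#' uniform base composition; `k` is a configured constant.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores
#' @param lambda,k Karlin-Altschul parameters for [evalue_from_score()]
#' @return an object of class `scoring_params`
#' @export
scoring_params <- function(match = 2L, mismatch = -3L,
                           gap_open = 5L, gap_extend = 2L,
                           lambda = NULL, k = 0.71) {
  stopifnot(match > 0, mismatch < 0, gap_open >= gap_extend, gap_extend >= 0,
            k > 0)
  if (is.null(lambda)) lambda <- karlin_lambda(match, mismatch)
  stopifnot(lambda > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, k = k),
            class = "scoring_params")
}

#' Karlin-Altschul e-value from a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a length-`m` query and a length-`n`
#' database.
#'
#' @param score raw alignment score S
#' @param query_len query length m
#' @param db_len total database length n
#' @param scoring a [scoring_params] supplying lambda and K
#' @return the e-value (non-negative real)
#' @export
evalue_from_score <- function(score, query_len, db_len, scoring = scoring_params()) {
  stopifnot(query_len > 0, db_len > 0)
  scoring$k * query_len * db_len * exp(-scoring$lambda * score)
}

#' Build a k-mer subject index
#'
#' Indexes every k-mer occurrence of every subject (k-mers containing N are
#' skipped). The index is single-stranded; minus-strand hits are found by
#' searching the reverse-complemented query.
#'
#' @param subjects list of [qual_seq_record] objects (or named character
#'   vector of sequences)
#' @param word_size k-mer length (default 11)
#' @return an object of class `subject_index`
#' @export
build_index <- function(subjects, word_size = 11L) {
  stopifnot(word_size >= 4L, length(subjects) > 0L)
  if (is.character(subjects)) {
    ids <- names(subjects)
    if (is.null(ids)) ids <- paste0("subject_", seq_along(subjects))
    seqs <- toupper(unname(subjects))
  } else {
    ids <- vapply(subjects, `[[`, "", "id")
    seqs <- vapply(subjects, `[[`, "", "seq")
  }
  idx <- structure(list(ids = ids, seqs = seqs, lengths = nchar(seqs),
                        word_size = as.integer(word_size),
                        total_length = sum(nchar(seqs)),
                        ptr = .ft_build_index(seqs, as.integer(word_size))),
                   class = "subject_index")
  idx
}

# XPtr survives within a session only; rebuild transparently after
# serialization (e.g. an index restored from an RDS).
.index_ptr <- function(index) {
  p <- index$ptr
  if (is.null(p) || !.ft_ptr_valid(p))
    p <- .ft_build_index(index$seqs, index$word_size)
  p
}

#' @export
print.subject_index <- function(x, ...) {
  cat(sprintf("<subject_index> %d subject(s), %s bp, word size %d\n",
              length(x$ids), format(x$total_length, big.mark = ","),
              x$word_size))
  invisible(x)
}

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             strand = character(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0), score = integer(0),
             evalue = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# >50% reciprocal-overlap dedup on (subject, strand); keep the higher score
.dedup_hits <- function(h) {
  if (nrow(h) < 2L) return(h)
  h <- h[order(-h$score, h$evalue, h$subject_id, h$s_start, h$strand),
         , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (h$subject_id[j] != h$subject_id[i] || h$strand[j] != h$strand[i]) next
      ov <- min(h$s_end[i], h$s_end[j]) - max(h$s_start[i], h$s_start[j])
      if (ov > 0.5 * min(h$s_end[i] - h$s_start[i], h$s_end[j] - h$s_start[j])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  h[keep, , drop = FALSE]
}

#' Seeded local-alignment search against an indexed subject set
#'
#' Both strands are searched (the reverse-complemented query against the
#' forward index). Seed clusters are resolved by exact affine-gap local DP on
#' a subject window; overlapping alignments on the same subject and strand
#' are deduplicated keeping the higher score. Hits are filtered to
#' `evalue <= evalue_cutoff` and sorted by descending score, ascending
#' e-value, then subject id and subject start.
#'
#' @param query a [qual_seq_record] (or plain string)
#' @param index a [build_index()] result
#' @param scoring a [scoring_params]
#' @param evalue_cutoff maximum reported e-value
#' @param both_strands search the minus strand too (default TRUE)
#' @return data.frame of hits: `query_id`, `subject_id`, `strand`,
#'   `q_start`/`q_end` (0-based half-open on the original query),
#'   `s_start`/`s_end` (0-based half-open, forward subject coordinates),
#'   `score`, `evalue`, `identity`
#' @export
search_hits <- function(query, index, scoring = scoring_params(),
                        evalue_cutoff = 10, both_strands = TRUE) {
  if (is.character(query)) query <- qual_seq_record("query", query)
  stopifnot(inherits(query, "qual_seq_record"),
            inherits(index, "subject_index"))
  qlen <- nchar(query$seq)
  ptr <- .index_ptr(index)
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (st in strands) {
    qs <- if (st == "+") query$seq else revcomp(query$seq)
    raw <- .ft_search(qs, ptr, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
    if (!nrow(raw)) next
    q_start <- raw$q_start; q_end <- raw$q_end
    if (st == "-") { q_start <- qlen - raw$q_end; q_end <- qlen - raw$q_start }
    out[[st]] <- data.frame(
      query_id = query$id, subject_id = index$ids[raw$subject], strand = st,
      q_start = q_start, q_end = q_end,
      s_start = raw$s_start, s_end = raw$s_end, score = raw$score,
      evalue = evalue_from_score(raw$score, qlen, index$total_length, scoring),
      identity = ifelse(raw$aln_len > 0, raw$n_match / raw$aln_len, 0),
      stringsAsFactors = FALSE)
  }
  h <- if (length(out)) do.call(rbind, out) else .empty_hits()
  rownames(h) <- NULL
  h <- .dedup_hits(h)
  h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
  h <- h[order(-h$score, h$evalue, h$subject_id, h$s_start, h$strand),
         , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Exact Smith-Waterman local alignment
#'
#' Full affine-gap dynamic program over the complete matrix; returns the
#' optimal local score and one optimal alignment's coordinates. Used as the
#' exact oracle for the seeded search.
#'
#' @param query,subject DNA strings
#' @param scoring a [scoring_params]
#' @return list: `score`, `q_start`/`q_end` and `s_start`/`s_end` (0-based
#'   half-open), `identity`
#' @export
smith_waterman <- function(query, subject, scoring = scoring_params()) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  a <- .ft_sw(toupper(query), toupper(subject), scoring$match,
              scoring$mismatch, scoring$gap_open, scoring$gap_extend)
  list(score = a$score, q_start = a$q_start, q_end = a$q_end,
       s_start = a$s_start, s_end = a$s_end,
       identity = if (a$aln_len > 0) a$n_match / a$aln_len else 0)
}

#' Align with an external BLASTN executable
#'
#' Runs `blastn` (tabular output) and parses hits into the same shape as
#' [search_hits()]. Coordinates are converted to 0-based half-open forward
#' strand.
#'
#' @param query_fasta,subject_fasta FASTA paths
#' @param evalue_cutoff e-value threshold passed to blastn
#' @param blastn path to the executable (default: found on PATH)
#' @return data.frame of hits as in [search_hits()]
#' @export
external_blastn <- function(query_fasta, subject_fasta, evalue_cutoff = 10,
                            blastn = Sys.which("blastn")) {
  if (!nzchar(blastn) || !file.exists(blastn))
    stop("external aligner unavailable: no blastn executable found; ",
         "use the internal aligner (search_hits)")
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  args <- c("-query", query_fasta, "-subject", subject_fasta,
            "-evalue", format(evalue_cutoff, scientific = TRUE),
            "-outfmt", shQuote("6 qseqid sseqid pident length qstart qend sstart send evalue bitscore score"),
            "-out", out)
  status <- system2(blastn, args, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) stop("blastn failed: ", paste(status, collapse = " "))
  lines <- readLines(out)
  if (!length(lines)) return(.empty_hits())
  fields <- strsplit(lines, "\t")
  bad <- which(vapply(fields, length, 0L) != 11L)
  if (length(bad))
    stop("unparsable blastn output line ", bad[1L], ": ", lines[bad[1L]])
  m <- do.call(rbind, fields)
  ss <- as.integer(m[, 7L]); se <- as.integer(m[, 8L])
  minus <- ss > se
  data.frame(query_id = m[, 1L], subject_id = m[, 2L],
             strand = ifelse(minus, "-", "+"),
             q_start = as.integer(m[, 5L]) - 1L, q_end = as.integer(m[, 6L]),
             s_start = ifelse(minus, se, ss) - 1L,
             s_end = ifelse(minus, ss, se),
             score = as.integer(m[, 11L]), evalue = as.numeric(m[, 9L]),
             identity = as.numeric(m[, 3L]) / 100,
             stringsAsFactors = FALSE)
}
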