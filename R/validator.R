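# Validating module: locate optional sequences (transgene border, PCR
# adaptor, vector backbone) within each FST, mask them, and classify the
# read as A (acceptable), NA (too short), VECTOR, or LOW (quality failure).

#' Bundle the optional border / adaptor / vector sequences
#'
#' Any of the three may be absent. Cutoffs are e-value thresholds applied to
#' local alignments of the FST against the respective sequence; defaults
#' 10.0 (border), 10.0 (adaptor), 1e-10 (vector). The permissive
#' border/adaptor thresholds admit short terminal stubs; the stringent vector
#' threshold demands substantial backbone identity.
#'
#' @param border,adaptor,vector [qual_seq_record] objects, plain strings, or
#'   NULL
#' @param cutoffs named numeric vector with elements `border`, `adaptor`,
#'   `vector`
#' @return an object of class `optional_seq_set`
#' @export
optional_seq_set <- function(border = NULL, adaptor = NULL, vector = NULL,
                             cutoffs = c(border = 10, adaptor = 10,
                                         vector = 1e-10)) {
  as_rec <- function(x, nm) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- qual_seq_record(nm, x)
    stopifnot(inherits(x, "qual_seq_record"))
    x
  }
  stopifnot(all(c("border", "adaptor", "vector") %in% names(cutoffs)),
            all(cutoffs > 0))
  structure(list(border = as_rec(border, "border"),
                 adaptor = as_rec(adaptor, "adaptor"),
                 vector = as_rec(vector, "vector"),
                 cutoffs = cutoffs),
            class = "optional_seq_set")
}

# one index per provided role; built once per batch
.optional_indexes <- function(optionals, word_size) {
  idx <- list()
  for (role in c("border", "adaptor", "vector")) {
    if (!is.null(optionals[[role]]))
      idx[[role]] <- build_index(list(optionals[[role]]), word_size)
  }
  idx
}

# mask annotation -> 2-column matrix of intervals (all roles)
.mask_matrix <- function(mask, roles = NULL) {
  iv <- mask$intervals
  if (!is.null(roles)) iv <- iv[vapply(iv, `[[`, "", "role") %in% roles]
  if (!length(iv)) return(matrix(numeric(0), ncol = 2))
  t(vapply(iv, function(z) z$interval, numeric(2)))
}

#' Locate and mask optional sequences within one FST
#'
#' Each provided optional sequence is aligned locally against the read; all
#' alignments at or below its role cutoff become mask intervals. Border and
#' adaptor masks reaching within 3 bp of a read end are extended to that end
#' (the unaligned terminal stub belongs to the synthetic construct, not the
#' genome).
#'
#' @param fst a post-trim [qual_seq_record]
#' @param optionals an [optional_seq_set]
#' @param scoring a [scoring_params]
#' @param word_size seed length for the search
#' @param indexes prebuilt per-role indexes (internal batch optimization)
#' @return an object of class `mask_annotation`: list of
#'   `(role, interval, hit)` entries with 0-based half-open intervals on the
#'   read
#' @export
annotate_optional_sequences <- function(fst, optionals,
                                        scoring = scoring_params(),
                                        word_size = 11L, indexes = NULL) {
  stopifnot(inherits(fst, "qual_seq_record"),
            inherits(optionals, "optional_seq_set"))
  if (is.null(indexes)) indexes <- .optional_indexes(optionals, word_size)
  n <- nchar(fst$seq)
  intervals <- list()
  for (role in names(indexes)) {
    if (n < indexes[[role]]$word_size) next
    hits <- search_hits(fst, indexes[[role]], scoring,
                        evalue_cutoff = optionals$cutoffs[[role]])
    for (i in seq_len(nrow(hits))) {
      iv <- c(hits$q_start[i], hits$q_end[i])
      if (role %in% c("border", "adaptor")) {
        if (iv[1L] <= 3) iv[1L] <- 0
        if (n - iv[2L] <= 3) iv[2L] <- n
      }
      intervals[[length(intervals) + 1L]] <-
        list(role = role, interval = iv, hit = hits[i, , drop = FALSE])
    }
  }
  structure(list(intervals = intervals, read_length = n),
            class = "mask_annotation")
}

#' Classify one masked FST
#'
#' Category priority LOW -> VECTOR -> NA -> A:
#' * `LOW`: the post-trim read is shorter than `msl` (quality failure);
#' * `VECTOR`: vector masks cover more than half of the read outside the
#'   border/adaptor masks;
#' * `A` when the maximal unmasked run (the genomic segment) is at least
#'   `msl` long, else `NA`.
#'
#' `border_end` and `adaptor_start` are reported 1-based inclusive;
#' `insert_length` is the genomic-segment length. When several unmasked runs
#' exist, the longest wins (ties: leftmost).
#'
#' @param fst the original [qual_seq_record] (pre-trim)
#' @param trim the [trim_by_quality()] result for `fst`
#' @param mask the [annotate_optional_sequences()] result on the trimmed read
#' @param msl minimum genomic-segment length (default 30)
#' @return an object of class `masked_fst`
#' @export
classify <- function(fst, trim, mask, msl = 30L) {
  rec <- trim$record
  n <- nchar(rec$seq)
  all_iv <- .merge_intervals(.mask_matrix(mask))
  # unmasked runs
  runs <- matrix(numeric(0), ncol = 2)
  cur <- 0
  if (nrow(all_iv)) {
    for (i in seq_len(nrow(all_iv))) {
      if (all_iv[i, 1L] > cur) runs <- rbind(runs, c(cur, all_iv[i, 1L]))
      cur <- max(cur, all_iv[i, 2L])
    }
    if (cur < n) runs <- rbind(runs, c(cur, n))
  } else if (n > 0) runs <- rbind(runs, c(0, n))
  if (nrow(runs)) {
    lens <- runs[, 2L] - runs[, 1L]
    seg <- runs[which.max(lens), ]      # which.max: leftmost on ties
  } else seg <- c(0, 0)
  seg_len <- seg[2L] - seg[1L]

  ba_iv <- .merge_intervals(.mask_matrix(mask, c("border", "adaptor")))
  ba_cov <- if (nrow(ba_iv)) sum(ba_iv[, 2L] - ba_iv[, 1L]) else 0
  nonborder <- n - ba_cov
  vec_iv <- .merge_intervals(.mask_matrix(mask, "vector"))
  # vector coverage outside the border/adaptor masks
  vec_cov <- 0
  if (nrow(vec_iv)) {
    for (i in seq_len(nrow(vec_iv))) {
      covered <- vec_iv[i, 2L] - vec_iv[i, 1L]
      if (nrow(ba_iv)) {
        ov <- pmax(0, pmin(vec_iv[i, 2L], ba_iv[, 2L]) -
                        pmax(vec_iv[i, 1L], ba_iv[, 1L]))
        covered <- covered - sum(ov)
      }
      vec_cov <- vec_cov + covered
    }
  }

  category <- if (n < msl) "LOW"
    else if (nonborder > 0 && vec_cov > 0.5 * nonborder) "VECTOR"
    else if (seg_len >= msl) "A" else "NA"

  b_iv <- .mask_matrix(mask, "border")
  a_iv <- .mask_matrix(mask, "adaptor")
  structure(list(record = rec, trim = trim, mask = mask,
                 genomic_segment = seg, category = category,
                 border_end = if (nrow(b_iv)) max(b_iv[, 2L]) else NA,
                 adaptor_start = if (nrow(a_iv)) min(a_iv[, 1L]) + 1 else NA,
                 insert_length = seg_len),
            class = "masked_fst")
}

#' @export
print.masked_fst <- function(x, ...) {
  cat(sprintf("<masked_fst> %s: %s, insert %d bp\n", x$record$id,
              x$category, x$insert_length))
  invisible(x)
}

#' Extract the genomic segment of a masked FST
#'
#' @param mfst a `masked_fst`
#' @return the unmasked genomic subsequence (possibly empty)
#' @export
genomic_segment <- function(mfst) {
  stopifnot(inherits(mfst, "masked_fst"))
  if (mfst$insert_length == 0) return("")
  substring(mfst$record$seq, mfst$genomic_segment[1L] + 1L,
            mfst$genomic_segment[2L])
}

#' Validate a batch of FSTs
#'
#' Trims each read, masks optional sequences, classifies, and aggregates a
#' per-read table plus per-category totals and percentages. Acceptable (`A`)
#' reads carry the genomic segment for the mapping stage.
#'
#' @param fsts list of [qual_seq_record] objects
#' @param optionals an [optional_seq_set] (may hold no sequences)
#' @param msl minimum genomic-segment length (default 30)
#' @param scoring a [scoring_params]
#' @param word_size seed length for optional-sequence masking
#' @param max_error_prob quality-trim threshold (default 0.03)
#' @return list with `masked` (list of `masked_fst`), `per_fst` (data.frame:
#'   `fst_id`, `category`, `border_end`, `adaptor_start`, `insert_length`),
#'   and `summary` (data.frame: `category`, `count`, `percent`)
#' @export
validate_batch <- function(fsts, optionals = optional_seq_set(), msl = 30L,
                           scoring = scoring_params(), word_size = 11L,
                           max_error_prob = 0.03) {
  stopifnot(length(fsts) > 0L)
  indexes <- .optional_indexes(optionals, word_size)
  masked <- vector("list", length(fsts))
  for (i in seq_along(fsts)) {
    tr <- trim_by_quality(fsts[[i]], max_error_prob)
    mk <- annotate_optional_sequences(tr$record, optionals, scoring,
                                      word_size, indexes = indexes)
    masked[[i]] <- classify(fsts[[i]], tr, mk, msl)
  }
  per_fst <- data.frame(
    fst_id = vapply(masked, function(m) m$record$id, ""),
    category = vapply(masked, `[[`, "", "category"),
    border_end = vapply(masked, function(m) as.numeric(m$border_end), 0),
    adaptor_start = vapply(masked, function(m) as.numeric(m$adaptor_start), 0),
    insert_length = vapply(masked, function(m) as.numeric(m$insert_length), 0),
    stringsAsFactors = FALSE)
  counts <- vapply(.ft_categories, function(cat)
    sum(per_fst$category == cat), 0)
  summary <- data.frame(category = .ft_categories, count = as.numeric(counts),
                        percent = round_half_up(100 * counts / length(fsts), 1),
                        stringsAsFactors = FALSE)
  summary <- rbind(summary,
                   data.frame(category = "Total", count = length(fsts),
                              percent = 100.0))
  list(masked = masked, per_fst = per_fst, summary = summary)
}
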