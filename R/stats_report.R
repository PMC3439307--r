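# Summary tables (insertional-type and per-chromosome counts), the
# sliding-window insertion-frequency profile, and the two figures
# (distribution map, frequency graph).

.placed_calls <- function(calls) {
  Filter(function(cl) !cl$itype %in% c("repeat", "unmapped") &&
           !is.na(cl$position), calls)
}

#' Summarize insertion calls by insertional type
#'
#' Genic = exon + intron + upstream5 + downstream3. Percentages are computed
#' on the total of genic + intergenic + repeat (unmapped calls are excluded
#' from the table and reported separately) and rounded half-up to one
#' decimal.
#'
#' @param calls list of categorized `insertion_call` objects
#' @return data.frame with columns `type`, `count`, `percent`; rows genic,
#'   exon, intron, upstream5, downstream3, intergenic, repeat, total (plus an
#'   `unmapped` attribute)
#' @export
summarize_types <- function(calls) {
  it <- vapply(calls, `[[`, "", "itype")
  n_unmapped <- sum(it == "unmapped")
  cnt <- function(x) sum(it == x)
  genic <- cnt("exon") + cnt("intron") + cnt("upstream5") + cnt("downstream3")
  total <- genic + cnt("intergenic") + cnt("repeat")
  pct <- function(x) if (total > 0) round_half_up(100 * x / total, 1) else 0
  out <- data.frame(
    type = c("genic", "exon", "intron", "upstream5", "downstream3",
             "intergenic", "repeat", "total"),
    count = c(genic, cnt("exon"), cnt("intron"), cnt("upstream5"),
              cnt("downstream3"), cnt("intergenic"), cnt("repeat"), total),
    stringsAsFactors = FALSE)
  out$percent <- vapply(out$count, pct, 0)
  attr(out, "unmapped") <- n_unmapped
  out
}

#' Summarize placed insertions per chromosome
#'
#' Density is insertions per Mb, rounded half-up to one decimal; ratio is the
#' percentage of all placed insertions. Repeat and unmapped calls are
#' excluded.
#'
#' @param calls list of `insertion_call` objects
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @return data.frame with columns `chrom`, `length_mb`, `count`, `ratio`,
#'   `density`, plus a total row
#' @export
summarize_chromosomes <- function(calls, chrom_lengths) {
  placed <- .placed_calls(calls)
  chroms <- names(chrom_lengths)
  counts <- vapply(chroms, function(ch)
    sum(vapply(placed, function(cl) identical(cl$chrom, ch), TRUE)), 0)
  total <- sum(counts)
  mb <- as.numeric(chrom_lengths) / 1e6
  out <- data.frame(
    chrom = chroms, length_mb = round_half_up(mb, 1), count = counts,
    ratio = if (total > 0) round_half_up(100 * counts / total, 1) else 0,
    density = round_half_up(counts / mb, 1),
    stringsAsFactors = FALSE, row.names = NULL)
  rbind(out, data.frame(
    chrom = "total", length_mb = round_half_up(sum(mb), 1), count = total,
    ratio = if (total > 0) 100 else 0,
    density = round_half_up(total / sum(mb), 1)))
}

#' Sliding-window insertion-frequency profile
#'
#' Windows of `window` bp advance by `step` bp from position 0 of each
#' chromosome; every window start below the chromosome length is kept, the
#' trailing windows truncated at the chromosome end. Each placed insertion is
#' counted in every window containing it.
#'
#' @param calls list of `insertion_call` objects (repeat/unmapped ignored)
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @param window window size in bp (default 500,000)
#' @param step window step in bp (default 100,000)
#' @return object of class `frequency_profile`: named list (per chromosome)
#'   of data.frames with `start` (0-based window start) and `count`
#' @export
frequency_profile <- function(calls, chrom_lengths, window = 500000,
                              step = 100000) {
  stopifnot(window >= step, step > 0)
  placed <- .placed_calls(calls)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = step)
    pos0 <- vapply(Filter(function(cl) identical(cl$chrom, ch), placed),
                   function(cl) cl$position - 1, 0)
    counts <- vapply(starts, function(s)
      sum(pos0 >= s & pos0 < s + window), 0)
    data.frame(start = starts, count = counts)
  })
  names(out) <- names(chrom_lengths)
  structure(out, class = "frequency_profile",
            window = window, step = step, chrom_lengths = chrom_lengths)
}

#' Render the chromosome distribution map
#'
#' One horizontal bar per chromosome, scaled by length, with one tick per
#' placed insertion.
#'
#' @param calls list of `insertion_call` objects
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @param path output PNG path
#' @param width,height image size in pixels
#' @return `path`, invisibly
#' @export
render_distribution_map <- function(calls, chrom_lengths, path,
                                    width = 900, height = NULL) {
  n <- length(chrom_lengths)
  if (n == 0L) stop("no chromosomes to draw")
  placed <- .placed_calls(calls)
  if (is.null(height)) height <- 80 + 50 * n
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  maxlen <- max(chrom_lengths)
  graphics::par(mar = c(4, 6, 2, 1))
  graphics::plot(NA, xlim = c(0, maxlen / 1e6), ylim = c(0.5, n + 0.5),
                 xlab = "position (Mb)", ylab = "", yaxt = "n",
                 main = "Insertion distribution map")
  graphics::axis(2, at = n:1, labels = names(chrom_lengths), las = 1)
  for (i in seq_len(n)) {
    y <- n - i + 1
    graphics::rect(0, y - 0.25, chrom_lengths[[i]] / 1e6, y + 0.25,
                   col = "grey90", border = "grey40")
    pos <- vapply(Filter(function(cl) identical(cl$chrom,
                                                names(chrom_lengths)[i]),
                         placed),
                  function(cl) cl$position, 0)
    if (length(pos))
      graphics::segments(pos / 1e6, y - 0.25, pos / 1e6, y + 0.25,
                         col = "red3")
  }
  invisible(path)
}

#' Render the insertion-frequency graph
#'
#' One panel per chromosome: window insertion counts against window
#' midpoints.
#'
#' @param profile a [frequency_profile()] result
#' @param path output PNG path
#' @param width image width in pixels
#' @return `path`, invisibly
#' @export
render_frequency_graph <- function(profile, path, width = 900) {
  stopifnot(inherits(profile, "frequency_profile"))
  n <- length(profile)
  if (n == 0L) stop("no chromosomes to draw")
  window <- attr(profile, "window")
  lens <- attr(profile, "chrom_lengths")
  grDevices::png(path, width = width, height = 140 * n + 60)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n, 1), mar = c(3, 4, 2, 1))
  ymax <- max(1, vapply(profile, function(d) max(d$count), 0))
  for (ch in names(profile)) {
    d <- profile[[ch]]
    mid <- pmin(d$start + window / 2, lens[[ch]]) / 1e6
    graphics::plot(mid, d$count, type = "l", col = "blue3",
                   xlim = c(0, max(lens) / 1e6), ylim = c(0, ymax),
                   xlab = "position (Mb)", ylab = "insertions", main = ch)
  }
  invisible(path)
}
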