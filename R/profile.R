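# Repeat-content profiling: per-position fold-over-expectation scores and a
# segmentation into repetitive regions, learned from the input genome(s)
# themselves. This honors the published output contract of genome-wide
# repeat scorers (zero at or below chance expectation, positive above it)
# without re-implementing any particular tool's internals.

#' Train a repeat-content profile on a genome set
#'
#' Counts genome-wide occurrences of every k-mer and compares them with the
#' expectation under an order-2 Markov background fitted to the same
#' sequences. The per-position score at each k-mer start is
#' `max(0, observed / max(1, expected) - 1)`: zero wherever the k-mer
#' occurs no more often than chance predicts (a k-mer seen once is never
#' repetitive), and the fold-above-expectation otherwise. In cross-species
#' mode the set simply contains several genomes, so counts are pooled over
#' all of them while scores remain per sequence.
#'
#' @param genomes a [genome_set()].
#' @param k profile k-mer size; defaults to
#'   `max(13, ceil(log4(total length)) + 2)` (capped at 24), so the chance
#'   expectation of any specific k-mer stays well below one and duplicated
#'   k-mers are genuinely surprising.
#' @param join_dist zero-score gaps up to this length are closed when
#'   segmenting repetitive regions (default 50 bp).
#' @param min_region_len repetitive regions shorter than this are dropped
#'   (default 100 bp).
#' @return object of class `repeat_profile`: list(k, scores, regions) with
#'   `scores` a per-sequence numeric vector (length = sequence length,
#'   trailing k-1 positions zero) and `regions` a per-sequence data.frame
#'   of 0-based half-open repetitive intervals.
#' @export
train_repeat_profile <- function(genomes, k = NULL, join_dist = 50,
                                 min_region_len = 100) {
  total <- sum(nchar(genomes$sequences))
  if (is.null(k)) {
    k <- max(13L, as.integer(ceiling(log(total) / log(4))) + 2L)
    k <- min(24L, k)
  }
  if (total < nchar(genomes$sequences[[1]])) stop("empty genome set")
  sc <- .profile_scores_cpp(as.list(unname(genomes$sequences)), as.integer(k))
  names(sc) <- names(genomes$sequences)
  prof <- structure(list(k = as.integer(k), scores = sc, regions = NULL,
                         join_dist = as.integer(join_dist),
                         min_region_len = as.integer(min_region_len)),
                    class = "repeat_profile")
  prof$regions <- repetitive_regions(prof, min_len = min_region_len,
                                     join_dist = join_dist)
  prof
}

#' @export
print.repeat_profile <- function(x, ...) {
  nz <- sum(vapply(x$scores, function(s) sum(s > 0), numeric(1)))
  tot <- sum(vapply(x$scores, length, numeric(1)))
  cat(sprintf("repeat_profile: k=%d, %d sequence(s), %.2f%% repetitive\n",
              x$k, length(x$scores), 100 * nz / max(1, tot)))
  invisible(x)
}

#' Segment a profile into repetitive regions
#'
#' Maximal runs of positions with positive repeat score, closing zero gaps
#' up to `join_dist` and dropping runs shorter than `min_len`.
#'
#' @param profile a [train_repeat_profile()] result (or compatible list
#'   with `scores`).
#' @param min_len minimum region length (bp).
#' @param join_dist maximum gap to close (bp).
#' @return named list of data.frames with 0-based half-open `start`, `end`.
#' @export
repetitive_regions <- function(profile, min_len = 100, join_dist = 50) {
  lapply(profile$scores, function(s) {
    r <- rle(s > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    pos <- which(r$values)
    if (length(pos) == 0) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    rs <- starts[pos]; re <- ends[pos]
    # close small gaps
    ks <- rs[1]; ke <- re[1]
    out_s <- integer(0); out_e <- integer(0)
    for (i in seq_along(rs)[-1]) {
      if (rs[i] - ke <= join_dist) {
        ke <- re[i]
      } else {
        out_s <- c(out_s, ks); out_e <- c(out_e, ke)
        ks <- rs[i]; ke <- re[i]
      }
    }
    out_s <- c(out_s, ks); out_e <- c(out_e, ke)
    keep <- (out_e - out_s) >= min_len
    data.frame(start = as.integer(out_s[keep]), end = as.integer(out_e[keep]))
  })
}

#' Fraction of repetitive positions in an interval
#'
#' `(# positions with positive repeat score) / interval length`. Used by
#' the matcher to require that a putative internal part repeats elsewhere
#' in the genome (threshold 0.33 by default there).
#'
#' @param profile a [train_repeat_profile()] result.
#' @param sequence_id sequence name.
#' @param start,end 0-based half-open interval.
#' @return fraction in [0, 1].
#' @export
repetitiveness_ratio <- function(profile, sequence_id, start, end) {
  if (end <= start) stop("empty interval")
  s <- profile$scores[[sequence_id]]
  stopifnot(!is.null(s), start >= 0, end <= length(s))
  mean(s[(start + 1L):end] > 0)
}

# index of the repetitive region containing position p (0-based), or NA
region_index_at <- function(regions, p) {
  if (nrow(regions) == 0) return(NA_integer_)
  i <- findInterval(p, regions$start)
  if (i >= 1 && p < regions$end[i]) i else NA_integer_
}

#' Read an externally produced per-position repeat-score TSV
#'
#' Adapter for plugging in repeat scores computed by an external tool.
#' The TSV must have columns `position` (0-based) and `score`; positions
#' absent from the file score 0.
#'
#' @param path TSV file.
#' @param sequence_id sequence the scores belong to.
#' @param length sequence length.
#' @param join_dist,min_region_len segmentation parameters, see
#'   [train_repeat_profile()].
#' @return a `repeat_profile` with a single sequence.
#' @export
read_repeat_scores <- function(path, sequence_id, length, join_dist = 50,
                               min_region_len = 100) {
  df <- read.table(path, header = TRUE, sep = "\t")
  s <- numeric(length)
  s[df$position + 1L] <- df$score
  prof <- structure(list(k = NA_integer_,
                         scores = stats::setNames(list(s), sequence_id),
                         regions = NULL, join_dist = as.integer(join_dist),
                         min_region_len = as.integer(min_region_len)),
                    class = "repeat_profile")
  prof$regions <- repetitive_regions(prof, min_len = min_region_len,
                                     join_dist = join_dist)
  prof
}
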