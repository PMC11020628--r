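#' Merger configuration
#'
#' The similarity margin is derived from the distribution of zero-score
#' gaps inside LTRs: mean + 3 standard deviations, covering ~99.7% of a
#' normal distribution. With the fitted values (mean 16.30 bp, sd 19.62 bp)
#' this gives 75 bp. Stretches spanning at least `keep_threshold` positions
#' are labelled `keep`, the rest `delete`.
#'
#' @param gap_mean,gap_sd fitted gap-size distribution parameters (bp).
#' @param keep_threshold minimum stretch size for a `keep` label (bp).
#' @return object of class `merger_config` with the derived
#'   `similarity_margin`.
#' @export
merger_config <- function(gap_mean = 16.30, gap_sd = 19.62,
                          keep_threshold = 16) {
  stopifnot(keep_threshold >= 1)
  structure(list(gap_mean = gap_mean, gap_sd = gap_sd,
                 keep_threshold = as.integer(keep_threshold),
                 similarity_margin = compute_margin(gap_mean, gap_sd)),
            class = "merger_config")
}

#' Similarity margin from the gap-size distribution
#'
#' `round(gap_mean + 3 * gap_sd)`: two scores are "similar" when their
#' absolute difference is strictly below this margin, and a zero-score gap
#' is bridgeable when strictly shorter than it.
#'
#' @param gap_mean,gap_sd non-negative gap statistics in bp.
#' @return margin in bp (integer).
#' @export
compute_margin <- function(gap_mean, gap_sd) {
  if (gap_mean < 0 || gap_sd < 0) stop("gap statistics must be non-negative")
  as.integer(round(gap_mean + 3 * gap_sd))
}

new_stretch <- function(start, end, height, label, members = NULL) {
  list(start = as.integer(start), end = as.integer(end),
       height = as.numeric(height), size = as.integer(end - start),
       label = label,
       members = if (is.null(members)) list(c(start, end)) else members)
}

#' Group a score track into stretches
#'
#' Step 1 of the merging procedure: maximal runs of the same exact non-zero
#' score become stretches (height = that score, size = run length); zero
#' runs become gaps. Step 2 labels stretches `keep` when their size reaches
#' `keep_threshold` (default 16), else `delete`.
#'
#' @param track a `score_track` from [score_sequence()].
#' @param config a [merger_config()].
#' @return list of stretches: each a list with `start`, `end` (0-based
#'   half-open over k-mer start positions), `height`, `size`, `label`,
#'   `members`.
#' @export
build_stretches <- function(track, config = merger_config()) {
  scores <- track$scores
  if (length(scores) == 0) return(list())
  r <- rle(scores)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    j <- j + 1L
    lab <- if (r$lengths[i] >= config$keep_threshold) "keep" else "delete"
    out[[j]] <- new_stretch(starts[i], ends[i], r$values[i], lab)
  }
  out
}

# pooled median of non-zero scores over a stretch's member intervals
pooled_height <- function(members, scores) {
  v <- unlist(lapply(members, function(m) scores[(m[1] + 1L):m[2]]))
  v <- v[v != 0]
  if (length(v) == 0) return(0)
  median(v)
}

fuse <- function(a, b, scores, keep_threshold) {
  members <- c(a$members, b$members)
  h <- pooled_height(members, scores)
  s <- new_stretch(min(a$start, b$start), max(a$end, b$end), h,
                   "keep", members)
  s$label <- if (s$size >= keep_threshold) "keep" else "delete"
  s
}

# one merging stage: repeatedly fuse the leftmost adjacent pair whose
# heights differ by less than the margin and whose gap is shorter than the
# margin, until no such pair remains (fixpoint)
merge_pass <- function(sts, scores, margin, keep_threshold) {
  i <- 1L
  while (i < length(sts)) {
    a <- sts[[i]]; b <- sts[[i + 1L]]
    gap <- b$start - a$end
    if (abs(a$height - b$height) < margin && gap < margin) {
      sts[[i]] <- fuse(a, b, scores, keep_threshold)
      sts[[i + 1L]] <- NULL
      if (i > 1L) i <- i - 1L # the new height may enable the previous pair
    } else {
      i <- i + 1L
    }
  }
  sts
}

#' Merge stretches (steps 3-7)
#'
#' Executes, in order: (3) merge adjacent similar stretches, (4) remove
#' interruptive stretches (delete-labelled stretches sitting between two
#' stretches that would merge without them), (5) re-merge, (6) remove the
#' remaining delete stretches, (7) re-merge. Merging pools the member
#' intervals, so a merged stretch's height is the median of its pooled
#' non-zero scores, and its label is recomputed from the merged size. Each
#' merging stage runs to a fixpoint, making the result scan-order
#' independent (idempotence is asserted in the test suite).
#'
#' @param stretches sorted, non-overlapping stretches of a single direction
#'   from [build_stretches()].
#' @param scores the score vector the stretches were built from.
#' @param config a [merger_config()].
#' @return list of merged stretches, all labelled `keep`.
#' @export
merge_stretches <- function(stretches, scores, config = merger_config()) {
  if (length(stretches) == 0) return(stretches)
  starts <- vapply(stretches, `[[`, integer(1), "start")
  ends <- vapply(stretches, `[[`, integer(1), "end")
  if (is.unsorted(starts) || any(head(ends, -1) > tail(starts, -1))) {
    stop("stretches must be sorted and non-overlapping")
  }
  m <- config$similarity_margin
  kt <- config$keep_threshold
  sts <- merge_pass(stretches, scores, m, kt) # step 3 (+5 fixpoint)
  # step 4: drop interruptive delete stretches
  if (length(sts) >= 3) {
    drop <- logical(length(sts))
    for (j in 2:(length(sts) - 1L)) {
      if (sts[[j]]$label != "delete") next
      a <- sts[[j - 1L]]; b <- sts[[j + 1L]]
      if (abs(a$height - b$height) < m && (b$start - a$end) < m) {
        drop[j] <- TRUE
      }
    }
    sts <- sts[!drop]
  }
  sts <- merge_pass(sts, scores, m, kt) # step 5
  sts <- Filter(function(s) s$label == "keep", sts) # step 6
  merge_pass(sts, scores, m, kt) # step 7
}

stretches_to_df <- function(stretches, direction = NA_character_) {
  if (length(stretches) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      height = numeric(0), size = integer(0),
                      label = character(0), direction = character(0)))
  }
  data.frame(start = vapply(stretches, `[[`, integer(1), "start"),
             end = vapply(stretches, `[[`, integer(1), "end"),
             height = vapply(stretches, `[[`, numeric(1), "height"),
             size = vapply(stretches, `[[`, integer(1), "size"),
             label = vapply(stretches, `[[`, character(1), "label"),
             direction = direction, stringsAsFactors = FALSE)
}

#' Write stretches as a debug TSV
#' @param stretches stretch list.
#' @param path output file.
#' @param direction direction tag for the TSV.
#' @return `path`, invisibly.
#' @export
write_stretches <- function(stretches, path, direction = NA_character_) {
  write.table(stretches_to_df(stretches, direction), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
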