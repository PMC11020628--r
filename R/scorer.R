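#' Scorer configuration
#'
#' @param k k-mer size (default 13, chosen for plant genomes).
#' @param min_dist,max_dist minimum and maximum match distance in bp
#'   (defaults 400 and 27000): matches outside this window score 0. The
#'   window brackets plausible LTR-to-LTR distances.
#' @return object of class `scorer_config`.
#' @export
scorer_config <- function(k = 13, min_dist = 400, max_dist = 27000) {
  stopifnot(k > 0, k <= 31, min_dist > 0, min_dist < max_dist)
  structure(list(k = as.integer(k), min_dist = as.integer(min_dist),
                 max_dist = as.integer(max_dist)), class = "scorer_config")
}

#' Score a sequence by bidirectional k-mer match distances
#'
#' For every k-mer start position `p` (0-based), the forward score is the
#' distance in bp to the start of the nearest identical k-mer downstream
#' whose distance lies within `[min_dist, max_dist]`, else 0; the backward
#' score is the symmetric quantity for upstream copies. The two directions
#' are computed independently, which keeps the score runs over the outer
#' LTRs of nearby same-family elements unfragmented (the "castle problem").
#' k-mers containing N are unscored (0).
#'
#' @param sequence nucleotide string.
#' @param config a [scorer_config()].
#' @param sequence_id label stored on the returned tracks.
#' @return list with `forward` and `backward`, each of class `score_track`:
#'   list(sequence_id, direction, k, scores) where `scores[i]` belongs to
#'   the k-mer starting at 0-based position `i - 1`.
#' @export
score_sequence <- function(sequence, config = scorer_config(),
                           sequence_id = "seq") {
  n <- nchar(sequence)
  if (n < config$k) {
    warning("sequence shorter than k; returning empty tracks")
    res <- list(forward = integer(0), backward = integer(0))
  } else {
    res <- .score_tracks_cpp(toupper(sequence), config$k, config$min_dist,
                             config$max_dist)
  }
  mk <- function(dir) {
    structure(list(sequence_id = sequence_id, direction = dir,
                   k = config$k, min_dist = config$min_dist,
                   max_dist = config$max_dist, scores = res[[dir]]),
              class = "score_track")
  }
  list(forward = mk("forward"), backward = mk("backward"))
}

#' @export
print.score_track <- function(x, ...) {
  nz <- sum(x$scores > 0)
  cat(sprintf("score_track (%s, %s): %d positions, %d scored (%.2f%%)\n",
              x$sequence_id, x$direction, length(x$scores), nz,
              if (length(x$scores)) 100 * nz / length(x$scores) else 0))
  invisible(x)
}

#' Dump forward/backward tracks as a TSV (position, forward, backward)
#' @param tracks result of [score_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- data.frame(position = seq_along(tracks$forward$scores) - 1L,
                   forward = tracks$forward$scores,
                   backward = tracks$backward$scores)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
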