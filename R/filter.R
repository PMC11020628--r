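# Structural confirmation filters and post-processing (lengths, LTR
# similarity, polypurine tract, MITE decoys, orphan solo removal, target
# site duplications).

#' Filter configuration
#'
#' Length bounds and alignment thresholds for the confirmation filters.
#' The Smith-Waterman scheme is match +2, mismatch -3, gap open -5,
#' gap extend -2 (blastn-like).
#'
#' @param min_ltr,max_ltr LTR length bounds: pass iff length is in
#'   `[min_ltr, max_ltr)`.
#' @param min_internal minimum internal-part length (nested spans
#'   excluded).
#' @param min_len_ratio LTR length-coverage ratio (short/long) that skips
#'   the alignment rescue.
#' @param sw_min_len,sw_min_sim local-alignment rescue thresholds for the
#'   similarity filter.
#' @param ppt_window,ppt_probe,ppt_min_align polypurine-tract search:
#'   window upstream of the 3' LTR, poly-A probe length, minimum alignment
#'   length (strictly greater than).
#' @param mite_tail,mite_min_align,mite_min_sim terminal-inverted-repeat
#'   test: tail length, minimum alignment length and similarity (both
#'   strictly greater than).
#' @param tsd_flank,tsd_min target-site duplication search: flank window
#'   and minimum duplication length.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_ltr = 200, max_ltr = 7000, min_internal = 200,
                          min_len_ratio = 0.8, sw_min_len = 80,
                          sw_min_sim = 0.80, ppt_window = 400,
                          ppt_probe = 100, ppt_min_align = 12,
                          mite_tail = 30, mite_min_align = 15,
                          mite_min_sim = 0.85, tsd_flank = 20, tsd_min = 4) {
  structure(as.list(environment()), class = "filter_config")
}

sw_align <- function(a, b) {
  # blastn-like costs: a lenient mismatch penalty lets local alignments of
  # unrelated flanks drift far past the homologous core, which breaks the
  # identity thresholds these filters rely on
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  list(length = len,
       identity = if (len > 0) Biostrings::nmatch(aln) / len else 0,
       subject_start = Biostrings::start(Biostrings::subject(aln)),
       subject_end = Biostrings::end(Biostrings::subject(aln)))
}

#' Length filter
#'
#' Both LTRs must be at least `min_ltr` and strictly less than `max_ltr`
#' bp; the internal part (with any nested child spans excluded) at least
#' `min_internal` bp.
#'
#' @param element an `element_candidate`.
#' @param config a [filter_config()].
#' @param child_spans optional list of `iv()` spans of nested children to
#'   exclude from the internal length.
#' @return TRUE/FALSE.
#' @export
check_lengths <- function(element, config = filter_config(),
                          child_spans = list()) {
  l5 <- iv_len(element$ltr5); l3 <- iv_len(element$ltr3)
  internal <- iv_len(element$internal)
  if (length(child_spans) > 0) {
    # union of child spans: grandchildren lie inside children and must not
    # be subtracted twice
    cl <- lapply(child_spans, function(cs) {
      iv(max(cs$start, element$internal$start),
         min(cs$end, element$internal$end))
    })
    cl <- Filter(function(x) x$end > x$start, cl)
    if (length(cl) > 0) {
      internal <- internal - union_length(
        vapply(cl, `[[`, integer(1), "start"),
        vapply(cl, `[[`, integer(1), "end"))
    }
  }
  l5 >= config$min_ltr && l5 < config$max_ltr &&
    l3 >= config$min_ltr && l3 < config$max_ltr &&
    internal >= config$min_internal
}

#' Similarity filter
#'
#' Pass when the LTR length-coverage ratio (shorter/longer) reaches
#' `min_len_ratio`; otherwise rescue by local alignment of the two LTRs,
#' requiring alignment length >= `sw_min_len` and identity >=
#' `sw_min_sim`.
#'
#' @param element an `element_candidate`.
#' @param sequence the nucleotide sequence.
#' @param config a [filter_config()].
#' @return TRUE/FALSE.
#' @export
check_similarity <- function(element, sequence, config = filter_config()) {
  l5 <- iv_len(element$ltr5); l3 <- iv_len(element$ltr3)
  if (min(l5, l3) / max(l5, l3) >= config$min_len_ratio) return(TRUE)
  a <- seq_slice(sequence, element$ltr5$start, element$ltr5$end)
  b <- seq_slice(sequence, element$ltr3$start, element$ltr3$end)
  aln <- sw_align(a, b)
  aln$length >= config$sw_min_len && aln$identity >= config$sw_min_sim
}

#' Polypurine tract search
#'
#' Takes the last `ppt_window` bp of the internal part upstream of the 3'
#' LTR, converts every G to A, and locally aligns a `ppt_probe`-long poly-A
#' probe against it; a PPT is confirmed when the alignment is longer than
#' `ppt_min_align` and the matched region of the original sequence holds
#' strictly more A than G. If that fails, the reversed-orientation
#' hypothesis is tried on the first `ppt_window` bp downstream of the 5'
#' LTR with C converted to T and a poly-T probe (more T than C).
#'
#' @param element an `element_candidate`.
#' @param sequence the nucleotide sequence.
#' @param config a [filter_config()].
#' @return `NULL` when no PPT is found, else a list with `interval`
#'   (0-based half-open, on the original sequence) and `strand`
#'   (`"+"` plus-strand PPT, `"-"` reversed orientation).
#' @export
find_ppt <- function(element, sequence, config = filter_config()) {
  int <- element$internal
  ilen <- iv_len(int)
  if (ilen < 1) return(NULL)
  w <- min(config$ppt_window, ilen)
  probe_hit <- function(window, from, probe_char, major, minor) {
    mapped <- chartr(minor, major, window)
    probe <- strrep(probe_char, config$ppt_probe)
    aln <- sw_align(probe, mapped)
    if (aln$length <= config$ppt_min_align) return(NULL)
    s <- from + aln$subject_start - 1L
    e <- from + aln$subject_end
    region <- seq_slice(sequence, s, e)
    n_major <- lengths(regmatches(region, gregexpr(major, region)))
    n_minor <- lengths(regmatches(region, gregexpr(minor, region)))
    if (n_major <= n_minor) return(NULL)
    list(interval = iv(s, e))
  }
  # plus strand: A/G run just upstream of the 3' LTR
  from <- int$end - w
  hit <- probe_hit(seq_slice(sequence, from, int$end), from, "A", "A", "G")
  if (!is.null(hit)) return(c(hit, strand = "+"))
  # reversed orientation: T/C run just downstream of the 5' LTR
  hit <- probe_hit(seq_slice(sequence, int$start, int$start + w), int$start,
                   "T", "T", "C")
  if (!is.null(hit)) return(c(hit, strand = "-"))
  NULL
}

#' MITE filter
#'
#' Tests each LTR for the terminal-inverted-repeat signature of a MITE:
#' the first `mite_tail` bp aligned against the reverse complement of the
#' last `mite_tail` bp, MITE-like iff alignment length > `mite_min_align`
#' and identity > `mite_min_sim`. The element is dropped only when BOTH
#' LTRs are MITE-like.
#'
#' @param element an `element_candidate`.
#' @param sequence the nucleotide sequence.
#' @param config a [filter_config()].
#' @return TRUE when the element is a MITE pair (i.e. should be dropped).
#' @export
is_mite <- function(element, sequence, config = filter_config()) {
  tir_like <- function(ltr) {
    if (iv_len(ltr) < 2 * config$mite_tail) return(FALSE)
    head_seq <- seq_slice(sequence, ltr$start, ltr$start + config$mite_tail)
    tail_seq <- seq_slice(sequence, ltr$end - config$mite_tail, ltr$end)
    aln <- sw_align(head_seq, revcomp(tail_seq))
    aln$length > config$mite_min_align && aln$identity > config$mite_min_sim
  }
  tir_like(element$ltr5) && tir_like(element$ltr3)
}

#' Orphan solo removal
#'
#' A solo LTR is kept only when its connected component contains at least
#' one element that survived filtering.
#'
#' @param solos list of solo intervals.
#' @param solo_components component id per solo.
#' @param surviving_components component ids holding >= 1 surviving
#'   element.
#' @return logical keep vector.
#' @export
drop_orphan_solos <- function(solos, solo_components, surviving_components) {
  solo_components %in% surviving_components
}

# longest common substring of two short strings; returns all maximal hits
lcs_hits <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0 || nb == 0) return(list(len = 0L))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  L <- matrix(0L, na + 1, nb + 1)
  best <- 0L; hits <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (av[i] == bv[j]) {
        L[i + 1, j + 1] <- L[i, j] + 1L
        if (L[i + 1, j + 1] > best) {
          best <- L[i + 1, j + 1]
          hits <- list(c(i, j))
        } else if (L[i + 1, j + 1] == best) {
          hits[[length(hits) + 1L]] <- c(i, j)
        }
      }
    }
  }
  list(len = best, ends = hits) # 1-based inclusive end positions
}

#' Target-site duplication search
#'
#' Looks at the `tsd_flank` bp immediately upstream and downstream of the
#' element for the longest common substring; a duplication of length >=
#' `tsd_min` is reported as the TSD and the element boundaries are widened
#' to touch it. Ties between equally long substrings resolve to the pair
#' closest to the element boundaries.
#'
#' @param element an `element_candidate`.
#' @param sequence the nucleotide sequence.
#' @param config a [filter_config()].
#' @return `NULL` when no TSD is found, else list(tsd5, tsd3, element)
#'   with the TSD intervals and the (possibly widened) element.
#' @export
find_tsd <- function(element, sequence, config = filter_config()) {
  n <- nchar(sequence)
  up_start <- max(0L, element$start - config$tsd_flank)
  dn_end <- min(n, element$end + config$tsd_flank)
  up <- seq_slice(sequence, up_start, element$start)
  dn <- seq_slice(sequence, element$end, dn_end)
  res <- lcs_hits(up, dn)
  if (res$len < config$tsd_min) return(NULL)
  # tie-break: upstream copy as close to the element start as possible,
  # downstream copy as close to the element end
  cost <- vapply(res$ends, function(e) {
    (nchar(up) - e[1]) + (e[2] - res$len)
  }, numeric(1))
  e <- res$ends[[which.min(cost)]]
  tsd5 <- iv(up_start + e[1] - res$len, up_start + e[1])
  tsd3 <- iv(element$end + e[2] - res$len, element$end + e[2])
  if (tsd5$end < element$start) {
    element$ltr5$start <- tsd5$end
    element$start <- tsd5$end
  }
  if (tsd3$start > element$end) {
    element$ltr3$end <- tsd3$start
    element$end <- tsd3$start
  }
  element$internal <- iv(element$ltr5$end, element$ltr3$start)
  list(tsd5 = tsd5, tsd3 = tsd3, element = element)
}
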