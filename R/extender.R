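# Boundary sharpening before filtering: k-mer extension and
# missing-region extension.

#' Extend the 3' LTR by k-1 bp
#'
#' The last score of a candidate belongs to its last k-mer, not its last
#' nucleotide, so the 3' LTR end is short by k-1 bp; this restores it
#' (clamped at the sequence end). Nothing else changes.
#'
#' @param element an `element_candidate`.
#' @param k scorer k-mer size.
#' @param seq_length length of the underlying sequence.
#' @return the adjusted element.
#' @export
kmer_extend <- function(element, k, seq_length) {
  new_end <- element$ltr3$end + k - 1L
  if (new_end > seq_length) {
    warning("3' LTR extension clamped at sequence end")
    new_end <- seq_length
  }
  element$ltr3$end <- as.integer(new_end)
  element$end <- element$ltr3$end
  element
}

ltr_identity <- function(element, sequence, model) {
  a <- seq_slice(sequence, element$ltr5$start, element$ltr5$end)
  b <- seq_slice(sequence, element$ltr3$start, element$ltr3$end)
  global_identity(a, b, model)
}

#' Extend the shorter LTR to match the longer one
#'
#' When the paired LTRs differ in length (usually from failed stretch
#' merging), the shorter one is tentatively extended backward and forward
#' by the missing length; each tentative extension is kept only if it
#' strictly improves the identity between the paired LTRs under the
#' standard model. The extension never crosses the partner LTR or the
#' sequence bounds, and never makes the length difference worse.
#'
#' @param element an `element_candidate`.
#' @param sequence the nucleotide sequence.
#' @param model standard [identity_model()].
#' @return the adjusted element.
#' @export
missing_region_extend <- function(element, sequence,
                                  model = identity_model("standard")) {
  len5 <- iv_len(element$ltr5); len3 <- iv_len(element$ltr3)
  if (len5 == len3) return(element)
  short <- if (len5 < len3) "ltr5" else "ltr3"
  long <- if (short == "ltr5") "ltr3" else "ltr5"
  diff <- abs(len5 - len3)
  base <- ltr_identity(element, sequence, model)
  lo_bound <- if (short == "ltr5") 0L else element$ltr5$end
  hi_bound <- if (short == "ltr5") element$ltr3$start else nchar(sequence)
  # a genuine missing region resembles the corresponding terminus of the
  # longer LTR; an extension into unrelated sequence does not, even though
  # it can nudge the global matches/length ratio upward by chance
  snippet_ok <- function(el, side) {
    s <- el[[short]]
    snip <- if (side == "back") seq_slice(sequence, s$start, s$start + diff)
            else seq_slice(sequence, s$end - diff, s$end)
    l <- element[[long]]
    ref <- if (side == "back") seq_slice(sequence, l$start, l$start + diff)
           else seq_slice(sequence, l$end - diff, l$end)
    nchar(snip) > 0 && nchar(ref) > 0 &&
      global_identity(snip, ref, model) > 0.5
  }
  cand <- list()
  back <- element
  back[[short]]$start <- max(lo_bound, back[[short]]$start - diff)
  if (snippet_ok(back, "back")) cand$back <- back
  fwd <- element
  fwd[[short]]$end <- min(hi_bound, fwd[[short]]$end + diff)
  if (snippet_ok(fwd, "fwd")) cand$fwd <- fwd
  best <- element; best_id <- base
  for (c in cand) {
    idc <- ltr_identity(c, sequence, model)
    if (idc > best_id) { best <- c; best_id <- idc }
  }
  best$internal <- iv(best$ltr5$end, best$ltr3$start)
  best$start <- best$ltr5$start
  best$end <- best$ltr3$end
  best
}
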