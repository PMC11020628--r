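#' Identity model
#'
#' Pairwise global identity scoring with two operating ranges: the
#' `standard` model is trusted on pairs of 80-100% identity, the `recent`
#' model on 60-100% (used when comparing internal parts of recently nested
#' elements, whose divergence may be inflated by foreign insertions). The
#' default method computes exact global (Needleman-Wunsch) identity; the
#' `kmer` method is a fast alignment-free estimator contracted to agree
#' with the exact value within +/- 0.05 inside the model's trusted range.
#'
#' @param mode `"standard"` or `"recent"`.
#' @param method `"exact"` or `"kmer"`.
#' @param k sketch k-mer size for the `kmer` method.
#' @return object of class `identity_model`.
#' @export
identity_model <- function(mode = c("standard", "recent"),
                           method = c("exact", "kmer"), k = 15) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  range <- if (mode == "standard") c(0.80, 1.0) else c(0.60, 1.0)
  structure(list(mode = mode, method = method, k = as.integer(k),
                 trusted_range = range), class = "identity_model")
}

nw_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / len
}

kmer_identity <- function(a, b, k) {
  km <- function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    unique(substring(s, 1:n, k:(n + k - 1)))
  }
  ka <- km(a); kb <- km(b)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  inter <- length(intersect(ka, kb))
  j <- inter / (length(ka) + length(kb) - inter)
  if (j <= 0) return(0)
  # Mash-style Jaccard-to-identity conversion
  max(0, min(1, 1 + log(2 * j / (1 + j)) / k))
}

#' Global identity of two sequences
#'
#' Exact method: matches / alignment-length from global alignment with
#' match +1, mismatch -1, gap -2 per gapped position. Values in [0, 1].
#'
#' @param a,b nucleotide strings (non-empty).
#' @param model an [identity_model()].
#' @return identity fraction in [0, 1].
#' @export
global_identity <- function(a, b, model = identity_model()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (model$method == "kmer") kmer_identity(a, b, model$k) else
    nw_identity(a, b)
}
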