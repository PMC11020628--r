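# Evaluation: reciprocal-overlap true positives, family-aware false
# positives, recall/precision/F1, and genome coverage.

ann_df <- function(x) {
  if (is.data.frame(x)) return(x)
  annotations_to_df(x)
}

#' Match predictions to truth by 80% reciprocal overlap
#'
#' A prediction is a true positive iff it overlaps some truth element by
#' at least `threshold` of its own length AND `threshold` of the truth
#' element's length. Matching is one-to-one greedy by decreasing overlap,
#' ties resolved to the larger overlap then to the leftmost pair.
#'
#' @param predictions,truth data.frames (or annotation lists) with
#'   `sequence_id`, `start`, `end`.
#' @param threshold reciprocal-overlap threshold (default 0.8).
#' @return data.frame of matched pairs: `pred` and `truth` row indices and
#'   the `overlap` in bp.
#' @export
true_positives <- function(predictions, truth, threshold = 0.8) {
  p <- ann_df(predictions); t <- ann_df(truth)
  pairs <- list()
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(t))) {
      if (p$sequence_id[i] != t$sequence_id[j]) next
      ov <- max(0, min(p$end[i], t$end[j]) - max(p$start[i], t$start[j]))
      if (ov >= threshold * (p$end[i] - p$start[i]) &&
          ov >= threshold * (t$end[j] - t$start[j])) {
        pairs[[length(pairs) + 1L]] <- c(i, j, ov)
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(pred = integer(0), truth = integer(0),
                      overlap = integer(0)))
  }
  m <- do.call(rbind, pairs)
  m <- m[order(-m[, 3], m[, 1], m[, 2]), , drop = FALSE]
  used_p <- logical(nrow(p)); used_t <- logical(nrow(t))
  keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    if (!used_p[m[r, 1]] && !used_t[m[r, 2]]) {
      keep[r] <- TRUE
      used_p[m[r, 1]] <- TRUE; used_t[m[r, 2]] <- TRUE
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(pred = m[, 1], truth = m[, 2], overlap = m[, 3])
}

#' Count false positives against a family-labelled repeat dataset
#'
#' A prediction counts as a false positive iff each of its two LTRs has an
#' 80% reciprocal overlap with an element of the false-positive dataset
#' and both matched elements carry the same family label.
#'
#' @param predictions data.frame with `sequence_id`, `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end` (as from [annotations_to_df()]).
#' @param fp_dataset data.frame with `sequence_id`, `start`, `end`,
#'   `family`.
#' @param threshold reciprocal-overlap threshold (default 0.8).
#' @return number of false positives.
#' @export
false_positives <- function(predictions, fp_dataset, threshold = 0.8) {
  p <- ann_df(predictions)
  if (nrow(p) == 0 || nrow(fp_dataset) == 0) return(0L)
  match_fam <- function(s, e, sid) {
    for (j in seq_len(nrow(fp_dataset))) {
      if (fp_dataset$sequence_id[j] != sid) next
      ov <- max(0, min(e, fp_dataset$end[j]) - max(s, fp_dataset$start[j]))
      if (ov >= threshold * (e - s) &&
          ov >= threshold * (fp_dataset$end[j] - fp_dataset$start[j])) {
        return(fp_dataset$family[j])
      }
    }
    NA_character_
  }
  n <- 0L
  for (i in seq_len(nrow(p))) {
    if (is.na(p$ltr5_start[i]) || is.na(p$ltr3_start[i])) next
    f5 <- match_fam(p$ltr5_start[i], p$ltr5_end[i], p$sequence_id[i])
    f3 <- match_fam(p$ltr3_start[i], p$ltr3_end[i], p$sequence_id[i])
    if (!is.na(f5) && !is.na(f3) && f5 == f3) n <- n + 1L
  }
  n
}

#' Recall, precision and F1
#'
#' `recall = TP / truth_count`; `precision = TP / (TP + FP)` (computed
#' over confirmed positives); `F1 = 2PR / (P + R)`; 0 when undefined.
#'
#' @param tp,fp true/false positive counts.
#' @param truth_count number of truth elements.
#' @return named vector (fractions in [0, 1]).
#' @export
prediction_metrics <- function(tp, fp, truth_count) {
  recall <- if (truth_count > 0) tp / truth_count else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(recall = recall, precision = precision, f1 = f1)
}

#' Genome coverage of annotated elements
#'
#' Union length of element intervals divided by total genome length, plus
#' the same restricted to nested elements (nesting_level >= 1).
#'
#' @param annotations list of [annotation()]s or their data.frame.
#' @param genome a [genome_set()].
#' @return named vector `coverage` and `nested_coverage` (fractions).
#' @export
coverage <- function(annotations, genome) {
  df <- ann_df(annotations)
  df <- df[df$kind == "element", , drop = FALSE]
  total <- sum(nchar(genome$sequences))
  cov_of <- function(d) {
    if (nrow(d) == 0) return(0)
    s <- 0L
    for (sid in unique(d$sequence_id)) {
      dd <- d[d$sequence_id == sid, ]
      s <- s + union_length(dd$start, dd$end)
    }
    s / total
  }
  c(coverage = cov_of(df),
    nested_coverage = cov_of(df[df$nesting_level >= 1, , drop = FALSE]))
}

#' Evaluate predictions against a truth set
#'
#' Convenience wrapper: true positives at 80% reciprocal overlap over
#' elements, optional family-aware false positives, and the resulting
#' metrics.
#'
#' @param predictions,truth annotation lists or data.frames.
#' @param fp_dataset optional family-labelled repeat data.frame.
#' @param threshold reciprocal-overlap threshold.
#' @return list with `tp_pairs`, `tp`, `fp`, `metrics`.
#' @export
evaluate_predictions <- function(predictions, truth, fp_dataset = NULL,
                                 threshold = 0.8) {
  p <- ann_df(predictions); t <- ann_df(truth)
  p <- p[p$kind == "element", , drop = FALSE]
  t <- t[t$kind == "element", , drop = FALSE]
  tp_pairs <- true_positives(p, t, threshold)
  fp <- if (is.null(fp_dataset)) {
    # without a family-labelled repeat set, count unmatched predictions
    nrow(p) - nrow(tp_pairs)
  } else {
    false_positives(p, fp_dataset, threshold)
  }
  list(tp_pairs = tp_pairs, tp = nrow(tp_pairs), fp = fp,
       truth_count = nrow(t), prediction_count = nrow(p),
       metrics = prediction_metrics(nrow(tp_pairs), fp, nrow(t)))
}
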