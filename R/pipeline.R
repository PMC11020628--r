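# End-to-end detection pipeline: scorer -> merger -> detector -> matcher
# (with splice-and-recurse deep-nesting resolution) -> extender -> filters
# -> TSD post-processing.

lift_point <- function(p, origmap) origmap[p + 1L]

lift_interval <- function(x, origmap) {
  # hull of the original positions a (possibly spliced) interval maps to
  iv(origmap[x$start + 1L], origmap[x$end] + 1L)
}

lift_element <- function(el, origmap) {
  el$ltr5 <- lift_interval(el$ltr5, origmap)
  el$ltr3 <- lift_interval(el$ltr3, origmap)
  el$internal <- iv(el$ltr5$end, el$ltr3$start)
  el$start <- el$ltr5$start
  el$end <- el$ltr3$end
  el
}

profile_view <- function(profile, sequence_id, origmap) {
  s <- profile$scores[[sequence_id]][origmap + 1L]
  pv <- structure(list(k = profile$k,
                       scores = stats::setNames(list(s), sequence_id),
                       regions = NULL, join_dist = profile$join_dist,
                       min_region_len = profile$min_region_len),
                  class = "repeat_profile")
  pv$regions <- repetitive_regions(pv, min_len = profile$min_region_len,
                                   join_dist = profile$join_dist)
  pv
}

run_stage <- function(sequence, sequence_id, prof, model, scorer_cfg,
                      merger_cfg, matcher_cfg, id_std, id_rec) {
  tracks <- score_sequence(sequence, scorer_cfg, sequence_id)
  f_str <- merge_stretches(build_stretches(tracks$forward, merger_cfg),
                           tracks$forward$scores, merger_cfg)
  b_str <- merge_stretches(build_stretches(tracks$backward, merger_cfg),
                           tracks$backward$scores, merger_cfg)
  fc <- assemble_candidates(f_str, model, prof, sequence_id, "forward")
  bc <- assemble_candidates(b_str, model, prof, sequence_id, "backward")
  graph <- build_match_graph(fc, bc, tracks, sequence, sequence_id)
  graph <- trim_hyperextension(graph, sequence, matcher_cfg)
  res <- resolve_components(graph, prof, sequence, matcher_cfg, id_std,
                            id_rec)
  list(tracks = tracks, stretches = list(forward = f_str, backward = b_str),
       candidates = list(forward = fc, backward = bc), graph = graph,
       resolved = res, k = tracks$forward$k)
}

extend_element <- function(el, k, sequence, id_std) {
  el <- kmer_extend(el, k, nchar(sequence))
  missing_region_extend(el, sequence, id_std)
}

detect_sequence <- function(sequence, sequence_id, profile, model,
                            scorer_cfg, merger_cfg, matcher_cfg, filter_cfg,
                            id_std, id_rec, verbose = FALSE) {
  n <- nchar(sequence)
  origmap <- 0:(n - 1L)
  cur <- sequence
  harvested <- list()
  depth <- 0L
  final <- NULL
  repeat {
    prof <- profile_view(profile, sequence_id, origmap)
    st <- run_stage(cur, sequence_id, prof, model, scorer_cfg, merger_cfg,
                    matcher_cfg, id_std, id_rec)
    res <- st$resolved
    if (verbose) {
      message(sprintf(
        "[%s depth %d] stretches f/b: %d/%d, candidates f/b: %d/%d, components: %d, elements: %d, solos: %d",
        sequence_id, depth, length(st$stretches$forward),
        length(st$stretches$backward), nrow(st$candidates$forward),
        nrow(st$candidates$backward),
        length(unique(st$graph$comp)), length(res$elements),
        length(res$solos)))
    }
    if (length(res$nested) > 0 && depth < matcher_cfg$recursion_depth) {
      # harvest the inner elements, splice them out, and go around again:
      # the outer elements become contiguous and resolve as singles later
      inners <- res$elements[res$nested]
      spans <- list()
      for (el in inners) {
        el <- extend_element(el, st$k, cur, id_std)
        spans[[length(spans) + 1L]] <- iv(el$start, el$end)
        harvested[[length(harvested) + 1L]] <- lift_element(el, origmap)
      }
      spans <- spans[order(-vapply(spans, `[[`, integer(1), "start"))]
      drop_idx <- integer(0)
      for (sp in spans) {
        drop_idx <- c(drop_idx, (sp$start + 1L):sp$end)
      }
      origmap <- origmap[-drop_idx]
      keep <- setdiff(seq_len(nchar(cur)), drop_idx)
      cur <- paste(strsplit(cur, "")[[1]][keep], collapse = "")
      depth <- depth + 1L
      next
    }
    final <- list(stage = st, origmap = origmap, cur = cur)
    break
  }

  st <- final$stage
  res <- st$resolved
  origmap <- final$origmap
  elements <- harvested
  element_comp <- rep(NA_integer_, length(harvested))
  for (i in seq_along(res$elements)) {
    if (i %in% res$nested) next # already harvested in an earlier round
    el <- extend_element(res$elements[[i]], st$k, final$cur, id_std)
    elements[[length(elements) + 1L]] <- lift_element(el, origmap)
    element_comp <- c(element_comp, res$element_component[i])
  }
  solos <- lapply(res$solos, lift_interval, origmap = origmap)
  complexes <- lapply(res$complex_regions, lift_interval, origmap = origmap)

  # containment-based nesting levels and child spans on original coords
  nel <- length(elements)
  level <- integer(nel)
  children <- vector("list", nel)
  if (nel > 1) {
    for (i in seq_len(nel)) {
      for (j in seq_len(nel)) {
        if (i == j) next
        if (elements[[j]]$start <= elements[[i]]$start &&
            elements[[j]]$end >= elements[[i]]$end &&
            (elements[[j]]$end - elements[[j]]$start) >
            (elements[[i]]$end - elements[[i]]$start)) {
          level[i] <- level[i] + 1L
          children[[j]] <- c(children[[j]], i)
        }
      }
    }
  }

  # structural filters on the original sequence
  keep <- logical(nel)
  ppt_hits <- vector("list", nel)
  for (i in seq_len(nel)) {
    el <- elements[[i]]
    spans <- lapply(children[[i]] %||% integer(0), function(j) {
      iv(elements[[j]]$start, elements[[j]]$end)
    })
    if (!check_lengths(el, filter_cfg, spans)) next
    if (!check_similarity(el, sequence, filter_cfg)) next
    ppt <- find_ppt(el, sequence, filter_cfg)
    if (is.null(ppt)) next
    if (is_mite(el, sequence, filter_cfg)) next
    keep[i] <- TRUE
    ppt_hits[[i]] <- ppt
  }

  # orphan solos: a solo survives only if its component kept an element
  comp_span <- lapply(unique(st$graph$comp), function(cid) {
    nidx <- which(st$graph$comp == cid)
    lift_interval(iv(min(st$graph$nodes$start[nidx]),
                     max(st$graph$nodes$end[nidx])), origmap)
  })
  names(comp_span) <- as.character(unique(st$graph$comp))
  solo_keep <- vapply(seq_along(solos), function(si) {
    cid <- as.character(res$solo_component[si])
    span <- comp_span[[cid]]
    any(vapply(which(keep), function(ei) {
      iv_overlap(span, iv(elements[[ei]]$start, elements[[ei]]$end)) > 0
    }, logical(1)))
  }, logical(1))

  # TSD post-processing on survivors
  anns <- list()
  for (i in which(keep)) {
    el <- elements[[i]]
    tsd <- find_tsd(el, sequence, filter_cfg)
    tsd_pair <- NULL
    if (!is.null(tsd)) {
      el <- tsd$element
      tsd_pair <- list(tsd$tsd5, tsd$tsd3)
    }
    ppt <- ppt_hits[[i]]
    anns[[length(anns) + 1L]] <-
      annotation(sequence_id, el$start, el$end, ltr5 = el$ltr5,
                 ltr3 = el$ltr3, ppt = ppt$interval,
                 ppt_strand = ppt$strand, tsd = tsd_pair,
                 nesting_level = level[i], kind = "element",
                 id = sprintf("%s_el%03d", sequence_id, i))
  }
  for (si in which(solo_keep)) {
    s <- solos[[si]]
    anns[[length(anns) + 1L]] <-
      annotation(sequence_id, s$start, s$end, ltr5 = s, kind = "solo_ltr",
                 id = sprintf("%s_solo%03d", sequence_id, si))
  }
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    anns[[length(anns) + 1L]] <-
      annotation(sequence_id, cx$start, cx$end, kind = "complex_region",
                 id = sprintf("%s_cx%03d", sequence_id, ci))
  }
  anns
}

#' Detect LTR retrotransposons in a genome set
#'
#' Full pipeline: a repeat-content profile is trained once on the whole
#' set (pooling counts across genomes in cross-species mode), then each
#' sequence is scored by bidirectional k-mer match distances, score runs
#' are merged into stretches and assembled into candidate LTRs by the
#' merge classifier, candidates are paired in the match graph and resolved
#' case by case (single / solo / recently nested / complex), deep nests
#' are peeled by splicing resolved inner elements out and re-running the
#' scorer through the matcher on the spliced sequence, and surviving
#' elements are boundary-extended, filtered (length, LTR similarity, PPT,
#' MITE) and annotated with target-site duplications.
#'
#' @param genomes a [genome_set()] (or path(s) to FASTA files).
#' @param model a `merge_model`; defaults to the packaged model.
#' @param profile optional pre-trained [train_repeat_profile()]; computed
#'   from `genomes` when `NULL`.
#' @param scorer_cfg,merger_cfg,matcher_cfg,filter_cfg module
#'   configurations.
#' @param verbose emit per-stage counts.
#' @return list of [annotation()]s across all sequences.
#' @export
detect_ltrs <- function(genomes, model = default_merge_model(),
                        profile = NULL, scorer_cfg = scorer_config(),
                        merger_cfg = merger_config(),
                        matcher_cfg = matcher_config(),
                        filter_cfg = filter_config(), verbose = FALSE) {
  if (is.character(genomes)) genomes <- read_fasta(genomes)
  if (is.null(profile)) profile <- train_repeat_profile(genomes)
  id_std <- identity_model("standard")
  id_rec <- identity_model("recent")
  anns <- list()
  for (sid in names(genomes$sequences)) {
    anns <- c(anns, detect_sequence(genomes$sequences[[sid]], sid, profile,
                                    model, scorer_cfg, merger_cfg,
                                    matcher_cfg, filter_cfg, id_std, id_rec,
                                    verbose = verbose))
  }
  anns
}

#' Build labelled training pairs for the merge classifier
#'
#' Runs the scorer and merger on a truth-set genome (typically a
#' semi-synthetic one) and labels each consecutive pair of merged
#' stretches by whether both stretches lie mostly (>= 50%) inside the same
#' truth LTR interval.
#'
#' @param truth_set a [generate_genome()] result (or compatible list with
#'   `genome` and `annotations`).
#' @param profile optional repeat profile; trained on the truth genome
#'   when `NULL`.
#' @param scorer_cfg,merger_cfg configurations.
#' @return list with `features` (matrix) and `labels` (logical).
#' @export
merge_training_data <- function(truth_set, profile = NULL,
                                scorer_cfg = scorer_config(),
                                merger_cfg = merger_config()) {
  g <- truth_set$genome
  if (is.null(profile)) profile <- train_repeat_profile(g)
  ltrs <- list()
  for (a in truth_set$annotations) {
    if (!is.null(a$ltr5)) {
      ltrs[[length(ltrs) + 1L]] <- c(a$sequence_id, a$ltr5$start, a$ltr5$end)
    }
    if (!is.null(a$ltr3)) {
      ltrs[[length(ltrs) + 1L]] <- c(a$sequence_id, a$ltr3$start, a$ltr3$end)
    }
  }
  ltr_of <- function(sid, s, e) {
    for (li in seq_along(ltrs)) {
      l <- ltrs[[li]]
      if (l[1] != sid) next
      ov <- max(0, min(e, as.integer(l[3])) - max(s, as.integer(l[2])))
      if (ov >= 0.5 * (e - s)) return(li)
    }
    NA_integer_
  }
  feats <- list(); labs <- logical(0)
  for (sid in names(g$sequences)) {
    tracks <- score_sequence(g$sequences[[sid]], scorer_cfg, sid)
    for (dir in c("forward", "backward")) {
      str <- merge_stretches(build_stretches(tracks[[dir]], merger_cfg),
                             tracks[[dir]]$scores, merger_cfg)
      if (length(str) < 2) next
      for (i in seq_len(length(str) - 1)) {
        f <- featurize_pair(str[[i]], str[[i + 1]], profile, sid)
        l1 <- ltr_of(sid, str[[i]]$start, str[[i]]$end)
        l2 <- ltr_of(sid, str[[i + 1]]$start, str[[i + 1]]$end)
        feats[[length(feats) + 1L]] <- f
        labs <- c(labs, !is.na(l1) && !is.na(l2) && l1 == l2)
      }
    }
  }
  list(features = do.call(rbind, feats), labels = labs)
}
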