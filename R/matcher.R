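# Matcher: builds the directed-weighted graph over candidate LTRs, repairs
# hyper-extension, and resolves each connected component into element
# candidates, solo LTRs and complex regions.

#' Matcher configuration
#'
#' @param min_edge_weight minimum edge weight (shared k-mer fraction) for a
#'   matched pair, default 0.27 (95th-percentile calibration).
#' @param min_internal_ratio minimum repetitiveness ratio of an internal
#'   part, default 0.33 (98th-percentile calibration).
#' @param nested_min_identity minimum identity between inner and outer
#'   internal parts of a recently nested pair (recent model), default 0.60.
#' @param complex_min_identity minimum identity between inter-node regions
#'   for a complex (sequential) call (standard model), default 0.80.
#' @param trim_ratio hyper-extension trigger: trim when the lower edge
#'   weight is below `trim_ratio` times the higher one.
#' @param recursion_depth maximum deep-nesting recursion depth.
#' @return object of class `matcher_config`.
#' @export
matcher_config <- function(min_edge_weight = 0.27, min_internal_ratio = 0.33,
                           nested_min_identity = 0.60,
                           complex_min_identity = 0.80, trim_ratio = 0.5,
                           recursion_depth = 5) {
  stopifnot(min_edge_weight >= 0, min_edge_weight <= 1,
            min_internal_ratio >= 0, min_internal_ratio <= 1)
  structure(list(min_edge_weight = min_edge_weight,
                 min_internal_ratio = min_internal_ratio,
                 nested_min_identity = nested_min_identity,
                 complex_min_identity = complex_min_identity,
                 trim_ratio = trim_ratio,
                 recursion_depth = as.integer(recursion_depth)),
            class = "matcher_config")
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) {
  while (p[i] != i) i <- p[i]
  i
}
uf_union <- function(p, a, b) {
  ra <- uf_find(p, a); rb <- uf_find(p, b)
  if (ra != rb) p[ra] <- rb
  p
}

# k-mer strings of the sequence region [start, end) (0-based half-open)
kmer_strings <- function(sequence, start, end, k) {
  n <- end - start - k + 1
  if (n < 1) return(character(0))
  st <- start + seq_len(n) - 1L
  substring(sequence, st + 1L, st + k)
}

node_weight <- function(sequence, src, tgt, k) {
  .kmer_fraction_shared_cpp(sequence, src$start, src$end + k - 1L,
                            tgt$start, tgt$end + k - 1L, k)
}

#' Build the directed-weighted match graph
#'
#' Every candidate LTR becomes a node (forward or backward). A forward node
#' gets an edge to each backward node that contains at least one of the
#' positions its scores point at (position + score), and vice versa; no
#' edges join two nodes of the same direction. Edge weight = fraction of
#' the source candidate's k-mers having an exact copy in the target.
#' Overlapping forward/backward nodes are joined by unweighted vertical
#' connections (they represent the same physical LTR). Components are
#' computed over weighted edges and vertical connections together.
#'
#' @param fwd,bwd candidate data.frames from [assemble_candidates()].
#' @param tracks score tracks from [score_sequence()].
#' @param sequence the nucleotide sequence the candidates lie on.
#' @param sequence_id sequence name.
#' @return object of class `match_graph`: nodes, edges, verticals,
#'   component ids.
#' @export
build_match_graph <- function(fwd, bwd, tracks, sequence,
                              sequence_id = "seq") {
  k <- tracks$forward$k
  nf <- nrow(fwd); nb <- nrow(bwd)
  nodes <- data.frame(
    direction = c(rep("forward", nf), rep("backward", nb)),
    start = c(fwd$start, bwd$start), end = c(fwd$end, bwd$end),
    stringsAsFactors = FALSE)
  n <- nrow(nodes)
  edges <- data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0))
  # a candidate points where its stretches' heights indicate: for each
  # member stretch, the span [start + height, end + height) (mirrored for
  # backward candidates) must land inside the target node
  cand_stretches <- c(fwd$stretches, bwd$stretches)
  add_edges <- function(src_rows, tgt_rows, sign) {
    res <- list()
    if (length(src_rows) == 0 || length(tgt_rows) == 0) return(res)
    for (i in src_rows) {
      hits <- integer(0)
      for (st in cand_stretches[[i]]) {
        lo <- st$start + sign * st$height
        hi <- st$end + sign * st$height
        ov <- tgt_rows[pmin(hi, nodes$end[tgt_rows]) >
                         pmax(lo, nodes$start[tgt_rows])]
        hits <- union(hits, ov)
      }
      for (tgt in hits) res[[length(res) + 1L]] <- c(i, tgt)
    }
    res
  }
  fr <- which(nodes$direction == "forward")
  br <- which(nodes$direction == "backward")
  pairs <- c(add_edges(fr, br, +1L), add_edges(br, fr, -1L))
  if (length(pairs) > 0) {
    em <- do.call(rbind, pairs)
    w <- vapply(seq_len(nrow(em)), function(r) {
      node_weight(sequence, as.list(nodes[em[r, 1], ]),
                  as.list(nodes[em[r, 2], ]), k)
    }, numeric(1))
    edges <- data.frame(from = em[, 1], to = em[, 2], weight = w)
  }
  verticals <- data.frame(a = integer(0), b = integer(0))
  if (nf > 0 && nb > 0) {
    vp <- list()
    for (i in fr) {
      ov <- br[pmin(nodes$end[i], nodes$end[br]) >
                 pmax(nodes$start[i], nodes$start[br])]
      for (j in ov) vp[[length(vp) + 1L]] <- c(i, j)
    }
    if (length(vp)) {
      vm <- do.call(rbind, vp)
      verticals <- data.frame(a = vm[, 1], b = vm[, 2])
    }
  }
  p <- uf_new(n)
  for (r in seq_len(nrow(edges))) p <- uf_union(p, edges$from[r], edges$to[r])
  for (r in seq_len(nrow(verticals))) {
    p <- uf_union(p, verticals$a[r], verticals$b[r])
  }
  comp <- vapply(seq_len(n), function(i) uf_find(p, i), integer(1))
  comp <- match(comp, unique(comp))
  structure(list(nodes = nodes, edges = edges, verticals = verticals,
                 comp = if (n > 0) comp else integer(0), k = k,
                 sequence_id = sequence_id),
            class = "match_graph")
}

#' @export
print.match_graph <- function(x, ...) {
  cat(sprintf(
    "match_graph: %d nodes, %d edges, %d verticals, %d component(s)\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$verticals),
    length(unique(x$comp))))
  invisible(x)
}

#' Repair hyper-extension by trimming asymmetric node pairs
#'
#' A candidate wrongly fused with a neighboring unrelated repeat shows up
#' as a mutually connected pair whose two edge weights are strongly
#' asymmetric. When the lower weight falls below `trim_ratio` times the
#' higher one, the node the low-weight edge comes from is trimmed to the
#' sub-interval whose k-mers actually match the partner, and all weights
#' touching that node are recomputed. Trimming never widens a node.
#'
#' @param graph a [build_match_graph()] result.
#' @param sequence the underlying nucleotide sequence.
#' @param config a [matcher_config()].
#' @return the repaired `match_graph`.
#' @export
trim_hyperextension <- function(graph, sequence, config = matcher_config()) {
  e <- graph$edges
  if (nrow(e) < 2) return(graph)
  for (src in seq_len(nrow(graph$nodes))) {
    # judge a node only against its best mutual partner: the one whose
    # return edge carries the highest weight
    out <- which(graph$edges$from == src)
    if (length(out) == 0) next
    partners <- graph$edges$to[out]
    back_w <- vapply(partners, function(b) {
      r <- which(graph$edges$from == b & graph$edges$to == src)
      if (length(r) == 0) NA_real_ else max(graph$edges$weight[r])
    }, numeric(1))
    if (all(is.na(back_w))) next
    best <- which.max(back_w)
    w1 <- graph$edges$weight[out[best]] # src -> best partner
    w2 <- back_w[best]                  # best partner -> src
    tgt <- partners[best]
    if (max(w1, w2) <= 0) next
    if (w1 >= w2 || w1 / w2 >= config$trim_ratio) next
    k <- graph$k
    sk <- kmer_strings(sequence, graph$nodes$start[src],
                       graph$nodes$end[src] + k - 1L, k)
    tk <- unique(kmer_strings(sequence, graph$nodes$start[tgt],
                              graph$nodes$end[tgt] + k - 1L, k))
    hit <- which(sk %in% tk)
    if (length(hit) == 0) next
    new_start <- graph$nodes$start[src] + hit[1] - 1L
    new_end <- graph$nodes$start[src] + hit[length(hit)]
    if (new_start == graph$nodes$start[src] &&
        new_end == graph$nodes$end[src]) next
    graph$nodes$start[src] <- new_start
    graph$nodes$end[src] <- new_end
    touched <- which(graph$edges$from == src | graph$edges$to == src)
    for (tt in touched) {
      graph$edges$weight[tt] <- node_weight(
        sequence, as.list(graph$nodes[graph$edges$from[tt], ]),
        as.list(graph$nodes[graph$edges$to[tt], ]), k)
    }
  }
  graph
}

element_candidate <- function(ltr5, ltr3, case_origin, weights,
                              sequence_id) {
  structure(list(ltr5 = ltr5, ltr3 = ltr3,
                 internal = iv(ltr5$end, ltr3$start),
                 start = ltr5$start, end = ltr3$end,
                 case_origin = case_origin, weights = weights,
                 children = list(), sequence_id = sequence_id),
            class = "element_candidate")
}

# slots: physical LTR loci = vertical-connected groups of nodes
component_slots <- function(graph, comp_id) {
  nidx <- which(graph$comp == comp_id)
  p <- uf_new(nrow(graph$nodes))
  for (r in seq_len(nrow(graph$verticals))) {
    p <- uf_union(p, graph$verticals$a[r], graph$verticals$b[r])
  }
  roots <- vapply(nidx, function(i) uf_find(p, i), integer(1))
  slots <- lapply(unique(roots), function(rt) {
    memb <- nidx[roots == rt]
    fwd <- memb[graph$nodes$direction[memb] == "forward"]
    bwd <- memb[graph$nodes$direction[memb] == "backward"]
    list(nodes = memb,
         fwd = if (length(fwd)) fwd[which.max(graph$nodes$end[fwd] -
                                                graph$nodes$start[fwd])]
               else NA_integer_,
         bwd = if (length(bwd)) bwd[which.max(graph$nodes$end[bwd] -
                                                graph$nodes$start[bwd])]
               else NA_integer_,
         start = min(graph$nodes$start[memb]),
         end = max(graph$nodes$end[memb]))
  })
  slots[order(vapply(slots, `[[`, integer(1), "start"))]
}

# best weight of an edge from a node of `sa` with direction `sense` to any
# node of `sb`; NA when no such edge exists
slot_edge_weight <- function(graph, sa, sb, sense) {
  rows <- graph$edges$from %in% sa$nodes[graph$nodes$direction[sa$nodes] ==
                                           sense] &
    graph$edges$to %in% sb$nodes
  if (!any(rows)) return(NA_real_)
  max(graph$edges$weight[rows])
}

slot_pair_weights <- function(graph, sequence, sa, sb) {
  w1 <- slot_edge_weight(graph, sa, sb, "forward")
  w2 <- slot_edge_weight(graph, sb, sa, "backward")
  if (is.na(w1)) {
    w1 <- node_weight(sequence, list(start = sa$start, end = sa$end),
                      list(start = sb$start, end = sb$end), graph$k)
  }
  if (is.na(w2)) {
    w2 <- node_weight(sequence, list(start = sb$start, end = sb$end),
                      list(start = sa$start, end = sa$end), graph$k)
  }
  c(w1, w2)
}

slot_iv <- function(graph, slot, which) {
  i <- slot[[which]]
  if (is.na(i)) iv(slot$start, slot$end) else
    iv(graph$nodes$start[i], graph$nodes$end[i])
}

ratio_of <- function(profile, sequence_id, start, end) {
  if (end - start < 1) return(NA_real_)
  repetitiveness_ratio(profile, sequence_id, start, end)
}

#' Resolve one connected component into candidates
#'
#' Applies the case analysis in order of structural specificity: single
#' (mutually connected forward/backward pair with both weights >= 0.27 and
#' a repetitive internal part; all qualifying pairs are kept and left to
#' the filter), solo (three chained LTRs lateralized by the repetitiveness
#' of the two in-between regions; both repetitive emits all three
#' pairings), recently nested (an inner single pair flanked by outer
#' forward/backward slots pointing into it, confirmed by outer-internal
#' repetitiveness and >= 0.60 identity between inner and outer internal
#' parts under the recent model), and complex (>= 2 inter-node regions
#' with >= 0.80 identity under the standard model). Deep nesting is
#' handled by the caller through splice-and-recurse (see
#' [detect_ltrs()]).
#'
#' @param graph a [build_match_graph()] result (ideally after
#'   [trim_hyperextension()]).
#' @param comp_id component id.
#' @param profile a [train_repeat_profile()] result.
#' @param sequence the nucleotide sequence.
#' @param config a [matcher_config()].
#' @param id_standard,id_recent [identity_model()]s for the standard and
#'   recent ranges.
#' @return list with `elements` (element_candidate list), `solos`
#'   (intervals), `complex_regions` (intervals), and `nested` (indices
#'   into `elements` of inner elements of recently nested pairs).
#' @export
resolve_component <- function(graph, comp_id, profile, sequence,
                              config = matcher_config(),
                              id_standard = identity_model("standard"),
                              id_recent = identity_model("recent")) {
  sid <- graph$sequence_id
  slots <- component_slots(graph, comp_id)
  ns <- length(slots)
  nidx <- which(graph$comp == comp_id)
  elements <- list(); solos <- list(); complex_regions <- list()
  nested <- integer(0)
  add_solo <- function(s) {
    solos[[length(solos) + 1L]] <<- iv(s$start, s$end)
  }
  # qualifying mutually connected node pairs (the single case): a forward
  # node and a downstream backward node pointing at each other
  single_pairs <- list()
  fw_nodes <- nidx[graph$nodes$direction[nidx] == "forward"]
  bw_nodes <- nidx[graph$nodes$direction[nidx] == "backward"]
  for (f in fw_nodes) {
    for (b in bw_nodes) {
      if (graph$nodes$start[b] <= graph$nodes$end[f]) next
      fb <- which(graph$edges$from == f & graph$edges$to == b)
      bf <- which(graph$edges$from == b & graph$edges$to == f)
      if (length(fb) == 0 || length(bf) == 0) next
      wf <- max(graph$edges$weight[fb]); wb <- max(graph$edges$weight[bf])
      if (wf < config$min_edge_weight || wb < config$min_edge_weight) next
      l5 <- iv(graph$nodes$start[f], graph$nodes$end[f])
      l3 <- iv(graph$nodes$start[b], graph$nodes$end[b])
      rr <- ratio_of(profile, sid, l5$end, l3$start)
      if (is.na(rr) || rr < config$min_internal_ratio) next
      single_pairs[[length(single_pairs) + 1L]] <-
        list(f = f, b = b, ltr5 = l5, ltr3 = l3, weights = c(wf, wb))
    }
  }

  if (ns == 1) {
    add_solo(slots[[1]])
  } else if (ns == 3) {
    # solo case: element + solo LTR, lateralized by the repetitiveness of
    # the two in-between regions
    s1 <- slots[[1]]; s2 <- slots[[2]]; s3 <- slots[[3]]
    r12 <- ratio_of(profile, sid, s1$end, s2$start)
    r23 <- ratio_of(profile, sid, s2$end, s3$start)
    rep12 <- !is.na(r12) && r12 >= config$min_internal_ratio
    rep23 <- !is.na(r23) && r23 >= config$min_internal_ratio
    try_pair <- function(a, b, case) {
      w <- slot_pair_weights(graph, sequence, slots[[a]], slots[[b]])
      if (any(w < config$min_edge_weight)) return(FALSE)
      l5 <- slot_iv(graph, slots[[a]], "fwd")
      l3 <- slot_iv(graph, slots[[b]], "bwd")
      if (l3$start <= l5$end) return(FALSE)
      elements[[length(elements) + 1L]] <<-
        element_candidate(l5, l3, case, w, sid)
      TRUE
    }
    if (rep12 && !rep23) {
      if (try_pair(1, 2, "solo")) add_solo(s3) else {
        add_solo(s1); add_solo(s2); add_solo(s3)
      }
    } else if (rep23 && !rep12) {
      if (try_pair(2, 3, "solo")) add_solo(s1) else {
        add_solo(s1); add_solo(s2); add_solo(s3)
      }
    } else if (rep12 && rep23) {
      ok1 <- try_pair(1, 2, "solo"); ok2 <- try_pair(2, 3, "solo")
      ok3 <- try_pair(1, 3, "solo")
      if (ok1) add_solo(s3)
      if (ok2) add_solo(s1)
      if (ok3) add_solo(s2)
      if (!ok1 && !ok2 && !ok3) { add_solo(s1); add_solo(s2); add_solo(s3) }
    } else {
      add_solo(s1); add_solo(s2); add_solo(s3)
    }
  } else {
    # ns == 2 or ns >= 4: emit all qualifying single pairs
    used <- logical(ns)
    node_slot <- function(i) {
      which(vapply(slots, function(s) i %in% s$nodes, logical(1)))[1]
    }
    for (sp in single_pairs) {
      elements[[length(elements) + 1L]] <-
        element_candidate(sp$ltr5, sp$ltr3, "single", sp$weights, sid)
      used[node_slot(sp$f)] <- TRUE; used[node_slot(sp$b)] <- TRUE
    }
    if (ns >= 4 && length(single_pairs) > 0) {
      # recently nested: an inner single pair flanked by an outer forward
      # node upstream and an outer backward node downstream, both pointing
      # into the inner span. A recent insertion has near-identical LTRs,
      # so among qualifying pairs the one with the highest mutual weight
      # is claimed as the inner element; the recursion peels deeper
      # levels one at a time.
      rank_of <- vapply(single_pairs, function(sp) min(sp$weights),
                        numeric(1))
      for (spn in order(-rank_of)) {
        sp <- single_pairs[[spn]]
        inner_el <- elements[[spn]]
        inner_nodes <- nidx[graph$nodes$end[nidx] > inner_el$start &
                              graph$nodes$start[nidx] < inner_el$end]
        points_into <- function(i) {
          any(graph$edges$from == i & graph$edges$to %in% inner_nodes)
        }
        lefts <- fw_nodes[graph$nodes$end[fw_nodes] <=
                            inner_el$start + graph$k &
                            vapply(fw_nodes, points_into, logical(1))]
        rights <- bw_nodes[graph$nodes$start[bw_nodes] >=
                             inner_el$end - graph$k &
                             vapply(bw_nodes, points_into, logical(1))]
        if (length(lefts) == 0 || length(rights) == 0) next
        # hull of the qualifying outer nodes approximates the outer
        # LTR-plus-internal-slice regions on each side
        h <- list(start = min(graph$nodes$start[lefts]),
                  end = max(graph$nodes$end[lefts]))
        g_i <- rights[which.min(graph$nodes$start[rights])]
        g <- list(start = min(graph$nodes$start[rights]),
                  end = max(graph$nodes$end[rights]))
        L5 <- iv_len(inner_el$ltr5); L3 <- iv_len(inner_el$ltr3)
        outer5 <- iv(h$start, min(h$start + L5, h$end))
        outer3 <- iv(max(g$end - L3, g$start), g$end)
        # the regions immediately flanking the inner element belong to the
        # outer element's internal part: they must be repetitive and must
        # share >= 60% identity (recent operating range) with the inner
        # internal part to confirm a same-family nest. Local alignment is
        # used because the outer internal is fragmentary at this stage.
        inner_int <- seq_slice(sequence, inner_el$internal$start,
                               inner_el$internal$end)
        if (nchar(inner_int) < 100) next
        W <- min(1000L, nchar(inner_int))
        left_w <- c(max(0L, inner_el$start - W), inner_el$start)
        right_w <- c(inner_el$end, min(nchar(sequence), inner_el$end + W))
        ok <- FALSE
        for (wnd in list(left_w, right_w)) {
          if (wnd[2] - wnd[1] < 50) next
          rr <- ratio_of(profile, sid, wnd[1], wnd[2])
          if (is.na(rr) || rr < config$min_internal_ratio) next
          ws <- seq_slice(sequence, wnd[1], wnd[2])
          aln <- sw_align(ws, inner_int)
          if (aln$length >= 0.5 * min(nchar(ws), nchar(inner_int)) &&
              aln$identity > config$nested_min_identity) {
            ok <- TRUE
            break
          }
        }
        if (!ok) next
        outer_w <- slot_pair_weights(graph, sequence, h, g)
        outer_el <- element_candidate(outer5, outer3, "recently_nested",
                                      outer_w, sid)
        inner_el$case_origin <- "recently_nested"
        outer_el$children <- list(inner_el)
        elements[[spn]] <- inner_el
        elements[[length(elements) + 1L]] <- outer_el
        nested <- c(nested, spn)
        used[node_slot(lefts[1])] <- TRUE
        used[node_slot(g_i)] <- TRUE
        break
      }
    }
    if (ns >= 4 && length(single_pairs) == 0) {
      # complex case: sequential same-family insertions
      regions <- list()
      for (i in seq_len(ns - 1)) {
        a <- slots[[i]]$end; b <- slots[[i + 1]]$start
        if (b - a >= 80) regions[[length(regions) + 1L]] <- c(a, b)
      }
      hit <- FALSE
      if (length(regions) >= 2) {
        for (i in seq_len(length(regions) - 1)) {
          for (j in (i + 1):length(regions)) {
            sa <- seq_slice(sequence, regions[[i]][1], regions[[i]][2])
            sb <- seq_slice(sequence, regions[[j]][1], regions[[j]][2])
            if (global_identity(sa, sb, id_standard) >=
                config$complex_min_identity) {
              hit <- TRUE
              break
            }
          }
          if (hit) break
        }
      }
      if (hit) {
        complex_regions[[length(complex_regions) + 1L]] <-
          iv(slots[[1]]$start, slots[[ns]]$end)
      }
    }
    for (i in which(!used)) add_solo(slots[[i]])
  }
  list(elements = elements, solos = solos,
       complex_regions = complex_regions, nested = nested)
}

#' Resolve every component of a match graph
#'
#' @inheritParams resolve_component
#' @return same shape as [resolve_component()], pooled over components,
#'   with `component` ids attached to elements and solos.
#' @export
resolve_components <- function(graph, profile, sequence,
                               config = matcher_config(),
                               id_standard = identity_model("standard"),
                               id_recent = identity_model("recent")) {
  out <- list(elements = list(), solos = list(), complex_regions = list(),
              nested = integer(0), solo_component = integer(0),
              element_component = integer(0))
  for (cid in unique(graph$comp)) {
    res <- resolve_component(graph, cid, profile, sequence, config,
                             id_standard, id_recent)
    base <- length(out$elements)
    out$elements <- c(out$elements, res$elements)
    out$nested <- c(out$nested, res$nested + base)
    out$element_component <- c(out$element_component,
                               rep(cid, length(res$elements)))
    out$solos <- c(out$solos, res$solos)
    out$solo_component <- c(out$solo_component, rep(cid, length(res$solos)))
    out$complex_regions <- c(out$complex_regions, res$complex_regions)
  }
  out
}
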