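stage_for <- function(ts, model = default_merge_model()) {
  g <- ts$genome
  sid <- names(g$sequences)[1]
  seqc <- g$sequences[[1]]
  prof <- train_repeat_profile(g)
  tracks <- score_sequence(seqc, scorer_config(), sid)
  cfg <- merger_config()
  fs <- merge_stretches(build_stretches(tracks$forward, cfg),
                        tracks$forward$scores, cfg)
  bs <- merge_stretches(build_stretches(tracks$backward, cfg),
                        tracks$backward$scores, cfg)
  fc <- assemble_candidates(fs, model, prof, sid, "forward")
  bc <- assemble_candidates(bs, model, prof, sid, "backward")
  list(graph = build_match_graph(fc, bc, tracks, seqc, sid),
       profile = prof, sequence = seqc, sid = sid)
}

test_that("a perfect element yields two nodes with mutual weight-1 edges", {
  ts <- generate_genome(list(plant_spec("f", ltr_divergence = 0,
                                        family_divergence = 0,
                                        copy_number = 1)), 8e4, seed = 71)
  st <- stage_for(ts)
  gr <- st$graph
  a <- ts$annotations[[1]]
  expect_equal(nrow(gr$nodes), 2)
  expect_setequal(gr$nodes$direction, c("forward", "backward"))
  expect_equal(nrow(gr$edges), 2)
  expect_true(all(gr$edges$weight > 0.97))
  expect_equal(length(unique(gr$comp)), 1)
  fwd <- gr$nodes[gr$nodes$direction == "forward", ]
  expect_lt(abs(fwd$start - a$ltr5$start), 20)
})

test_that("component partition equals a union-find oracle over declared edges", {
  ts <- benchmark_genome(2e5 * 3, seed = 72)
  st <- stage_for(ts)
  gr <- st$graph
  n <- nrow(gr$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (r in seq_len(nrow(gr$edges))) link(gr$edges$from[r], gr$edges$to[r])
  for (r in seq_len(nrow(gr$verticals))) {
    link(gr$verticals$a[r], gr$verticals$b[r])
  }
  want <- vapply(seq_len(n), find, integer(1))
  # identical partitions up to relabelling
  expect_equal(length(unique(want)), length(unique(gr$comp)))
  expect_true(all(tapply(gr$comp, want, function(v) length(unique(v))) == 1))
})

test_that("vertical connections join only overlapping opposite-direction nodes", {
  ts <- benchmark_genome(2e5 * 3, seed = 73)
  gr <- stage_for(ts)$graph
  if (nrow(gr$verticals) > 0) {
    for (r in seq_len(nrow(gr$verticals))) {
      a <- gr$verticals$a[r]; b <- gr$verticals$b[r]
      expect_true(gr$nodes$direction[a] != gr$nodes$direction[b])
      expect_gt(min(gr$nodes$end[a], gr$nodes$end[b]),
                max(gr$nodes$start[a], gr$nodes$start[b]))
    }
  }
  # no weighted edges between nodes of the same direction
  expect_true(all(gr$nodes$direction[gr$edges$from] !=
                    gr$nodes$direction[gr$edges$to]))
})

test_that("trimming is a no-op on symmetric pairs and never widens nodes", {
  ts <- benchmark_genome(2e5 * 3, seed = 74)
  st <- stage_for(ts)
  gr0 <- st$graph
  gr1 <- trim_hyperextension(gr0, st$sequence)
  w0 <- gr0$nodes$end - gr0$nodes$start
  w1 <- gr1$nodes$end - gr1$nodes$start
  expect_true(all(w1 <= w0))
  expect_true(all(gr1$nodes$start >= gr0$nodes$start))
  expect_true(all(gr1$nodes$end <= gr0$nodes$end))
  # perfectly symmetric pair: untouched
  ts2 <- generate_genome(list(plant_spec("f", ltr_divergence = 0,
                                         family_divergence = 0,
                                         copy_number = 1)), 8e4, seed = 75)
  st2 <- stage_for(ts2)
  gr2 <- trim_hyperextension(st2$graph, st2$sequence)
  expect_identical(gr2$nodes, st2$graph$nodes)
})

test_that("single case config thresholds are respected", {
  ts <- tiny_world(seed = 76, copy_number = 2, ltr_divergence = 0.01,
                   family_divergence = 0.03)
  st <- stage_for(ts)
  cfg <- matcher_config()
  res <- resolve_components(st$graph, st$profile, st$sequence, cfg)
  expect_gte(length(res$elements), 2)
  for (el in res$elements) {
    expect_gte(min(el$weights), cfg$min_edge_weight)
    expect_gte(repetitiveness_ratio(st$profile, st$sid,
                                    el$internal$start, el$internal$end),
               cfg$min_internal_ratio)
    expect_lt(el$ltr5$end, el$ltr3$start)
  }
})

test_that("solo case lateralizes by spacer repetitiveness", {
  ts <- generate_genome(list(plant_spec("f", copy_number = 2,
                                        solo_count = 1)), 2.5e5, seed = 77)
  anns <- detect_ltrs(ts$genome)
  kinds <- vapply(anns, function(a) a$kind, character(1))
  expect_equal(sum(kinds == "solo_ltr"), 1)
  expect_equal(sum(kinds == "element"), 2)
  truth_solo <- Filter(function(a) a$kind == "solo_ltr", ts$annotations)[[1]]
  pred_solo <- anns[[which(kinds == "solo_ltr")]]
  expect_lt(abs(pred_solo$start - truth_solo$start), 60)
})

test_that("a one-level same-family nest resolves with correct containment", {
  ts <- generate_genome(list(plant_spec("f", ltr_divergence = 0.02,
                                        copy_number = 3,
                                        nesting = plant_spec(
                                          "f", ltr_divergence = 0.01))),
                        3e5, seed = 78)
  anns <- detect_ltrs(ts$genome)
  ev <- evaluate_predictions(anns, ts$annotations)
  expect_gte(ev$metrics["recall"], 0.75)
  lv <- vapply(anns, function(a) a$nesting_level, integer(1))
  expect_gte(sum(lv == 1), 1)
  child <- anns[[which(lv == 1)[1]]]
  parents <- Filter(function(a) a$nesting_level == 0 &&
                      a$start <= child$start && a$end >= child$end, anns)
  expect_gte(length(parents), 1)
})

test_that("a two-level nest resolves into three contained elements", {
  inner2 <- plant_spec("f", ltr_divergence = 0.005, internal_length = 2500)
  inner1 <- plant_spec("f", ltr_divergence = 0.015, internal_length = 2500,
                       nesting = inner2)
  ts <- generate_genome(list(plant_spec("f", ltr_divergence = 0.03,
                                        internal_length = 2500,
                                        copy_number = 2,
                                        nesting = inner1)), 3e5, seed = 79)
  anns <- detect_ltrs(ts$genome)
  lv <- sort(vapply(Filter(function(a) a$kind == "element", anns),
                    function(a) a$nesting_level, integer(1)))
  expect_true(all(c(0, 1, 2) %in% lv))
  ev <- evaluate_predictions(anns, ts$annotations)
  expect_gte(ev$tp, 3)
})

test_that("hyper-extension repair trims the over-merged LTR to its match", {
  set.seed(80)
  L <- rand_dna(400)
  R <- rand_dna(600) # unrelated repeat wrongly fused onto the 3' LTR
  s <- paste0(rand_dna(1000), L, rand_dna(2000), R, L, rand_dna(1000))
  nodes <- data.frame(direction = c("forward", "backward"),
                      start = c(1000L, 3400L), end = c(1400L, 4400L),
                      stringsAsFactors = FALSE)
  nw <- function(a, b) ltrscout:::node_weight(s, as.list(nodes[a, ]),
                                              as.list(nodes[b, ]), 13L)
  graph <- structure(list(nodes = nodes,
                          edges = data.frame(from = c(1L, 2L), to = c(2L, 1L),
                                             weight = c(nw(1, 2), nw(2, 1))),
                          verticals = data.frame(a = integer(0),
                                                 b = integer(0)),
                          comp = c(1L, 1L), k = 13L, sequence_id = "x"),
                     class = "match_graph")
  lo0 <- min(graph$edges$weight)
  expect_lt(lo0 / max(graph$edges$weight), 0.5)
  got <- trim_hyperextension(graph, s)
  # the fused unrelated repeat is cut off the backward node
  expect_gte(got$nodes$start[2], 4000 - 13)
  # node intervals live in k-mer-start space: the last matching k-mer
  # starts k-1 bp before the sequence-space end
  expect_gte(got$nodes$end[2], 4400 - 13)
  expect_identical(got$nodes[1, ], graph$nodes[1, ])
  # both weights become symmetric and the lower one never decreases
  expect_gte(min(got$edges$weight), lo0)
  expect_gt(min(got$edges$weight), 0.95)
  # the trimmed LTR now matches the 5' LTR length within margin
  expect_lt(abs((got$nodes$end[2] - got$nodes$start[2]) - 400), 30)

})
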