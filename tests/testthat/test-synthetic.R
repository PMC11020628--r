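test_that("zero-divergence elements carry identical LTRs and exact TSDs", {
  ts <- generate_genome(list(plant_spec("f", ltr_divergence = 0,
                                        family_divergence = 0,
                                        copy_number = 1)), 1e5, seed = 4)
  expect_length(ts$annotations, 1)
  a <- ts$annotations[[1]]
  g <- ts$genome$sequences[[1]]
  l5 <- substr(g, a$ltr5$start + 1, a$ltr5$end)
  l3 <- substr(g, a$ltr3$start + 1, a$ltr3$end)
  expect_identical(l5, l3)
  t5 <- substr(g, a$tsd[[1]]$start + 1, a$tsd[[1]]$end)
  t3 <- substr(g, a$tsd[[2]]$start + 1, a$tsd[[2]]$end)
  expect_identical(t5, t3)
  expect_equal(nchar(t5), 5)
  # PPT annotation is purine rich with more A than G
  ppt <- substr(g, a$ppt$start + 1, a$ppt$end)
  expect_false(grepl("[CT]", ppt))
  expect_gt(lengths(regmatches(ppt, gregexpr("A", ppt))),
            lengths(regmatches(ppt, gregexpr("G", ppt))))
})

test_that("same-family nesting yields a level-1 child strictly inside the parent internal", {
  sp <- plant_spec("f", copy_number = 1,
                   nesting = plant_spec("f"))
  ts <- generate_genome(list(sp), 1e5, seed = 9)
  lv <- vapply(ts$annotations, function(a) a$nesting_level, integer(1))
  expect_setequal(lv, c(0L, 1L))
  parent <- ts$annotations[[which(lv == 0)]]
  child <- ts$annotations[[which(lv == 1)]]
  expect_gt(child$start, parent$ltr5$end)
  expect_lt(child$end, parent$ltr3$start)
  # child TSD duplicates parent-internal host sequence
  g <- ts$genome$sequences[[1]]
  expect_identical(substr(g, child$tsd[[1]]$start + 1, child$tsd[[1]]$end),
                   substr(g, child$tsd[[2]]$start + 1, child$tsd[[2]]$end))
})

test_that("generation is byte-deterministic for a fixed seed", {
  specs <- list(plant_spec("a", copy_number = 3, solo_count = 1),
                plant_spec("b", copy_number = 2,
                           nesting = plant_spec("b")),
                plant_spec("m", kind = "mite", copy_number = 4))
  t1 <- generate_genome(specs, 4e5, seed = 77)
  t2 <- generate_genome(specs, 4e5, seed = 77)
  expect_identical(t1$genome$sequences, t2$genome$sequences)
  expect_identical(annotations_to_df(t1$annotations),
                   annotations_to_df(t2$annotations))
  t3 <- generate_genome(specs, 4e5, seed = 78)
  expect_false(identical(t1$genome$sequences, t3$genome$sequences))
})

test_that("truth annotations substrings match their structural roles", {
  ts <- tiny_world(seed = 12, copy_number = 3)
  g <- ts$genome$sequences[[1]]
  for (a in ts$annotations) {
    expect_lte(a$end, nchar(g))
    expect_true(a$ltr5$end <= if (is.null(a$ltr3)) a$end else a$ltr3$start)
  }
})

test_that("generator rejects overflowing insertions", {
  expect_error(generate_genome(list(plant_spec("f", copy_number = 10)),
                               5e4, seed = 1), "overflow")
})

test_that("semi-synthetic transform: degenerate whole-shuffle case", {
  g <- genome_set(c(c1 = rand_dna(2000)))
  ss <- make_semisynthetic(g, list(), seed = 3)
  expect_equal(nchar(ss$sequences[[1]]), 2000)
  expect_false(identical(ss$sequences[[1]], g$sequences[[1]]))
  count <- function(s) table(strsplit(s, "")[[1]])
  expect_equal(count(ss$sequences[[1]]), count(g$sequences[[1]]))
})

test_that("semi-synthetic transform preserves elements and permutes flanks", {
  set.seed(5)
  g <- genome_set(c(c1 = rand_dna(3000)))
  a <- annotation("c1", 100, 600,
                  ltr5 = list(start = 100, end = 250),
                  ltr3 = list(start = 450, end = 600))
  ss <- make_semisynthetic(g, list(a), seed = 7)
  s0 <- g$sequences[[1]]; s1 <- ss$sequences[[1]]
  expect_equal(nchar(s1), nchar(s0))
  expect_identical(substr(s1, 101, 600), substr(s0, 101, 600))
  count <- function(s) table(factor(strsplit(s, "")[[1]],
                                    c("A", "C", "G", "T")))
  # per-region base multisets preserved (exact)
  expect_equal(count(substr(s1, 1, 100)), count(substr(s0, 1, 100)))
  expect_equal(count(substr(s1, 601, 3000)), count(substr(s0, 601, 3000)))
})

test_that("semi-synthetic transform rejects partial overlaps", {
  g <- genome_set(c(c1 = rand_dna(3000)))
  mk <- function(s, e) annotation("c1", s, e,
                                  ltr5 = list(start = s, end = s + 100),
                                  ltr3 = list(start = e - 100, end = e))
  expect_error(make_semisynthetic(g, list(mk(100, 900), mk(600, 1400)),
                                  seed = 1), "overlapping")
  # containment (declared nesting) is fine
  expect_silent(make_semisynthetic(g, list(mk(100, 1400), mk(600, 900)),
                                   seed = 1))
})
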