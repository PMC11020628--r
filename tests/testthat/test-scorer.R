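make_worked_example <- function(seed = 1) {
  # G-free background so a planted poly-G 13-mer is unique; copies at
  # 0-based positions 1000 and 2000
  set.seed(seed)
  bg <- rand_dna(4000, alphabet = c("A", "C", "T"))
  km <- strrep("G", 13)
  paste0(substr(bg, 1, 1000), km, substr(bg, 1014, 2000), km,
         substr(bg, 2014, 4000))
}

test_that("worked example: copies at 1000/2000 score 1000 in each track", {
  s <- make_worked_example()
  tr <- score_sequence(s, scorer_config())
  expect_equal(tr$forward$scores[1000 + 1], 1000)
  expect_equal(tr$backward$scores[2000 + 1], 1000)
  expect_equal(tr$backward$scores[1000 + 1], 0)
  expect_equal(tr$forward$scores[2000 + 1], 0)
})

test_that("sequence without in-window repeats scores zero everywhere", {
  set.seed(2)
  s <- rand_dna(3000)
  tr <- score_sequence(s, scorer_config())
  # a random 3 kb sequence essentially never repeats a 13-mer
  expect_true(all(tr$forward$scores == 0))
  expect_true(all(tr$backward$scores == 0))
})

test_that("matches closer than min_dist are excluded", {
  set.seed(3)
  block <- rand_dna(300)
  s <- paste0(rand_dna(200), block, rand_dna(300), block, rand_dna(200))
  tr <- score_sequence(s, scorer_config()) # copies 600 apart > 400: scored
  expect_gt(sum(tr$forward$scores > 0), 200)
  s2 <- paste0(rand_dna(200), block, rand_dna(80), block, rand_dna(200))
  tr2 <- score_sequence(s2, scorer_config()) # 380 apart < 400: excluded
  expect_true(all(tr2$forward$scores == 0))
  expect_true(all(tr2$backward$scores == 0))
})

test_that("short sequences yield empty tracks with a warning", {
  expect_warning(tr <- score_sequence("ACGT", scorer_config()), "shorter")
  expect_length(tr$forward$scores, 0)
})

test_that("k-mers containing N are unscored", {
  set.seed(6)
  block <- rand_dna(60)
  s <- paste0(rand_dna(100), block, strrep("N", 20), rand_dna(400), block,
              rand_dna(100))
  cfg <- scorer_config(min_dist = 100, max_dist = 2000)
  tr <- score_sequence(s, cfg)
  m <- nchar(s) - 13 + 1
  km <- substring(s, 1:m, 13:(m + 12))
  has_n <- grepl("N", km, fixed = TRUE)
  expect_true(all(tr$forward$scores[has_n] == 0))
  expect_true(all(tr$backward$scores[has_n] == 0))
  expect_gt(sum(tr$forward$scores > 0), 0)
})

test_that("production scorer equals the brute-force oracle", {
  set.seed(11)
  cfg <- scorer_config()
  for (rep in 1:6) {
    s <- rand_dna(5000)
    # plant 3 duplications at assorted distances
    for (d in sample(c(450, 900, 2600), 3)) {
      block <- rand_dna(40)
      at <- sample(1000:1500, 1)
      substr(s, at, at + 39) <- block
      substr(s, at + d, at + d + 39) <- block
    }
    tr <- score_sequence(s, cfg)
    oracle <- brute_force_scores(s, cfg$k, cfg$min_dist, cfg$max_dist)
    expect_identical(tr$forward$scores, oracle$forward)
    expect_identical(tr$backward$scores, oracle$backward)
  }
})

test_that("forward/backward symmetry: forward[p]=d implies backward[p+d]<=d", {
  set.seed(12)
  s <- rand_dna(4000)
  block <- rand_dna(50)
  for (at in c(500, 1500)) {
    substr(s, at, at + 49) <- block
    substr(s, at + 800, at + 849) <- block
  }
  tr <- score_sequence(s, scorer_config())
  f <- tr$forward$scores; b <- tr$backward$scores
  for (p in which(f > 0)) {
    expect_lte(b[p + f[p]], f[p])
  }
})

test_that("reverse complement swaps and mirrors the two tracks", {
  set.seed(13)
  s <- rand_dna(3000)
  block <- rand_dna(60)
  substr(s, 400, 459) <- block
  substr(s, 1400, 1459) <- block
  cfg <- scorer_config(min_dist = 400, max_dist = 5000)
  tr <- score_sequence(s, cfg)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  tr_rc <- score_sequence(rc, cfg)
  # k-mer at 0-based position p maps to position n-k-p on the reverse strand
  m <- length(tr$forward$scores)
  expect_identical(tr_rc$forward$scores, rev(tr$backward$scores))
  expect_identical(tr_rc$backward$scores, rev(tr$forward$scores))
  expect_length(tr_rc$forward$scores, m)
})

test_that("castle layout keeps outer LTR runs unfragmented per direction", {
  # two same-family elements nearby: identical LTRs within each element,
  # 2% divergence between elements
  for (seed in c(1, 2)) {
    ts <- generate_genome(list(plant_spec("fam", ltr_divergence = 0,
                                          family_divergence = 0.02,
                                          copy_number = 2,
                                          sequential_run = 2)),
                          6e4, seed = seed)
    a1 <- ts$annotations[[1]]
    a2 <- ts$annotations[[2]]
    tr <- score_sequence(ts$genome$sequences[[1]], scorer_config())
    cfg <- merger_config()
    n_stretch <- function(scores, lo, hi) {
      seg <- scores[(lo + 1):hi]
      length(merge_stretches(build_stretches(list(scores = seg), cfg),
                             seg, cfg))
    }
    expect_equal(n_stretch(tr$forward$scores, a1$ltr5$start, a1$ltr5$end), 1)
    expect_equal(n_stretch(tr$backward$scores, a2$ltr3$start, a2$ltr3$end), 1)
  }
})
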