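mk_el <- function(l5s, l5e, l3s, l3e) {
  structure(list(ltr5 = list(start = as.integer(l5s), end = as.integer(l5e)),
                 ltr3 = list(start = as.integer(l3s), end = as.integer(l3e)),
                 internal = list(start = as.integer(l5e),
                                 end = as.integer(l3s)),
                 start = as.integer(l5s), end = as.integer(l3e),
                 case_origin = "single", weights = c(1, 1),
                 children = list(), sequence_id = "x"),
            class = "element_candidate")
}

test_that("length filter enforces LTR and internal bounds", {
  cfg <- filter_config()
  expect_true(check_lengths(mk_el(0, 300, 1310, 1620), cfg))
  expect_false(check_lengths(mk_el(0, 150, 1310, 1620), cfg))     # LTR 150
  expect_false(check_lengths(mk_el(0, 7000, 8000, 8300), cfg))    # 7000 exactly
  expect_false(check_lengths(mk_el(0, 300, 400, 700), cfg))       # internal 100
  # nested child spans are excluded from the internal length
  el <- mk_el(0, 300, 3000, 3300)
  child <- list(iv(400, 2900))
  expect_true(check_lengths(el, cfg, child))                      # 200 left
  child2 <- list(iv(350, 2950))
  expect_false(check_lengths(el, cfg, child2))                    # 100 left
  # overlapping children (grandchild inside child) are not double-counted
  expect_true(check_lengths(el, cfg, list(iv(400, 2900), iv(600, 2000))))
})

test_that("similarity filter: ratio shortcut and local-alignment rescue", {
  cfg <- filter_config()
  set.seed(91)
  # 400 vs 500: ratio exactly 0.8, passes without alignment
  g1 <- paste0(rand_dna(100), rand_dna(400), rand_dna(800), rand_dna(500))
  expect_true(check_similarity(mk_el(100, 500, 1300, 1800), g1, cfg))
  # 200 vs 400 with a shared identical 100 bp core: rescued
  core <- rand_dna(100)
  l5 <- paste0(rand_dna(50), core, rand_dna(50))
  l3 <- paste0(rand_dna(150), core, rand_dna(150))
  g2 <- paste0(rand_dna(100), l5, rand_dna(700), l3, rand_dna(100))
  expect_true(check_similarity(mk_el(100, 300, 1000, 1400), g2, cfg))
  # 200 vs 400 unrelated: fails
  g3 <- paste0(rand_dna(100), rand_dna(200), rand_dna(700), rand_dna(400),
               rand_dna(100))
  expect_false(check_similarity(mk_el(100, 300, 1000, 1400), g3, cfg))
})

test_that("PPT search finds plus-strand and reversed tracts, rejects none", {
  cfg <- filter_config()
  set.seed(92)
  ppt <- paste(sample(c("A", "G"), 15, TRUE, prob = c(0.8, 0.2)),
               collapse = "")
  # ensure more A than G
  ppt <- paste0(substr(ppt, 1, 10), "AAAAA")
  internal <- paste0(rand_dna(1000, alphabet = c("C", "T")), ppt,
                     rand_dna(60, alphabet = c("C", "T")))
  g <- paste0(rand_dna(300), internal, rand_dna(300))
  el <- mk_el(0, 300, 300 + nchar(internal), nchar(g))
  hit <- find_ppt(el, g, cfg)
  expect_false(is.null(hit))
  expect_equal(hit$strand, "+")
  expect_gte(hit$interval$start, el$internal$end - 400)
  region <- substr(g, hit$interval$start + 1, hit$interval$end)
  expect_gt(lengths(regmatches(region, gregexpr("A", region))),
            lengths(regmatches(region, gregexpr("G", region))))

  # pyrimidine tract just after the 5' LTR: reversed orientation
  tct <- paste0(paste(sample(c("T", "C"), 10, TRUE, prob = c(0.8, 0.2)),
                      collapse = ""), "TTTTT")
  internal2 <- paste0(rand_dna(40, alphabet = c("A", "G")), tct,
                      rand_dna(1000, alphabet = c("A", "G")))
  # note: internal is A/G-free beyond the probe region on the minus test
  g2 <- paste0(rand_dna(300, alphabet = c("C", "T")), internal2,
               rand_dna(300, alphabet = c("C", "T")))
  el2 <- mk_el(0, 300, 300 + nchar(internal2), nchar(g2))
  hit2 <- find_ppt(el2, g2, cfg)
  expect_false(is.null(hit2))

  # balanced GC internal with no purine run: nothing fires
  set.seed(93)
  internal3 <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  g3 <- paste0(rand_dna(300), internal3, rand_dna(300))
  el3 <- mk_el(0, 300, 1300, 1600)
  expect_null(find_ppt(el3, g3, cfg))
})

test_that("MITE filter drops only double-TIR elements", {
  cfg <- filter_config()
  set.seed(94)
  tir <- rand_dna(20)
  mite <- function() paste0(tir, rand_dna(360), revcomp(tir))
  normal <- function() rand_dna(400)
  mk_g <- function(a, b) paste0(rand_dna(100), a, rand_dna(800), b,
                                rand_dna(100))
  el <- mk_el(100, 500, 1300, 1700)
  expect_true(is_mite(el, mk_g(mite(), mite()), cfg))
  expect_false(is_mite(el, mk_g(mite(), normal()), cfg))
  expect_false(is_mite(el, mk_g(normal(), normal()), cfg))
})

test_that("orphan solo removal follows component membership", {
  keep <- drop_orphan_solos(list(iv(0, 10), iv(20, 30), iv(40, 50)),
                            solo_components = c(1L, 2L, 3L),
                            surviving_components = c(1L, 3L))
  expect_equal(keep, c(TRUE, FALSE, TRUE))
})

test_that("TSD search recovers planted duplications and widens the element", {
  cfg <- filter_config()
  set.seed(95)
  tsd <- "ACTGATTG" # 8 bp: chance 8-mer collisions in 20 bp flanks are rare
  g <- paste0(rand_dna(92), tsd, rand_dna(1000), tsd, rand_dna(100))
  el <- mk_el(100, 400, 800, 1100)
  got <- find_tsd(el, g, cfg)
  expect_false(is.null(got))
  expect_equal(substr(g, got$tsd5$start + 1, got$tsd5$end), tsd)
  expect_equal(got$tsd5, iv(92, 100))
  expect_equal(got$tsd3, iv(1100, 1108))
  expect_equal(got$element$start, 100L) # already touching
  # flanks sharing only a 3-mer: nothing reported
  set.seed(96)
  g2 <- paste0(strrep("A", 20), rand_dna(500, alphabet = c("C", "G")),
               strrep("T", 17), "AAA")
  el2 <- mk_el(20, 220, 320, 520)
  got2 <- find_tsd(el2, g2, cfg)
  if (!is.null(got2)) expect_gte(got2$tsd5$end - got2$tsd5$start, 4)
  # identical 20 bp flanks: maximal 20 bp TSD
  fl <- rand_dna(20)
  g3 <- paste0(fl, rand_dna(600, alphabet = c("C", "G")), fl)
  el3 <- mk_el(20, 220, 420, 620)
  got3 <- find_tsd(el3, g3, cfg)
  expect_equal(got3$tsd5, iv(0, 20))
  expect_equal(got3$tsd3, iv(620, 640))
})

test_that("TSD length equals the longest-common-substring oracle", {
  set.seed(97)
  cfg <- filter_config()
  for (i in 1:20) {
    up <- rand_dna(20)
    dn <- rand_dna(20)
    g <- paste0(up, rand_dna(300), dn)
    el <- mk_el(20, 170, 170, 320)
    el$internal <- list(start = 170L, end = 170L)
    want <- lcs_oracle(up, dn)
    got <- find_tsd(el, g, cfg)
    if (want >= cfg$tsd_min) {
      expect_false(is.null(got))
      expect_equal(got$tsd5$end - got$tsd5$start, want)
    } else {
      expect_null(got)
    }
  }
})
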