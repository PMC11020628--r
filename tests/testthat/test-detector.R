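mk_stretch <- function(start, end, height) {
  list(start = as.integer(start), end = as.integer(end), height = height,
       size = as.integer(end - start), label = "keep",
       members = list(c(as.integer(start), as.integer(end))))
}

mk_profile <- function(scores, regions = NULL) {
  if (is.null(regions)) {
    regions <- data.frame(start = 0L, end = length(scores))
  }
  list(scores = list(x = scores), regions = list(x = regions))
}

const_model <- function(accept) {
  structure(list(weights = rep(0, 10), bias = if (accept) 1 else -1,
                 feature_means = rep(0, 9), feature_sds = rep(1, 9)),
            class = "merge_model")
}

test_that("features of identical adjacent stretches under uniform repeat score", {
  r <- 2.5
  prof <- mk_profile(rep(r, 200))
  f <- featurize_pair(mk_stretch(0, 50, 1000), mk_stretch(50, 100, 1000),
                      prof, "x")
  expect_equal(unname(f[c("gap", "dheight", "dmedian_rep", "dmean_rep",
                          "mean_rep_gap")]), rep(0, 5))
  expect_equal(unname(f["mean_rep1"]), r)
  expect_equal(unname(f["mean_rep2"]), r)
  expect_equal(unname(f["same_region"]), 1)
  expect_length(f, 10)
})

test_that("stretches in distinct repetitive regions get same_region = 0", {
  prof <- mk_profile(rep(1, 200),
                     data.frame(start = c(0L, 60L), end = c(40L, 100L)))
  f <- featurize_pair(mk_stretch(0, 40, 500), mk_stretch(60, 100, 500),
                      prof, "x")
  expect_equal(unname(f["same_region"]), 0)
  expect_error(featurize_pair(mk_stretch(0, 50, 1), mk_stretch(40, 80, 1),
                              prof, "x"), "overlap")
})

test_that("features equal a direct recount oracle on random fixtures", {
  set.seed(61)
  for (i in 1:25) {
    sc <- runif(300, 0, 3) * rbinom(300, 1, 0.6)
    prof <- mk_profile(sc)
    a <- sort(sample(0:120, 2)); b <- sort(sample(150:290, 2))
    if (diff(a) == 0 || diff(b) == 0) next
    s1 <- mk_stretch(a[1], a[2], 700)
    s2 <- mk_stretch(b[1], b[2], 900)
    f <- featurize_pair(s1, s2, prof, "x")
    seg <- function(lo, hi) sc[(lo + 1):hi]
    mnz <- function(v) { v <- v[v > 0]; if (length(v)) median(v) else 0 }
    expect_equal(unname(f["size1"]), a[2] - a[1])
    expect_equal(unname(f["size2"]), b[2] - b[1])
    expect_equal(unname(f["gap"]), b[1] - a[2])
    expect_equal(unname(f["dheight"]), 200)
    expect_equal(unname(f["dmedian_rep"]),
                 abs(mnz(seg(a[1], a[2])) - mnz(seg(b[1], b[2]))))
    expect_equal(unname(f["mean_rep_gap"]), mean(seg(a[2], b[1])))
  }
})

make_separable <- function(n, seed) {
  set.seed(seed)
  X <- cbind(matrix(runif(n * 2, 10, 300), n, 2),  # sizes
             runif(n, 0, 200),                     # gap
             matrix(runif(n * 6, 0, 2), n, 6),
             rbinom(n, 1, 0.5))
  colnames(X) <- c("size1", "size2", "gap", "dheight", "dmedian_rep",
                   "dmean_rep", "mean_rep1", "mean_rep2", "mean_rep_gap",
                   "same_region")
  list(X = X, y = X[, "gap"] < 100)
}

test_that("training on separable data reaches test F1 >= 0.95", {
  d <- make_separable(600, 62)
  m <- train_merge_model(d$X, d$y, seed = 1, n_iter = 15)
  expect_gte(m$test_metrics["f1"], 0.95)
  expect_length(m$weights, 10)
  # standardization constants exist for the 9 continuous features only
  expect_length(m$feature_means, 9)
})

test_that("label-permuted data scores near the prevalence baseline", {
  d <- make_separable(600, 63)
  set.seed(64)
  y_perm <- sample(d$y)
  m <- train_merge_model(d$X, y_perm, seed = 2, n_iter = 10)
  p <- mean(y_perm)
  baseline <- 2 * p / (1 + p) # all-positive classifier F1
  expect_lt(m$test_metrics["f1"], baseline + 0.15)
})

test_that("single-class labels are rejected", {
  d <- make_separable(100, 65)
  expect_error(train_merge_model(d$X, rep(TRUE, 100)), "single class")
})

test_that("model JSON serialization round-trips predictions", {
  d <- make_separable(400, 66)
  m <- train_merge_model(d$X, d$y, seed = 3, n_iter = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_merge_model(m, f)
  m2 <- read_merge_model(f)
  expect_equal(m2$weights, m$weights)
  expect_identical(predict_merge(m2, d$X), predict_merge(m, d$X))
})

test_that("assemble_candidates honors the model and the 200 bp floor", {
  prof <- mk_profile(rep(1, 5000))
  # a lone 300 bp stretch with rejecting model: one candidate
  st <- list(mk_stretch(100, 400, 900))
  got <- assemble_candidates(st, const_model(FALSE), prof, "x", "forward")
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100L)
  # a lone 150 bp stretch: discarded
  st <- list(mk_stretch(100, 250, 900))
  got <- assemble_candidates(st, const_model(FALSE), prof, "x", "forward")
  expect_equal(nrow(got), 0)
  # accept-all model fuses everything into the hull
  st <- list(mk_stretch(100, 200, 900), mk_stretch(1000, 1100, 900),
             mk_stretch(2600, 2700, 2000))
  got <- assemble_candidates(st, const_model(TRUE), prof, "x", "forward")
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 100L)
  expect_equal(got$end, 2700L)
  # reject-all model keeps them apart; the sub-200 ones vanish
  got <- assemble_candidates(st, const_model(FALSE), prof, "x", "forward")
  expect_equal(nrow(got), 0)
})

test_that("the packaged default model loads and performs on fresh pairs", {
  m <- default_merge_model()
  expect_s3_class(m, "merge_model")
  expect_length(m$weights, 10)
  ts <- generate_genome(list(plant_spec("t", ltr_divergence = 0.1,
                                        family_divergence = 0.1,
                                        copy_number = 3,
                                        indel_rate = 0.003)), 2e5,
                        seed = 67)
  td <- merge_training_data(ts)
  if (length(td$labels) > 4 && length(unique(td$labels)) == 2) {
    pred <- predict_merge(m, td$features)
    expect_gt(mean(pred == td$labels), 0.6)
  }
})
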