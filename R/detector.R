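# Detector: decides whether consecutive stretches belong to the same LTR
# using a linear classifier over 10 features, then assembles stretches into
# candidate LTRs.

FEATURE_NAMES <- c("size1", "size2", "gap", "dheight", "dmedian_rep",
                   "dmean_rep", "mean_rep1", "mean_rep2", "mean_rep_gap",
                   "same_region")

#' Features of a consecutive stretch pair
#'
#' The 10 features: sizes of the two stretches, gap size, absolute height
#' difference, absolute difference of the median non-zero repeat scores,
#' absolute difference of the mean repeat scores, mean repeat score of each
#' stretch and of the gap, and a binary flag for both stretches lying in
#' the same repetitive region. Only the last is binary; the rest are
#' non-negative reals.
#'
#' @param s1,s2 adjacent stretches of the same direction (`s1` upstream).
#' @param profile a [train_repeat_profile()] result.
#' @param sequence_id the sequence the stretches lie on.
#' @return named numeric vector of length 10.
#' @export
featurize_pair <- function(s1, s2, profile, sequence_id) {
  if (s2$start < s1$end) stop("stretches overlap")
  rep_scores <- profile$scores[[sequence_id]]
  regions <- profile$regions[[sequence_id]]
  seg <- function(a, b) if (b <= a) numeric(0) else rep_scores[(a + 1L):b]
  r1 <- seg(s1$start, s1$end); r2 <- seg(s2$start, s2$end)
  rg <- seg(s1$end, s2$start)
  med_nz <- function(v) { v <- v[v > 0]; if (length(v)) median(v) else 0 }
  mid1 <- (s1$start + s1$end) %/% 2L
  mid2 <- (s2$start + s2$end) %/% 2L
  reg1 <- region_index_at(regions, mid1)
  reg2 <- region_index_at(regions, mid2)
  c(size1 = s1$size, size2 = s2$size, gap = s2$start - s1$end,
    dheight = abs(s1$height - s2$height),
    dmedian_rep = abs(med_nz(r1) - med_nz(r2)),
    dmean_rep = abs(mean(r1) - mean(r2)),
    mean_rep1 = mean(r1), mean_rep2 = mean(r2),
    mean_rep_gap = if (length(rg)) mean(rg) else 0,
    same_region = as.numeric(!is.na(reg1) && !is.na(reg2) && reg1 == reg2))
}

standardize <- function(X, means, sds) {
  Xs <- X
  for (j in 1:9) Xs[, j] <- (X[, j] - means[j]) / sds[j]
  Xs
}

# plain SGD for a linear classifier; y in {-1, +1}
sgd_fit <- function(X, y, loss = c("log", "hinge"), lambda = 1e-4,
                    eta0 = 0.01, epochs = 10) {
  loss <- match.arg(loss)
  n <- nrow(X); d <- ncol(X)
  w <- numeric(d); b <- 0
  t <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- eta0 / (1 + lambda * eta0 * t)
      f <- sum(w * X[i, ]) + b
      if (loss == "hinge") {
        g <- if (y[i] * f < 1) -y[i] else 0
      } else {
        g <- -y[i] / (1 + exp(y[i] * f))
      }
      w <- w - eta * (lambda * w + g * X[i, ])
      b <- b - eta * g
    }
  }
  list(w = w, b = b)
}

f1_score <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

#' Train the stretch-merging classifier
#'
#' Standard supervised protocol: 70/20/10 train/validation/test split;
#' features 1-9 standardized with training-set statistics (the binary
#' feature is left alone); random search over SGD hyperparameters (loss,
#' L2 strength, learning rate, epochs) scored by 10-fold cross-validated F1
#' on the training split; the candidate with the best validation F1 is
#' kept, test metrics are reported, and the winner is refit on the entire
#' dataset with rescaled standardization constants.
#'
#' @param features numeric matrix (n x 10) from [featurize_pair()].
#' @param labels logical or 0/1 vector: TRUE when the pair belongs to the
#'   same LTR.
#' @param seed integer seed.
#' @param n_iter random-search iterations (default 30; scaled down from
#'   a full-size search for desk-scale training sets).
#' @param cv_folds cross-validation folds (default 10).
#' @return object of class `merge_model`: weights, bias, standardization
#'   constants, winning hyperparameters and held-out metrics.
#' @export
train_merge_model <- function(features, labels, seed = 1, n_iter = 30,
                              cv_folds = 10) {
  set.seed(seed)
  X <- as.matrix(features)
  stopifnot(ncol(X) == 10)
  y <- ifelse(as.logical(labels), 1, -1)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  n <- nrow(X)
  idx <- sample.int(n)
  n_tr <- floor(0.7 * n); n_va <- floor(0.2 * n)
  tr <- idx[seq_len(n_tr)]
  va <- idx[n_tr + seq_len(n_va)]
  te <- idx[(n_tr + n_va + 1):n]
  means <- colMeans(X[tr, 1:9, drop = FALSE])
  sds <- apply(X[tr, 1:9, drop = FALSE], 2, sd)
  sds[sds == 0 | is.na(sds)] <- 1
  Xtr <- standardize(X[tr, , drop = FALSE], means, sds)
  Xva <- standardize(X[va, , drop = FALSE], means, sds)
  Xte <- standardize(X[te, , drop = FALSE], means, sds)

  draw <- function() list(loss = sample(c("log", "hinge"), 1),
                          lambda = 10^runif(1, -6, -2),
                          eta0 = 10^runif(1, -3, -0.5),
                          epochs = sample(c(5L, 10L, 20L), 1))
  folds <- rep_len(seq_len(cv_folds), length(tr))[sample.int(length(tr))]
  best <- NULL
  for (it in seq_len(n_iter)) {
    hp <- draw()
    f1s <- vapply(seq_len(cv_folds), function(f) {
      hold <- folds == f
      if (all(hold) || !any(hold)) return(NA_real_)
      fit <- sgd_fit(Xtr[!hold, , drop = FALSE], y[tr][!hold], hp$loss,
                     hp$lambda, hp$eta0, hp$epochs)
      pred <- Xtr[hold, , drop = FALSE] %*% fit$w + fit$b > 0
      f1_score(y[tr][hold] > 0, pred)
    }, numeric(1))
    cv <- mean(f1s, na.rm = TRUE)
    fit <- sgd_fit(Xtr, y[tr], hp$loss, hp$lambda, hp$eta0, hp$epochs)
    va_f1 <- f1_score(y[va] > 0, Xva %*% fit$w + fit$b > 0)
    if (is.null(best) || va_f1 > best$va_f1) {
      best <- list(hp = hp, fit = fit, cv = cv, va_f1 = va_f1)
    }
  }
  pred_te <- Xte %*% best$fit$w + best$fit$b > 0
  tp <- sum(y[te] > 0 & pred_te); fp <- sum(y[te] < 0 & pred_te)
  fn <- sum(y[te] > 0 & !pred_te)
  test_metrics <- c(recall = if (tp + fn) tp / (tp + fn) else 0,
                    precision = if (tp + fp) tp / (tp + fp) else 0,
                    f1 = f1_score(y[te] > 0, pred_te))
  # refit on the entire dataset with rescaled statistics
  means_all <- colMeans(X[, 1:9, drop = FALSE])
  sds_all <- apply(X[, 1:9, drop = FALSE], 2, sd)
  sds_all[sds_all == 0 | is.na(sds_all)] <- 1
  Xall <- standardize(X, means_all, sds_all)
  fit_all <- sgd_fit(Xall, y, best$hp$loss, best$hp$lambda, best$hp$eta0,
                     best$hp$epochs)
  structure(list(weights = as.numeric(fit_all$w), bias = fit_all$b,
                 feature_means = as.numeric(means_all),
                 feature_sds = as.numeric(sds_all),
                 hyperparameters = best$hp, cv_f1 = best$cv,
                 validation_f1 = best$va_f1, test_metrics = test_metrics,
                 version = "1"),
            class = "merge_model")
}

#' Predict whether stretch pairs merge
#' @param model a `merge_model`.
#' @param features matrix or vector of 10 features.
#' @return logical vector.
#' @export
predict_merge <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1) else
    as.matrix(features)
  Xs <- standardize(X, model$feature_means, model$feature_sds)
  as.vector(Xs %*% model$weights + model$bias > 0)
}

#' Write / read a merge model as versioned JSON
#' @param model a `merge_model`.
#' @param path file path.
#' @return the model (read) or `path` invisibly (write).
#' @export
write_merge_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_merge_model
#' @export
read_merge_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$test_metrics <- unlist(m$test_metrics)
  structure(m, class = "merge_model")
}

#' The packaged pre-trained merge model
#'
#' Trained on shipped synthetic fixtures with a fixed seed (see
#' `tools/train_default_model.R`), so detection works out of the box.
#' @return a `merge_model`.
#' @export
default_merge_model <- function() {
  path <- system.file("extdata", "merge_model.json", package = "ltrscout")
  if (path == "") stop("packaged model not found")
  read_merge_model(path)
}

#' Assemble merged stretches into candidate LTRs
#'
#' Consecutive stretch pairs accepted by the classifier are chain-merged
#' (transitively); stretches that merge with nothing stand alone as
#' candidates. Candidates shorter than `min_len` (200 bp, the minimum LTR
#' size) are discarded.
#'
#' @param stretches merged stretches of one direction from
#'   [merge_stretches()].
#' @param model a `merge_model`.
#' @param profile a [train_repeat_profile()] result.
#' @param sequence_id sequence name.
#' @param direction `"forward"` or `"backward"`.
#' @param min_len minimum candidate length in bp.
#' @return data.frame of candidates: `start`, `end` (0-based half-open over
#'   k-mer starts), `direction`, plus a list-column `stretches`.
#' @export
assemble_candidates <- function(stretches, model, profile, sequence_id,
                                direction, min_len = 200) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      direction = character(0))
  if (length(stretches) == 0) {
    empty$stretches <- list()
    return(empty)
  }
  n <- length(stretches)
  grp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      f <- featurize_pair(stretches[[i]], stretches[[i + 1]], profile,
                          sequence_id)
      if (predict_merge(model, f)) grp[i + 1] <- grp[i]
    }
  }
  out <- lapply(unique(grp), function(g) {
    memb <- stretches[grp == g]
    list(start = memb[[1]]$start, end = memb[[length(memb)]]$end,
         stretches = memb)
  })
  out <- Filter(function(c) (c$end - c$start) >= min_len, out)
  if (length(out) == 0) {
    empty$stretches <- list()
    return(empty)
  }
  df <- data.frame(start = vapply(out, `[[`, integer(1), "start"),
                   end = vapply(out, `[[`, integer(1), "end"),
                   direction = direction, stringsAsFactors = FALSE)
  df$stretches <- lapply(out, `[[`, "stretches")
  df
}
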