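# Independent oracles and fixture helpers shared by the test files. These
# deliberately use naive algorithms (literal scans, quadratic DP) so they
# stay independent of the production code paths they check.

rand_dna <- function(n, gc = 0.42, alphabet = c("A", "C", "G", "T")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)[seq_along(alphabet)]
  paste(sample(alphabet, n, replace = TRUE, prob = p / sum(p)),
        collapse = "")
}

substitute_bases <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# literal nearest-match scan: for every position, look at all other
# positions within the window for an exact k-mer match, take the minimum
# distance per direction
brute_force_scores <- function(s, k = 13, min_dist = 400, max_dist = 27000) {
  n <- nchar(s)
  m <- n - k + 1
  km <- substring(s, 1:m, k:(m + k - 1))
  valid <- !grepl("N", km, fixed = TRUE)
  fwd <- integer(m)
  bwd <- integer(m)
  for (p in seq_len(m)) {
    if (!valid[p]) next
    lo <- p + min_dist
    hi <- min(m, p + max_dist)
    if (lo <= hi) {
      q <- which(km[lo:hi] == km[p] & valid[lo:hi])
      if (length(q)) fwd[p] <- q[1] + min_dist - 1L
    }
    lo2 <- max(1L, p - max_dist)
    hi2 <- p - min_dist
    if (lo2 <= hi2) {
      q <- which(km[lo2:hi2] == km[p] & valid[lo2:hi2])
      if (length(q)) bwd[p] <- p - (lo2 + q[length(q)] - 1L)
    }
  }
  list(forward = fwd, backward = bwd)
}

# quadratic Needleman-Wunsch with traceback: match +1, mismatch -1, gap -2
# per gapped position; identity = matches / alignment length
nw_identity_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av)
  nb <- length(bv)
  S <- matrix(0, na + 1, nb + 1)
  S[, 1] <- -2 * (0:na)
  S[1, ] <- -2 * (0:nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- S[i, j] + if (av[i] == bv[j]) 1 else -1
      S[i + 1, j + 1] <- max(d, S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
  }
  i <- na; j <- nb
  matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) 1 else -1)) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    len <- len + 1L
  }
  matches / len
}

# literal seven-step merge oracle: data.frame based, merging always the
# leftmost eligible pair and restarting from the beginning
oracle_df <- function(stretches) {
  data.frame(start = vapply(stretches, `[[`, integer(1), "start"),
             end = vapply(stretches, `[[`, integer(1), "end"),
             height = vapply(stretches, `[[`, numeric(1), "height"),
             label = vapply(stretches, `[[`, character(1), "label"),
             members = I(lapply(stretches, `[[`, "members")))
}

oracle_merge_pass <- function(df, scores, margin, kt) {
  repeat {
    if (nrow(df) < 2) return(df)
    done <- TRUE
    for (i in seq_len(nrow(df) - 1)) {
      if (abs(df$height[i] - df$height[i + 1]) < margin &&
          (df$start[i + 1] - df$end[i]) < margin) {
        members <- c(df$members[[i]], df$members[[i + 1]])
        v <- unlist(lapply(members, function(m) scores[(m[1] + 1):m[2]]))
        v <- v[v != 0]
        row <- data.frame(start = df$start[i], end = df$end[i + 1],
                          height = stats::median(v),
                          label = ifelse(df$end[i + 1] - df$start[i] >= kt,
                                         "keep", "delete"),
                          members = I(list(members)))
        df <- rbind(if (i > 1) df[1:(i - 1), ] else NULL, row,
                    if (i + 1 < nrow(df)) df[(i + 2):nrow(df), ] else NULL)
        done <- FALSE
        break
      }
    }
    if (done) return(df)
  }
}

oracle_merge <- function(stretches, scores, config) {
  m <- config$similarity_margin
  kt <- config$keep_threshold
  df <- oracle_df(stretches)
  df <- oracle_merge_pass(df, scores, m, kt)           # step 3
  if (nrow(df) >= 3) {                                 # step 4
    drop <- logical(nrow(df))
    for (j in 2:(nrow(df) - 1)) {
      if (df$label[j] == "delete" &&
          abs(df$height[j - 1] - df$height[j + 1]) < m &&
          (df$start[j + 1] - df$end[j - 1]) < m) {
        drop[j] <- TRUE
      }
    }
    df <- df[!drop, ]
  }
  df <- oracle_merge_pass(df, scores, m, kt)           # step 5
  df <- df[df$label == "keep", ]                       # step 6
  oracle_merge_pass(df, scores, m, kt)                 # step 7
}

# longest common substring length via literal suffix comparison
lcs_oracle <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      l <- 0L
      while (i + l <= na && j + l <= nb &&
             substr(a, i + l, i + l) == substr(b, j + l, j + l)) {
        l <- l + 1L
      }
      best <- max(best, l)
    }
  }
  best
}

# random score vector with plateau runs, for merger fixtures
random_score_vector <- function(n = 200, n_runs = 8, heights = NULL) {
  s <- integer(n)
  if (is.null(heights)) heights <- sample(c(450, 500, 520, 1000, 5000), 5)
  for (r in seq_len(n_runs)) {
    len <- sample(1:40, 1)
    at <- sample(n - len, 1)
    s[at:(at + len - 1)] <- sample(heights, 1)
  }
  s
}

# a small single-element truth world used by several module tests
tiny_world <- function(seed = 42, copy_number = 2, ...) {
  generate_genome(list(plant_spec("fam", copy_number = copy_number, ...)),
                  2e5, seed = seed)
}

truth_element_candidate <- function(a) {
  el <- list(ltr5 = a$ltr5, ltr3 = a$ltr3,
             internal = list(start = a$ltr5$end, end = a$ltr3$start),
             start = a$start, end = a$end, case_origin = "truth",
             weights = c(1, 1), children = list(),
             sequence_id = a$sequence_id)
  class(el) <- "element_candidate"
  el
}
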