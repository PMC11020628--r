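# Synthetic plant-like genomes with planted LTR retrotransposons and exact
# truth annotations. The generator supports same-family multi-copy
# insertions, solo LTRs, one- and multi-level same-family nesting,
# sequential same-family runs, and MITE decoys with terminal inverted
# repeats.

#' Specify a planted repeat family
#'
#' Describes one family of insertions for [generate_genome()]. An LTR
#' family (`kind = "ltr"`) consists of `copy_number` full elements
#' (5' LTR + internal part carrying a polypurine tract + 3' LTR, flanked by
#' a target-site duplication), optional solo LTRs placed downstream of full
#' copies, optional sequential runs, and an optional nested insertion
#' planted inside the first copy's internal part. A MITE family
#' (`kind = "mite"`) plants small decoys bounded by terminal inverted
#' repeats and no internal signature.
#'
#' @param family_id family label; specs sharing a label share a consensus,
#'   so nesting a spec with the same `family_id` produces same-family nests.
#' @param ltr_length LTR length in bp (>= 200).
#' @param internal_length internal-part length in bp (>= 200).
#' @param ltr_divergence substitution rate between the two LTRs of one
#'   insertion, in [0, 0.4].
#' @param family_divergence approximate pairwise substitution divergence
#'   between family copies (each copy drifts from the consensus at half
#'   this rate).
#' @param copy_number number of full elements.
#' @param tsd_length target-site duplication length (>= 4).
#' @param ppt_length polypurine tract length (>= 13).
#' @param solo_count number of solo LTRs, each placed 2-8 kb downstream of
#'   one full copy (so graph components link them to their family).
#' @param sequential_run if >= 2, that many of the copies are placed
#'   back-to-back with 1-3 kb gaps.
#' @param nesting optional `plant_spec` planted inside the first copy;
#'   may itself carry `nesting` for multi-level nests.
#' @param indel_rate per-base indel rate applied alongside substitutions
#'   (default 0: substitutions only).
#' @param kind `"ltr"` or `"mite"`.
#' @param mite_length,tir_length MITE geometry (only for `kind = "mite"`).
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(family_id, ltr_length = 500, internal_length = 2000,
                       ltr_divergence = 0.02, family_divergence = 0.05,
                       copy_number = 2, tsd_length = 5, ppt_length = 15,
                       solo_count = 0, sequential_run = 0, nesting = NULL,
                       indel_rate = 0, kind = c("ltr", "mite"),
                       mite_length = 400, tir_length = 25) {
  kind <- match.arg(kind)
  if (kind == "ltr") {
    stopifnot(ltr_length >= 200, internal_length >= 200,
              ltr_divergence >= 0, ltr_divergence <= 0.4,
              family_divergence >= 0, family_divergence <= 0.4,
              tsd_length >= 4, ppt_length >= 13, copy_number >= 1)
    if (!is.null(nesting)) stopifnot(inherits(nesting, "plant_spec"))
  }
  structure(list(family_id = family_id, ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 ltr_divergence = ltr_divergence,
                 family_divergence = family_divergence,
                 copy_number = as.integer(copy_number),
                 tsd_length = as.integer(tsd_length),
                 ppt_length = as.integer(ppt_length),
                 solo_count = as.integer(solo_count),
                 sequential_run = as.integer(sequential_run),
                 nesting = nesting, indel_rate = indel_rate, kind = kind,
                 mite_length = as.integer(mite_length),
                 tir_length = as.integer(tir_length)),
            class = "plant_spec")
}

rand_seq <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# substitutions always; indels optional (length ~ 1 + geometric, mean ~30,
# capped at 150 bp, insertion or deletion with equal probability)
mutate_seq <- function(s, rate, indel_rate = 0) {
  if (nchar(s) == 0) return(s)
  v <- strsplit(s, "")[[1]]
  if (rate > 0) {
    hit <- which(runif(length(v)) < rate)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  if (indel_rate > 0) {
    sites <- which(runif(length(v)) < indel_rate)
    for (i in rev(sites)) { # right to left keeps positions valid
      len <- min(150L, 1L + stats::rgeom(1, 1 / 30))
      if (runif(1) < 0.5) { # deletion
        drop <- i:min(length(v), i + len - 1L)
        v <- v[-drop]
      } else { # insertion
        ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        v <- append(v, ins, after = i)
      }
    }
  }
  paste(v, collapse = "")
}

# family consensus: LTR, internal with an embedded polypurine tract placed
# inside the last 400 bp of the internal part (so the PPT filter can fire)
make_consensus <- function(spec, gc) {
  internal <- rand_seq(spec$internal_length, gc)
  ppt_start <- spec$internal_length - 80L - spec$ppt_length
  if (ppt_start < 0) ppt_start <- max(0L, spec$internal_length - spec$ppt_length)
  ppt <- paste(sample(c("A", "G"), spec$ppt_length, replace = TRUE,
                      prob = c(0.85, 0.15)), collapse = "")
  internal <- paste0(substr(internal, 1, ppt_start),
                     ppt,
                     substr(internal, ppt_start + spec$ppt_length + 1,
                            spec$internal_length))
  list(ltr = rand_seq(spec$ltr_length, gc), internal = internal,
       ppt = iv(ppt_start, ppt_start + spec$ppt_length))
}

# Build one element copy (recursively inserting a nested child block).
# Returns list(seq, anns) where anns hold 0-based coordinates relative to
# the element start and the element itself is anns[[1]].
build_element_block <- function(spec, consensus_of, level = 0L) {
  cons <- consensus_of(spec)
  # each copy drifts from the consensus at half the family divergence, so
  # family_divergence approximates the pairwise divergence between copies
  ltr5 <- mutate_seq(cons$ltr, spec$family_divergence / 2, spec$indel_rate)
  ltr3 <- mutate_seq(ltr5, spec$ltr_divergence, spec$indel_rate)
  internal <- mutate_seq(cons$internal, spec$family_divergence / 2,
                         spec$indel_rate)
  l5 <- nchar(ltr5); il <- nchar(internal); l3 <- nchar(ltr3)
  anns <- list()
  child_anns <- list()
  if (!is.null(spec$nesting)) {
    child <- build_element_block(spec$nesting, consensus_of, level + 1L)
    t <- spec$nesting$tsd_length
    # insertion offset near the middle of the internal part, clear of the PPT
    max_off <- min(il %/% 2L + il %/% 10L, cons$ppt$start - 50L - t)
    min_off <- max(150L, il %/% 2L - il %/% 10L)
    if (max_off < min_off) stop("internal part too short to host a nest")
    off <- min_off + floor(runif(1) * (max_off - min_off + 1))
    tsd <- substr(internal, off + 1L, off + t)
    internal <- paste0(substr(internal, 1L, off + t), child$seq,
                       substr(internal, off + 1L, il))
    # shift child annotations into internal coordinates
    child_shift <- l5 + off + t
    child_anns <- lapply(child$anns, function(a) {
      shift_rel_ann(a, child_shift)
    })
    # the child's own TSD copies flank the child element
    clen <- nchar(child$seq)
    child_anns[[1]]$tsd <- list(iv(child_shift - t, child_shift),
                                iv(child_shift + clen,
                                   child_shift + clen + t))
    il <- nchar(internal)
  }
  seq <- paste0(ltr5, internal, ltr3)
  # the PPT lies downstream of any insertion offset by construction, so it
  # is shifted by the full inserted length when a nest is present
  ins_len <- il - nchar(cons$internal)
  ppt <- iv(l5 + cons$ppt$start + ins_len, l5 + cons$ppt$end + ins_len)
  self <- list(start = 0L, end = nchar(seq),
               ltr5 = iv(0L, l5), ltr3 = iv(l5 + il, l5 + il + l3),
               ppt = ppt, ppt_strand = "+", tsd = NULL,
               nesting_level = level, kind = "element",
               family = spec$family_id)
  list(seq = seq, anns = c(list(self), child_anns))
}

shift_rel_ann <- function(a, by) {
  for (f in c("ltr5", "ltr3", "ppt")) {
    if (!is.null(a[[f]])) a[[f]] <- iv(a[[f]]$start + by, a[[f]]$end + by)
  }
  if (!is.null(a$tsd)) {
    a$tsd <- lapply(a$tsd, function(t) iv(t$start + by, t$end + by))
  }
  a$start <- a$start + by
  a$end <- a$end + by
  a
}

build_solo_block <- function(spec, consensus_of) {
  cons <- consensus_of(spec)
  seq <- mutate_seq(cons$ltr, spec$family_divergence / 2, spec$indel_rate)
  list(seq = seq,
       anns = list(list(start = 0L, end = nchar(seq),
                        ltr5 = iv(0L, nchar(seq)), ltr3 = NULL, ppt = NULL,
                        ppt_strand = NA_character_, tsd = NULL,
                        nesting_level = 0L, kind = "solo_ltr",
                        family = spec$family_id)))
}

build_mite_block <- function(spec, gc) {
  tir <- rand_seq(spec$tir_length, gc)
  filler <- rand_seq(max(0L, spec$mite_length - 2L * spec$tir_length), gc)
  seq <- paste0(tir, filler, revcomp(tir))
  list(seq = seq,
       anns = list(list(start = 0L, end = nchar(seq), ltr5 = NULL,
                        ltr3 = NULL, ppt = NULL, ppt_strand = NA_character_,
                        tsd = NULL, nesting_level = 0L, kind = "mite",
                        family = spec$family_id)))
}

#' Generate a synthetic genome with planted LTR retrotransposons
#'
#' Builds an i.i.d. background at the requested GC content and inserts the
#' families described by `specs`, each full element flanked by a target-site
#' duplication copied from the insertion site. Deterministic for a fixed
#' seed. MITE decoys are returned separately from the truth annotations.
#'
#' @param specs list of [plant_spec()] objects.
#' @param background_length background length in bp before insertions.
#' @param gc background GC fraction (default 0.42, plant-like).
#' @param seed integer seed.
#' @param min_spacing minimum background distance between independent
#'   insertions (default 30000 bp, beyond the scorer's match window so
#'   unrelated copies do not cross-talk).
#' @param sequence_id name of the single output sequence.
#' @return object of class `truth_set`: list with `genome` (a
#'   [genome_set()]), `annotations` (list of [annotation()]; elements and
#'   solo LTRs), and `decoys` (MITE annotations).
#' @export
generate_genome <- function(specs, background_length, gc = 0.42, seed = 1,
                            min_spacing = 30000, sequence_id = "chr1") {
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  set.seed(seed)
  bg <- rand_seq(background_length, gc)

  consensus_cache <- new.env(parent = emptyenv())
  consensus_of <- function(spec) {
    key <- spec$family_id
    if (!exists(key, envir = consensus_cache)) {
      assign(key, make_consensus(spec, gc), envir = consensus_cache)
    }
    cons <- get(key, envir = consensus_cache)
    if (nchar(cons$ltr) != spec$ltr_length ||
        nchar(cons$internal) != spec$internal_length) {
      stop("specs sharing family_id '", key, "' must share geometry")
    }
    cons
  }

  # assemble the ordered list of insertion units; `gap` is the background
  # distance in front of each unit, `tsd` its target-site duplication length
  units <- list()
  push <- function(block, gap, tsd) {
    units[[length(units) + 1L]] <<- list(block = block, gap = gap,
                                         tsd = as.integer(tsd))
  }
  small_gap <- function() 2000L + floor(runif(1) * 6000L)
  run_gap <- function() 1000L + floor(runif(1) * 2000L)
  for (spec in specs) {
    if (spec$kind == "mite") {
      # same-family MITEs cluster within the scorer window so they act as
      # genuine pairing decoys
      for (i in seq_len(spec$copy_number)) {
        push(build_mite_block(spec, gc),
             if (i == 1L) min_spacing else small_gap(), 0L)
      }
      next
    }
    n_run <- min(spec$sequential_run, spec$copy_number)
    solo_after <- rep(FALSE, spec$copy_number)
    if (spec$solo_count > 0) {
      idx <- seq(to = spec$copy_number, length.out = min(spec$solo_count,
                                                         spec$copy_number))
      solo_after[idx] <- TRUE
    }
    for (i in seq_len(spec$copy_number)) {
      nest_here <- if (i == 1L) spec$nesting else NULL
      sp_i <- spec
      sp_i$nesting <- nest_here
      gap <- if (i > 1L && i <= n_run) run_gap() else min_spacing
      push(build_element_block(sp_i, consensus_of), gap, spec$tsd_length)
      if (solo_after[i]) push(build_solo_block(spec, consensus_of),
                              small_gap(), spec$tsd_length)
    }
  }
  if (length(units) == 0L) {
    g <- genome_set(stats::setNames(bg, sequence_id))
    return(structure(list(genome = g, annotations = list(), decoys = list()),
                     class = "truth_set"))
  }

  # anchors in the background, left to right, honoring per-unit gaps
  margin <- 2000L
  anchors <- integer(length(units))
  pos <- margin + floor(runif(1) * 1000L)
  for (i in seq_along(units)) {
    if (i > 1L) pos <- anchors[i - 1L] + units[[i]]$gap +
        floor(runif(1) * (units[[i]]$gap %/% 5L + 1L))
    anchors[i] <- pos
  }
  if (anchors[length(anchors)] > background_length - margin) {
    stop("insertions overflow background: need anchors up to ",
         anchors[length(anchors)], " in ", background_length, " bp")
  }

  # splice units into the background, duplicating the TSD at each site
  pieces <- character(0)
  anns <- list()
  prev <- 0L
  offset <- 0L # cumulative inserted length
  for (i in seq_along(units)) {
    u <- units[[i]]
    a <- anchors[i]
    blk <- u$block
    t <- u$tsd
    pieces <- c(pieces, substr(bg, prev + 1L, a + t), blk$seq)
    ins_at <- a + offset + t # genomic start of the block
    for (ba in blk$anns) {
      anns[[length(anns) + 1L]] <- shift_rel_ann(ba, ins_at)
    }
    if (t > 0L) {
      anns[[length(anns) - length(blk$anns) + 1L]]$tsd <-
        list(iv(ins_at - t, ins_at), iv(ins_at + nchar(blk$seq),
                                        ins_at + nchar(blk$seq) + t))
    }
    prev <- a
    offset <- offset + nchar(blk$seq) + t
  }
  pieces <- c(pieces, substr(bg, prev + 1L, background_length))
  genome_seq <- paste(pieces, collapse = "")

  truth <- list(); decoys <- list()
  for (a in anns) {
    obj <- annotation(sequence_id, a$start, a$end, ltr5 = a$ltr5,
                      ltr3 = a$ltr3, ppt = a$ppt, ppt_strand = a$ppt_strand,
                      tsd = a$tsd, nesting_level = a$nesting_level,
                      kind = if (a$kind == "mite") "complex_region" else a$kind,
                      id = paste0(a$family, "_", length(truth) +
                                    length(decoys) + 1L))
    if (a$kind == "mite") decoys[[length(decoys) + 1L]] <- obj
    else truth[[length(truth) + 1L]] <- obj
  }
  g <- genome_set(stats::setNames(genome_seq, sequence_id))
  structure(list(genome = g, annotations = truth, decoys = decoys),
            class = "truth_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.truth_set <- function(x, ...) {
  kinds <- vapply(x$annotations, function(a) a$kind, character(1))
  cat(sprintf("truth_set: %d bp genome, %d elements, %d solo LTRs, %d decoys\n",
              sum(nchar(x$genome$sequences)), sum(kinds == "element"),
              sum(kinds == "solo_ltr"), length(x$decoys)))
  invisible(x)
}

#' Build a semi-synthetic genome by shuffling inter-element regions
#'
#' Keeps every truth element in place and randomly permutes the residues of
#' every region between elements, destroying all other repeats while
#' preserving total length, per-region base composition, and the element
#' substrings byte for byte. This is the construction used to train the
#' stretch-merging classifier on genomes whose annotation is incomplete.
#'
#' @param genome a [genome_set()].
#' @param truth list of [annotation()] objects valid in `genome`.
#' @param seed integer seed.
#' @return a [genome_set()] of the same shape.
#' @export
make_semisynthetic <- function(genome, truth, seed = 1) {
  set.seed(seed)
  out <- genome$sequences
  for (sid in names(out)) {
    s <- out[[sid]]
    n <- nchar(s)
    ann <- Filter(function(a) a$sequence_id == sid &&
                    a$kind %in% c("element", "solo_ltr"), truth)
    if (length(ann) > 0) {
      starts <- vapply(ann, function(a) a$start, integer(1))
      ends <- vapply(ann, function(a) a$end, integer(1))
      o <- order(starts)
      starts <- starts[o]; ends <- ends[o]
      # collapse nested/contained spans; partial overlap is an error
      ms <- starts[1]; me <- ends[1]
      keep_s <- integer(0); keep_e <- integer(0)
      for (i in seq_along(starts)[-1]) {
        if (starts[i] < me) {
          if (ends[i] > me) stop("overlapping truth intervals without ",
                                 "declared nesting")
          next
        }
        keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me)
        ms <- starts[i]; me <- ends[i]
      }
      keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me)
      starts <- keep_s; ends <- keep_e
    } else {
      starts <- integer(0); ends <- integer(0)
    }
    bounds <- c(0L, rbind(starts, ends), n)
    pieces <- character(0)
    for (j in seq(1, length(bounds) - 1)) {
      a <- bounds[j]; b <- bounds[j + 1]
      piece <- seq_slice(s, a, b)
      if (j %% 2 == 1 && nchar(piece) > 1) { # inter-element region
        piece <- paste(sample(strsplit(piece, "")[[1]]), collapse = "")
      }
      pieces <- c(pieces, piece)
    }
    out[[sid]] <- paste(pieces, collapse = "")
  }
  genome_set(out, genome$source)
}

#' The benchmark validation world
#'
#' A 1 Mb genome with 17 planted elements across four families (two
#' one-level nests and one two-level nest among them), 3 solo LTRs, and a
#' cluster of 6 MITE decoys, all at pairwise divergence <= 0.05. This is
#' the stated world for the end-to-end recovery tests: recall and
#' precision of the full pipeline are measured against it at 80%
#' reciprocal overlap.
#'
#' @param background_length background size in bp (default 1e6).
#' @param seed integer seed.
#' @return a `truth_set`, see [generate_genome()].
#' @export
benchmark_genome <- function(background_length = 1e6, seed = 1) {
  specs <- list(
    plant_spec("famA", ltr_length = 500, internal_length = 2000,
               ltr_divergence = 0.02, family_divergence = 0.05,
               copy_number = 5, solo_count = 2),
    plant_spec("famB", ltr_length = 400, internal_length = 2500,
               ltr_divergence = 0.03, family_divergence = 0.05,
               copy_number = 4, solo_count = 1,
               # nested children inserted recently: near-identical LTRs
               nesting = plant_spec("famB", ltr_length = 400,
                                    internal_length = 2500,
                                    ltr_divergence = 0.01,
                                    family_divergence = 0.05)),
    plant_spec("famC", ltr_length = 300, internal_length = 3000,
               ltr_divergence = 0.02, family_divergence = 0.04,
               copy_number = 2,
               nesting = plant_spec("famC", ltr_length = 300,
                                    internal_length = 3000,
                                    ltr_divergence = 0.015,
                                    family_divergence = 0.04,
                                    nesting = plant_spec(
                                      "famC", ltr_length = 300,
                                      internal_length = 3000,
                                      ltr_divergence = 0.005,
                                      family_divergence = 0.04))),
    plant_spec("famD", ltr_length = 600, internal_length = 1800,
               ltr_divergence = 0.05, family_divergence = 0.05,
               copy_number = 2,
               nesting = plant_spec("famD", ltr_length = 600,
                                    internal_length = 1800,
                                    ltr_divergence = 0.01,
                                    family_divergence = 0.05)),
    plant_spec("mite1", kind = "mite", copy_number = 6, mite_length = 400,
               tir_length = 25))
  generate_genome(specs, background_length, seed = seed)
}
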