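#' Construct a genome set
#'
#' A genome set is the unit of input for detection: an ordered collection of
#' named nucleotide sequences, each tagged with the genome (file or species)
#' it came from. Cross-species runs simply put several genomes in one set.
#'
#' @param sequences named character vector of nucleotide sequences
#'   (A/C/G/T/N after uppercasing; other IUPAC codes are rejected).
#' @param source character vector of genome-of-origin labels, recycled to
#'   the number of sequences.
#' @return an object of class `genome_set` with elements `sequences` and
#'   `source`.
#' @export
genome_set <- function(sequences, source = "genome") {
  if (length(sequences) == 0L) stop("genome set must contain sequences")
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "")) stop("all sequences must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1L])
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-ACGTN residues in sequence: ", ids[bad][1L])
  }
  if (any(nchar(sequences) == 0L)) {
    stop("empty sequence: ", ids[nchar(sequences) == 0L][1L])
  }
  source <- rep_len(source, length(sequences))
  structure(list(sequences = sequences, source = source),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d sequence(s), %d bp total, %d genome(s)\n",
              length(x$sequences), sum(nchar(x$sequences)),
              length(unique(x$source))))
  invisible(x)
}

#' Read one or more FASTA files into a genome set
#'
#' Records are uppercased on load; each record keeps the basename of its
#' file as its genome-of-origin tag. Record order is preserved within and
#' across files.
#'
#' @param paths character vector of FASTA file paths.
#' @return a [genome_set()].
#' @export
read_fasta <- function(paths) {
  seqs <- character(0)
  src <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    ss <- Biostrings::readDNAStringSet(p)
    if (length(ss) == 0L) stop("empty FASTA file: ", p)
    v <- as.character(ss)
    # keep only the first whitespace-delimited token of each header
    names(v) <- sub("\\s.*$", "", names(ss))
    seqs <- c(seqs, v)
    src <- c(src, rep(basename(p), length(v)))
  }
  genome_set(seqs, src)
}

#' Write a genome set to FASTA
#' @param genomes a [genome_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(genomes, path) {
  ss <- Biostrings::DNAStringSet(genomes$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct an annotation
#'
#' One annotated feature on one sequence: a full LTR retrotransposon
#' (`kind = "element"`, with 5' and 3' LTR sub-intervals and optionally a
#' polypurine tract and target-site duplication), a solo LTR, or a complex
#' region of sequential same-family insertions. All intervals are 0-based
#' half-open.
#'
#' @param sequence_id sequence the feature lies on.
#' @param start,end element interval.
#' @param ltr5,ltr3 LTR intervals (lists with `start`/`end`), `NULL` where
#'   not applicable.
#' @param ppt optional polypurine-tract interval; `ppt_strand` is `"+"` for
#'   the plus-strand (A/G upstream of the 3' LTR) or `"-"` for the reversed
#'   orientation hypothesis.
#' @param ppt_strand PPT orientation, see above.
#' @param tsd optional list of two intervals (upstream, downstream copy).
#' @param nesting_level 0 for top-level insertions.
#' @param kind `"element"`, `"solo_ltr"` or `"complex_region"`.
#' @param id optional feature identifier.
#' @return object of class `ltr_annotation`.
#' @export
annotation <- function(sequence_id, start, end, ltr5 = NULL, ltr3 = NULL,
                       ppt = NULL, ppt_strand = NA_character_, tsd = NULL,
                       nesting_level = 0L,
                       kind = c("element", "solo_ltr", "complex_region"),
                       id = NA_character_) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("empty element interval")
  if (kind == "element") {
    if (is.null(ltr5) || is.null(ltr3)) stop("element needs both LTRs")
    if (!(ltr5$end <= ltr3$start)) stop("ltr5 must precede ltr3")
    if (ltr5$start < start || ltr3$end > end) {
      stop("LTRs must lie within the element interval")
    }
  }
  structure(list(sequence_id = sequence_id, start = start, end = end,
                 ltr5 = ltr5, ltr3 = ltr3, ppt = ppt,
                 ppt_strand = ppt_strand, tsd = tsd,
                 nesting_level = as.integer(nesting_level), kind = kind,
                 id = id),
            class = "ltr_annotation")
}

ann_field <- function(x, what) {
  f <- x[[what]]
  if (is.null(f)) c(NA_integer_, NA_integer_) else c(f$start, f$end)
}

#' Convert a list of annotations to a data frame
#'
#' One row per annotation; interval columns are 0-based half-open, absent
#' sub-features are `NA`.
#'
#' @param annotations list of [annotation()] objects.
#' @return data.frame.
#' @export
annotations_to_df <- function(annotations) {
  if (length(annotations) == 0L) {
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), kind = character(0)))
  }
  do.call(rbind, lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    l5 <- ann_field(a, "ltr5"); l3 <- ann_field(a, "ltr3")
    pp <- ann_field(a, "ppt")
    t5 <- if (is.null(a$tsd)) c(NA, NA) else c(a$tsd[[1]]$start, a$tsd[[1]]$end)
    t3 <- if (is.null(a$tsd)) c(NA, NA) else c(a$tsd[[2]]$start, a$tsd[[2]]$end)
    data.frame(sequence_id = a$sequence_id, start = a$start, end = a$end,
               kind = a$kind, nesting_level = a$nesting_level,
               id = if (is.na(a$id)) sprintf("feat%04d", i) else a$id,
               ltr5_start = l5[1], ltr5_end = l5[2],
               ltr3_start = l3[1], ltr3_end = l3[2],
               ppt_start = pp[1], ppt_end = pp[2], ppt_strand = a$ppt_strand,
               tsd5_start = t5[1], tsd5_end = t5[2],
               tsd3_start = t3[1], tsd3_end = t3[2],
               stringsAsFactors = FALSE)
  }))
}

df_to_annotations <- function(df) {
  mk <- function(s, e) {
    if (is.na(s) || is.na(e)) NULL else iv(s, e)
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tsd <- NULL
    if (!is.na(r$tsd5_start)) {
      tsd <- list(iv(r$tsd5_start, r$tsd5_end), iv(r$tsd3_start, r$tsd3_end))
    }
    annotation(r$sequence_id, r$start, r$end,
               ltr5 = mk(r$ltr5_start, r$ltr5_end),
               ltr3 = mk(r$ltr3_start, r$ltr3_end),
               ppt = mk(r$ppt_start, r$ppt_end), ppt_strand = r$ppt_strand,
               tsd = tsd, nesting_level = r$nesting_level, kind = r$kind,
               id = r$id)
  })
}

#' Write annotations to BED or GFF3
#'
#' BED output is 0-based half-open with extra columns carrying the LTR, PPT
#' and TSD sub-intervals; GFF3 output is 1-based inclusive, with the PPT and
#' TSD emitted as child features and nested elements referencing their
#' parent through the `Parent` attribute.
#'
#' @param annotations list of [annotation()] objects.
#' @param path output file.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  df <- annotations_to_df(annotations)
  if (format == "bed") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
    if (nrow(df) > 0) {
      write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE, na = ".")
    }
    return(invisible(path))
  }
  # GFF3
  lines <- "##gff-version 3"
  if (nrow(df) > 0) {
    # assign Parent for nested elements by containment
    for (i in seq_len(nrow(df))) {
      r <- df[i, ]
      type <- switch(r$kind, element = "LTR_retrotransposon",
                     solo_ltr = "solo_LTR", complex_region = "repeat_region")
      parent <- ""
      if (r$nesting_level > 0) {
        cand <- which(df$sequence_id == r$sequence_id &
                        df$start <= r$start & df$end >= r$end &
                        df$nesting_level == r$nesting_level - 1L)
        if (length(cand) > 0) parent <- paste0(";Parent=", df$id[cand[1L]])
      }
      lines <- c(lines, sprintf("%s\tltrscout\t%s\t%d\t%d\t.\t+\t.\tID=%s%s",
                                r$sequence_id, type, r$start + 1L, r$end,
                                r$id, parent))
      child <- function(type, s, e, suffix, extra = "") {
        sprintf("%s\tltrscout\t%s\t%d\t%d\t.\t+\t.\tID=%s_%s;Parent=%s%s",
                r$sequence_id, type, s + 1L, e, r$id, suffix, r$id, extra)
      }
      if (!is.na(r$ltr5_start)) {
        lines <- c(lines, child("long_terminal_repeat", r$ltr5_start,
                                r$ltr5_end, "ltr5"))
      }
      if (!is.na(r$ltr3_start)) {
        lines <- c(lines, child("long_terminal_repeat", r$ltr3_start,
                                r$ltr3_end, "ltr3"))
      }
      if (!is.na(r$ppt_start)) {
        lines <- c(lines, child("RR_tract", r$ppt_start, r$ppt_end, "ppt",
                                sprintf(";ppt_strand=%s", r$ppt_strand)))
      }
      if (!is.na(r$tsd5_start)) {
        lines <- c(lines,
                   child("target_site_duplication", r$tsd5_start, r$tsd5_end,
                         "tsd5"),
                   child("target_site_duplication", r$tsd3_start, r$tsd3_end,
                         "tsd3"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read annotations from a BED file written by [write_annotations()]
#' @param path BED file.
#' @return list of [annotation()] objects.
#' @export
read_annotations <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  body <- readLines(path)[-1L]
  if (length(body) == 0L) return(list())
  df <- read.table(text = body, sep = "\t", col.names = cols, na.strings = ".",
                   stringsAsFactors = FALSE)
  df_to_annotations(df)
}
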