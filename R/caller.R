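# Amplicon indel calling against a reference.
#
# Reads are aligned end-to-end (global, end-anchored Needleman-Wunsch via
# Biostrings) and gaps are mapped to reference-coordinate deletion
# intervals and insertion events.  Indels are normalised VCF-style: every
# event is shifted to its lowest reference coordinate compatible with the
# flanking sequence, so shift-equivalent placements inside repeats collapse
# to one canonical representative.  Substitution-only reads are treated as
# sequencing error, never as edits.

#' Alignment scoring parameters
#'
#' Conventional amplicon settings: match +2, mismatch -3, gap open -6,
#' gap extend -1, where a gap of length L costs `open + (L-1) * extend`.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring values (penalties
#'   positive).
#' @return List of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 6,
                          gap_extend = 1) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0,
            gap_extend <= gap_open)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

.subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

# Shift a deletion [s, e) (0-based, half-open) to its lowest reference
# coordinate: shifting left by one is allowed when ref[s-1] == ref[e-1]
# (0-based), i.e. the remaining sequence is unchanged.  `floor` bounds the
# shift (end of the previous deletion).
.left_align_del <- function(ref_chars, s, e, floor = 0L) {
  while (s > floor && ref_chars[s] == ref_chars[e]) {
    s <- s - 1L
    e <- e - 1L
  }
  c(s, e)
}

# Shift an insertion at junction p (0-based inter-base index) with sequence
# `seq` to its lowest junction: allowed when the reference base left of the
# junction equals the last inserted base (rotate the insertion).
.left_align_ins <- function(ref_chars, p, seq) {
  v <- strsplit(seq, "")[[1L]]
  k <- length(v)
  while (p > 0L && ref_chars[p] == v[k]) {
    v <- c(v[k], v[-k])
    p <- p - 1L
  }
  list(point = p, seq = paste0(v, collapse = ""))
}

# Canonicalize a set of deletions (matrix-like df with start,end) and
# insertions (df with point,seq): left-align each, merge deletions that
# become adjacent or overlapping, keep sorted.
.canonicalize <- function(ref_chars, dels, ins) {
  if (nrow(dels) > 0L) {
    dels$start <- as.integer(dels$start)
    dels$end <- as.integer(dels$end)
    dels <- dels[order(dels$start), , drop = FALSE]
    out <- list()
    floor <- 0L
    for (i in seq_len(nrow(dels))) {
      se <- .left_align_del(ref_chars, dels$start[i], dels$end[i], floor)
      if (length(out) > 0L && se[1] <= out[[length(out)]][2]) {
        prev <- out[[length(out)]]
        out[[length(out)]] <- c(prev[1], max(prev[2], se[2]))
      } else {
        out[[length(out) + 1L]] <- se
      }
      floor <- out[[length(out)]][2]
    }
    dels <- data.frame(start = vapply(out, `[`, integer(1), 1L),
                       end = vapply(out, `[`, integer(1), 2L))
  }
  if (nrow(ins) > 0L) {
    ins$point <- as.integer(ins$point)
    shifted <- lapply(seq_len(nrow(ins)), function(i) {
      .left_align_ins(ref_chars, ins$point[i], ins$seq[i])
    })
    ins <- data.frame(point = vapply(shifted, `[[`, integer(1), "point"),
                      seq = vapply(shifted, `[[`, character(1), "seq"),
                      stringsAsFactors = FALSE)
    ins <- ins[order(ins$point), , drop = FALSE]
    rownames(ins) <- NULL
  }
  list(deletions = dels, insertions = ins)
}

# Extract indels, in 0-based reference coordinates, from a
# PairwiseAlignmentsSingleSubject.  insertion()/deletion() report gap
# ranges in gapped-alignment column space; reference and read coordinates
# are recovered by subtracting the widths of the other kind of gap lying
# to the left.  Returns a list (one element per alignment) of
# deletions/insertions data frames.
.indels_from_aln <- function(aln, reads) {
  ins_l <- Biostrings::insertion(aln)
  del_l <- Biostrings::deletion(aln)
  lapply(seq_along(reads), function(k) {
    iv <- ins_l[[k]]
    dv <- del_l[[k]]
    is <- IRanges::start(iv); iw <- IRanges::width(iv)
    ds <- IRanges::start(dv); dw <- IRanges::width(dv)
    dels <- if (length(ds)) {
      ref0 <- vapply(seq_along(ds), function(m) {
        ds[m] - 1L - sum(iw[is < ds[m]])
      }, integer(1))
      data.frame(start = ref0, end = ref0 + dw)
    } else {
      data.frame(start = integer(), end = integer())
    }
    inss <- if (length(is)) {
      pt <- vapply(seq_along(is), function(m) {
        is[m] - 1L - sum(iw[is < is[m]])
      }, integer(1))
      rd0 <- vapply(seq_along(is), function(m) {
        is[m] - sum(dw[ds < is[m]])
      }, integer(1))
      data.frame(point = pt,
                 seq = substring(reads[k], rd0, rd0 + iw - 1L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(point = integer(), seq = character(),
                 stringsAsFactors = FALSE)
    }
    list(deletions = dels, insertions = inss)
  })
}

.classify <- function(n_del, n_ins) {
  if (n_del == 0L && n_ins == 0L) return("unedited")
  if (n_del > 0L && n_ins == 0L) return("deletion")
  if (n_del == 0L && n_ins == 1L) return("insertion")
  if (n_del > 0L && n_ins >= 1L) return("deletion_plus_insertion")
  "complex"  # multiple insertions, no deletion
}

.indel_call <- function(read_id, edit_class,
                        deletions = data.frame(start = integer(),
                                               end = integer()),
                        insertions = data.frame(point = integer(),
                                                seq = character(),
                                                stringsAsFactors = FALSE),
                        mean_quality = NA_real_) {
  ins_seq <- if (nrow(insertions) == 1L) insertions$seq[1] else ""
  ins_point <- if (nrow(insertions) == 1L) insertions$point[1] else NA_integer_
  structure(
    list(read_id = read_id, edit_class = edit_class,
         deletions = deletions, insertions = insertions,
         insertion_seq = ins_seq, insertion_point = ins_point,
         mean_quality = mean_quality),
    class = "indel_call"
  )
}

#' @export
print.indel_call <- function(x, ...) {
  cat(sprintf("<indel_call> %s: %s", x$read_id, x$edit_class))
  if (nrow(x$deletions)) {
    cat(" del:", paste(sprintf("[%d,%d)", x$deletions$start, x$deletions$end),
                       collapse = " "))
  }
  if (nrow(x$insertions)) {
    cat(" ins:", paste(sprintf("%s@%d", x$insertions$seq, x$insertions$point),
                       collapse = " "))
  }
  cat("\n")
  invisible(x)
}

.mean_phred <- function(qual) {
  if (is.na(qual) || nchar(qual) == 0L) return(NA_real_)
  mean(utf8ToInt(qual) - 33L)
}

#' Align one read to the reference and call its indels
#'
#' End-anchored global alignment of the read to the reference under the
#' configured scoring; gaps are mapped to reference-coordinate deletion
#' intervals and insertion events and left-normalised.  Reads failing the
#' mean-quality or length floor are classed `low_quality`;
#' substitution-only reads are `unedited`.
#'
#' @param read Read sequence (character).
#' @param reference Reference amplicon sequence.
#' @param qualities Optional Phred+33 quality string for the read.
#' @param scoring An [align_scoring()] object.
#' @param read_id Identifier recorded in the call.
#' @param min_mean_quality Mean Phred floor (default 20); only applied when
#'   qualities are supplied.
#' @param min_read_length Reads shorter than this are `low_quality`
#'   (default 30 nt).
#' @return An `indel_call` with fields `read_id`, `edit_class`, `deletions`
#'   (0-based half-open reference intervals, canonical), `insertions`,
#'   `insertion_seq`, `insertion_point`.
#' @examples
#' ref <- strrep("ACGTT", 20)
#' align_and_call(paste0(substr(ref, 1, 40), substr(ref, 55, 100)), ref)
#' @export
align_and_call <- function(read, reference, qualities = NA_character_,
                           scoring = align_scoring(), read_id = "read",
                           min_mean_quality = 20, min_read_length = 30L) {
  reference <- .norm_reference(reference)
  stopifnot(is.character(read), length(read) == 1L)
  read <- toupper(read)
  mq <- .mean_phred(qualities)
  if (nchar(read) < min_read_length ||
      (!is.na(mq) && mq < min_mean_quality)) {
    return(.indel_call(read_id, "low_quality", mean_quality = mq))
  }
  ref_chars <- strsplit(reference, "")[[1L]]
  if (identical(read, reference)) {
    return(.indel_call(read_id, "unedited", mean_quality = mq))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(read), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = .subst_matrix(scoring),
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend)
  ind <- .indels_from_aln(aln, read)[[1L]]
  ind <- .canonicalize(ref_chars, ind$deletions, ind$insertions)
  cls <- .classify(nrow(ind$deletions), nrow(ind$insertions))
  .indel_call(read_id, cls, ind$deletions, ind$insertions, mean_quality = mq)
}

# Vectorised calling of many reads against one reference.  Unique sequences
# are aligned once (alignment depends only on the sequence; quality gating
# happens per read before deduplication).
.call_many <- function(seqs, quals, ids, reference, scoring,
                       min_mean_quality, min_read_length) {
  reference <- .norm_reference(reference)
  ref_chars <- strsplit(reference, "")[[1L]]
  n <- length(seqs)
  if (n == 0L) return(list())
  mq <- vapply(quals, .mean_phred, numeric(1), USE.NAMES = FALSE)
  lowq <- nchar(seqs) < min_read_length | (!is.na(mq) & mq < min_mean_quality)
  calls <- vector("list", n)
  todo <- which(!lowq)
  for (i in which(lowq)) {
    calls[[i]] <- .indel_call(ids[i], "low_quality", mean_quality = mq[i])
  }
  if (length(todo) == 0L) return(calls)
  useq <- unique(seqs[todo])
  umap <- match(seqs[todo], useq)
  ucall <- vector("list", length(useq))
  exact <- useq == reference
  for (k in which(exact)) ucall[[k]] <- list(edit_class = "unedited")
  pending <- useq[!exact]
  pending_idx <- which(!exact)
  if (length(pending) > 0L) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(pending), Biostrings::DNAString(reference),
      type = "global", substitutionMatrix = .subst_matrix(scoring),
      gapOpening = scoring$gap_open - scoring$gap_extend,
      gapExtension = scoring$gap_extend)
    inds <- .indels_from_aln(aln, pending)
    for (k in seq_along(pending)) {
      ind <- .canonicalize(ref_chars, inds[[k]]$deletions,
                           inds[[k]]$insertions)
      ucall[[pending_idx[k]]] <- list(
        edit_class = .classify(nrow(ind$deletions), nrow(ind$insertions)),
        deletions = ind$deletions, insertions = ind$insertions)
    }
  }
  for (w in seq_along(todo)) {
    i <- todo[w]
    u <- ucall[[umap[w]]]
    calls[[i]] <- if (u$edit_class == "unedited") {
      .indel_call(ids[i], "unedited", mean_quality = mq[i])
    } else {
      .indel_call(ids[i], u$edit_class, u$deletions, u$insertions,
                  mean_quality = mq[i])
    }
  }
  calls
}

# Does a call carry an indel of at least min_indel_nt intersecting the
# window [w1, w2)?
.is_edited <- function(call, window, min_indel_nt) {
  if (call$edit_class %in% c("unedited", "low_quality")) return(FALSE)
  d <- call$deletions
  if (nrow(d) > 0L &&
      any((d$end - d$start) >= min_indel_nt &
          d$start < window[2] & d$end > window[1])) {
    return(TRUE)
  }
  i <- call$insertions
  nrow(i) > 0L && any(nchar(i$seq) >= min_indel_nt &
                      i$point >= window[1] & i$point <= window[2])
}

#' Call edits across an amplicon read set
#'
#' Aligns every read to the reference, calls indels, and scores a read as
#' edited when it carries an indel of at least `min_indel_nt` intersecting
#' the window around the nicks.  The indel frequency is the edited fraction
#' normalised by transfection efficiency (capped at 1).
#'
#' @param reads A FASTQ path (gz transparent), a named character vector of
#'   sequences, or a `DNAStringSet` (qualities taken from
#'   `mcols()$qualities` when present).
#' @param reference Reference amplicon sequence.
#' @param window 0-based half-open reference interval in which an indel
#'   counts as an edit.  Defaults to `nicks` +/- 20 nt when `nicks` is
#'   given, else the whole reference.
#' @param nicks Optional integer vector of nick junctions used to derive
#'   the default window.
#' @param min_indel_nt Minimum indel size that counts as an edit (default 1).
#' @param transfection_efficiency Fraction in (0, 1] used to normalise the
#'   edited fraction (default 1).
#' @inheritParams align_and_call
#' @return List with `stats` (an `editing_stats`: `total_reads`,
#'   `edited_reads`, `indel_frequency`, `transfection_efficiency`),
#'   `calls` (list of `indel_call` in input order) and `edited` (logical
#'   vector parallel to `calls`).
#' @export
call_edits <- function(reads, reference, window = NULL, nicks = NULL,
                       min_indel_nt = 1L, transfection_efficiency = 1,
                       scoring = align_scoring(), min_mean_quality = 20,
                       min_read_length = 30L) {
  reference <- .norm_reference(reference)
  stopifnot(transfection_efficiency > 0, transfection_efficiency <= 1)
  if (is.null(window)) {
    window <- if (!is.null(nicks)) {
      c(max(0L, min(nicks) - 20L), min(nchar(reference), max(nicks) + 20L))
    } else {
      c(0L, nchar(reference))
    }
  }
  if (window[1] < 0L || window[2] > nchar(reference) ||
      window[1] >= window[2]) {
    stop("window must be a non-empty interval inside the reference",
         call. = FALSE)
  }
  rd <- .norm_reads(reads)
  calls <- .call_many(rd$seq, rd$qual, rd$id, reference, scoring,
                      min_mean_quality, min_read_length)
  edited <- vapply(calls, .is_edited, logical(1),
                   window = window, min_indel_nt = min_indel_nt)
  total <- length(calls)
  stats <- structure(
    list(total_reads = total, edited_reads = sum(edited),
         indel_frequency = if (total == 0L) 0 else
           min(1, (sum(edited) / total) / transfection_efficiency),
         transfection_efficiency = transfection_efficiency,
         window = as.integer(window), min_indel_nt = as.integer(min_indel_nt)),
    class = "editing_stats")
  list(stats = stats, calls = calls, edited = edited)
}

#' @export
print.editing_stats <- function(x, ...) {
  cat(sprintf(
    "<editing_stats> %d/%d reads edited; indel frequency %.4f (TE %.2f)\n",
    x$edited_reads, x$total_reads, x$indel_frequency,
    x$transfection_efficiency))
  invisible(x)
}

#' Tabulate indel calls
#'
#' One row per read: class, the primary (longest, leftmost at ties)
#' deletion, total deleted nt, number of deletions and total inserted nt.
#'
#' @param calls List of `indel_call` objects.
#' @return A data frame.
#' @export
calls_table <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(read_id = character(), edit_class = character(),
                      n_del = integer(), del_start = integer(),
                      del_end = integer(), del_total_nt = integer(),
                      ins_len = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(cl) {
    d <- cl$deletions
    if (nrow(d) > 0L) {
      w <- d$end - d$start
      k <- which(w == max(w))[1L]
      ds <- d$start[k]; de <- d$end[k]; dt <- sum(w)
    } else {
      ds <- NA_integer_; de <- NA_integer_; dt <- 0L
    }
    data.frame(read_id = cl$read_id, edit_class = cl$edit_class,
               n_del = nrow(d), del_start = ds, del_end = de,
               del_total_nt = dt,
               ins_len = if (nrow(cl$insertions)) sum(nchar(cl$insertions$seq))
                         else 0L,
               stringsAsFactors = FALSE)
  }))
}
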