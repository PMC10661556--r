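# Nick-anchored junction analysis of deletion calls.
#
# Each deletion-bearing read is anchored to the nick junction nearest one
# of its deletion boundaries ("first nick"), and its signed deletion length
# records how far the other boundary extends toward (+) or away from (-)
# the second nick.  Frequencies of these signed lengths, per anchor, form
# the deletion spectrum; summary metrics are the percentage of edited reads
# whose deletions remove the whole inter-nick interval (full overhang
# removal), the median deletion length, and the precise nick-to-nick
# deletion fraction.

#' Anchor a deletion call to its first nick
#'
#' The deletion boundary nearest (within `boundary_tol_nt`) to either nick
#' junction defines the first nick; the signed length measures how far the
#' other boundary of that deletion extends toward (positive) or away from
#' (negative) the second nick.  When both boundaries sit on nicks (the full
#' nick-to-nick deletion) the left nick (NickA) wins the tie.
#'
#' @param call An `indel_call` with at least one deletion.
#' @param nick_a,nick_b Nick junctions, `nick_a < nick_b`.
#' @param boundary_tol_nt Maximum distance between a deletion boundary and
#'   a nick junction for anchoring (default 1 nt).
#' @return A `junction_record`: list with `read_id`, `first_nick`
#'   (`"NickA"`, `"NickB"` or `"unassigned"`) and `signed_length_nt`.
#' @export
assign_first_nick <- function(call, nick_a, nick_b, boundary_tol_nt = 1L) {
  stopifnot(inherits(call, "indel_call"), nick_a < nick_b)
  d <- call$deletions
  if (nrow(d) == 0L) {
    stop("call carries no deletion; nothing to anchor", call. = FALSE)
  }
  best <- NULL
  for (i in seq_len(nrow(d))) {
    for (b in c(d$start[i], d$end[i])) {
      for (nick in c("NickA", "NickB")) {
        j <- if (nick == "NickA") nick_a else nick_b
        dist <- abs(b - j)
        cand <- list(dist = dist, nick = nick, row = i, boundary = b)
        if (is.null(best) ||
            dist < best$dist ||
            (dist == best$dist && nick == "NickA" && best$nick == "NickB")) {
          best <- cand
        }
      }
    }
  }
  if (best$dist > boundary_tol_nt) {
    rec <- list(read_id = call$read_id, first_nick = "unassigned",
                signed_length_nt = NA_integer_)
    return(structure(rec, class = "junction_record"))
  }
  i <- best$row
  other <- if (best$boundary == d$start[i]) d$end[i] else d$start[i]
  signed <- if (best$nick == "NickA") {
    other - nick_a          # positive toward NickB
  } else {
    nick_b - other          # positive toward NickA
  }
  structure(list(read_id = call$read_id, first_nick = best$nick,
                 signed_length_nt = as.integer(signed)),
            class = "junction_record")
}

#' Nick-anchored deletion-length spectrum
#'
#' Frequency of each (first nick, signed deletion length) bin, with either
#' all reads or edited reads as the denominator.  Records that could not
#' be anchored to a nick are retained as an `"unassigned"` bin (signed
#' length `NA`) so that edited-denominator frequencies, together with the
#' non-deletion edited classes, account for every edited read.
#'
#' @param records List of `junction_record`s (see [assign_first_nick()]).
#' @param stats An `editing_stats` from [call_edits()].
#' @param denominator `"total_reads"` or `"edited_reads"`.
#' @return Data frame with columns `first_nick`, `signed_length_nt`,
#'   `count`, `frequency`, plus attributes `denominator` and `denom_n`.
#' @export
deletion_spectrum <- function(records, stats,
                              denominator = c("total_reads",
                                              "edited_reads")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(stats, "editing_stats"))
  denom <- stats[[denominator]]
  if (denom == 0L) {
    stop("denominator '", denominator, "' is zero: empty experiment",
         call. = FALSE)
  }
  if (length(records) == 0L) {
    out <- data.frame(first_nick = character(), signed_length_nt = integer(),
                      count = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      first_nick = vapply(records, `[[`, character(1), "first_nick"),
      signed_chr = vapply(records, function(r) {
        if (is.na(r$signed_length_nt)) "NA" else
          as.character(r$signed_length_nt)
      }, character(1)),
      stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                            by = df[c("first_nick", "signed_chr")],
                            FUN = sum)
    agg$signed_length_nt <- suppressWarnings(as.integer(agg$signed_chr))
    agg <- agg[order(agg$first_nick, agg$signed_length_nt,
                     na.last = TRUE), , drop = FALSE]
    rownames(agg) <- NULL
    agg$frequency <- agg$count / denom
    out <- agg[, c("first_nick", "signed_length_nt", "count", "frequency")]
  }
  attr(out, "denominator") <- denominator
  attr(out, "denom_n") <- denom
  out
}

# Rightmost placement start of a deletion [s, s+L) shift-equivalent to the
# canonical (leftmost) one: moving right by one is allowed while the base
# leaving on the left equals the base entering on the right.
.right_shift_max <- function(ref_chars, s, L) {
  n <- length(ref_chars)
  t <- s
  while (t + L < n && ref_chars[t + 1L] == ref_chars[t + L + 1L]) {
    t <- t + 1L
  }
  t
}

# Maximum number of bases of [a, b) removable by the read's deletions,
# allowing each deletion any of its shift-equivalent placements.  A read
# whose deletion is alignment-ambiguous still counts as covering the
# interval if SOME equivalent placement does.  Without the reference,
# canonical placements are used as-is.
.covered_nt <- function(dels, a, b, ref_chars = NULL) {
  if (nrow(dels) == 0L) return(0L)
  span <- b - a
  tot <- 0L
  for (i in seq_len(nrow(dels))) {
    s <- dels$start[i]
    L <- dels$end[i] - s
    smax <- if (is.null(ref_chars)) s else .right_shift_max(ref_chars, s, L)
    cand <- unique(pmin(pmax(c(s, smax, a, b - L), s), smax))
    ov <- max(pmin(cand + L, b) - pmax(cand, a), 0L)
    tot <- tot + ov
  }
  min(tot, span)
}

#' Summary metrics of the junction spectrum
#'
#' For a set of calls and the two nick junctions, computes:
#' * `full_removal_fraction` -- percentage of edited reads whose deletions
#'   cover the entire inter-nick interval (the candidate 3'-overhang
#'   region), and `near_full_removal_fraction` allowing
#'   `near_full_tolerance_nt` uncovered nt;
#' * `median_deletion_length_nt` -- median total deleted nt, by default
#'   over deletion-bearing reads (`median_over = "edited_reads"` includes
#'   insertion-only and complex edited reads as zero-deletion lengths);
#' * `precise_deletion_fraction` -- fraction of edited reads whose single
#'   deletion is exactly nick-to-nick with no insertion.
#'
#' With zero edited reads all summary fields are `NA`.
#'
#' @param calls List of `indel_call`s.
#' @param nick_a,nick_b Nick junctions, `nick_a < nick_b`.
#' @param near_full_tolerance_nt Tolerance, in nt, for "near-full" coverage
#'   (default 3).
#' @param median_over `"deletion_reads"` (default) or `"edited_reads"`.
#' @param edited Optional logical vector marking which calls count as
#'   edited; defaults to any call whose class is not `unedited`/
#'   `low_quality`.
#' @param reference Optional reference sequence.  When supplied, coverage
#'   and precision are assessed over all placements shift-equivalent to
#'   the canonical left-aligned deletion, so reads whose deletion is
#'   alignment-ambiguous but consistent with removing the inter-nick
#'   interval still count as full removals.
#' @return A list of class `spectrum_summary`.
#' @export
summarize_junctions <- function(calls, nick_a, nick_b,
                                near_full_tolerance_nt = 3L,
                                median_over = c("deletion_reads",
                                                "edited_reads"),
                                edited = NULL, reference = NULL) {
  median_over <- match.arg(median_over)
  stopifnot(nick_a < nick_b)
  ref_chars <- if (!is.null(reference)) {
    strsplit(.norm_reference(reference), "")[[1L]]
  }
  if (is.null(edited)) {
    edited <- vapply(calls, function(cl) {
      !(cl$edit_class %in% c("unedited", "low_quality"))
    }, logical(1))
  }
  span <- nick_b - nick_a
  ecalls <- calls[edited]
  n_edited <- length(ecalls)
  if (n_edited == 0L) {
    return(structure(
      list(n_edited = 0L, full_removal_fraction = NA_real_,
           near_full_removal_fraction = NA_real_,
           near_full_tolerance_nt = as.integer(near_full_tolerance_nt),
           median_deletion_length_nt = NA_real_,
           precise_deletion_fraction = NA_real_,
           nick_a = nick_a, nick_b = nick_b, median_over = median_over),
      class = "spectrum_summary"))
  }
  covered <- vapply(ecalls, function(cl) {
    .covered_nt(cl$deletions, nick_a, nick_b, ref_chars)
  }, numeric(1))
  full <- covered >= span
  near_full <- covered >= (span - near_full_tolerance_nt)
  precise <- vapply(ecalls, function(cl) {
    if (!(nrow(cl$deletions) == 1L && nrow(cl$insertions) == 0L &&
          (cl$deletions$end[1] - cl$deletions$start[1]) == span)) {
      return(FALSE)
    }
    s <- cl$deletions$start[1]
    if (s == nick_a) return(TRUE)
    if (is.null(ref_chars) || s > nick_a) return(FALSE)
    # some shift-equivalent placement of the single deletion is [a, b)
    .right_shift_max(ref_chars, s, span) >= nick_a
  }, logical(1))
  del_len <- vapply(ecalls, function(cl) {
    if (nrow(cl$deletions) == 0L) 0 else
      sum(cl$deletions$end - cl$deletions$start)
  }, numeric(1))
  med_lens <- if (median_over == "deletion_reads") {
    del_len[del_len > 0]
  } else {
    del_len
  }
  structure(
    list(n_edited = n_edited,
         full_removal_fraction = 100 * mean(full),
         near_full_removal_fraction = 100 * mean(near_full),
         near_full_tolerance_nt = as.integer(near_full_tolerance_nt),
         median_deletion_length_nt = if (length(med_lens)) median(med_lens)
                                     else NA_real_,
         precise_deletion_fraction = mean(precise),
         nick_a = nick_a, nick_b = nick_b, median_over = median_over),
    class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<spectrum_summary> n_edited=%d full removal %.1f%% ",
           "(near-full %.1f%% @ %d nt) median deletion %.1f nt ",
           "precise fraction %.3f\n"),
    x$n_edited, x$full_removal_fraction, x$near_full_removal_fraction,
    x$near_full_tolerance_nt, x$median_deletion_length_nt,
    x$precise_deletion_fraction))
  invisible(x)
}

#' Fold change of an indel frequency over its control
#'
#' @param freq_condition,freq_control Frequencies (fractions).
#' @return `freq_condition / freq_control`, or `NA` when the control
#'   frequency is zero (no pseudocounts are applied).
#' @examples
#' fold_change(0.36, 0.01)  # 36
#' @export
fold_change <- function(freq_condition, freq_control) {
  stopifnot(freq_condition >= 0, freq_control >= 0)
  if (freq_control == 0) return(NA_real_)
  freq_condition / freq_control
}

#' Linear regression of stimulation on overhang length
#'
#' Ordinary least squares of fold stimulation on 3'-overhang length, with
#' the Pearson correlation coefficient and its two-sided p value from the
#' exact t transform with n-2 degrees of freedom.
#'
#' @param table Data frame with columns `overhang_length_nt` and
#'   `fold_stimulation` (at least 3 rows, non-constant x).
#' @return List with `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
overhang_stimulation_regression <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("overhang_length_nt", "fold_stimulation") %in%
                names(table)))
  x <- table$overhang_length_nt
  y <- table$fold_stimulation
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("overhang lengths are constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
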