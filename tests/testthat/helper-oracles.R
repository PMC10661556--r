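# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the protospacer scan is a regex sweep, the
# alignment oracle is a from-scratch affine-gap dynamic programme, and the
# Pearson oracle is the closed form.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste0(sample(BASES, n, replace = TRUE),
                                 collapse = "")

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Regex-style exhaustive protospacer scan of both strands (0-based starts).
brute_protospacers <- function(ref, spacer_len = 20L) {
  n <- nchar(ref)
  flen <- spacer_len + 3L
  out <- list()
  if (n >= flen) {
    for (s in 0:(n - flen)) {
      fp <- substr(ref, s + 1L, s + flen)
      pam_plus <- substr(fp, spacer_len + 1L, flen)
      if (grepl("^.GG$", pam_plus)) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "+")
      }
      pam_minus <- substr(revcomp_chr(fp), spacer_len + 1L, flen)
      if (grepl("^.GG$", pam_minus)) {
        out[[length(out) + 1L]] <- data.frame(start = s, strand = "-")
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), strand = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand == "-"), , drop = FALSE]
}

# Nick junction by per-base enumeration: walk the protospacer strand
# 5'->3' over the spacer and stop between positions 17 and 18.
enumerate_nick_junction <- function(start, strand, spacer_len = 20L) {
  if (strand == "+") {
    # spacer occupies plus positions start .. start+spacer_len-1, 5'->3'
    spacer_positions <- start:(start + spacer_len - 1L)
    # junction after the 17th spacer base: right edge of that base
    spacer_positions[17L] + 1L
  } else {
    # spacer runs right-to-left on the plus axis: plus positions
    # start+spacer_len+2 .. start+3 in 5'->3' order of the minus strand
    spacer_positions <- (start + spacer_len + 2L):(start + 3L)
    # junction after the 17th spacer base = left edge of that base
    spacer_positions[17L]
  }
}

# Strand-separation oracle: cut the plus strand at junction p and the
# minus strand at junction m; the left fragment keeps plus bases [0, p)
# and minus bases [0, m).  The protruding single-stranded stretch ends at
# the minus strand's 5' terminus when m > p (5' overhang) and at the plus
# strand's 3' terminus when p > m (3' overhang).
separation_oracle <- function(plus_j, minus_j) {
  if (plus_j < minus_j) {
    list(polarity = "five_prime", length = minus_j - plus_j)
  } else if (plus_j > minus_j) {
    list(polarity = "three_prime", length = plus_j - minus_j)
  } else {
    list(polarity = "blunt", length = 0L)
  }
}

# Optimal global affine-gap alignment score, computed row-wise with the
# cummax trick for the in-row gap state.  Gap of length L costs
# open + (L - 1) * extend; ends are penalised (end-anchored).
nw_affine_score <- function(read, ref, match = 2, mismatch = -3,
                            open = 6, extend = 1) {
  NEG <- -1e15
  r <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(s)
  gap0 <- function(L) ifelse(L == 0, 0, -(open + (L - 1) * extend))
  H_prev <- gap0(0:m)
  F_prev <- rep(NEG, m + 1L)
  ks <- 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(s == r[i], match, mismatch)
    Fi <- pmax(H_prev - open, F_prev - extend)
    G <- c(gap0(i), H_prev[1:m] + sub)          # diag terms, j = 0..m
    G <- pmax(G, c(NEG, Fi[2:(m + 1L)]))
    A <- cummax(G + ks * extend)
    E <- c(NEG, A[1:m] - open - (ks[2:(m + 1L)] - 1) * extend)
    H <- pmax(G, E)
    H_prev <- H
    F_prev <- Fi
  }
  H_prev[m + 1L]
}

# Score achieved by an indel call: rebuild the aligned read from the
# reference and the call's indels, pair it with the read and total up
# matches, mismatches and gap costs.  Errors out if the call is not
# length-consistent with the read.
score_of_call <- function(ref, read, call, match = 2, mismatch = -3,
                          open = 6, extend = 1) {
  s <- strsplit(ref, "")[[1]]
  keep <- rep(TRUE, length(s))
  gap_cost <- 0
  d <- call$deletions
  for (i in seq_len(nrow(d))) {
    keep[(d$start[i] + 1L):d$end[i]] <- FALSE
    gap_cost <- gap_cost + open + (d$end[i] - d$start[i] - 1L) * extend
  }
  pieces <- character(0)
  is_ins <- logical(0)           # inserted read bases sit in gap columns:
                                 # they carry gap cost, never match score
  ins <- call$insertions
  ins <- ins[order(ins$point), , drop = FALSE]
  pos <- 0L
  for (i in seq_len(nrow(ins))) {
    p <- ins$point[i]
    if (p > pos) {
      kept <- s[(pos + 1L):p][keep[(pos + 1L):p]]
      pieces <- c(pieces, kept)
      is_ins <- c(is_ins, rep(FALSE, length(kept)))
    }
    iv <- strsplit(ins$seq[i], "")[[1]]
    pieces <- c(pieces, iv)
    is_ins <- c(is_ins, rep(TRUE, length(iv)))
    gap_cost <- gap_cost + open + (nchar(ins$seq[i]) - 1L) * extend
    pos <- p
  }
  if (pos < length(s)) {
    kept <- s[(pos + 1L):length(s)][keep[(pos + 1L):length(s)]]
    pieces <- c(pieces, kept)
    is_ins <- c(is_ins, rep(FALSE, length(kept)))
  }
  rd <- strsplit(read, "")[[1]]
  stopifnot(length(pieces) == length(rd))
  nmatch <- sum(pieces == rd & !is_ins)
  nmis <- sum(pieces != rd & !is_ins)
  nmatch * match + nmis * mismatch - gap_cost
}

# Closed-form Pearson correlation and its exact-t two-sided p value.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p)
}

# Exact pmf of the simulator's total-deleted-length distribution over
# deletion-bearing reads, for computing the theoretical median.
deletion_length_pmf <- function(scenario, span, max_len = 400L) {
  w <- scenario$component_weights
  w_del <- w[["nick_local"]] + w[["full_span"]]
  p_nl <- w[["nick_local"]] / w_del
  pmf <- numeric(max_len + 1L)            # index k+1 = length k
  # nick-local: 1 + Geom(p)
  p1 <- scenario$nick_local_p
  k <- 1:max_len
  pmf[k + 1L] <- pmf[k + 1L] + p_nl * stats::dgeom(k - 1L, p1)
  # full-span: span + G1 + G2, G ~ Geom(p2); sum of two geoms pmf
  p2 <- scenario$extra_resection_p
  for (k in span:max_len) {
    e <- k - span
    pe <- sum(stats::dgeom(0:e, p2) * stats::dgeom(e - (0:e), p2))
    pmf[k + 1L] <- pmf[k + 1L] + (1 - p_nl) * pe
  }
  pmf / sum(pmf)
}

theoretical_median <- function(pmf) {
  which(cumsum(pmf) >= 0.5)[1L] - 1L
}

# 99% order-statistic confidence interval for a population median.
median_ci99 <- function(x) {
  x <- sort(x)
  m <- length(x)
  lo <- stats::qbinom(0.005, m, 0.5)
  hi <- stats::qbinom(0.995, m, 0.5) + 1L
  c(x[max(1L, lo)], x[min(m, hi)])
}
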