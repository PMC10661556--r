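# Synthetic references and amplicon read sets.
#
# The simulator emulates the qualitative contrast seen in junction analyses
# of paired-nickase editing: without TREX2, most indel reads lose a few
# nucleotides around one nick (nick-local deletions); with TREX2
# (overexpressed or fused) most indel reads delete the full inter-nick
# interval, often with extra resection beyond it.  Length laws are
# geometric -- the minimal-assumption choice, since no empirical length
# distribution is available -- and all randomness flows from one integer
# seed in a documented per-read draw order.

#' Scenario configuration for the read simulator
#'
#' @param edit_rate Probability that a read is edited.
#' @param component_weights Named numeric, weights of the edited-read
#'   components `nick_local`, `full_span`, `insertion`; must sum to 1.
#' @param nick_local_p Geometric parameter (success probability in (0, 1])
#'   for nick-local deletion lengths (length = 1 + Geom).
#' @param extra_resection_p Geometric parameter for the per-side overshoot
#'   of full-span deletions beyond the inter-nick interval.
#' @param insertion_length_max Maximum insertion length in nt (uniform on
#'   1..max).
#' @param substitution_error_rate Per-base sequencing substitution rate.
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed; the same configuration and seed yield
#'   byte-identical output.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(edit_rate,
                            component_weights = c(nick_local = 0.5,
                                                  full_span = 0.4,
                                                  insertion = 0.1),
                            nick_local_p = 0.25,
                            extra_resection_p = 0.4,
                            insertion_length_max = 6L,
                            substitution_error_rate = 0.001,
                            n_reads = 10000L,
                            seed = 1L) {
  w <- component_weights
  if (!all(c("nick_local", "full_span", "insertion") %in% names(w))) {
    stop("component_weights must name nick_local, full_span, insertion",
         call. = FALSE)
  }
  w <- w[c("nick_local", "full_span", "insertion")]
  if (abs(sum(w) - 1) > 1e-9) {
    stop("component weights must sum to 1", call. = FALSE)
  }
  rates <- c(edit_rate, w, substitution_error_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(nick_local_p > 0, nick_local_p <= 1,
            extra_resection_p > 0, extra_resection_p <= 1,
            insertion_length_max >= 1L, n_reads >= 0L)
  structure(list(edit_rate = edit_rate, component_weights = w,
                 nick_local_p = nick_local_p,
                 extra_resection_p = extra_resection_p,
                 insertion_length_max = as.integer(insertion_length_max),
                 substitution_error_rate = substitution_error_rate,
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Preset simulation scenarios
#'
#' `EV_like` mimics the empty-vector control: editing is rare and indel
#' reads are dominated by small nick-local deletions.  `TREX2_like` mimics
#' TREX2 overexpression: editing is frequent and full inter-nick-span
#' deletions dominate.  `fused_like` mimics the nickase-TREX2 fusion, with
#' a full-span-dominated spectrum and deeper resection tails.
#'
#' @param name One of `"EV_like"`, `"TREX2_like"`, `"fused_like"`.
#' @param n_reads,seed Passed through to [scenario_config()].
#' @return A `scenario_config`.
#' @export
preset_scenario <- function(name = c("EV_like", "TREX2_like", "fused_like"),
                            n_reads = 10000L, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    EV_like = scenario_config(
      edit_rate = 0.02,
      component_weights = c(nick_local = 0.75, full_span = 0.10,
                            insertion = 0.15),
      nick_local_p = 0.25, extra_resection_p = 0.5,
      n_reads = n_reads, seed = seed),
    TREX2_like = scenario_config(
      edit_rate = 0.30,
      component_weights = c(nick_local = 0.20, full_span = 0.70,
                            insertion = 0.10),
      nick_local_p = 0.25, extra_resection_p = 0.4,
      n_reads = n_reads, seed = seed),
    fused_like = scenario_config(
      edit_rate = 0.25,
      component_weights = c(nick_local = 0.15, full_span = 0.75,
                            insertion = 0.10),
      nick_local_p = 0.25, extra_resection_p = 0.3,
      n_reads = n_reads, seed = seed))
  cfg$preset <- name
  cfg
}

#' Build a reference with a planted pair of nickase targets
#'
#' Generates a random background sequence and plants two 23-bp targets on
#' opposite strands (the first protospacer on the plus strand, the second
#' on the minus strand) realising the requested layout:
#'
#' * `"pam_in"`: PAMs between the outer footprint edges; with
#'   `inter_nick_distance` D the minus-strand footprint starts 11 + D bases
#'   right of the plus-strand one.  D10A pairs give 3' overhangs, H840A 5'.
#' * `"pam_out"`: PAMs at the outer edges (offset 11 - D); D10A gives 5'
#'   overhangs, H840A 3'.
#' * `"overlapping"`: footprints intersect by `overlap_length` bp.  For
#'   D10A the PAM-in branch is used (overlap 1-12, overhangs 11-0); for
#'   H840A the `branch` argument picks the near branch (overlap 12-23,
#'   overhang = overlap - 12) or the far branch (overlap 1-23, overhang =
#'   34 - overlap); `"auto"` chooses near for overlap >= 12.
#'
#' Placements where one target's GG PAM bases would have to coincide with
#' the other's CC (minus-strand offset 20-22: D10A overlapping pairs with
#' overhangs 9-11) cannot exist in real DNA and raise an error, as do
#' layouts that are out of the feasible overlap/overhang range.
#'
#' @param length Reference length in bp.
#' @param layout `"pam_in"`, `"pam_out"` or `"overlapping"`.
#' @param variant `"D10A"` or `"H840A"` (used to validate feasibility and
#'   returned in the geometry).
#' @param inter_nick_distance Inter-nick distance in bp (`pam_in`/
#'   `pam_out`).
#' @param overlap_length Footprint overlap in bp (`overlapping`).
#' @param branch `"auto"`, `"near"` or `"far"` (H840A overlapping only).
#' @param seed Integer seed for the background sequence.
#' @param margin Minimum distance between either footprint and the
#'   reference ends.
#' @return List with `reference` (character), `reference_id`, `site1`,
#'   `site2`, `geometry` (a [pair_geometry()]), `nick_a`, `nick_b`.
#' @examples
#' mk <- make_reference(240, "pam_in", "D10A", inter_nick_distance = 40,
#'                      seed = 7)
#' mk$geometry$overhang_polarity
#' @export
make_reference <- function(length = 240L,
                           layout = c("pam_in", "pam_out", "overlapping"),
                           variant = c("D10A", "H840A"),
                           inter_nick_distance = NULL,
                           overlap_length = NULL,
                           branch = c("auto", "near", "far"),
                           seed = 1L, margin = 60L) {
  layout <- match.arg(layout)
  variant <- match.arg(variant)
  branch <- match.arg(branch)
  flen <- 23L
  if (layout %in% c("pam_in", "pam_out")) {
    if (is.null(inter_nick_distance)) {
      stop("layout '", layout, "' needs inter_nick_distance", call. = FALSE)
    }
    D <- as.integer(inter_nick_distance)
    if (D < 0L) stop("inter_nick_distance must be >= 0", call. = FALSE)
    d <- if (layout == "pam_in") 11L + D else 11L - D
  } else {
    if (is.null(overlap_length)) {
      stop("layout 'overlapping' needs overlap_length", call. = FALSE)
    }
    ov <- as.integer(overlap_length)
    if (ov < 1L || ov > 23L) {
      stop("overlap_length must lie in 1..23 (23-bp targets); a D10A ",
           "overlapping pair supports overlaps 1..12 (overhang 11..0)",
           call. = FALSE)
    }
    if (variant == "D10A") {
      if (ov > 12L) {
        stop("D10A overlapping layout is limited to overlap 1..12 ",
             "(3' overhangs 0..11)", call. = FALSE)
      }
      d <- 23L - ov                      # PAM-in branch
    } else {
      use_near <- switch(branch, near = TRUE, far = FALSE, auto = ov >= 12L)
      if (use_near && ov < 12L) {
        stop("near branch requires overlap 12..23", call. = FALSE)
      }
      d <- if (use_near) 23L - ov else ov - 23L
    }
  }
  if (d %in% 20:22) {
    stop("infeasible layout: the second target's CC (PAM) would coincide ",
         "with the first target's GG at minus-strand offset ", d,
         call. = FALSE)
  }
  length <- as.integer(length)
  margin <- as.integer(margin)
  a <- margin + max(0L, -d)              # plus-strand footprint start
  b <- a + d
  hi <- max(a, b) + flen
  if (hi + margin > length) {
    stop("reference too short for the requested layout and margin",
         call. = FALSE)
  }
  ref <- with_seed(seed, {
    chars <- sample(.BASES, length, replace = TRUE)
    # plant PAMs: plus-strand site1 NGG at [a+20, a+23)
    chars[a + 22L] <- "G"; chars[a + 23L] <- "G"
    # minus-strand site2: CCN at [b, b+3) on the plus strand
    chars[b + 1L] <- "C"; chars[b + 2L] <- "C"
    paste0(chars, collapse = "")
  })
  rid <- "synthetic_amplicon"
  site1 <- protospacer_site(ref, a, "+", reference_id = rid)
  site2 <- protospacer_site(ref, b, "-", reference_id = rid)
  geom <- pair_geometry(site1, site2, variant)
  list(reference = ref, reference_id = rid, site1 = site1, site2 = site2,
       geometry = geom,
       nick_a = geom$nick_a$junction, nick_b = geom$nick_b$junction)
}

# One geometric draw (support 0, 1, 2, ...).
.rgeom1 <- function(p) rgeom(1L, p)

#' Simulate an amplicon read set with ground truth
#'
#' Each read is, independently: unedited with probability
#' `1 - edit_rate`; otherwise one component drawn by weight --
#' `nick_local`, a deletion starting at a uniformly chosen nick with
#' geometric length (`1 + Geom(nick_local_p)`), extending toward or away
#' from the other nick with equal probability; `full_span`, a deletion
#' covering the whole inter-nick interval with independent geometric
#' overshoot (`Geom(extra_resection_p)`) on each side; or `insertion`, a
#' uniform-random sequence of length 1..`insertion_length_max` at a
#' uniformly chosen nick.  Per-base substitution errors are applied last;
#' qualities are constant Q30.  Intervals are clamped to the reference.
#'
#' Per-read draw order (one RNG stream seeded from `scenario$seed`):
#' edit?; component; component-specific draws (nick; direction/length, or
#' left/right overshoot, or length then bases); number of sequencing
#' errors, their positions, their substituted bases.
#'
#' @param reference Reference sequence (character).
#' @param nick_a,nick_b Nick junctions, `nick_a < nick_b`.
#' @param scenario A [scenario_config()].
#' @return List with `reads` (data frame `read_id`, `seq`, `qual`),
#'   `truth` (data frame `read_id`, `class`, `del_start`, `del_end`,
#'   `ins_point`, `ins_seq`) and `scenario`.
#' @export
simulate_reads <- function(reference, nick_a, nick_b, scenario) {
  stopifnot(inherits(scenario, "scenario_config"), nick_a < nick_b)
  reference <- .norm_reference(reference)
  n <- scenario$n_reads
  len <- nchar(reference)
  ref_chars <- strsplit(reference, "")[[1L]]
  w <- scenario$component_weights
  comps <- names(w)
  out_seq <- character(n)
  cls <- character(n)
  del_s <- rep(NA_integer_, n); del_e <- rep(NA_integer_, n)
  ins_p <- rep(NA_integer_, n); ins_q <- rep(NA_character_, n)
  with_seed(scenario$seed, {
    for (i in seq_len(n)) {
      edited <- runif(1L) < scenario$edit_rate
      s <- NA_integer_; e <- NA_integer_
      ip <- NA_integer_; iseq <- NA_character_
      if (!edited) {
        comp <- "unedited"
      } else {
        comp <- sample(comps, 1L, prob = w)
        if (comp == "nick_local") {
          j <- if (runif(1L) < 0.5) nick_a else nick_b
          toward <- runif(1L) < 0.5
          L <- 1L + .rgeom1(scenario$nick_local_p)
          right <- (j == nick_a) == toward   # toward = toward the other nick
          if (right) { s <- j; e <- min(len, j + L) }
          else { s <- max(0L, j - L); e <- j }
        } else if (comp == "full_span") {
          exL <- .rgeom1(scenario$extra_resection_p)
          exR <- .rgeom1(scenario$extra_resection_p)
          s <- max(0L, nick_a - exL)
          e <- min(len, nick_b + exR)
        } else {  # insertion
          ip <- if (runif(1L) < 0.5) nick_a else nick_b
          L <- sample.int(scenario$insertion_length_max, 1L)
          iseq <- paste0(sample(.BASES, L, replace = TRUE), collapse = "")
        }
      }
      chars <- ref_chars
      if (!is.na(s)) chars <- chars[-seq.int(s + 1L, e)]
      if (!is.na(ip)) {
        chars <- append(chars, strsplit(iseq, "")[[1L]], after = ip)
      }
      if (scenario$substitution_error_rate > 0 && length(chars) > 0L) {
        nerr <- rbinom(1L, length(chars), scenario$substitution_error_rate)
        if (nerr > 0L) {
          pos <- sample.int(length(chars), nerr)
          for (p in pos) {
            chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
          }
        }
      }
      out_seq[i] <- paste0(chars, collapse = "")
      cls[i] <- comp
      del_s[i] <- s; del_e[i] <- e; ins_p[i] <- ip; ins_q[i] <- iseq
    }
  })
  ids <- sprintf("read%06d", seq_len(n))
  list(
    reads = data.frame(read_id = ids, seq = out_seq,
                       qual = strrep("?", nchar(out_seq)),  # Phred+33 Q30
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = ids, class = cls, del_start = del_s,
                       del_end = del_e, ins_point = ins_p, ins_seq = ins_q,
                       stringsAsFactors = FALSE),
    scenario = scenario)
}
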