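# Sequential-nicking viability model.
#
# Overlapping (or closely spaced) nickase targets cannot be bound by both
# Cas9n-sgRNA complexes at once, so the two nicks must be laid down
# sequentially.  Whether the SECOND nick can still be induced depends on
# where the first nick sits relative to the second target, and -- when the
# TREX2 3'-5' exonuclease is present -- on how much of the strand released
# by the first nick has been chewed back before the second complex unwinds
# its target.  The rules, applied in order:
#
#   R1  first nick at or inside the second site's 3-bp PAM: the second
#       ternary complex cannot be stabilised -> nonviable.
#   R2  (D10A) first nick on the second site's nontarget strand, within
#       d10a_block_max_dist_nt (17) of its PAM: target unwinding terminates
#       prematurely at the nick -> nonviable.
#   R3  (H840A) first nick on the second site's target strand within
#       min_pairing_nt - 1 (17) nt PAM-distal of its PAM: fewer than 18 nt
#       of PAM-proximal target strand are available for spacer pairing
#       -> nonviable.
#   R4  (H840A first nicks only) TREX2 shortens the released 17-nt 3'
#       segment from its 3' terminus at the nick: by up to
#       free_trex2_max_degrade_nt (8 nt) for free TREX2 and by at least
#       fused_trex2_min_degrade_nt (9 nt) for the nickase-TREX2 fusion.
#       If the intact PAM-proximal pairing stretch of the second target
#       drops below min_pairing_nt (18) -> nonviable.
#
# Distances are nucleotides along the relevant strand between the first
# nick junction and the PAM-proximal spacer edge of the second site.

#' Parameters of the sequential-nicking viability model
#'
#' @param min_pairing_nt Minimum intact PAM-proximal pairing between the
#'   second spacer and its target strand required to activate nicking
#'   (default 18 nt).
#' @param released_len_nt Length of the PAM-distal 3' nontarget-strand
#'   segment released by an H840A nick (default 17 nt for a 20-nt spacer).
#' @param free_trex2_min_degrade_nt,free_trex2_max_degrade_nt Depth range,
#'   in nt, to which free TREX2 degrades the released segment (defaults 5
#'   and 8).  The maximum is used as the worst case for viability.
#' @param fused_trex2_min_degrade_nt Minimum degradation depth of
#'   nickase-fused TREX2 (default 9 nt); used as the fused-mode worst case.
#' @param d10a_block_max_dist_nt Maximum distance, in nt, at which a nick on
#'   the second site's nontarget strand blocks D10A target unwinding
#'   (default 17).
#' @return A validated list of class `viability_params`.
#' @export
viability_params <- function(min_pairing_nt = 18L,
                             released_len_nt = 17L,
                             free_trex2_min_degrade_nt = 5L,
                             free_trex2_max_degrade_nt = 8L,
                             fused_trex2_min_degrade_nt = 9L,
                             d10a_block_max_dist_nt = 17L) {
  p <- list(min_pairing_nt = as.integer(min_pairing_nt),
            released_len_nt = as.integer(released_len_nt),
            free_trex2_min_degrade_nt = as.integer(free_trex2_min_degrade_nt),
            free_trex2_max_degrade_nt = as.integer(free_trex2_max_degrade_nt),
            fused_trex2_min_degrade_nt = as.integer(fused_trex2_min_degrade_nt),
            d10a_block_max_dist_nt = as.integer(d10a_block_max_dist_nt))
  if (any(vapply(p, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("viability parameters must be non-negative integers", call. = FALSE)
  }
  if (p$min_pairing_nt > 20L) {
    stop("min_pairing_nt cannot exceed the 20-nt spacer", call. = FALSE)
  }
  if (!(p$free_trex2_min_degrade_nt <= p$free_trex2_max_degrade_nt &&
        p$free_trex2_max_degrade_nt < p$fused_trex2_min_degrade_nt)) {
    stop("degradation depths must satisfy free min <= free max < fused min",
         call. = FALSE)
  }
  if (p$fused_trex2_min_degrade_nt > p$released_len_nt) {
    stop("fused degradation depth cannot exceed the released segment",
         call. = FALSE)
  }
  structure(p, class = "viability_params")
}

.verdict <- function(viable, rule, intact, first_nicker, trex_mode,
                     degrade_depth) {
  structure(
    list(viable = viable, rule_triggered = rule,
         intact_pairing_nt = intact, first_nicker = first_nicker,
         trex_mode = trex_mode, degrade_depth_nt = degrade_depth),
    class = "viability_verdict"
  )
}

#' @export
print.viability_verdict <- function(x, ...) {
  cat(sprintf(
    "<viability_verdict> %s (rule %s, intact pairing %s nt, %s TREX2)\n",
    if (isTRUE(x$viable)) "viable" else "nonviable", x$rule_triggered,
    ifelse(is.na(x$intact_pairing_nt), "NA", x$intact_pairing_nt),
    x$trex_mode))
  invisible(x)
}

# Core rule engine on the signed nick-to-PAM distance.
#   dist_pam_distal > 0: first nick lies PAM-distal of the second site's
#     PAM-proximal spacer edge (inside or beyond the spacer);
#   dist_pam_distal <= 0 with in_pam = FALSE: nick beyond the PAM on the
#     far side, no interaction.
.viability_core <- function(variant, dist_pam_distal, in_pam,
                            trex_mode, params, degrade_depth = NULL,
                            first_nicker = NA_integer_) {
  spacer <- 20L
  depth <- 0L
  if (variant == "H840A" && trex_mode != "none") {
    depth <- if (!is.null(degrade_depth)) {
      as.integer(degrade_depth)
    } else if (trex_mode == "free") {
      params$free_trex2_max_degrade_nt
    } else {
      params$fused_trex2_min_degrade_nt
    }
  }
  intact_of <- function(dist, dep) {
    as.integer(max(0L, min(spacer, dist - dep)))
  }
  if (in_pam) {
    return(.verdict(FALSE, "nick_in_or_at_second_pam", spacer,
                    first_nicker, trex_mode, depth))
  }
  d <- dist_pam_distal
  if (d <= 0L) {
    # first nick beyond the second PAM, outside the footprint: no modelled
    # interaction with second-target unwinding.
    return(.verdict(TRUE, "none", spacer, first_nicker, trex_mode, depth))
  }
  if (variant == "D10A") {
    if (d <= params$d10a_block_max_dist_nt) {
      return(.verdict(FALSE, "d10a_nontarget_nick_proximal",
                      intact_of(d, 0L), first_nicker, trex_mode, depth))
    }
    return(.verdict(TRUE, "none", intact_of(d, 0L), first_nicker,
                    trex_mode, depth))
  }
  # H840A
  if (d <= params$min_pairing_nt - 1L) {
    return(.verdict(FALSE, "h840a_target_strand_nick_proximal",
                    intact_of(d, 0L), first_nicker, trex_mode, depth))
  }
  intact <- intact_of(d, depth)
  if (trex_mode != "none" && intact < params$min_pairing_nt) {
    return(.verdict(FALSE, "trex2_gap_extension", intact, first_nicker,
                    trex_mode, depth))
  }
  .verdict(TRUE, "none", intact, first_nicker, trex_mode, depth)
}

#' Second-nick viability at a given nick-to-PAM distance
#'
#' Evaluates the sequential-nicking rule engine directly on the distance, in
#' nucleotides, between the first nick junction and the PAM-proximal spacer
#' edge of the second target (positive distances are PAM-distal, i.e. into
#' or beyond the spacer).  Useful for parameter sweeps; pairs of concrete
#' sites are handled by [second_nick_viability()].
#'
#' @param distance_nt Signed nick-to-PAM distance in nt.
#' @param variant Nickase variant of the pair (`"H840A"` or `"D10A"`).
#' @param trex_mode `"none"`, `"free"` (TREX2 overexpressed) or `"fused"`
#'   (TREX2 fused to the nickase).
#' @param params A [viability_params()] object.
#' @param degrade_depth Optional override, in nt, of the worst-case TREX2
#'   degradation depth (H840A first nicks only).
#' @return A `viability_verdict`.
#' @examples
#' viability_at_distance(22, "H840A", "free")$viable  # FALSE
#' viability_at_distance(26, "H840A", "free")$viable  # TRUE
#' @export
viability_at_distance <- function(distance_nt,
                                  variant = c("H840A", "D10A"),
                                  trex_mode = c("none", "free", "fused"),
                                  params = viability_params(),
                                  degrade_depth = NULL) {
  variant <- match.arg(variant)
  trex_mode <- match.arg(trex_mode)
  stopifnot(inherits(params, "viability_params"))
  .viability_core(variant, as.integer(distance_nt), in_pam = FALSE,
                  trex_mode = trex_mode, params = params,
                  degrade_depth = degrade_depth)
}

#' Can the second nick of a pair be induced?
#'
#' Applies the sequential-nicking rules (see [viability_params()]) to a
#' concrete site pair: the designated first nicker lays down its nick, and
#' the verdict states whether the remaining site can still be nicked to
#' complete the double-strand break.  Two nicks on the same strand never
#' form a DSB and return rule `same_strand_no_dsb`.
#'
#' @param pair A [pair_geometry()].
#' @param first_nicker Which source site nicks first: 1 or 2, indexing
#'   `site1`/`site2` as passed to [pair_geometry()] (after junction
#'   ordering, `pair$nick_a` and `pair$nick_b`).
#' @inheritParams viability_at_distance
#' @return A `viability_verdict` with fields `viable`, `rule_triggered`,
#'   `intact_pairing_nt`, `first_nicker`, `trex_mode`, `degrade_depth_nt`.
#' @export
second_nick_viability <- function(pair, first_nicker = 1L,
                                  trex_mode = c("none", "free", "fused"),
                                  params = viability_params(),
                                  degrade_depth = NULL) {
  trex_mode <- match.arg(trex_mode)
  stopifnot(inherits(pair, "pair_geometry"), first_nicker %in% c(1L, 2L))
  stopifnot(inherits(params, "viability_params"))
  if (pair$overhang_polarity == "same_strand") {
    return(.verdict(FALSE, "same_strand_no_dsb", NA_integer_,
                    first_nicker, trex_mode, 0L))
  }
  first <- if (first_nicker == 1L) pair$nick_a else pair$nick_b
  second <- if (first_nicker == 1L) pair$nick_b else pair$nick_a
  second_site <- second$source_site
  j <- first$junction
  pam_rng <- .pam_junction_range(second_site)
  in_pam <- j >= pam_rng[1] && j <= pam_rng[2]
  q <- .pam_proximal_edge(second_site)
  dist <- if (second_site$strand == "+") q - j else j - q
  .viability_core(pair$variant, dist, in_pam, trex_mode, params,
                  degrade_depth, first_nicker)
}

#' Viability of a pair under either nicking order
#'
#' The sequential model does not fix which sgRNA binds first, so a pair is
#' considered workable if either ordering allows the second nick.
#'
#' @inheritParams second_nick_viability
#' @return List with `viable` (TRUE if either ordering is viable) and the
#'   per-ordering verdicts `ordering1`, `ordering2`.
#' @export
pair_viability <- function(pair, trex_mode = c("none", "free", "fused"),
                           params = viability_params(),
                           degrade_depth = NULL) {
  trex_mode <- match.arg(trex_mode)
  v1 <- second_nick_viability(pair, 1L, trex_mode, params, degrade_depth)
  v2 <- second_nick_viability(pair, 2L, trex_mode, params, degrade_depth)
  list(viable = v1$viable || v2$viable, ordering1 = v1, ordering2 = v2)
}

# Variant-specific empirical stimulation windows (bp between paired nicks)
# reported for TREX2-stimulated editing; carried as annotations only.
.STIM_SUBWINDOWS <- list(
  D10A = list(reporter = c(14L, 81L), AAVS1 = c(13L, 43L)),
  H840A = list(reporter = c(29L, 86L), EMX1 = c(34L, 96L))
)

#' Is a pair predicted to respond to TREX2 stimulation?
#'
#' TREX2 stimulates mutagenic end joining only of 3'-overhanging ends, and
#' robust stimulation is confined to a window of inter-nick distances
#' (default 13-96 bp).  A pair is `stimulable` if the second nick is viable,
#' the polarity is `three_prime`, and the inter-nick distance falls inside
#' the window; `no_dsb` if no double-strand break forms at all.
#' Variant-specific empirical sub-windows are attached as annotations, not
#' applied as filters.
#'
#' @param pair A [pair_geometry()].
#' @param verdict A `viability_verdict` for the pair (e.g. the better
#'   ordering from [pair_viability()]).
#' @param window Length-2 numeric: inclusive inter-nick distance bounds.
#' @return List with `status` (`"stimulable"`, `"not_stimulable"`,
#'   `"no_dsb"`) and `annotations`.
#' @export
stimulation_prediction <- function(pair, verdict, window = c(13L, 96L)) {
  stopifnot(inherits(pair, "pair_geometry"), length(window) == 2L)
  no_dsb <- pair$overhang_polarity == "same_strand" ||
    identical(verdict$rule_triggered, "same_strand_no_dsb")
  status <- if (no_dsb) {
    "no_dsb"
  } else if (isTRUE(verdict$viable) &&
             pair$overhang_polarity == "three_prime" &&
             pair$inter_nick_distance >= window[1] &&
             pair$inter_nick_distance <= window[2]) {
    "stimulable"
  } else {
    "not_stimulable"
  }
  list(status = status,
       annotations = list(window = as.integer(window),
                          variant_subwindows = .STIM_SUBWINDOWS[[pair$variant]]))
}
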