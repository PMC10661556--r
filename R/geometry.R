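# Cut-site geometry of single and paired SpCas9 nickase targets.
#
# Coordinate conventions used throughout the package:
#   * all reference coordinates are 0-based, half-open intervals;
#   * a nick "junction" j is an inter-base index: the cut lies between
#     reference positions j-1 and j, i.e. j bases lie to its left;
#   * a site's 23-bp footprint is [start, start+23).  On the plus strand the
#     spacer occupies [start, start+20) and the NGG PAM [start+20, start+23);
#     on the minus strand the PAM appears as CCN at [start, start+3) on the
#     plus strand and the spacer at [start+3, start+23).

.norm_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    if (length(reference) == 0L) stop("empty reference set", call. = FALSE)
    reference <- reference[[1L]]
  }
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  if (!is.character(reference) || length(reference) != 1L || is.na(reference)) {
    stop("reference must be a single nucleotide sequence", call. = FALSE)
  }
  reference <- toupper(reference)
  if (nchar(reference) == 0L) stop("reference sequence is empty", call. = FALSE)
  if (grepl("[^ACGTN]", reference)) {
    stop("reference contains non-nucleotide characters", call. = FALSE)
  }
  reference
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "")[[1L]]
  if (!all(chars %in% names(map))) stop("invalid IUPAC pattern: ", pattern, call. = FALSE)
  paste0(map[chars], collapse = "")
}

#' Construct a protospacer site
#'
#' A protospacer site is a `spacer_length`-nt spacer followed immediately by
#' an NGG PAM on the protospacer-bearing (nontarget) strand.  The site is
#' validated against the reference: the footprint must lie within the
#' reference and the PAM must match NGG on the protospacer strand.
#'
#' @param reference Reference sequence (character, `DNAString`, or
#'   `DNAStringSet`; the first sequence is used).
#' @param start 0-based start of the 23-bp footprint (spacer + PAM) on the
#'   plus strand.
#' @param strand `"+"` or `"-"`: the strand bearing the protospacer and PAM.
#' @param reference_id Identifier recorded with the site.
#' @param spacer_length Spacer length in nt (default 20, the SpCas9 spacer).
#' @return An object of class `protospacer_site` with fields
#'   `reference_id`, `start`, `strand`, `spacer_seq`, `pam_seq`,
#'   `spacer_length` and `footprint` (0-based half-open).
#' @examples
#' ref <- paste0(strrep("A", 5), "GATTACAGATTACAGATTAC", "AGG", strrep("A", 5))
#' protospacer_site(ref, start = 5, strand = "+")
#' @export
protospacer_site <- function(reference, start, strand,
                             reference_id = "ref", spacer_length = 20L) {
  reference <- .norm_reference(reference)
  stopifnot(length(start) == 1L, start >= 0, strand %in% c("+", "-"))
  start <- as.integer(start)
  spacer_length <- as.integer(spacer_length)
  flen <- spacer_length + 3L
  if (start + flen > nchar(reference)) {
    stop("site footprint extends beyond the reference", call. = FALSE)
  }
  footprint <- substr(reference, start + 1L, start + flen)
  if (strand == "+") {
    spacer <- substr(footprint, 1L, spacer_length)
    pam <- substr(footprint, spacer_length + 1L, flen)
  } else {
    rc <- .revcomp(footprint)
    spacer <- substr(rc, 1L, spacer_length)
    pam <- substr(rc, spacer_length + 1L, flen)
  }
  if (!grepl("^[ACGT]GG$", pam)) {
    stop("PAM is not NGG on the protospacer strand (found ", pam, ")",
         call. = FALSE)
  }
  structure(
    list(reference_id = reference_id, start = start, strand = strand,
         spacer_seq = spacer, pam_seq = pam, spacer_length = spacer_length,
         footprint = c(start, start + flen)),
    class = "protospacer_site"
  )
}

#' @export
print.protospacer_site <- function(x, ...) {
  cat(sprintf("<protospacer_site> %s:%d-%d (%s) spacer=%s pam=%s\n",
              x$reference_id, x$footprint[1], x$footprint[2], x$strand,
              x$spacer_seq, x$pam_seq))
  invisible(x)
}

# PAM-proximal spacer edge of a site, as a junction index.
.pam_proximal_edge <- function(site) {
  if (site$strand == "+") site$footprint[2] - 3L else site$footprint[1] + 3L
}

# Inclusive junction range touching the 3-bp PAM footprint.
.pam_junction_range <- function(site) {
  if (site$strand == "+") {
    c(site$footprint[2] - 3L, site$footprint[2])
  } else {
    c(site$footprint[1], site$footprint[1] + 3L)
  }
}

#' Scan a reference for protospacer/PAM sites on both strands
#'
#' Sites are `spacer_length`-nt spacers immediately 5' of a PAM matching
#' `pam_pattern` on the protospacer-bearing strand.  Both strands are
#' scanned; results are ordered by ascending footprint start, plus strand
#' before minus at ties.
#'
#' @inheritParams protospacer_site
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @return List of [protospacer_site()] objects (possibly empty).
#' @examples
#' ref <- paste0("TTT", strrep("ACGT", 20), "TGGTT")
#' length(find_protospacers(ref))
#' @export
find_protospacers <- function(reference, pam_pattern = "NGG",
                              reference_id = "ref", spacer_length = 20L) {
  reference <- .norm_reference(reference)
  n <- nchar(reference)
  flen <- spacer_length + 3L
  if (n < flen) return(list())
  subj <- Biostrings::DNAString(reference)
  hits <- list()
  # plus strand: PAM at [p, p+3) with spacer_length nt upstream
  m <- Biostrings::matchPattern(Biostrings::DNAString(pam_pattern), subj,
                                fixed = FALSE)
  for (p in Biostrings::start(m) - 1L) {
    s <- p - spacer_length
    if (s >= 0L) {
      hits[[length(hits) + 1L]] <- list(start = s, strand = "+")
    }
  }
  # minus strand: plus-strand reverse complement of the PAM, spacer downstream
  rc_pam <- .revcomp(pam_pattern)
  m <- Biostrings::matchPattern(Biostrings::DNAString(rc_pam), subj,
                                fixed = FALSE)
  for (p in Biostrings::start(m) - 1L) {
    if (p + flen <= n) {
      hits[[length(hits) + 1L]] <- list(start = p, strand = "-")
    }
  }
  if (length(hits) == 0L) return(list())
  ord <- order(vapply(hits, `[[`, integer(1), "start"),
               vapply(hits, function(h) h$strand == "-", logical(1)))
  lapply(hits[ord], function(h) {
    protospacer_site(reference, h$start, h$strand,
                     reference_id = reference_id,
                     spacer_length = spacer_length)
  })
}

#' Summarise a list of sites as a data frame
#'
#' @param sites List of [protospacer_site()] objects.
#' @return A data frame with one row per site.
#' @export
sites_table <- function(sites) {
  if (length(sites) == 0L) {
    return(data.frame(reference_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer_seq = character(), pam_seq = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(sites, function(s) {
    data.frame(reference_id = s$reference_id, start = s$footprint[1],
               end = s$footprint[2], strand = s$strand,
               spacer_seq = s$spacer_seq, pam_seq = s$pam_seq,
               stringsAsFactors = FALSE)
  }))
}

#' Length of the single-stranded segment released on nicking
#'
#' When H840A nicks the nontarget (PAM-bearing) strand, the PAM-distal part
#' of the nontarget strand inside the R-loop -- everything 5' of the nick
#' within the spacer region -- is freed with a new 3' terminus at the nick:
#' `spacer_length - 3` nt (17 nt for the canonical 20-nt spacer).  A D10A
#' nick on the target strand frees no such segment, because the target
#' strand stays paired with the sgRNA spacer.
#'
#' @param variant `"D10A"` or `"H840A"`.
#' @param spacer_length Spacer length in nt.
#' @return Integer number of nt of released 3' single-stranded DNA.
#' @examples
#' released_ssdna_length("H840A")  # 17
#' released_ssdna_length("D10A")   # 0
#' @export
released_ssdna_length <- function(variant = c("D10A", "H840A"),
                                  spacer_length = 20L) {
  variant <- match.arg(variant)
  if (variant == "H840A") as.integer(spacer_length) - 3L else 0L
}

#' Nick coordinates of a nickase variant on a site
#'
#' Both SpCas9 nuclease domains cut 3 bp 5' of the PAM (between spacer
#' positions 17 and 18 for a 20-nt spacer).  D10A (RuvC inactivated, HNH
#' active) nicks the target strand -- the strand base-paired with the sgRNA,
#' i.e. the strand opposite the protospacer; H840A (HNH inactivated, RuvC
#' active) nicks the nontarget, protospacer-bearing strand.
#'
#' @param site A [protospacer_site()].
#' @param variant `"D10A"` or `"H840A"`.
#' @return An object of class `nick_site` with fields `strand_nicked`,
#'   `junction` (0-based inter-base index), `variant`, `released_ssdna_nt`
#'   and `source_site`.
#' @export
nick_position <- function(site, variant = c("D10A", "H840A")) {
  variant <- match.arg(variant)
  stopifnot(inherits(site, "protospacer_site"))
  junction <- if (site$strand == "+") {
    site$footprint[2] - 6L   # 3 bp 5' of the PAM start
  } else {
    site$footprint[1] + 6L
  }
  strand_nicked <- if (variant == "H840A") {
    site$strand
  } else {
    if (site$strand == "+") "-" else "+"
  }
  structure(
    list(strand_nicked = strand_nicked, junction = junction,
         variant = variant,
         released_ssdna_nt = released_ssdna_length(variant, site$spacer_length),
         source_site = site),
    class = "nick_site"
  )
}

#' @export
print.nick_site <- function(x, ...) {
  cat(sprintf("<nick_site> %s strand %s junction %d (released 3' ssDNA %d nt)\n",
              x$variant, x$strand_nicked, x$junction, x$released_ssdna_nt))
  invisible(x)
}

#' Joint cut geometry of a pair of nickase sites
#'
#' Computes the two nick junctions under a common nickase variant and
#' derives the double-strand-break geometry: polarity is decided from the
#' plus-strand and minus-strand junctions (plus left of minus gives
#' protruding 5' ends, plus right of minus protruding 3' ends, equal blunt),
#' overhang length equals the inter-nick distance for staggered ends, and
#' the overlap length is the intersection of the two 23-bp target
#' footprints (spacer + PAM).  Two nicks on the same strand produce no
#' double-strand break and are flagged `same_strand`.
#'
#' @param site1,site2 [protospacer_site()] objects on the same reference.
#' @param variant `"D10A"` or `"H840A"`, applied to both sites.
#' @return An object of class `pair_geometry` with fields `nick_a`,
#'   `nick_b` (nicks ordered by junction), `inter_nick_distance`,
#'   `overlap_length`, `overhang_polarity` (`"blunt"`, `"five_prime"`,
#'   `"three_prime"` or `"same_strand"`), `overhang_length`,
#'   `released_ssdna_lengths` and `variant`.
#' @export
pair_geometry <- function(site1, site2, variant = c("D10A", "H840A")) {
  variant <- match.arg(variant)
  stopifnot(inherits(site1, "protospacer_site"),
            inherits(site2, "protospacer_site"))
  if (!identical(site1$reference_id, site2$reference_id)) {
    stop("sites lie on different references", call. = FALSE)
  }
  n1 <- nick_position(site1, variant)
  n2 <- nick_position(site2, variant)
  if (n1$strand_nicked == n2$strand_nicked) {
    polarity <- "same_strand"
    dist <- abs(n1$junction - n2$junction)
    overhang <- 0L
  } else {
    plus_j <- if (n1$strand_nicked == "+") n1$junction else n2$junction
    minus_j <- if (n1$strand_nicked == "-") n1$junction else n2$junction
    dist <- abs(plus_j - minus_j)
    polarity <- if (plus_j < minus_j) {
      "five_prime"
    } else if (plus_j > minus_j) {
      "three_prime"
    } else {
      "blunt"
    }
    overhang <- if (polarity == "blunt") 0L else dist
  }
  ov <- min(site1$footprint[2], site2$footprint[2]) -
    max(site1$footprint[1], site2$footprint[1])
  nicks <- if (n1$junction <= n2$junction) list(n1, n2) else list(n2, n1)
  structure(
    list(nick_a = nicks[[1L]], nick_b = nicks[[2L]],
         inter_nick_distance = as.integer(dist),
         overlap_length = as.integer(max(0L, ov)),
         overhang_polarity = polarity,
         overhang_length = as.integer(overhang),
         released_ssdna_lengths = c(site1 = n1$released_ssdna_nt,
                                    site2 = n2$released_ssdna_nt),
         variant = variant),
    class = "pair_geometry"
  )
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf(
    "<pair_geometry> %s nicks @%d/%d dist=%d overlap=%d %s overhang=%d nt\n",
    x$variant, x$nick_a$junction, x$nick_b$junction, x$inter_nick_distance,
    x$overlap_length, x$overhang_polarity, x$overhang_length))
  invisible(x)
}

#' Enumerate double-strand-break-forming site pairs
#'
#' All unordered pairs of sites whose nicks fall on opposite strands
#' (`polarity != "same_strand"`) and whose inter-nick distance does not
#' exceed `max_distance`, in deterministic order (leftmost nick junction,
#' then inter-nick distance).
#'
#' @param sites List of [protospacer_site()] objects from one reference.
#' @param variant `"D10A"` or `"H840A"`.
#' @param max_distance Maximum inter-nick distance in bp.
#' @return A data frame with one row per retained pair (site indices refer
#'   to positions in `sites`), plus a `"pairs"` attribute holding the
#'   corresponding [pair_geometry()] objects.
#' @export
enumerate_pairs <- function(sites, variant = c("D10A", "H840A"),
                            max_distance = 150L) {
  variant <- match.arg(variant)
  empty <- data.frame(site1 = integer(), site2 = integer(),
                      nick_a = integer(), nick_b = integer(),
                      inter_nick_distance = integer(),
                      overlap_length = integer(),
                      overhang_polarity = character(),
                      overhang_length = integer(),
                      stringsAsFactors = FALSE)
  if (length(sites) < 2L) {
    attr(empty, "pairs") <- list()
    return(empty)
  }
  rows <- list()
  geoms <- list()
  for (i in seq_len(length(sites) - 1L)) {
    for (j in (i + 1L):length(sites)) {
      g <- pair_geometry(sites[[i]], sites[[j]], variant)
      if (g$overhang_polarity == "same_strand") next
      if (g$inter_nick_distance > max_distance) next
      rows[[length(rows) + 1L]] <- data.frame(
        site1 = i, site2 = j,
        nick_a = g$nick_a$junction, nick_b = g$nick_b$junction,
        inter_nick_distance = g$inter_nick_distance,
        overlap_length = g$overlap_length,
        overhang_polarity = g$overhang_polarity,
        overhang_length = g$overhang_length,
        stringsAsFactors = FALSE)
      geoms[[length(geoms) + 1L]] <- g
    }
  }
  if (length(rows) == 0L) {
    attr(empty, "pairs") <- list()
    return(empty)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$nick_a, out$inter_nick_distance, out$site1, out$site2)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pairs") <- geoms[ord]
  out
}

# Abstract two-site geometry: site1 protospacer on the plus strand with
# footprint [0, 23); site2 on the minus strand with footprint [d, d + 23).
# Returns junctions and derived geometry without requiring a realisable
# sequence, mirroring nick_position()/pair_geometry() arithmetic.
.abstract_pair <- function(d, variant, spacer_length = 20L) {
  flen <- spacer_length + 3L
  j1 <- flen - 6L          # site1 nick junction (3 bp 5' of its PAM)
  j2 <- d + 6L             # site2 nick junction
  if (variant == "H840A") {
    plus_j <- j1; minus_j <- j2
  } else {
    plus_j <- j2; minus_j <- j1
  }
  dist <- abs(plus_j - minus_j)
  polarity <- if (plus_j < minus_j) "five_prime"
              else if (plus_j > minus_j) "three_prime" else "blunt"
  ov <- min(flen, d + flen) - max(0L, d)
  list(offset = d, overlap_length = max(0L, ov), polarity = polarity,
       overhang_length = if (polarity == "blunt") 0L else dist,
       inter_nick_distance = dist, plus_junction = plus_j,
       minus_junction = minus_j)
}

#' Slide one target past another and tabulate the overhang geometry
#'
#' Enumerates relative placements of two 23-bp targets on opposite strands
#' (the first on the plus strand at offset 0, the second on the minus strand
#' at the given offsets) and reports overlap, polarity and overhang length
#' for a common nickase variant.  With the default offsets the table covers
#' every overlapping placement (`offset` -22 to 22, overlap 1-23 bp),
#' traversing both the PAM-in branch (positive offsets, PAMs between the
#' outer footprint edges) and the PAM-out branch (negative offsets).
#'
#' This is pure coordinate arithmetic: placements are tabulated whether or
#' not a concrete sequence can realise them (a handful of deeply overlapping
#' placements are impossible in real DNA because one site's GG would have to
#' coincide with the other's CC; see [make_reference()]).
#'
#' @param variant `"D10A"` or `"H840A"`.
#' @param offsets Integer offsets of the minus-strand footprint start
#'   relative to the plus-strand footprint start.
#' @param spacer_length Spacer length in nt.
#' @return Data frame with columns `offset`, `overlap_length`,
#'   `overhang_polarity`, `overhang_length`, `inter_nick_distance`.
#' @examples
#' s <- overlap_series("D10A")
#' s[s$overhang_length == 0 & s$overlap_length == 12, ]
#' @export
overlap_series <- function(variant = c("D10A", "H840A"),
                           offsets = -22:22, spacer_length = 20L) {
  variant <- match.arg(variant)
  rows <- lapply(offsets, function(d) {
    g <- .abstract_pair(as.integer(d), variant, spacer_length)
    data.frame(offset = g$offset, overlap_length = g$overlap_length,
               overhang_polarity = g$polarity,
               overhang_length = g$overhang_length,
               inter_nick_distance = g$inter_nick_distance,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
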