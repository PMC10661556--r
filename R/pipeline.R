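# Pipeline entry points tying the stages together.  Each cmd_* function is
# a pure function of (inputs, config, seed): outputs carry a config echo in
# their headers and reruns are byte-identical.  A thin command-line wrapper
# around these functions ships as inst/cli/pairnick.R.

.version_echo <- function() {
  paste0("pairnick ", as.character(utils::packageVersion("pairnick")))
}

#' Design paired-nickase sites for a reference amplicon
#'
#' Scans the first FASTA record for protospacer/NGG sites on both strands,
#' enumerates double-strand-break-forming pairs within `max_distance`,
#' classifies second-nick viability under both nicking orders and the given
#' TREX2 mode, and predicts TREX2 stimulability.
#'
#' @param fasta Path to the reference FASTA.
#' @param variant `"D10A"` or `"H840A"`.
#' @param max_distance Maximum inter-nick distance in bp.
#' @param trex_mode `"none"`, `"free"` or `"fused"`.
#' @param params A [viability_params()].
#' @param window Stimulation window (bp) for [stimulation_prediction()].
#' @param out_dir Optional output directory; when given, writes
#'   `sites.tsv`, `pairs.tsv`, `verdicts.tsv` and `nicks.bed`.
#' @return Invisibly, a list with `sites` (data frame), `pairs` (data
#'   frame), `verdicts` (data frame), `site_list`.
#' @export
cmd_design <- function(fasta, variant = c("D10A", "H840A"),
                       max_distance = 150L,
                       trex_mode = c("free", "none", "fused"),
                       params = viability_params(),
                       window = c(13L, 96L), out_dir = NULL) {
  variant <- match.arg(variant)
  trex_mode <- match.arg(trex_mode)
  ref <- read_reference(fasta)
  sites <- find_protospacers(ref$seq, reference_id = ref$id)
  st <- sites_table(sites)
  pairs <- enumerate_pairs(sites, variant, max_distance)
  geoms <- attr(pairs, "pairs")
  verdicts <- if (length(geoms) == 0L) {
    data.frame(pair = integer(), first_nicker = integer(),
               trex_mode = character(), viable = logical(),
               rule_triggered = character(), intact_pairing_nt = integer(),
               stimulable = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_along(geoms), function(k) {
      g <- geoms[[k]]
      pv <- pair_viability(g, trex_mode, params)
      best <- if (pv$ordering1$viable) pv$ordering1 else pv$ordering2
      stim <- stimulation_prediction(g, best, window)
      do.call(rbind, lapply(1:2, function(o) {
        v <- pv[[paste0("ordering", o)]]
        data.frame(pair = k, first_nicker = o, trex_mode = trex_mode,
                   viable = v$viable, rule_triggered = v$rule_triggered,
                   intact_pairing_nt = v$intact_pairing_nt,
                   stimulable = stim$status, stringsAsFactors = FALSE)
      }))
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    echo <- list(tool = .version_echo(), fasta = fasta, variant = variant,
                 max_distance = max_distance, trex_mode = trex_mode,
                 window = paste(window, collapse = "-"))
    write_tsv(st, file.path(out_dir, "sites.tsv"), echo)
    write_tsv(as.data.frame(pairs), file.path(out_dir, "pairs.tsv"), echo)
    write_tsv(verdicts, file.path(out_dir, "verdicts.tsv"), echo)
    nicks <- unlist(lapply(geoms, function(g) list(g$nick_a, g$nick_b)),
                    recursive = FALSE)
    if (length(nicks)) {
      write_nicks_bed(nicks, file.path(out_dir, "nicks.bed"))
    }
  }
  invisible(list(sites = st, pairs = pairs, verdicts = verdicts,
                 site_list = sites))
}

#' Simulate a synthetic paired-nickase amplicon experiment
#'
#' Builds a reference with a planted site pair (see [make_reference()]),
#' simulates reads under a scenario, and optionally writes
#' `reference.fasta`, `reads.fastq`, `truth.tsv` and `scenario.json`.
#'
#' @param scenario A [scenario_config()] or preset name for
#'   [preset_scenario()].
#' @param layout,variant,inter_nick_distance,overlap_length,branch,length
#'   Passed to [make_reference()].
#' @param seed Seed for both the reference background and the read
#'   simulation (overrides `scenario$seed`).
#' @param out_dir Optional output directory.
#' @return Invisibly, the [simulate_reads()] result plus `reference`,
#'   `nick_a`, `nick_b`, `geometry`.
#' @export
cmd_simulate <- function(scenario = "TREX2_like", layout = "pam_in",
                         variant = "D10A", inter_nick_distance = 40L,
                         overlap_length = NULL, branch = "auto",
                         length = 240L, seed = 1L, out_dir = NULL) {
  if (is.character(scenario)) scenario <- preset_scenario(scenario)
  scenario$seed <- as.integer(seed)
  mk <- make_reference(length, layout, variant,
                       inter_nick_distance = inter_nick_distance,
                       overlap_length = overlap_length, branch = branch,
                       seed = seed)
  sim <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, scenario)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(setNames(mk$reference, mk$reference_id),
                file.path(out_dir, "reference.fasta"))
    write_fastq(sim$reads, file.path(out_dir, "reads.fastq"))
    echo <- list(tool = .version_echo(), layout = layout, variant = variant,
                 nick_a = mk$nick_a, nick_b = mk$nick_b, seed = seed)
    write_tsv(sim$truth, file.path(out_dir, "truth.tsv"), echo)
    sc <- sim$scenario
    class(sc) <- NULL
    write_json(c(list(tool = .version_echo(), nick_a = mk$nick_a,
                      nick_b = mk$nick_b), sc),
               file.path(out_dir, "scenario.json"))
  }
  invisible(c(sim, mk["reference"], list(reference_id = mk$reference_id,
                                         nick_a = mk$nick_a,
                                         nick_b = mk$nick_b,
                                         geometry = mk$geometry)))
}

#' Call edits in an amplicon FASTQ against a reference FASTA
#'
#' @param fastq FASTQ path (or any input accepted by [call_edits()]).
#' @param fasta Reference FASTA path.
#' @param nicks Integer vector of nick junctions (defines the default
#'   edit window, nicks +/- 20 nt).
#' @param out_dir Optional output directory; writes `calls.tsv` and
#'   `stats.json`.
#' @inheritParams call_edits
#' @return Invisibly, the [call_edits()] result.
#' @export
cmd_call <- function(fastq, fasta, nicks = NULL, window = NULL,
                     min_indel_nt = 1L, transfection_efficiency = 1,
                     scoring = align_scoring(), out_dir = NULL) {
  ref <- read_reference(fasta)
  res <- call_edits(fastq, ref$seq, window = window, nicks = nicks,
                    min_indel_nt = min_indel_nt,
                    transfection_efficiency = transfection_efficiency,
                    scoring = scoring)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    echo <- list(tool = .version_echo(),
                 window = paste(res$stats$window, collapse = "-"),
                 min_indel_nt = min_indel_nt,
                 transfection_efficiency = transfection_efficiency)
    write_tsv(calls_table(res$calls), file.path(out_dir, "calls.tsv"), echo)
    s <- res$stats
    class(s) <- NULL
    write_json(c(list(tool = .version_echo()), s),
               file.path(out_dir, "stats.json"))
  }
  invisible(res)
}

#' Junction spectrum and summary from calls
#'
#' @param calls List of `indel_call`s (from [call_edits()]).
#' @param stats The matching `editing_stats`.
#' @param nick_a,nick_b Nick junctions, `nick_a < nick_b` (checked).
#' @param boundary_tol_nt,near_full_tolerance_nt,median_over See
#'   [assign_first_nick()] and [summarize_junctions()].
#' @param denominator Denominator for [deletion_spectrum()].
#' @param reference Optional reference sequence for shift-aware coverage
#'   (see [summarize_junctions()]).
#' @param out_dir Optional output directory; writes `spectrum.tsv` and
#'   `summary.json`.
#' @return Invisibly, list with `spectrum`, `summary`, `records`.
#' @export
cmd_spectrum <- function(calls, stats, nick_a, nick_b,
                         boundary_tol_nt = 1L, near_full_tolerance_nt = 3L,
                         median_over = "deletion_reads",
                         denominator = "edited_reads", reference = NULL,
                         out_dir = NULL) {
  if (!(nick_a < nick_b)) {
    stop("nick_a must be less than nick_b", call. = FALSE)
  }
  edited <- vapply(calls, .is_edited, logical(1),
                   window = stats$window, min_indel_nt = stats$min_indel_nt)
  with_del <- Filter(function(cl) nrow(cl$deletions) > 0L, calls[edited])
  records <- lapply(with_del, assign_first_nick, nick_a = nick_a,
                    nick_b = nick_b, boundary_tol_nt = boundary_tol_nt)
  spectrum <- deletion_spectrum(records, stats, denominator)
  summary <- summarize_junctions(calls, nick_a, nick_b,
                                 near_full_tolerance_nt,
                                 median_over = median_over,
                                 edited = edited, reference = reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    echo <- list(tool = .version_echo(), nick_a = nick_a, nick_b = nick_b,
                 boundary_tol_nt = boundary_tol_nt,
                 near_full_tolerance_nt = near_full_tolerance_nt,
                 denominator = denominator, median_over = median_over)
    write_tsv(spectrum, file.path(out_dir, "spectrum.tsv"), echo)
    s <- summary
    class(s) <- NULL
    write_json(c(list(tool = .version_echo()), s),
               file.path(out_dir, "summary.json"))
  }
  invisible(list(spectrum = spectrum, summary = summary, records = records))
}
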