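# Synthetic reference construction and seeded read simulation.

test_that("make_reference realises the requested geometry exactly", {
  mk <- make_reference(240, "overlapping", "D10A", overlap_length = 12,
                       seed = 3)
  expect_equal(mk$geometry$overlap_length, 12L)
  expect_equal(mk$geometry$overhang_polarity, "blunt")

  mk2 <- make_reference(260, "overlapping", "H840A", overlap_length = 1,
                        seed = 3)
  expect_equal(mk2$geometry$overlap_length, 1L)
  expect_equal(mk2$geometry$overhang_polarity, "three_prime")
  expect_equal(mk2$geometry$overhang_length, 33L)

  mk3 <- make_reference(260, "overlapping", "H840A", overlap_length = 15,
                        seed = 4, branch = "near")
  expect_equal(mk3$geometry$overlap_length, 15L)
  expect_equal(mk3$geometry$overhang_length, 3L)

  for (D in c(0L, 14L, 40L)) {
    mk4 <- make_reference(300, "pam_in", "D10A", inter_nick_distance = D,
                          seed = D + 1L)
    expect_equal(mk4$geometry$inter_nick_distance, D)
    expect_equal(mk4$geometry$overhang_polarity,
                 if (D == 0L) "blunt" else "three_prime")
    mk5 <- make_reference(300, "pam_out", "H840A", inter_nick_distance = D,
                          seed = D + 2L)
    expect_equal(mk5$geometry$inter_nick_distance, D)
    expect_equal(mk5$geometry$overhang_polarity,
                 if (D == 0L) "blunt" else "three_prime")
  }
})

test_that("infeasible layouts raise explicit geometry errors", {
  # a 12-nt 3' overhang would need overlap 0: out of the D10A 0-11 range
  expect_error(make_reference(240, "overlapping", "D10A",
                              overlap_length = 0), "1\\.\\.23")
  expect_error(make_reference(240, "overlapping", "D10A",
                              overlap_length = 13), "overlap 1\\.\\.12")
  # overlaps 1-3 for D10A put one site's CC onto the other's GG
  for (ov in 1:3) {
    expect_error(make_reference(240, "overlapping", "D10A",
                                overlap_length = ov), "coincide")
  }
  expect_error(make_reference(240, "overlapping", "H840A",
                              overlap_length = 5, branch = "near"),
               "near branch")
  expect_error(make_reference(80, "pam_in", "D10A",
                              inter_nick_distance = 40), "too short")
})

test_that("scenario configs validate rates and weights", {
  expect_error(scenario_config(0.3, c(nick_local = 0.5, full_span = 0.4,
                                      insertion = 0.2)), "sum to 1")
  expect_error(scenario_config(1.3), "\\[0, 1\\]")
  expect_error(scenario_config(0.3, c(bad = 1)), "must name")
  for (nm in c("EV_like", "TREX2_like", "fused_like")) {
    sc <- preset_scenario(nm)
    expect_s3_class(sc, "scenario_config")
    expect_equal(sum(sc$component_weights), 1)
  }
  ev <- preset_scenario("EV_like")
  tx <- preset_scenario("TREX2_like")
  expect_lt(ev$component_weights[["full_span"]],
            ev$component_weights[["nick_local"]])
  expect_gt(tx$component_weights[["full_span"]],
            tx$component_weights[["nick_local"]])
  expect_lt(ev$edit_rate, tx$edit_rate)
})

test_that("simulation is deterministic in the seed and respects edit_rate 0", {
  mk <- make_reference(220, "pam_in", "D10A", inter_nick_distance = 35,
                       seed = 9)
  sc <- scenario_config(edit_rate = 0.5, n_reads = 80L, seed = 42L)
  s1 <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)
  s2 <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  sc2 <- scenario_config(edit_rate = 0.5, n_reads = 80L, seed = 43L)
  s3 <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc2)
  expect_false(identical(s1$reads$seq, s3$reads$seq))

  sc0 <- scenario_config(edit_rate = 0, n_reads = 50L, seed = 1L,
                         substitution_error_rate = 0)
  s0 <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc0)
  expect_true(all(s0$truth$class == "unedited"))
  expect_true(all(s0$reads$seq == mk$reference))
})

test_that("written FASTQ bytes are identical across reruns", {
  mk <- make_reference(220, "pam_in", "D10A", inter_nick_distance = 35,
                       seed = 10)
  sc <- scenario_config(edit_rate = 0.3, n_reads = 40L, seed = 7L)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)$reads,
              f1)
  write_fastq(simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)$reads,
              f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("with zero sequencing error the caller reproduces the ground truth", {
  mk <- make_reference(240, "pam_in", "D10A", inter_nick_distance = 40,
                       seed = 15)
  ref <- mk$reference
  ch <- strsplit(ref, "")[[1]]
  sc <- scenario_config(edit_rate = 0.5, n_reads = 400L, seed = 21L,
                        substitution_error_rate = 0)
  sim <- simulate_reads(ref, mk$nick_a, mk$nick_b, sc)
  res <- call_edits(setNames(sim$reads$seq, sim$reads$read_id), ref,
                    nicks = c(mk$nick_a, mk$nick_b))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    cl <- res$calls[[i]]
    if (tr$class == "unedited") {
      expect_equal(cl$edit_class, "unedited", info = tr$read_id)
    } else if (tr$class %in% c("nick_local", "full_span")) {
      expect_equal(cl$edit_class, "deletion", info = tr$read_id)
      want <- pairnick:::.canonicalize(
        ch, data.frame(start = tr$del_start, end = tr$del_end),
        data.frame(point = integer(), seq = character()))
      expect_equal(cl$deletions, want$deletions, info = tr$read_id)
    } else {
      expect_equal(cl$edit_class, "insertion", info = tr$read_id)
      want <- pairnick:::.canonicalize(
        ch, data.frame(start = integer(), end = integer()),
        data.frame(point = tr$ins_point, seq = tr$ins_seq,
                   stringsAsFactors = FALSE))
      expect_equal(cl$insertions, want$insertions, info = tr$read_id)
    }
  }
})

test_that("spectrum mass recovers the programmed mixture weights", {
  mk <- make_reference(240, "pam_in", "D10A", inter_nick_distance = 40,
                       seed = 16)
  sc <- preset_scenario("TREX2_like", n_reads = 3000L, seed = 22L)
  sim <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)
  res <- call_edits(setNames(sim$reads$seq, sim$reads$read_id),
                    mk$reference, nicks = c(mk$nick_a, mk$nick_b))
  sp <- cmd_spectrum(res$calls, res$stats, mk$nick_a, mk$nick_b,
                     reference = mk$reference)
  # full-span component: spectrum mass at signed length near or past the
  # span (left-shift ambiguity can shave a few nt off the signed length)
  span <- mk$nick_b - mk$nick_a
  full_mass <- sum(sp$spectrum$frequency[
    !is.na(sp$spectrum$signed_length_nt) &
      sp$spectrum$signed_length_nt >= span - 3L])
  w <- sc$component_weights
  # a full-span read is nick-anchored only if at least one resection
  # overshoot leaves a boundary within the 1-nt tolerance
  p_far <- (1 - sc$extra_resection_p)^2       # P(overshoot >= 2)
  expect_equal(full_mass, w[["full_span"]] * (1 - p_far^2),
               tolerance = 0.1)
  ins_frac <- mean(vapply(res$calls[res$edited], `[[`, character(1),
                          "edit_class") == "insertion")
  expect_equal(ins_frac, w[["insertion"]], tolerance = 0.5)
})
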