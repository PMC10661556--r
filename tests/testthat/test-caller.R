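# Amplicon indel calling: alignment, canonicalization, classification.

test_that("identity reads are unedited and damaged reads are low quality", {
  ref <- with_test_seed(1, random_seq(120L))
  expect_equal(align_and_call(ref, ref)$edit_class, "unedited")
  # substitutions only: still unedited
  mut <- paste0(substr(ref, 1, 59), "A", substr(ref, 61, 120))
  cl <- align_and_call(mut, ref)
  expect_true(cl$edit_class %in% c("unedited"))
  # short read floor
  expect_equal(align_and_call(substr(ref, 1, 10), ref)$edit_class,
               "low_quality")
  # mean quality floor (Phred+33; "#" = Q2)
  expect_equal(align_and_call(ref, ref,
                              qualities = strrep("#", 120))$edit_class,
               "low_quality")
  expect_equal(align_and_call(ref, ref,
                              qualities = strrep("?", 120))$edit_class,
               "unedited")
})

test_that("a constructed deletion is recovered as its canonical interval", {
  ref <- with_test_seed(2, random_seq(120L))
  read <- paste0(substr(ref, 1, 40), substr(ref, 55, 120))  # delete [40, 54)
  cl <- align_and_call(read, ref)
  expect_equal(cl$edit_class, "deletion")
  expect_equal(nrow(cl$deletions), 1L)
  # canonical equivalent of [40, 54): left-aligned
  want <- pairnick:::.canonicalize(strsplit(ref, "")[[1]],
                                   data.frame(start = 40L, end = 54L),
                                   data.frame(point = integer(),
                                              seq = character()))
  expect_equal(cl$deletions, want$deletions)
})

test_that("insertions are recovered with their canonical junction", {
  ref <- with_test_seed(3, random_seq(120L))
  read <- paste0(substr(ref, 1, 63), "GTCA", substr(ref, 64, 120))
  cl <- align_and_call(read, ref)
  expect_equal(cl$edit_class, "insertion")
  want <- pairnick:::.canonicalize(strsplit(ref, "")[[1]],
                                   data.frame(start = integer(),
                                              end = integer()),
                                   data.frame(point = 63L, seq = "GTCA",
                                              stringsAsFactors = FALSE))
  expect_equal(cl$insertions, want$insertions)
  expect_equal(cl$insertion_seq, want$insertions$seq[1])
})

test_that("shift-equivalent deletions in a repeat collapse to one representative", {
  ref <- paste0(strrep("T", 40), strrep("AC", 10), strrep("G", 40))
  # deleting any "AC" unit of the repeat yields the same read
  reads <- vapply(seq(41, 57, by = 2), function(s) {
    paste0(substr(ref, 1, s - 1), substr(ref, s + 2, nchar(ref)))
  }, character(1))
  expect_equal(length(unique(reads)), 1L)
  cl <- align_and_call(reads[1], ref)
  expect_equal(cl$edit_class, "deletion")
  expect_equal(cl$deletions$start, 40L)   # leftmost placement
  expect_equal(cl$deletions$end, 42L)
})

test_that("canonicalization is idempotent", {
  ref <- with_test_seed(4, random_seq(150L))
  ch <- strsplit(ref, "")[[1]]
  for (seed in 1:25) {
    dels <- with_test_seed(seed, {
      s <- sort(sample(0:120, 2))
      data.frame(start = s, end = s + sample(1:10, 2))
    })
    dels <- dels[dels$end <= 150 & dels$end[1] <= dels$start[2], ,
                 drop = FALSE]
    ins <- data.frame(point = 130L, seq = "AAG", stringsAsFactors = FALSE)
    once <- pairnick:::.canonicalize(ch, dels, ins)
    twice <- pairnick:::.canonicalize(ch, once$deletions, once$insertions)
    expect_identical(once, twice)
  }
})

test_that("calls match the affine-gap dynamic-programming oracle on planted indels", {
  n_bad <- 0L
  for (seed in 1:40) {
    ref <- with_test_seed(seed, random_seq(with_test_seed(seed + 500,
                                                          sample(80:120, 1))))
    cases <- with_test_seed(seed + 1000, {
      lapply(1:5, function(i) {
        if (runif(1) < 0.5) {
          L <- sample(1:12, 1)
          s <- sample(0:(nchar(ref) - L - 10), 1) + 5L
          list(read = paste0(substr(ref, 1, s), substr(ref, s + L + 1,
                                                       nchar(ref))))
        } else {
          L <- sample(1:6, 1)
          p <- sample(5:(nchar(ref) - 5), 1)
          list(read = paste0(substr(ref, 1, p),
                             paste0(sample(BASES, L, replace = TRUE),
                                    collapse = ""),
                             substr(ref, p + 1, nchar(ref))))
        }
      })
    })
    for (cs in cases) {
      cl <- align_and_call(cs$read, ref)
      got <- score_of_call(ref, cs$read, cl)
      want <- nw_affine_score(cs$read, ref)
      if (got != want) n_bad <- n_bad + 1L
    }
  }
  expect_equal(n_bad, 0L)
})

test_that("call_edits computes stats per the normalised-frequency definition", {
  ref <- with_test_seed(7, random_seq(150L))
  edited_read <- paste0(substr(ref, 1, 70), substr(ref, 81, 150))
  reads <- c(rep(edited_read, 250), rep(ref, 750))
  names(reads) <- paste0("r", seq_along(reads))
  res <- call_edits(reads, ref, window = c(60L, 100L),
                    transfection_efficiency = 0.5)
  expect_equal(res$stats$total_reads, 1000L)
  expect_equal(res$stats$edited_reads, 250L)
  expect_equal(res$stats$indel_frequency, 0.5)

  # empty input
  e <- call_edits(character(0), ref)
  expect_equal(e$stats$total_reads, 0L)
  expect_equal(e$stats$indel_frequency, 0)
  expect_length(e$calls, 0L)

  # window must be sane
  expect_error(call_edits(reads, ref, window = c(100L, 60L)), "window")
})

test_that("indel frequency is invariant to read order and duplication", {
  mk <- make_reference(200, "pam_in", "D10A", inter_nick_distance = 30,
                       seed = 31)
  sc <- scenario_config(edit_rate = 0.4, n_reads = 120L, seed = 5L,
                        substitution_error_rate = 0.002)
  sim <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)
  reads <- setNames(sim$reads$seq, sim$reads$read_id)
  base <- call_edits(reads, mk$reference, nicks = c(mk$nick_a, mk$nick_b))
  perm <- with_test_seed(8, sample(length(reads)))
  shuffled <- call_edits(reads[perm], mk$reference,
                         nicks = c(mk$nick_a, mk$nick_b))
  doubled <- call_edits(c(reads, reads), mk$reference,
                        nicks = c(mk$nick_a, mk$nick_b))
  expect_equal(shuffled$stats$indel_frequency, base$stats$indel_frequency)
  expect_equal(doubled$stats$indel_frequency, base$stats$indel_frequency)
  expect_equal(doubled$stats$total_reads, 2L * base$stats$total_reads)
})

test_that("reads stream identically from FASTQ files and in-memory vectors", {
  mk <- make_reference(200, "pam_in", "D10A", inter_nick_distance = 30,
                       seed = 33)
  sc <- scenario_config(edit_rate = 0.3, n_reads = 60L, seed = 6L)
  sim <- simulate_reads(mk$reference, mk$nick_a, mk$nick_b, sc)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  from_file <- call_edits(fq, mk$reference, nicks = c(mk$nick_a, mk$nick_b))
  from_mem <- call_edits(setNames(sim$reads$seq, sim$reads$read_id),
                         mk$reference, nicks = c(mk$nick_a, mk$nick_b))
  expect_equal(from_file$stats$edited_reads, from_mem$stats$edited_reads)
  expect_equal(vapply(from_file$calls, `[[`, character(1), "edit_class"),
               vapply(from_mem$calls, `[[`, character(1), "edit_class"))
  unlink(fq)
})
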