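# Fixture builders: all fixtures are generated in code at test time.

# Reference with two planted opposite-strand targets whose minus-strand
# footprint starts `d` bases right of the plus-strand one.  Offsets 20-22
# are sequence-infeasible (PAM clash) and rejected by make_reference.
plant_pair <- function(d, variant, seed = 1L, length = 300L) {
  if (d >= 11L) {
    make_reference(length, "pam_in", variant,
                   inter_nick_distance = d - 11L, seed = seed)
  } else {
    make_reference(length, "pam_out", variant,
                   inter_nick_distance = 11L - d, seed = seed)
  }
}

feasible_offsets <- function(offsets = -22:22) {
  setdiff(offsets, 20:22)
}

# A quick valid plus-strand site on a fresh random background.
plant_single_site <- function(seed = 1L, length = 80L, at = 30L) {
  ref <- with_test_seed(seed, {
    ch <- sample(BASES, length, replace = TRUE)
    ch[at + 22L] <- "G"; ch[at + 23L] <- "G"
    paste0(ch, collapse = "")
  })
  list(reference = ref, site = protospacer_site(ref, at, "+"))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
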