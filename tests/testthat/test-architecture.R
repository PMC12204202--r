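test_that("domain segmentation follows the TMH-end / final-100 rule", {
  p <- ss_profile("x", strrep("C", 300), tmh_span = c(10, 30))
  seg <- segment_domains(p)
  expect_equal(seg$domain2, c(31, 200))
  expect_equal(seg$domain3, c(201, 300))
  expect_equal(seg$d2_length, 170)
  expect_false(seg$flagged)
  # too short for domain II: flagged
  p2 <- ss_profile("y", strrep("C", 120), tmh_span = c(10, 30))
  seg2 <- segment_domains(p2)
  expect_true(seg2$flagged)
  expect_equal(seg2$d2_length, 0)
  # boundary: TMH ending at 31 in a 131-residue protein
  p3 <- ss_profile("z", strrep("C", 131), tmh_span = c(1, 31))
  seg3 <- segment_domains(p3)
  expect_equal(seg3$domain2, c(32, 31))
  expect_equal(seg3$domain3, c(32, 131))
  expect_true(seg3$flagged)
  expect_error(segment_domains(ss_profile("w", strrep("C", 300))),
               "segmentation error")
})

test_that("domain spans are ordered and disjoint whenever domain II is non-empty", {
  set.seed(7)
  for (i in 1:20) {
    L <- sample(150:500, 1)
    tmh_start <- sample(1:20, 1)
    tmh_end <- tmh_start + sample(15:25, 1)
    p <- ss_profile("x", strrep("C", L), tmh_span = c(tmh_start, tmh_end))
    seg <- segment_domains(p)
    if (seg$flagged) next
    expect_lt(seg$domain1[2], seg$domain2[1])
    expect_lt(seg$domain2[2], seg$domain3[1])
    expect_equal(seg$domain3[2], L)
    expect_equal(seg$d2_length + 100 + seg$domain1[2], L)
  }
})

mk_motorbox_profile <- function(offset, strand_len = 4, flank = 3, L = 300,
                                tmh = c(10, 30)) {
  states <- rep("C", L)
  states[tmh[1]:tmh[2]] <- "H"
  st <- tmh[2] + offset
  states[st:(st + strand_len - 1)] <- "E"
  ss_profile("mb", paste(states, collapse = ""), tmh_span = tmh)
}

test_that("motor box detection finds a flanked strand near the start of domain II", {
  p <- mk_motorbox_profile(offset = 6)
  seg <- segment_domains(p)
  expect_equal(detect_motor_box(p, seg$domain2), c(36, 39))
  # all-coil domain II: nothing to find
  p2 <- ss_profile("c", paste(c(rep("C", 9), rep("H", 21), rep("C", 270)),
                              collapse = ""), tmh_span = c(10, 30))
  expect_null(detect_motor_box(p2, segment_domains(p2)$domain2))
  # a strand shorter than min_strand is ignored
  p3 <- mk_motorbox_profile(offset = 6, strand_len = 2)
  expect_null(detect_motor_box(p3, segment_domains(p3)$domain2))
  # a strand hugging the TMH has no coil flank on the left
  p4 <- mk_motorbox_profile(offset = 1)
  expect_null(detect_motor_box(p4, segment_domains(p4)$domain2))
})

test_that("detection flips exactly at the window boundary", {
  # strand starts at domain II position 40
  p <- mk_motorbox_profile(offset = 40)
  seg <- segment_domains(p)
  expect_null(detect_motor_box(p, seg$domain2, window = 39))
  expect_equal(detect_motor_box(p, seg$domain2, window = 40),
               c(70, 73))
})

test_that("composition metrics are exact arithmetic over domain II", {
  # all-H domain II, no prolines
  states <- c(rep("C", 9), rep("H", 21), rep("H", 170), rep("C", 100))
  p <- ss_profile("x", paste(states, collapse = ""), tmh_span = c(10, 30))
  seqc <- strrep("A", 300)
  m <- composition_metrics(p, seqc, c(31, 200))
  expect_equal(m$helix_pct, 100)
  expect_equal(m$proline_pct, 0)
  expect_equal(m$d2_length, 170)
  # 200-residue domain II with 50 H and 20 P
  states2 <- c(rep("C", 9), rep("H", 21), rep("H", 50), rep("C", 150),
               rep("C", 100))
  seq2 <- paste(c(rep("A", 30), rep("A", 180), rep("P", 20), rep("G", 100)),
                collapse = "")
  p2 <- ss_profile("y", paste(states2, collapse = ""), tmh_span = c(10, 30))
  m2 <- composition_metrics(p2, seq2, c(31, 230))
  expect_equal(m2$helix_pct, 25)
  expect_equal(m2$proline_pct, 10)
  # empty domain II: undefined
  expect_true(composition_metrics(p, seqc, c(31, 30))$undefined)
})

test_that("metrics match an independent per-character count on a generated protein", {
  g <- generate_profile(protein_length = 350, helix_count = 44,
                        proline_count = 17, seed = 99)
  seg <- segment_domains(g$profile)
  m <- composition_metrics(g$profile, g$sequence, seg$domain2)
  # hand count: walk the strings character by character
  st <- strsplit(g$profile$states, "")[[1]]
  sq <- strsplit(g$sequence, "")[[1]]
  h <- 0; pr <- 0
  for (i in seg$domain2[1]:seg$domain2[2]) {
    if (st[i] == "H") h <- h + 1
    if (sq[i] == "P") pr <- pr + 1
  }
  expect_equal(m$helix_pct, 100 * h / seg$d2_length)
  expect_equal(m$proline_pct, 100 * pr / seg$d2_length)
  expect_equal(h, 44)
  expect_equal(pr, 17)
})

test_that("state percentages over domain II sum to 100", {
  g <- generate_profile(protein_length = 280, helix_count = 30,
                        proline_count = 10, seed = 5)
  seg <- segment_domains(g$profile)
  d2 <- substring(g$profile$states, seg$domain2[1], seg$domain2[2])
  n <- nchar(d2)
  pct <- vapply(c("H", "E", "C"), function(s)
    100 * lengths(regmatches(d2, gregexpr(s, d2))) / n, numeric(1))
  expect_equal(sum(pct), 100)
  m <- composition_metrics(g$profile, g$sequence, seg$domain2)
  expect_equal(m$helix_pct, pct[["H"]])
})

test_that("composition classes follow the ratio/floor rule", {
  expect_equal(classify_composition(60, 5), "alpha_dominant")
  expect_equal(classify_composition(5, 30), "proline_dominant")
  expect_equal(classify_composition(4, 4), "disordered")
  expect_equal(classify_composition(30, 20), "mixed")
  expect_equal(classify_composition(20, 10), "alpha_dominant")  # exactly r.p
  expect_true(is.na(classify_composition(NA, 5)))
})

test_that("PPII summary is the fraction of domain II residues above cutoff", {
  expect_equal(ppii_summary(rep(1, 100), c(11, 60)), 1)
  expect_equal(ppii_summary(rep(0, 100), c(11, 60)), 0)
  expect_equal(ppii_summary(rep(c(0.6, 0.4), 50), c(1, 100)), 0.5)
  expect_true(is.na(ppii_summary(NULL, c(1, 10))))
  expect_true(is.na(ppii_summary(rep(1, 100), c(11, 10))))
})

test_that("lipoprotein classification: passthrough beats heuristic; lipobox needs Cys", {
  expect_equal(classify_lipoprotein("lipoprotein", "AAAA"), "lipoprotein")
  expect_equal(classify_lipoprotein("sec_signal"), "sec_signal")
  seq_lipo <- paste0("MKKLLIAGTTA", "LLAGC", strrep("A", 100))  # Cys at 16
  expect_equal(classify_lipoprotein(NULL, seq_lipo), "lipoprotein")
  expect_equal(classify_lipoprotein(NULL, strrep("A", 100)), "none")
  # lipobox too late in the sequence does not count
  late <- paste0(strrep("A", 60), "LAGC", strrep("A", 40))
  expect_equal(classify_lipoprotein(NULL, late), "none")
  expect_error(classify_lipoprotein("garbled"), "unknown signal_call")
})

test_that("transducers without a TMH are emitted flagged with empty spans", {
  p <- ss_profile("x", strrep("C", 300))
  row <- analyze_transducer(p, strrep("A", 300))
  expect_true(row$flagged)
  expect_true(is.na(row$d2_start))
  expect_true(is.na(row$helix_pct))
})
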