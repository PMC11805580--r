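test_that("direction, membrane and reaction primitives follow the tie conventions", {
  expect_equal(ratio_direction(1.0, 1.1), "I")
  expect_equal(ratio_direction(1.1, 1.0), "D")
  expect_equal(ratio_direction(1.0, 1.0), "I")     # remains-equal counts as I
  expect_error(ratio_direction(NaN, 1), "NaN")
  expect_equal(membrane_state(0.5), "IN")
  expect_equal(membrane_state(1.5), "EX")
  expect_equal(membrane_state(1.0), "EQ")
  expect_equal(reaction_state(1.0, 1.2, 2600), "AS")
  expect_equal(reaction_state(1.2, 1.0, 2600), "DIS")
  expect_equal(reaction_state(1.0, 1.0, 2600), "AS")  # tie follows <=
  expect_equal(reaction_state(2600, 2600, 2600), "SATURATED")
})

test_that("classification reproduces the canonical scenario outcomes", {
  s <- classify_rtm("I", "D", "D", "AS", "IN")
  expect_equal(s$kind, "RELATION")
  expect_equal(s$relation, "(IN>=AS)&(IN<=ECT+)")
  expect_equal(classify_rtm("I", "D", "D", "DIS", "IN")$kind, "TAUTOLOGY")
  expect_equal(classify_rtm("I", "I", "D", "AS", "EX")$kind, "CONTRADICTION")
  s2 <- classify_rtm("D", "I", "I", "AS", "IN", c1_dir = "D")
  expect_equal(s2$relation, "IN<=AS")
  s3 <- classify_rtm("I", "I", "I", "AS", "IN", c1_dir = "I")
  expect_equal(s3$relation, "IN>=AS")
  s4 <- classify_rtm("I", "I", "I", "AS", "IN")
  expect_equal(s4$relation, "(IN>=AS)|(IN>=ECT+)")
})

test_that("classification is total and saturation reroutes to the no-association branch", {
  dirs <- c("I", "D")
  for (d21 in dirs) for (d31 in dirs) for (d32 in dirs) {
    for (reac in c("AS", "DIS", "SATURATED")) {
      for (memb in c("IN", "EX", "EQ")) {
        st <- classify_rtm(d21, d31, d32, reac, memb)
        expect_true(st$kind %in% c("RELATION", "TAUTOLOGY", "CONTRADICTION"))
        if (st$kind == "RELATION") expect_false(is.na(st$relation))
        if (reac == "SATURATED") {
          twin <- classify_rtm(d21, d31, d32, "DIS", memb)
          expect_equal(st$kind, twin$kind)
          expect_equal(st$relation, twin$relation)
          expect_true(st$saturated)
        }
      }
    }
  }
})

test_that("mutually exclusive mechanisms never co-occur in a statement", {
  dirs <- c("I", "D")
  for (d21 in dirs) for (d31 in dirs) for (d32 in dirs) {
    for (reac in c("AS", "DIS")) for (memb in c("IN", "EX")) {
      st <- classify_rtm(d21, d31, d32, reac, memb)
      if (st$kind == "RELATION") {
        if (memb == "IN") expect_false(grepl("EX", st$relation, fixed = TRUE))
        if (memb == "EX") {
          expect_false(grepl("IN", st$relation, fixed = TRUE))
        }
        if (reac == "AS") expect_false(grepl("DIS", st$relation, fixed = TRUE))
      }
    }
  }
})

test_that("C1-direction refinements only ever narrow the truth set", {
  dirs <- c("I", "D")
  for (d21 in dirs) for (d31 in dirs) for (d32 in dirs) {
    for (reac in c("AS", "DIS")) for (memb in c("IN", "EX", "EQ")) {
      base <- rtm_truth_sets(d21, d31, d32, reac, memb)
      base_keys <- vapply(base$satisfying, tumorcord:::asn_key, "")
      for (cd in c("I", "D")) {
        ref <- rtm_truth_sets(d21, d31, d32, reac, memb, c1_dir = cd)
        ref_keys <- vapply(ref$satisfying, tumorcord:::asn_key, "")
        expect_true(all(ref_keys %in% base_keys))
      }
    }
  }
})

test_that("a trajectory map classifies every point and handles degenerate input", {
  traj <- smoke_mpk_traj()
  map <- rtm_map(traj)
  n_pts <- length(traj$snapshots[[2]]$r) * length(traj$snapshots[[2]]$z)
  expect_equal(nrow(map), n_pts * (length(traj$snapshots) - 1))
  # the first interval starts from the all-zero state: ratios undefined there
  first <- dplyr::filter(map, map$t_start_h == 0)
  expect_true(all(first$kind == "UNDEFINED"))
  later <- dplyr::filter(map, map$t_start_h > 0)
  expect_true(all(later$kind %in%
    c("RELATION", "TAUTOLOGY", "CONTRADICTION", "TRANSITION")))
  # legend covers every emitted code
  leg <- rtm_legend(map)
  expect_setequal(unique(map$code), leg$code)
  # constant (frozen) trajectory: ties classify without error
  frozen <- traj
  frozen$snapshots <- lapply(frozen$snapshots, function(s) {
    s$C1[] <- 1; s$C2[] <- 0.5; s$C3[] <- 10; s
  })
  mf <- rtm_map(frozen)
  expect_true(all(mf$code == "III.AS.IN"))
  expect_true(all(mf$kind != "UNDEFINED"))
})

test_that("endpoint-agreement mode tags membrane flips as transitions", {
  traj <- smoke_mpk_traj()
  map <- rtm_map(traj, membrane_at = "both")
  # the MPK run flips from internalization to externalization early on
  expect_true(any(map$kind == "TRANSITION"))
  tr <- dplyr::filter(map, map$kind == "TRANSITION")
  expect_true(all(grepl(">", tr$code)))
  expect_true(all(grepl(" to ", tr$relation)))
})
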