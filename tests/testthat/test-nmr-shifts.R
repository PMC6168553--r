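test_that("secondary shifts subtract random-coil values per atom", {
  rc <- read_random_coil_table()
  tab <- make_shift_tables("AQGLV")$solution   # base = random coil
  ss <- secondary_shifts(tab, rc)
  expect_true(all(ss$d_ca == 0))
  expect_true(all(is.na(ss$d_cb[ss$aa == "G"])))
  expect_true(all(ss$d_cb[ss$aa != "G"] == 0))

  # a planted helical stretch of +2.5 on CA is recovered exactly
  helical <- tab
  helical$shift_ppm[helical$atom == "CA"] <-
    helical$shift_ppm[helical$atom == "CA"] + 2.5
  ss2 <- secondary_shifts(shift_table(helical), rc)
  expect_equal(ss2$d_ca, rep(2.5, 5))
  # sign convention switch flips, never rescales
  ss3 <- secondary_shifts(shift_table(helical), rc,
                          convention = "rc_minus_obs")
  expect_equal(ss3$d_ca, rep(-2.5, 5))

  bad <- data.frame(resno = 1, aa = "X", atom = "CA", shift_ppm = 50)
  expect_error(secondary_shifts(shift_table(bad), rc), "absent")
})

test_that("state perturbation sums |dCA| + |dCB| and flags at threshold", {
  tabs <- make_shift_tables("AQLVTE")
  same <- state_perturbation(tabs$solution, tabs$solid)
  expect_true(all(same$perturbation$sum_ppm == 0))
  expect_false(any(same$perturbation$flag))

  tabs2 <- make_shift_tables("AQLVTE", perturbed = list(`3` = c(1.0, 0.5)))
  p <- state_perturbation(tabs2$solution, tabs2$solid, threshold = 1.2)
  expect_equal(p$perturbation$sum_ppm[p$perturbation$resno == 3], 1.5)
  expect_identical(p$perturbation$resno[p$perturbation$flag], 3L)

  # symmetric in the two states
  p_rev <- state_perturbation(tabs2$solid, tabs2$solution, threshold = 1.2)
  expect_equal(p_rev$perturbation$sum_ppm, p$perturbation$sum_ppm)

  # monotone in threshold
  p_lo <- state_perturbation(tabs2$solution, tabs2$solid, threshold = 0.5)
  expect_true(all(p$perturbation$flag <= p_lo$perturbation$flag))

  # residues present in only one table are unassessed
  solid_cut <- tabs2$solid[tabs2$solid$resno != 6, ]
  p_cut <- state_perturbation(tabs2$solution, shift_table(solid_cut))
  expect_identical(p_cut$unassessed, 6L)
})

test_that("planted perturbations >= 1.2 ppm are recovered exactly at sigma 0.05", {
  seq60 <- paste(rep(c("A", "Q", "L", "V", "T", "E"), 10), collapse = "")
  planted <- list(`7` = c(1.0, 0.6), `15` = c(-1.4, 0.2), `23` = c(0.8, 0.7),
                  `38` = c(2.0, 0.3), `51` = c(-0.9, -0.5))
  tabs <- make_shift_tables(seq60, perturbed = planted, noise_sigma = 0.05,
                            seed = 101)
  p <- state_perturbation(tabs$solution, tabs$solid, threshold = 1.2)
  flagged <- p$perturbation$resno[p$perturbation$flag]
  expect_setequal(flagged, c(7L, 15L, 23L, 38L, 51L))
})

test_that("perturbation equals the difference of secondary-shift profiles", {
  rc <- read_random_coil_table()
  tabs <- make_shift_tables("AQLVTE", perturbed = list(`2` = c(0.7, -0.4)))
  ss_sol <- secondary_shifts(tabs$solution, rc)
  ss_sol_d <- secondary_shifts(tabs$solid, rc)
  # random-coil terms cancel in the difference
  d_ca <- abs(ss_sol_d$d_ca - ss_sol$d_ca)
  d_cb <- abs(ss_sol_d$d_cb - ss_sol$d_cb)
  total <- d_ca + ifelse(is.na(d_cb), 0, d_cb)
  p <- state_perturbation(tabs$solution, tabs$solid)
  expect_equal(p$perturbation$sum_ppm, total, tolerance = 1e-12)
})

test_that("signal accounting reproduces the narrated counting pattern", {
  # construct: ordered core with 9 L / 6 T / 5 V / 1 P, disordered tail
  # holding the other 5 L / 2 V / 3 P
  core <- c(rep(c("L", "T", "A"), 6), rep(c("L", "V", "A"), 3),
            rep("V", 2), "P")
  tail <- c(rep(c("L", "A"), 5), "V", "V", rep("P", 3))
  seqv <- c(core, tail)
  assigned <- seq_along(core)   # the tail is never assigned
  acc <- signal_accounting(assigned, seqv)
  got <- acc[match(c("L", "T", "V", "P"), acc$aa), c("observed", "expected")]
  expect_equal(unname(as.matrix(got)),
               matrix(c(9, 14, 6, 6, 5, 7, 1, 4), 4, 2, byrow = TRUE))
  # missing positions all lie in the tail
  missing <- as.integer(unlist(strsplit(acc$missing, ",")))
  expect_true(all(missing > length(core)))

  all_assigned <- signal_accounting(seq_along(seqv), seqv)
  expect_equal(all_assigned$observed, all_assigned$expected)
  none <- signal_accounting(integer(0), seqv)
  expect_true(all(none$observed == 0))
  expect_error(signal_accounting(999, seqv), "outside sequence")
})

test_that("shift tables round-trip through TSV and NMR-STAR subset", {
  tab <- make_shift_tables("AQLV", first_resno = 441L)$solution
  tsv <- tempfile(fileext = ".tsv")
  write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_shift_table(tsv)
  expect_equal(back$shift_ppm, tab$shift_ppm)

  star <- tempfile(fileext = ".str")
  aa3 <- c(A = "ALA", Q = "GLN", L = "LEU", V = "VAL")
  writeLines(c(
    "loop_",
    "  _Atom_chem_shift.Comp_index_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    sprintf("  %d %s %s %.3f", tab$resno, aa3[tab$aa], tab$atom,
            tab$shift_ppm),
    "stop_"), star)
  back2 <- read_nmr_star(star)
  expect_equal(back2$resno, tab$resno)
  expect_equal(back2$shift_ppm, tab$shift_ppm, tolerance = 1e-3)
})
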