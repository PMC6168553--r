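test_that("subunit contacts match the all-pairs brute-force oracle", {
  sym <- helical_symmetry(-90, 5)
  asm <- build_filament(toy_contact_monomer(), sym, c(0, 4))
  got <- subunit_contacts(asm, cutoff = 4, max_offset = 3)
  want <- brute_contacts(asm, cutoff = 4, max_offset = 3)
  expect_identical(nrow(got), nrow(want))
  expect_equal(got$dist, want$dist, tolerance = 1e-9)
  expect_identical(got$resno_i, want$resno_i)
  expect_identical(got$resno_j, want$resno_j)

  # the planted pair: residue 2 of subunit k+1 sits 2 A from residue 1
  expect_true(any(got$offset == 1 & got$resno_i == 1 & got$resno_j == 2 &
                    abs(got$dist - 2) < 1e-9))

  # richer assembly, exact set equality against brute force
  asm2 <- build_filament(toy_shell_monomer(30), helical_symmetry(-101.124, 4.848),
                         c(0, 5))
  got2 <- subunit_contacts(asm2, cutoff = 6, max_offset = 4)
  want2 <- brute_contacts(asm2, cutoff = 6, max_offset = 4)
  if (is.null(want2)) {
    expect_identical(nrow(got2), 0L)
  } else {
    expect_identical(nrow(got2), nrow(want2))
    expect_equal(got2$dist, want2$dist, tolerance = 1e-9)
  }

  # distant atoms give no contacts
  far <- fil_structure(data.frame(
    elety = "CA", resid = "ALA", chain = "A", resno = 1,
    x = 10, y = 0, z = 0, element = "C"))
  asm3 <- build_filament(far, helical_symmetry(-90, 10), c(0, 1))
  expect_identical(nrow(subunit_contacts(asm3, 4, 1)), 0L)
  expect_error(subunit_contacts(asm3, 4, max_offset = 5), "need >=")
})

test_that("contacts are identical between any subunit pair at one offset", {
  sym <- helical_symmetry(-101.124, 4.848)
  asm <- build_filament(toy_shell_monomer(30), sym, c(0, 8))
  a <- asm$atoms
  ref <- subunit_contacts(asm, 6, 3)
  for (m in 1:3) {
    shifted <- asm
    shifted$atoms <- a[a$subunit >= m, ]
    shifted$atoms$subunit <- shifted$atoms$subunit - m
    got <- subunit_contacts(shifted, 6, 3)
    expect_identical(nrow(got), nrow(ref))
    expect_equal(got$dist, ref$dist, tolerance = 1e-6)
  }
})

test_that("offset classification recovers planted interface types", {
  ann <- structure(list(
    list(type = "I", surface_a = c(1, 2), surface_b = c(11, 12), pairs = list()),
    list(type = "II", surface_a = 3, surface_b = c(13, 14), pairs = list()),
    list(type = "III", surface_a = c(4, 5), surface_b = 15, pairs = list())),
    class = "interface_annotations")

  contacts <- data.frame(
    offset = c(1, 1, 2, 3, 3),
    resno_i = c(1, 2, 3, 4, 5), elety_i = "CA", resid_i = "ALA",
    resno_j = c(11, 12, 13, 15, 15), elety_j = "CA", resid_j = "ALA",
    dist = 3.5)
  cls <- classify_offsets(contacts, ann)
  expect_identical(cls$type, c("I", "II", "III"))
  expect_equal(cls$score[1], 1.0)
  expect_true(all(cls$score >= 0 & cls$score <= 1))

  # classification is stable under row permutation
  set.seed(3)
  cls2 <- classify_offsets(contacts[sample(nrow(contacts)), ], ann)
  expect_equal(cls2[order(cls2$offset), ], cls[order(cls$offset), ],
               ignore_attr = TRUE)

  # matching in the swapped orientation still scores
  swapped <- contacts[1:2, ]
  swapped[, c("resno_i", "resno_j")] <- swapped[, c("resno_j", "resno_i")]
  cls3 <- classify_offsets(swapped, ann)
  expect_identical(cls3$type, "I")
  expect_equal(cls3$score, 1.0)
})

test_that("interface report flags annotated pairs and salt bridges", {
  # planted salt bridge: ARG NH1 (res 1) near GLU OE1 (res 2) of next subunit
  mono <- fil_structure(data.frame(
    elety = c("NH1", "OE1"), resid = c("ARG", "GLU"), chain = "A",
    resno = c(1, 2),
    x = c(10, 10 * cos(pi / 2)), y = c(0, 10 * sin(pi / 2)),
    z = c(0, -1.8), element = c("N", "O")))
  asm <- build_filament(mono, helical_symmetry(-90, 5), c(0, 4))
  ann <- structure(list(
    list(type = "I", surface_a = 1, surface_b = 2, pairs = list(c(1, 2)))),
    class = "interface_annotations")
  rep <- interface_report(asm, ann, cutoff = 4)
  expect_true(rep$pairs$found[1])
  expect_equal(rep$pairs$min_dist[1], 3.2, tolerance = 1e-9)
  expect_true(nrow(rep$salt_bridges) >= 1)
  expect_true(any(rep$salt_bridges$elety_i == "NH1" &
                    rep$salt_bridges$elety_j == "OE1"))

  # a pair out of reach is reported not-found with its actual distance
  ann2 <- structure(list(
    list(type = "I", surface_a = 1, surface_b = 2,
         pairs = list(c(1, 2), c(2, 2)))),
    class = "interface_annotations")
  rep2 <- interface_report(asm, ann2, cutoff = 2)
  expect_false(rep2$pairs$found[1])
  expect_equal(rep2$pairs$min_dist[1], 3.2, tolerance = 1e-9)

  # annotations outside the modelled range are rejected
  ann3 <- structure(list(
    list(type = "I", surface_a = 99, surface_b = 2, pairs = list())),
    class = "interface_annotations")
  expect_error(interface_report(asm, ann3), "outside the modelled range")
})

test_that("mutation burial counts equal brute-force enumeration", {
  sym <- helical_symmetry(-90, 5)
  asm <- build_filament(toy_contact_monomer(), sym, c(0, 4))
  burial <- mutation_burial(asm, c(1, 2, 3), cutoff = 4, max_offset = 3)
  bf <- brute_contacts(asm, 4, 3)
  for (r in 1:3) {
    want <- sum(bf$resno_i == r | bf$resno_j == r)
    expect_identical(burial$n_contacts[burial$resno == r], want)
  }
  expect_identical(burial$n_contacts[burial$resno == 3], 0L)
  expect_error(mutation_burial(asm, 42), "not in model")
})

test_that("the curated annotation file is valid and covers all three types", {
  ann <- read_interface_annotations()
  expect_setequal(vapply(ann, `[[`, "", "type"), c("I", "II", "III"))
  res <- unlist(lapply(ann, function(a)
    c(a$surface_a, a$surface_b, unlist(a$pairs))))
  expect_true(all(res >= 433 & res <= 518))
  # the flagship interactions are annotated as pairs
  all_pairs <- do.call(rbind, lapply(ann, function(a)
    cbind(type = a$type, do.call(rbind, a$pairs))))
  expect_true(any(all_pairs[, 2] == 444 & all_pairs[, 3] == 461))
  expect_true(any(all_pairs[, 2] == 470 & all_pairs[, 3] == 455))
  expect_true(any(all_pairs[, 2] == 472 & all_pairs[, 3] == 488))
})

test_that("burial report covers the mutated type II surface residues", {
  # the eight positions probed by mutagenesis, all within the modelled range
  mutated <- c(470, 497, 450, 452, 453, 455, 458, 512)
  mono <- toy_shell_monomer(n = 90)
  mono$atoms$resno <- 430 + seq_len(90)
  asm <- build_filament(mono, helical_symmetry(-101.124, 4.848), c(0, 4))
  burial <- mutation_burial(asm, mutated, cutoff = 8, max_offset = 4)
  expect_identical(burial$resno, mutated)
  expect_true(all(burial$n_contacts >= 0))
})
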