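# Standard / fp matrix assembly, two-body matrices, cooperativity.

# assemble a campaign's matrices straight from ground-truth records
assemble_gt <- function(gt, bsse = FALSE) {
  specs <- enumerate_campaign(gt$geometry, gt$subsystems, list(gt$setting),
                              bsse = bsse)
  roles <- vapply(specs, `[[`, "", "role")
  recs <- lapply(specs, truth_record, gt = gt)
  list(super = recs[roles == "supersystem"][[1]],
       parts = recs[roles == "subsystem"],
       pairs = recs[roles == "pair"],
       monomers = recs[roles == "monomer"],
       specs = specs)
}

test_that("interaction energy is the supersystem-minus-parts difference", {
  a <- two_fragment_record()
  b <- two_fragment_record()
  b$total_energy <- a$total_energy / 2
  b2 <- b
  # null interaction
  null_parts <- list(b, b)
  expect_equal(interaction_energy(a, null_parts), 0, tolerance = 1e-10)
  # unit conversion: -0.05 Eh difference
  s <- a; s$total_energy <- -200.05
  p1 <- a; p1$total_energy <- -100.00
  p2 <- a; p2$total_energy <- -100.00
  expect_equal(interaction_energy(s, list(p1, p2)), -0.05 * 627.5094740631,
               tolerance = 1e-9)
  # symmetric under part order
  expect_equal(interaction_energy(s, list(p2, p1)),
               interaction_energy(s, list(p1, p2)))
})

test_that("standard N-body assembly recovers planted terms and conserves", {
  for (bsse in c(FALSE, TRUE)) {
    gt <- generate_ground_truth(2, c(3, 3), seed = 31, solvation = FALSE)
    cam <- assemble_gt(gt, bsse)
    std <- assemble_standard_nbody(cam$super, cam$parts, gt$subsystems)
    want <- expected_matrix_set(gt, bsse = bsse, body_order = "nbody")
    for (cc in names(want$components)) {
      expect_equal(std$components[[cc]], want$components[[cc]],
                   tolerance = 1e-8, info = cc)
    }
    # grand total equals the interaction energy (conservation)
    expect_equal(matrix_grand_total(std),
                 interaction_energy(cam$super, cam$parts), tolerance = 1e-6)
    # elprep strictly diagonal in the standard layout
    off <- std$components$elprep
    diag(off) <- 0
    expect_true(all(off == 0))
    # same-strand differential cells exist only inside subsystem blocks
    expect_equal(sum(std$components$elstat[1:3, 4:6] == 0), 0)
  }
})

test_that("a supersystem identical to its parts yields a zero matrix", {
  gt <- generate_ground_truth(2, c(2, 1), seed = 8)
  gt$elprep$ref[] <- 0; gt$elprep$corr[] <- 0
  for (cc in c("elstat", "exch", "no_disp", "disp")) {
    gt$eps_diff[[cc]][] <- 0
    sel <- ledkit:::gt_sub_of(gt)[gt$eps_super$f1] !=
      ledkit:::gt_sub_of(gt)[gt$eps_super$f2]
    gt$eps_super[[cc]][sel] <- 0
  }
  cam <- assemble_gt(gt)
  std <- assemble_standard_nbody(cam$super, cam$parts, gt$subsystems)
  expect_equal(max(abs(std$components$total)), 0, tolerance = 1e-10)
  expect_equal(interaction_energy(cam$super, cam$parts), 0, tolerance = 1e-9)
})

test_that("fp redistribution conserves elprep exactly for every scheme", {
  gt <- generate_ground_truth(2, c(3, 2), seed = 17)
  cam <- assemble_gt(gt)
  std <- assemble_standard_nbody(cam$super, cam$parts, gt$subsystems)
  for (scheme in c("equal", "prop_eps")) {
    fp <- assemble_fp_nbody(std, scheme)
    # pairwise elprep sums to the diagonal it replaced, exactly
    expect_equal(sum(fp$components$elprep[upper.tri(fp$components$elprep)]),
                 sum(diag(std$components$elprep)), tolerance = 1e-12)
    expect_equal(diag(fp$components$elprep), rep(0, 5),
                 ignore_attr = TRUE)
    # epsilon components identical between layouts
    for (cc in c("elstat", "exch", "no_disp", "disp")) {
      expect_equal(fp$components[[cc]], std$components[[cc]])
    }
    # grand totals agree with the standard layout and the interaction energy
    expect_equal(matrix_grand_total(fp), matrix_grand_total(std),
                 tolerance = 1e-9)
    # component closure cellwise off the diagonal
    closure <- fp$components$elprep + fp$components$elstat +
      fp$components$exch + fp$components$no_disp + fp$components$disp
    diag(closure) <- 0
    expect_equal(closure, fp$components$total, tolerance = 1e-10)
  }
})

test_that("fp equal-split arithmetic matches the hand-computed 3-fragment case", {
  # elprep diagonal (3, 3, 3): each pair receives 1 + 1 + 1 = 3? No:
  # each fragment splits 3 over its 2 partners (1.5 each); a pair cell is the
  # two members' shares: 1.5 + 1.5 = 3; the three pair cells sum to 9.
  std <- ledkit:::new_matrix_set(
    "standard",
    list(total = diag(c(3, 3, 3)), elprep = diag(c(3, 3, 3)),
         elprep_ref = diag(c(3, 3, 3)), elprep_corr = diag(c(0, 0, 0)),
         elstat = matrix(0, 3, 3), exch = matrix(0, 3, 3),
         no_disp = matrix(0, 3, 3), disp = matrix(0, 3, 3)),
    fragment_labels = 1:3, subsystem_of = c(1, 2, 3),
    bsse_corrected = FALSE, body_order = "nbody",
    absent = matrix(FALSE, 3, 3))
  fp <- assemble_fp_nbody(std, "equal")
  off <- fp$components$elprep[upper.tri(fp$components$elprep)]
  expect_equal(off, rep(3, 3), ignore_attr = TRUE)
  expect_equal(sum(off), 9)

  # 2-fragment system: the single off-diagonal cell carries the whole diagonal
  # sum under any scheme (forced by conservation)
  std2 <- ledkit:::new_matrix_set(
    "standard",
    list(total = diag(c(2, 5)), elprep = diag(c(2, 5)),
         elprep_ref = diag(c(2, 5)), elprep_corr = diag(c(0, 0)),
         elstat = matrix(0, 2, 2), exch = matrix(0, 2, 2),
         no_disp = matrix(0, 2, 2), disp = matrix(0, 2, 2)),
    fragment_labels = 1:2, subsystem_of = c(1, 2),
    bsse_corrected = FALSE, body_order = "nbody",
    absent = matrix(FALSE, 2, 2))
  for (scheme in c("equal", "prop_eps")) {
    fp2 <- assemble_fp_nbody(std2, scheme)
    expect_equal(fp2$components$elprep[1, 2], 7)
  }
})

test_that("prop_eps weights follow epsilon magnitudes with equal fallback", {
  eps <- matrix(0, 3, 3)
  eps[1, 2] <- eps[2, 1] <- -4
  eps[1, 3] <- eps[3, 1] <- 0     # zero-magnitude partner for fragment 1
  eps[2, 3] <- eps[3, 2] <- -1
  std <- ledkit:::new_matrix_set(
    "standard",
    list(total = diag(c(6, 0, 0)) + eps, elprep = diag(c(6, 0, 0)),
         elprep_ref = diag(c(6, 0, 0)), elprep_corr = diag(c(0, 0, 0)),
         elstat = eps, exch = matrix(0, 3, 3),
         no_disp = matrix(0, 3, 3), disp = matrix(0, 3, 3)),
    fragment_labels = 1:3, subsystem_of = c(1, 2, 3),
    bsse_corrected = FALSE, body_order = "nbody",
    absent = matrix(FALSE, 3, 3))
  fp <- assemble_fp_nbody(std, "prop_eps")
  # fragment 1's elprep (6) goes entirely to partner 2 (|eps| 4 vs 0)
  expect_equal(fp$components$elprep[1, 2], 6)
  expect_equal(fp$components$elprep[1, 3], 0)
  expect_equal(sum(fp$components$elprep[upper.tri(eps)]), 6, tolerance = 1e-12)
})

test_that("two-body assembly fills spanning cells and flags the rest absent", {
  gt <- generate_ground_truth(2, c(3, 3), seed = 53)
  for (bsse in c(FALSE, TRUE)) {
    cam <- assemble_gt(gt, bsse)
    tb <- assemble_twobody(cam$pairs, cam$monomers, gt$subsystems,
                           bsse = bsse, layout = "standard",
                           reference = cam$super)
    want <- expected_matrix_set(gt, bsse = bsse, body_order = "twobody")
    for (cc in names(want$components)) {
      expect_equal(tb$components[[cc]], want$components[[cc]],
                   tolerance = 1e-8, info = cc)
    }
    up <- upper.tri(tb$absent)
    expect_equal(sum(!tb$absent[up]), 9)   # populated interstrand cells
    expect_equal(sum(tb$absent[up]), 6)    # absent same-strand cells
  }
  # missing pair record is reported with the pair
  expect_error(assemble_twobody(list(), list(), gt$subsystems),
               "completeness error")
  cam <- assemble_gt(gt)
  expect_error(assemble_twobody(cam$pairs[-1], cam$monomers, gt$subsystems,
                                reference = cam$super),
               "missing pair record")
})

test_that("N-body and two-body assemblies coincide for two-fragment systems", {
  gt <- generate_ground_truth(2, c(1, 1), seed = 42)
  # make the isolated-pair records numerically identical to the N-body ones:
  # with one fragment per subsystem the pair IS the supersystem and the
  # monomers ARE the subsystems
  gt$coop[c("elstat", "exch", "no_disp", "disp")] <-
    lapply(gt$eps_diff[c("elstat", "exch", "no_disp", "disp")], function(x) 0)
  gt$pair_prep$ref1 <- gt$w$ref[1] + gt$elprep$ref[1]
  gt$pair_prep$corr1 <- gt$w$corr[1] + gt$elprep$corr[1]
  gt$pair_prep$ref2 <- gt$w$ref[2] + gt$elprep$ref[2]
  gt$pair_prep$corr2 <- gt$w$corr[2] + gt$elprep$corr[2]
  for (cc in c("elstat", "exch", "no_disp", "disp")) gt$coop[[cc]][] <- 0
  for (bsse in c(FALSE, TRUE)) {
    cam <- assemble_gt(gt, bsse)
    nb <- assemble_standard_nbody(cam$super, cam$parts, gt$subsystems)
    tb <- assemble_twobody(cam$pairs, cam$monomers, gt$subsystems,
                           bsse = bsse, layout = "standard",
                           reference = cam$super)
    for (cc in names(nb$components)) {
      expect_equal(tb$components[[cc]], nb$components[[cc]],
                   tolerance = 1e-8, info = cc)
    }
    co <- cooperativity(nb, tb)
    expect_equal(max(abs(co$components$total)), 0, tolerance = 1e-7)
  }
})

test_that("cooperativity subtracts cellwise and flags fully cooperative cells", {
  gt <- generate_ground_truth(2, c(2, 2), seed = 61)
  cam <- assemble_gt(gt)
  nb <- assemble_standard_nbody(cam$super, cam$parts, gt$subsystems)
  tb <- assemble_twobody(cam$pairs, cam$monomers, gt$subsystems,
                         layout = "standard", reference = cam$super)
  co <- cooperativity(nb, tb)
  # where two-body exists: plain subtraction
  expect_equal(co$components$elstat[1, 3],
               nb$components$elstat[1, 3] - tb$components$elstat[1, 3])
  # same-subsystem cells have no two-body counterpart: N-body value, flagged
  expect_true(co$fully_coop[1, 2])
  expect_equal(co$components$total[1, 2], nb$components$total[1, 2])
  # self-subtraction is identically zero
  zero <- cooperativity(nb, nb)
  expect_equal(max(abs(zero$components$total)), 0)
  # trivial arithmetic
  expect_equal(-5 - (-3.5), -1.5)
  # label mismatch is an alignment error
  gt3 <- generate_ground_truth(2, c(2, 1), seed = 62)
  cam3 <- assemble_gt(gt3)
  nb3 <- assemble_standard_nbody(cam3$super, cam3$parts, gt3$subsystems)
  expect_error(cooperativity(nb, nb3), "alignment error")
})

test_that("HFLD-filtered records assemble with zero no_disp and ref-only elprep", {
  gt <- generate_ground_truth(2, c(2, 1), seed = 77,
                              setting = calc_setting("h", method = "HFLD"))
  cam <- assemble_gt(gt)
  recs <- lapply(c(list(cam$super), cam$parts), exclude_redundant_hfld)
  std <- assemble_standard_nbody(recs[[1]], recs[-1], gt$subsystems)
  expect_equal(max(abs(std$components$no_disp)), 0)
  expect_equal(max(abs(std$components$elprep_corr)), 0)
  expect_equal(std$components$elprep, std$components$elprep_ref)
})
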