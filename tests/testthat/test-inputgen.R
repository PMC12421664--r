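# Enumeration of N-body / two-body calculation campaigns and input rendering.

make_system <- function(f, seed = 5) {
  gt <- generate_ground_truth(length(f), f, seed = seed)
  list(geom = gt$geometry, subs = gt$subsystems, setting = gt$setting)
}

# independent oracle: count spanning pairs by direct double loop over the
# subsystem assignment
oracle_pair_count <- function(f) {
  sub_of <- rep(seq_along(f), f)
  n <- 0
  F <- sum(f)
  for (a in seq_len(F - 1)) for (b in seq(a + 1, F)) {
    if (sub_of[a] != sub_of[b]) n <- n + 1
  }
  n
}

test_that("N-body enumeration yields supersystem plus one spec per subsystem", {
  sys <- make_system(c(3, 3))
  specs <- enumerate_nbody(sys$geom, sys$subs, sys$setting, bsse = FALSE)
  expect_length(specs, 3)
  expect_equal(vapply(specs, `[[`, "", "role"),
               c("supersystem", "subsystem", "subsystem"))

  # degenerate single-subsystem partition still enumerates
  sys1 <- make_system(4)
  expect_length(enumerate_nbody(sys1$geom, sys1$subs, sys1$setting), 2)

  # corrected: each subsystem spec carries the others' fragments as ghosts
  sys3 <- make_system(c(2, 1, 2))
  sp <- enumerate_nbody(sys3$geom, sys3$subs, sys3$setting, bsse = TRUE)
  expect_length(sp, 4)
  for (k in 2:4) {
    expect_setequal(c(sp[[k]]$real_fragments, sp[[k]]$ghost_fragments), 1:5)
  }
  expect_error(enumerate_nbody(sys$geom, list(), sys$setting),
               "configuration error")
})

test_that("two-body enumeration matches the spanning-pair arithmetic", {
  sys <- make_system(c(3, 3))
  sp <- enumerate_twobody(sys$geom, sys$subs, sys$setting, bsse = FALSE)
  roles <- vapply(sp, `[[`, "", "role")
  expect_equal(sum(roles == "pair"), 9)        # 3 x 3 interstrand pairs
  expect_equal(sum(roles == "monomer"), 6)     # one per fragment

  sys32 <- make_system(c(3, 2))
  sp32 <- enumerate_twobody(sys32$geom, sys32$subs, sys32$setting)
  expect_equal(sum(vapply(sp32, `[[`, "", "role") == "pair"), 6)  # 3 x 2

  sys11 <- make_system(c(1, 1))
  for (bsse in c(FALSE, TRUE)) {
    sp11 <- enumerate_twobody(sys11$geom, sys11$subs, sys11$setting, bsse)
    r <- vapply(sp11, `[[`, "", "role")
    expect_equal(sum(r == "pair"), 1)
    expect_equal(sum(r == "monomer"), 2)
  }
  sys1 <- make_system(3)
  expect_error(enumerate_twobody(sys1$geom, sys1$subs, sys1$setting),
               "at least 2 subsystems")
})

test_that("corrected pair monomers are counterpoise mirror images", {
  sys <- make_system(c(2, 2))
  sp <- enumerate_twobody(sys$geom, sys$subs, sys$setting, bsse = TRUE)
  monos <- Filter(function(s) s$role == "monomer", sp)
  expect_length(monos, 8)   # 2 per pair, 4 pairs
  key <- vapply(monos, function(s)
    paste(sort(c(s$real_fragments, s$ghost_fragments)), collapse = "-"), "")
  for (k in unique(key)) {
    two <- monos[key == k]
    expect_length(two, 2)
    expect_equal(two[[1]]$real_fragments, two[[2]]$ghost_fragments)
    expect_equal(two[[1]]$ghost_fragments, two[[2]]$real_fragments)
  }
})

test_that("campaign totals reproduce the closed-form counts", {
  sys <- make_system(c(3, 3))
  one <- list(sys$setting)
  expect_length(enumerate_campaign(sys$geom, sys$subs, one, bsse = FALSE), 18)
  expect_length(enumerate_campaign(sys$geom, sys$subs, one, bsse = TRUE), 30)
  four <- lapply(1:4, function(k) calc_setting(paste0("S", k)))
  expect_length(enumerate_campaign(sys$geom, sys$subs, four, bsse = FALSE), 72)
  expect_length(enumerate_campaign(sys$geom, sys$subs, four, bsse = TRUE), 120)

  sys324 <- make_system(c(3, 2, 4))
  expect_length(enumerate_campaign(sys324$geom, sys324$subs, one, bsse = TRUE),
                1 + 3 + 3 * 26)

  expect_error(enumerate_campaign(sys$geom, sys$subs,
                                  list(sys$setting, sys$setting)),
               "duplicate setting labels")
})

test_that("closed-form counts match brute-force enumeration on random shapes", {
  set.seed(20)
  for (rep in 1:8) {
    S <- sample(2:4, 1)
    f <- sample(1:5, S, replace = TRUE)
    sys <- make_system(f, seed = 100 + rep)
    P <- oracle_pair_count(f)
    F <- sum(f)
    one <- list(sys$setting)
    n_un <- length(enumerate_campaign(sys$geom, sys$subs, one, bsse = FALSE))
    n_co <- length(enumerate_campaign(sys$geom, sys$subs, one, bsse = TRUE))
    expect_equal(n_un, 1 + S + P + F)
    expect_equal(n_co, 1 + S + 3 * P)
    # totals scale linearly in the number of settings
    two <- list(sys$setting, calc_setting("other"))
    expect_equal(length(enumerate_campaign(sys$geom, sys$subs, two,
                                           bsse = TRUE)), 2 * n_co)
    # filename uniqueness
    fn <- vapply(enumerate_campaign(sys$geom, sys$subs, two, bsse = TRUE),
                 `[[`, "", "filename")
    expect_equal(anyDuplicated(fn), 0)
  }
})

test_that("rendered inputs carry the right atoms, ghosts and fragment indices", {
  sys <- make_system(c(2, 2))
  atom_lines <- function(txt) {
    ln <- strsplit(txt, "\n")[[1]]
    grep("^  [A-Z][a-z]?:? *\\([0-9]+\\)", ln, value = TRUE)
  }

  # uncorrected monomer: only that fragment's atoms, no ghost markers
  sp <- enumerate_twobody(sys$geom, sys$subs, sys$setting, bsse = FALSE)
  mono <- Filter(function(s) s$role == "monomer", sp)[[1]]
  txt <- render_input(mono, sys$geom)
  al <- atom_lines(txt)
  expect_length(al, sum(sys$geom$fragment == mono$real_fragments))
  expect_false(any(grepl(":", al)))

  # corrected pair monomer: partner atoms ghost-marked, counts add up
  spc <- enumerate_twobody(sys$geom, sys$subs, sys$setting, bsse = TRUE)
  monoc <- Filter(function(s) s$role == "monomer", spc)[[1]]
  txtc <- render_input(monoc, sys$geom)
  alc <- atom_lines(txtc)
  n_real <- sum(sys$geom$fragment %in% monoc$real_fragments)
  n_ghost <- sum(sys$geom$fragment %in% monoc$ghost_fragments)
  expect_length(alc, n_real + n_ghost)
  expect_equal(sum(grepl("^  [A-Z][a-z]?:", alc)), n_ghost)
  # real fragments come first and indices are contiguous from 1
  idx <- as.integer(sub(".*\\((\\d+)\\).*", "\\1", alc))
  expect_equal(sort(unique(idx)), 1:2)
  expect_true(all(idx == cummax(idx)))

  # supersystem: as many distinct fragment indices as fragments
  super <- enumerate_nbody(sys$geom, sys$subs, sys$setting)[[1]]
  idx_s <- as.integer(sub(".*\\((\\d+)\\).*", "\\1",
                          atom_lines(render_input(super, sys$geom))))
  expect_equal(length(unique(idx_s)), n_fragments(sys$geom))

  # keyword line and LED directive present
  expect_match(txt, "! DLPNO-CCSD\\(T\\)")
  expect_match(txt, "LED 1")
  pno <- calc_setting("pno", tcutpno_exponent = 7)
  sp_pno <- enumerate_nbody(sys$geom, sys$subs, pno)[[1]]
  expect_match(render_input(sp_pno, sys$geom), "TCutPNO 1e-7")

  expect_error(render_input(
    ledkit:::new_calcspec("monomer", 99, integer(), sys$setting, FALSE, "x"),
    sys$geom), "consistency error")
})

test_that("written campaigns have one file per spec plus a manifest", {
  sys <- make_system(c(2, 1))
  dir <- withr::local_tempdir()
  specs <- enumerate_campaign(sys$geom, sys$subs, list(sys$setting),
                              bsse = TRUE)
  write_campaign(specs, sys$geom, dir)
  files <- list.files(dir)
  expect_true("manifest.csv" %in% files)
  expect_length(setdiff(files, "manifest.csv"), length(specs))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), length(specs))
  expect_setequal(unique(man$role),
                  c("supersystem", "subsystem", "pair", "monomer"))
})
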