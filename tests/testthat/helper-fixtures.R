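# Shared fixtures and independent oracles (kept free of the code paths they
# check).

# Union-find connected components: the brute-force oracle for fragment
# detection. Returns a partition label per vertex, renumbered by lowest
# member index.
union_find_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges$i[k]); b <- find(edges$j[k])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  first <- tapply(seq_len(n), roots, min)
  match(roots, as.integer(names(sort(first))))
}

# random geometry of n atoms in a box, elements drawn from light elements
random_geometry <- function(n, seed, box = 6) {
  set.seed(seed)
  geometry(sample(c("H", "C", "N", "O"), n, replace = TRUE),
           matrix(runif(3 * n, 0, box), ncol = 3))
}

# six rigid water molecules with O...O >= 2.7 A and O-H = 0.96 A
water_hexamer <- function() {
  unit <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  centers <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                   c(3, 3, 0), c(0, 0, 3), c(3, 0, 3))
  coords <- do.call(rbind, lapply(seq_len(6), function(k)
    sweep(unit, 2, centers[k, ], `+`)))
  geometry(rep(c("O", "H", "H"), 6), coords)
}

# parse every mock output of a campaign manifest into records split by role
read_campaign <- function(man) {
  list(super = parse_led_output(man$output[man$role == "supersystem"]),
       parts = lapply(man$output[man$role == "subsystem"], parse_led_output),
       pairs = lapply(man$output[man$role == "pair"], parse_led_output),
       monomers = lapply(man$output[man$role == "monomer"], parse_led_output))
}

# field-for-field record comparison at printed precision: energies printed at
# 12 decimals in Hartree, so equality is absolute, not relative
expect_abs_equal <- function(got, want, tol) {
  expect_equal(is.na(got), is.na(want))
  ok <- !is.na(want)
  if (any(ok)) expect_lt(max(abs(got[ok] - want[ok]), 0), tol)
  else succeed()
}

expect_record_equal <- function(got, want, tol = 1e-11) {
  expect_abs_equal(got$total_energy, want$total_energy, tol)
  expect_abs_equal(got$reference_energy, want$reference_energy, tol)
  expect_equal(got$ghost, want$ghost)
  expect_equal(unname(got$atoms$fragment), unname(want$atoms$fragment))
  expect_equal(got$atoms$element, want$atoms$element)
  expect_abs_equal(got$atoms$x, want$atoms$x, 1e-7)
  expect_equal(unname(got$intra$fragment), unname(want$intra$fragment))
  expect_abs_equal(got$intra$ref, want$intra$ref, tol)
  expect_abs_equal(got$intra$corr, want$intra$corr, tol)
  expect_equal(unname(got$pairwise$f1), unname(want$pairwise$f1))
  expect_equal(unname(got$pairwise$f2), unname(want$pairwise$f2))
  for (cc in c("elstat", "exch", "no_disp", "disp", "solv", "total")) {
    expect_abs_equal(got$pairwise[[cc]], want$pairwise[[cc]], tol)
  }
}

# small two-fragment record built by hand (energies in Hartree)
two_fragment_record <- function(elstat = -0.010, exch = -0.002,
                                no_disp = -0.001, disp = -0.003,
                                method = "DLPNO-CCSD(T)") {
  atoms <- data.frame(fragment = c(1L, 2L), element = c("He", "He"),
                      x = c(0, 3), y = 0, z = 0)
  intra <- data.frame(fragment = 1:2, ref = c(-2.9, -2.9),
                      corr = c(-0.04, -0.04))
  pw <- data.frame(f1 = 1L, f2 = 2L, elstat = elstat, exch = exch,
                   no_disp = no_disp, disp = disp, solv = NA_real_,
                   total = elstat + exch + no_disp + disp)
  led_record(atoms, ghost = c(FALSE, FALSE), intra = intra, pairwise = pw,
             total_energy = sum(intra$ref) + sum(intra$corr) + pw$total,
             reference_energy = sum(intra$ref) + elstat + exch,
             method = method)
}
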