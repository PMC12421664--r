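# Ground-truth generator: synthetic fragmented geometries plus
# component-resolved LED energies for every calculation context of a
# campaign, and a writer that serialises them as grammar-conforming mock
# output files. This makes every downstream stage testable without a
# quantum-chemistry engine. Energies are planted additively (supersystem
# terms = isolated terms + planted perturbations), so the standard-LED
# differences recover the planted quantities exactly and the acceptance
# surface is analytic. The energies are not physically realistic
# electronic-structure values, only realistically scaled.

#' Generate a ground-truth LED campaign
#'
#' Builds a reproducible synthetic system of `sum(f)` rigid water fragments
#' (O-H bond 0.96 Angstrom, units placed at least 2.5 Angstrom apart so
#' fragment detection separates them), grouped into `S` subsystems, together
#' with every planted energy needed to derive the LED record of any
#' calculation in the corresponding campaign:
#' \itemize{
#'   \item isolated monomer intra energies near -76 Eh (water-monomer scale),
#'   \item per-pair interfragment components drawn on the -30..+10 kcal/mol
#'     scale typical of strong noncovalent contacts (electrostatics dominant,
#'     exchange/dispersion attractive, non-dispersion small),
#'   \item positive electronic-preparation energies per fragment,
#'   \item counterpoise (ghost-basis) monomer stabilisations, so corrected
#'     monomer energies are below uncorrected ones,
#'   \item same-subsystem differential perturbations and spanning-pair
#'     cooperativity offsets on the ~1 kcal/mol scale.
#' }
#' Energy-conservation closure of the planted decomposition holds exactly by
#' construction.
#'
#' @param S number of subsystems (>= 1).
#' @param f integer vector of length `S`: fragments per subsystem (each >= 1).
#' @param seed integer random seed; the same seed reproduces the ground truth
#'   exactly.
#' @param setting a [calc_setting()] stamped into every derived record.
#' @param solvation include a solute-solvent interaction component?
#' @return Object of class `led_ground_truth`.
#' @export
generate_ground_truth <- function(S, f, seed = 1,
                                  setting = calc_setting("S1"),
                                  solvation = FALSE) {
  if (S < 1 || length(f) != S || any(f < 1)) {
    stop("configuration error: need S >= 1 subsystems and f_i >= 1 fragments",
         call. = FALSE)
  }
  F <- sum(f)
  set.seed(seed)

  # rigid water units on a jittered cubic grid, >= 2.5 A apart
  side <- ceiling(F^(1 / 3))
  idx <- 0:(F - 1)
  centers <- cbind(idx %% side, (idx %/% side) %% side, idx %/% side^2) * 3.2 +
    matrix(stats::runif(3 * F, -0.25, 0.25), ncol = 3)
  unit <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))  # O, H, H
  element <- rep(c("O", "H", "H"), F)
  coords <- do.call(rbind, lapply(seq_len(F), function(k)
    sweep(unit, 2, centers[k, ], `+`)))
  geom <- geometry(element, coords, fragment = rep(seq_len(F), each = 3),
                   comment = sprintf("ledkit synthetic water cluster seed=%d",
                                     seed))
  subsystems <- list()
  nxt <- 1L
  for (s in seq_len(S)) {
    subsystems[[s]] <- subsystem_spec(LETTERS[s], seq(nxt, nxt + f[s] - 1))
    nxt <- nxt + f[s]
  }
  sub_of <- subsystem_of_map(subsystems, F)

  kc <- 1 / HARTREE_TO_KCAL   # kcal/mol -> Eh
  pair_df <- function(span_only = FALSE, same_only = FALSE) {
    out <- list()
    for (a in seq_len(max(F - 1, 0))) for (b in seq(a + 1, F)) {
      span <- sub_of[a] != sub_of[b]
      if ((span_only && !span) || (same_only && span)) next
      out[[length(out) + 1]] <- c(a, b)
    }
    if (length(out) == 0) return(data.frame(f1 = integer(), f2 = integer()))
    data.frame(f1 = vapply(out, `[`, 0, 1), f2 = vapply(out, `[`, 0, 2))
  }

  draw_eps <- function(df, scale = 1) {
    n <- nrow(df)
    df$elstat <- stats::runif(n, -25, 5) * kc * scale
    df$exch <- stats::runif(n, -8, 0) * kc * scale
    df$no_disp <- stats::runif(n, -2, 1) * kc * scale
    df$disp <- stats::runif(n, -6, 0) * kc * scale
    df$solv <- if (solvation) stats::runif(n, -2, 0) * kc * scale else
      rep(NA_real_, n)
    df
  }

  gt <- list(
    geometry = geom, subsystems = subsystems, setting = setting,
    seed = seed, solvation = solvation,
    monomer_intra = data.frame(frag = seq_len(F),
                               ref = -76 + stats::rnorm(F, 0, 0.05),
                               corr = -0.25 + stats::rnorm(F, 0, 0.01)),
    # ghost-basis stabilisation of fragment X by fragment Y's basis (Eh)
    bsse = matrix(stats::runif(F * F, 1e-4, 1e-3), F, F) *
      (1 - diag(F)),
    # within-subsystem relaxation relative to the isolated monomer; zero for
    # single-fragment subsystems, whose subsystem context IS the monomer
    w = local({
      lone <- f[sub_of] == 1
      data.frame(frag = seq_len(F),
                 ref = stats::runif(F, 0, 2) * kc * !lone,
                 corr = stats::runif(F, 0, 0.5) * kc * !lone)
    }),
    # planted N-body electronic preparation (uncorrected convention)
    elprep = data.frame(frag = seq_len(F),
                        ref = stats::runif(F, 1, 8) * kc,
                        corr = stats::runif(F, 0, 2) * kc),
    eps_super = draw_eps(pair_df()),
    eps_diff = draw_eps(pair_df(same_only = TRUE), scale = 0.05),
    pair_prep = local({
      df <- pair_df(span_only = TRUE)
      n <- nrow(df)
      df$ref1 <- stats::runif(n, 0.5, 4) * kc
      df$corr1 <- stats::runif(n, 0, 1) * kc
      df$ref2 <- stats::runif(n, 0.5, 4) * kc
      df$corr2 <- stats::runif(n, 0, 1) * kc
      df
    }),
    coop = draw_eps(pair_df(span_only = TRUE), scale = 0.06))
  class(gt) <- "led_ground_truth"
  gt
}

#' @export
print.led_ground_truth <- function(x, ...) {
  cat(sprintf("<led_ground_truth> %d subsystems, %d fragments, seed %d\n",
              length(x$subsystems), nrow(x$monomer_intra), x$seed))
  invisible(x)
}

gt_sub_of <- function(gt) {
  subsystem_of_map(gt$subsystems, nrow(gt$monomer_intra))
}

gt_pair <- function(df, x, y) {
  a <- min(x, y); b <- max(x, y)
  df[df$f1 == a & df$f2 == b, , drop = FALSE]
}

# intra energies of fragment f in a given context:
#  monomer        : isolated value
#  monomer + ghosts: isolated - sum of ghost-basis stabilisations
#  subsystem      : isolated + within-subsystem relaxation
#  supersystem    : subsystem context + planted elprep
gt_intra <- function(gt, f, context, ghost_partners = integer()) {
  base_ref <- gt$monomer_intra$ref[f]
  base_corr <- gt$monomer_intra$corr[f]
  drop <- sum(gt$bsse[f, ghost_partners])
  switch(context,
    monomer = list(ref = base_ref - drop, corr = base_corr),
    subsystem = list(ref = base_ref + gt$w$ref[f] - drop,
                     corr = base_corr + gt$w$corr[f]),
    supersystem = list(ref = base_ref + gt$w$ref[f] + gt$elprep$ref[f],
                       corr = base_corr + gt$w$corr[f] + gt$elprep$corr[f]),
    pair = {
      pp <- gt_pair(gt$pair_prep, f, ghost_partners[1])  # partner, real here
      k <- if (pp$f1 == f) 1 else 2
      list(ref = base_ref + pp[[paste0("ref", k)]],
           corr = base_corr + pp[[paste0("corr", k)]])
    },
    stop("unknown context"))
}

eps_cols <- c("elstat", "exch", "no_disp", "disp", "solv")

finish_record <- function(gt, atoms, ghost, intra, pw) {
  pw$total <- rowSums(cbind(pw$elstat, pw$exch, pw$no_disp, pw$disp,
                            ifelse(is.na(pw$solv), 0, pw$solv)))
  total <- sum(intra$ref) + sum(intra$corr) + sum(pw$total)
  ref <- sum(intra$ref) +
    sum(pw$elstat + pw$exch + ifelse(is.na(pw$solv), 0, pw$solv))
  led_record(atoms = atoms, ghost = ghost, intra = intra, pairwise = pw,
             total_energy = total, reference_energy = ref,
             method = gt$setting$method, setting_label = gt$setting$label)
}

record_atoms <- function(gt, ids, local_of) {
  # atoms grouped by local fragment label (the order output files print them)
  do.call(rbind, lapply(ids, function(id) {
    sel <- which(gt$geometry$fragment == id)
    data.frame(fragment = unname(local_of[as.character(id)]),
               element = gt$geometry$element[sel],
               x = gt$geometry$coords[sel, 1],
               y = gt$geometry$coords[sel, 2],
               z = gt$geometry$coords[sel, 3])
  }))
}

#' Derive the LED record of one calculation from a ground truth
#'
#' Constructs the `led_record` a quantum-chemistry engine would have produced
#' for the given calculation spec, exactly consistent with the planted
#' energies (fragment labels are local to the file: contiguous from 1, real
#' fragments first, as in rendered inputs).
#'
#' @param gt an `led_ground_truth`.
#' @param spec an `led_calcspec` from the matching campaign enumeration.
#' @return An `led_record`.
#' @export
truth_record <- function(gt, spec) {
  real <- sort(spec$real_fragments)
  ghost <- sort(spec$ghost_fragments)
  ids <- c(real, ghost)
  local_of <- stats::setNames(seq_along(ids), ids)
  atoms <- record_atoms(gt, ids, local_of)
  gflag <- c(rep(FALSE, length(real)), rep(TRUE, length(ghost)))
  sub_of <- gt_sub_of(gt)

  intra <- data.frame(frag = integer(), ref = numeric(), corr = numeric())
  pw <- data.frame(f1 = integer(), f2 = integer())
  for (cc in eps_cols) pw[[cc]] <- numeric()

  ctx_intra <- switch(spec$role,
    supersystem = lapply(real, function(fg) gt_intra(gt, fg, "supersystem")),
    subsystem = lapply(real, function(fg)
      gt_intra(gt, fg, "subsystem", ghost_partners = ghost)),
    pair = lapply(real, function(fg)
      gt_intra(gt, fg, "pair", ghost_partners = setdiff(real, fg))),
    monomer = lapply(real, function(fg)
      gt_intra(gt, fg, "monomer", ghost_partners = ghost)))
  intra <- data.frame(fragment = unname(local_of[as.character(real)]),
                      ref = vapply(ctx_intra, `[[`, 0, "ref"),
                      corr = vapply(ctx_intra, `[[`, 0, "corr"))

  if (length(real) > 1) {
    for (a_i in seq_len(length(real) - 1)) {
      for (b_i in seq(a_i + 1, length(real))) {
        a <- real[a_i]; b <- real[b_i]
        super_row <- gt_pair(gt$eps_super, a, b)
        row <- super_row
        if (spec$role == "subsystem" && sub_of[a] == sub_of[b]) {
          dd <- gt_pair(gt$eps_diff, a, b)
          for (cc in eps_cols) row[[cc]] <- row[[cc]] - dd[[cc]]
        } else if (spec$role == "pair") {
          co <- gt_pair(gt$coop, a, b)
          for (cc in eps_cols) row[[cc]] <- row[[cc]] - co[[cc]]
        }
        pw <- rbind(pw, data.frame(f1 = local_of[as.character(a)],
                                   f2 = local_of[as.character(b)],
                                   row[eps_cols]))
      }
    }
  }
  rownames(pw) <- NULL
  finish_record(gt, atoms, gflag, intra, pw)
}

#' Write the mock output files of a campaign
#'
#' Enumerates the campaign implied by the arguments (via
#' [enumerate_campaign()]) and writes one grammar-conforming mock output file
#' per calculation, named after the input file with extension `.out`.
#'
#' @param gt an `led_ground_truth`.
#' @param dir output directory (created if needed).
#' @param bsse counterpoise-corrected campaign?
#' @param include_twobody include pair and monomer calculations?
#' @return Invisibly, the campaign manifest data frame with an extra
#'   `output` column of file paths.
#' @export
write_mock_outputs <- function(gt, dir, bsse = FALSE, include_twobody = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- enumerate_campaign(gt$geometry, gt$subsystems, list(gt$setting),
                              bsse = bsse, include_twobody = include_twobody)
  paths <- character(length(specs))
  for (k in seq_along(specs)) {
    rec <- truth_record(gt, specs[[k]])
    paths[k] <- file.path(dir, sub("\\.inp$", ".out", specs[[k]]$filename))
    write_led_output(rec, paths[k])
  }
  manifest <- campaign_manifest(specs)
  manifest$output <- paths
  invisible(manifest)
}

#' Planted expectation matrices of a ground truth
#'
#' The analytically expected matrix set the assembly stage must recover from
#' the mock outputs, computed directly from the planted quantities (never via
#' the parser or assembler, so tests comparing the two routes are meaningful).
#'
#' @param gt an `led_ground_truth`.
#' @param bsse corrected or uncorrected analysis convention.
#' @param body_order `"nbody"` or `"twobody"`.
#' @return An `led_matrix_set` in standard layout (for `"twobody"`, the
#'   standard two-body layout with same-subsystem cells absent).
#' @export
expected_matrix_set <- function(gt, bsse = FALSE, body_order = "nbody") {
  F <- nrow(gt$monomer_intra)
  labs <- seq_len(F)
  sub_of <- gt_sub_of(gt)
  eps_names <- c(LED_EPS_COMPONENTS, if (gt$solvation) "solv")
  comps <- c("elprep", "elprep_ref", "elprep_corr", eps_names)
  M <- lapply(stats::setNames(comps, comps),
              function(...) matrix(0, F, F, dimnames = list(labs, labs)))
  absent <- matrix(FALSE, F, F, dimnames = list(labs, labs))

  if (body_order == "nbody") {
    for (fg in labs) {
      other <- which(sub_of != sub_of[fg])
      M$elprep_ref[fg, fg] <- gt$elprep$ref[fg] +
        if (bsse) sum(gt$bsse[fg, other]) else 0
      M$elprep_corr[fg, fg] <- gt$elprep$corr[fg]
    }
    for (k in seq_len(nrow(gt$eps_super))) {
      a <- gt$eps_super$f1[k]; b <- gt$eps_super$f2[k]
      for (cc in eps_names) {
        v <- gt$eps_super[[cc]][k]
        if (sub_of[a] == sub_of[b]) v <- gt_pair(gt$eps_diff, a, b)[[cc]]
        M[[cc]][a, b] <- M[[cc]][b, a] <- v
      }
    }
  } else {
    absent[, ] <- TRUE
    diag(absent) <- FALSE
    for (k in seq_len(nrow(gt$pair_prep))) {
      a <- gt$pair_prep$f1[k]; b <- gt$pair_prep$f2[k]
      pr <- gt$pair_prep[k, ]
      bs_a <- if (bsse) gt$bsse[a, b] else 0
      bs_b <- if (bsse) gt$bsse[b, a] else 0
      M$elprep_ref[a, a] <- M$elprep_ref[a, a] + pr$ref1 + bs_a
      M$elprep_ref[b, b] <- M$elprep_ref[b, b] + pr$ref2 + bs_b
      M$elprep_corr[a, a] <- M$elprep_corr[a, a] + pr$corr1
      M$elprep_corr[b, b] <- M$elprep_corr[b, b] + pr$corr2
      co <- gt_pair(gt$coop, a, b)
      sup <- gt_pair(gt$eps_super, a, b)
      for (cc in eps_names) {
        M[[cc]][a, b] <- M[[cc]][b, a] <- sup[[cc]] - co[[cc]]
      }
      absent[a, b] <- absent[b, a] <- FALSE
    }
  }
  M$elprep <- M$elprep_ref + M$elprep_corr
  M <- lapply(M, function(m) m * HARTREE_TO_KCAL)
  M$total <- M$elprep + Reduce(`+`, M[eps_names])
  M <- M[c("total", "elprep", "elprep_ref", "elprep_corr", eps_names)]
  for (cc in names(M)) M[[cc]][absent] <- 0
  new_matrix_set("standard", M, labs, sub_of, bsse, body_order, absent,
                 provenance = "planted expectation")
}

#' Perturb a ground truth onto an extrapolation model form
#'
#' Produces the pair of ground truths at the two points of a CBS or CPS
#' extrapolation such that extrapolating any derived energy (record energies,
#' matrix cells) recovers the input ground truth exactly. Reference-level
#' planted fields follow `E(n) = E_limit + A exp(-alpha sqrt(n))` and
#' correlation-level fields `E(n) = E_limit + B n^-beta` (CBS); under CPS the
#' correlation fields are offset so the affine formula returns the limit and
#' reference fields are identical at both thresholds. Amplitudes are drawn
#' reproducibly from `seed`. Works because every derived energy is linear in
#' the planted fields.
#'
#' @param gt the limit `led_ground_truth`.
#' @param params an `led_extrap_params`.
#' @param seed seed for the amplitude draws.
#' @return List with elements `x` and `y`: ground truths at the two points,
#'   with setting labels suffixed by the point.
#' @export
ground_truth_series <- function(gt, params, seed = 1) {
  set.seed(seed)
  ref_fields <- list(c("monomer_intra", "ref"), c("w", "ref"),
                     c("elprep", "ref"),
                     c("eps_super", "elstat"), c("eps_super", "exch"),
                     c("eps_super", "solv"),
                     c("eps_diff", "elstat"), c("eps_diff", "exch"),
                     c("eps_diff", "solv"),
                     c("pair_prep", "ref1"), c("pair_prep", "ref2"),
                     c("coop", "elstat"), c("coop", "exch"), c("coop", "solv"))
  corr_fields <- list(c("monomer_intra", "corr"), c("w", "corr"),
                      c("elprep", "corr"),
                      c("eps_super", "no_disp"), c("eps_super", "disp"),
                      c("eps_diff", "no_disp"), c("eps_diff", "disp"),
                      c("pair_prep", "corr1"), c("pair_prep", "corr2"),
                      c("coop", "no_disp"), c("coop", "disp"))
  gx <- gt; gy <- gt
  perturb <- function(fields, dx, dy, amp) {
    for (fd in fields) {
      v <- gt[[fd[1]]][[fd[2]]]
      if (is.null(v) || all(is.na(v))) next
      a <- stats::runif(length(v), -amp, amp)
      gx[[fd[1]]][[fd[2]]] <<- v + a * dx
      gy[[fd[1]]][[fd[2]]] <<- v + a * dy
    }
  }
  if (params$kind == "CBS") {
    perturb(ref_fields, exp(-params$alpha * sqrt(params$X)),
            exp(-params$alpha * sqrt(params$Y)), amp = 0.5)
    perturb(corr_fields, params$X^-params$beta, params$Y^-params$beta,
            amp = 0.1)
  } else {
    # E_X = limit + d, E_Y = limit + d (1 - 1/F) so E_X + F (E_Y - E_X) = limit
    perturb(corr_fields, 1, 1 - 1 / params$F, amp = 0.01)
  }
  # bsse matrix is a reference-level quantity
  a <- matrix(stats::runif(length(gt$bsse), -1e-4, 1e-4), nrow(gt$bsse))
  a[gt$bsse == 0] <- 0
  if (params$kind == "CBS") {
    gx$bsse <- gt$bsse + a * exp(-params$alpha * sqrt(params$X))
    gy$bsse <- gt$bsse + a * exp(-params$alpha * sqrt(params$Y))
  }
  gx$setting <- calc_setting(paste0(gt$setting$label, "_", params$X),
                             method = gt$setting$method,
                             basis = gt$setting$basis)
  gy$setting <- calc_setting(paste0(gt$setting$label, "_", params$Y),
                             method = gt$setting$method,
                             basis = gt$setting$basis)
  list(x = gx, y = gy)
}
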