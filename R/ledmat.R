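# Assembly of component-resolved interaction-energy matrices from LED records:
# standard and fragment-pairwise (fp) layouts, N-body and two-body variants,
# and cooperativity (many-body) analysis.
#
# Component bookkeeping: alongside the canonical components (total, elprep,
# elstat, exch, no_disp, disp, solv) each matrix set carries elprep_ref and
# elprep_corr (elprep = elprep_ref + elprep_corr), because basis-set and PNO
# extrapolation treat the reference and correlation parts of the electronic
# preparation differently.

LED_EPS_COMPONENTS <- c("elstat", "exch", "no_disp", "disp")

new_matrix_set <- function(layout, components, fragment_labels, subsystem_of,
                           bsse_corrected, body_order, absent,
                           fully_coop = NULL, scheme = NULL,
                           provenance = character()) {
  structure(list(layout = layout, components = components,
                 fragment_labels = fragment_labels,
                 subsystem_of = subsystem_of,
                 bsse_corrected = bsse_corrected, body_order = body_order,
                 absent = absent, fully_coop = fully_coop, scheme = scheme,
                 provenance = provenance),
            class = "led_matrix_set")
}

#' @export
print.led_matrix_set <- function(x, ...) {
  cat(sprintf("<led_matrix_set> %s %s layout, %d fragments, %s, kcal/mol\n",
              x$body_order, x$layout, length(x$fragment_labels),
              if (x$bsse_corrected) "CP-corrected" else "uncorrected"))
  cat("components:", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}

#' Grand total of a matrix set
#'
#' Sums the defined cells of the total component: the diagonal plus each
#' unordered off-diagonal pair once. Equals the interaction energy for N-body
#' sets (energy conservation between the decomposition and the supersystem
#' minus subsystem energies).
#'
#' @param ms an `led_matrix_set`.
#' @param component component name (default `"total"`).
#' @return kcal/mol scalar.
#' @export
matrix_grand_total <- function(ms, component = "total") {
  m <- ms$components[[component]]
  m[ms$absent] <- 0
  sum(diag(m)) + sum(m[upper.tri(m)])
}

subsystem_of_map <- function(subsystems, F) {
  out <- integer(F)
  for (k in seq_along(subsystems)) out[subsystems[[k]]$fragment_ids] <- k
  out
}

#' Supersystem interaction energy
#'
#' The difference between the supersystem energy and the sum of the part
#' energies at the supersystem geometry, in kcal/mol. For the counterpoise
#' (BSSE)-corrected interaction energy, pass the ghost-padded part records.
#'
#' @param super `led_record` of the supersystem.
#' @param parts list of `led_record`s, one per subsystem (or per fragment).
#' @return kcal/mol scalar.
#' @export
interaction_energy <- function(super, parts) {
  es <- vapply(parts, `[[`, 0, "total_energy")
  if (any(!is.finite(es)) || !is.finite(super$total_energy)) {
    stop("missing total energies", call. = FALSE)
  }
  (super$total_energy - sum(es)) * HARTREE_TO_KCAL
}

# align each part onto the supersystem labels and check the real fragments
# of the parts partition the supersystem fragments
align_parts <- function(super, parts, tol = 1e-4) {
  parts <- lapply(parts, function(p) relabel_record(p, align_labels(p, super, tol)))
  reals <- lapply(parts, real_labels)
  allr <- unlist(reals)
  if (anyDuplicated(allr)) {
    stop("partition error: fragment present in two part records", call. = FALSE)
  }
  if (!setequal(allr, real_labels(super))) {
    stop("partition error: part records do not cover the supersystem fragments",
         call. = FALSE)
  }
  parts
}

intra_total <- function(rec, f) {
  row <- rec$intra[rec$intra$fragment == f, ]
  if (nrow(row) == 0) stop("missing intra block for fragment ", f, call. = FALSE)
  list(ref = row$ref[1],
       corr = if (is.na(row$corr[1])) 0 else row$corr[1])
}

pair_row <- function(rec, x, y) {
  a <- min(x, y); b <- max(x, y)
  rec$pairwise[rec$pairwise$f1 == a & rec$pairwise$f2 == b, ]
}

#' Assemble the standard-LED N-body matrix set
#'
#' Diagonal cells hold the electronic-preparation energies (supersystem intra
#' minus part-record intra, per fragment). Off-diagonal cells hold the
#' interfragment components: for pairs spanning different subsystems the
#' supersystem values directly (genuine intersubsystem interactions); for
#' pairs within one subsystem the supersystem-minus-part differentials
#' (perturbation of the pair's energy upon complex formation). The total
#' component is the cellwise sum of the others. All values in kcal/mol.
#'
#' @param super supersystem `led_record`.
#' @param parts list of part `led_record`s, one per subsystem (ghost-padded
#'   for the BSSE-corrected analysis).
#' @param subsystems list of [subsystem_spec()].
#' @param tol alignment tolerance (Angstrom).
#' @return An `led_matrix_set` with `layout = "standard"`.
#' @export
assemble_standard_nbody <- function(super, parts, subsystems, tol = 1e-4) {
  parts <- align_parts(super, parts, tol)
  labs <- real_labels(super)
  F <- length(labs)
  check_fragment_cover(labs, subsystems)
  sub_of <- subsystem_of_map(subsystems, F)
  bsse <- any(vapply(parts, function(p) any(p$ghost), TRUE))

  part_of <- integer(F)   # which part record holds fragment f as real
  for (k in seq_along(parts)) part_of[real_labels(parts[[k]])] <- k

  has_solv <- all(!is.na(super$pairwise$solv)) &&
    all(vapply(parts, function(p) nrow(p$pairwise) == 0 ||
                 all(!is.na(p$pairwise$solv)), TRUE))
  comps <- c("elprep", "elprep_ref", "elprep_corr", LED_EPS_COMPONENTS,
             if (has_solv) "solv")
  M <- lapply(stats::setNames(comps, comps),
              function(...) matrix(0, F, F, dimnames = list(labs, labs)))

  for (f in labs) {
    s <- intra_total(super, f)
    p <- intra_total(parts[[part_of[f]]], f)
    M$elprep_ref[f, f] <- s$ref - p$ref
    M$elprep_corr[f, f] <- s$corr - p$corr
    M$elprep[f, f] <- M$elprep_ref[f, f] + M$elprep_corr[f, f]
  }
  eps_names <- c(LED_EPS_COMPONENTS, if (has_solv) "solv")
  for (a in seq_len(F - 1)) {
    for (b in seq(a + 1, F)) {
      sr <- pair_row(super, a, b)
      if (nrow(sr) == 0) stop("supersystem record lacks pair ", a, "-", b,
                              call. = FALSE)
      for (cc in eps_names) {
        v <- sr[[cc]][1]
        if (is.na(v)) v <- 0
        if (sub_of[a] == sub_of[b]) {
          pr <- pair_row(parts[[part_of[a]]], a, b)
          pv <- if (nrow(pr) == 0 || is.na(pr[[cc]][1])) 0 else pr[[cc]][1]
          v <- v - pv
        }
        M[[cc]][a, b] <- M[[cc]][b, a] <- v
      }
    }
  }
  M <- lapply(M, function(m) m * HARTREE_TO_KCAL)
  M$total <- M$elprep + Reduce(`+`, M[eps_names])
  M <- M[c("total", "elprep", "elprep_ref", "elprep_corr", eps_names)]
  new_matrix_set("standard", M, labs, sub_of, bsse, "nbody",
                 absent = matrix(FALSE, F, F, dimnames = list(labs, labs)),
                 provenance = sprintf("assembled from %d part records", length(parts)))
}

check_fragment_cover <- function(labs, subsystems) {
  ids <- unlist(lapply(subsystems, `[[`, "fragment_ids"))
  if (!setequal(ids, labs) || anyDuplicated(ids)) {
    stop("configuration error: subsystem fragment ids must partition ",
         "the record's fragments", call. = FALSE)
  }
}

fp_shares <- function(elprep_diag, eps_total, scheme) {
  # returns an F x F matrix W with W[x, y] = share of fragment x's elprep
  # assigned to pair (x, y); rows sum to 1 (F > 1)
  F <- length(elprep_diag)
  W <- matrix(0, F, F)
  if (F == 1) return(W)
  for (x in seq_len(F)) {
    w <- abs(eps_total[x, ])
    w[x] <- 0
    if (scheme == "equal" || sum(w) == 0) {
      w <- rep(1 / (F - 1), F)
      w[x] <- 0
    } else {
      w <- w / sum(w)
    }
    W[x, ] <- w
  }
  W
}

#' Convert a standard-layout set to the fragment-pairwise (fp) layout
#'
#' Redistributes the cumulative per-fragment electronic-preparation energies
#' of the diagonal into a symmetric off-diagonal pairwise matrix, so that
#' every matrix element becomes a pair quantity (the fp-LED picture, in which
#' cell (X, Y) is the total pair interaction: its elprep share plus the
#' interfragment components). Conservation is exact by construction: the sum
#' of the pairwise elprep cells equals the sum of the diagonal it replaces.
#'
#' Built-in partitioning schemes:
#' \describe{
#'   \item{`"equal"`}{each fragment's elprep is split evenly over its F-1
#'     partners; the pair cell is the sum of the two members' shares.}
#'   \item{`"prop_eps"`}{each fragment's elprep is split over partners in
#'     proportion to the magnitude of the pair's total interfragment
#'     component, falling back to an even split when all magnitudes vanish.}
#' }
#'
#' @param std an `led_matrix_set` with `layout == "standard"`.
#' @param scheme partitioning scheme id.
#' @return An `led_matrix_set` with `layout == "fp"`.
#' @export
assemble_fp_nbody <- function(std, scheme = c("equal", "prop_eps")) {
  scheme <- match.arg(scheme)
  if (std$layout != "standard") {
    stop("assemble_fp_nbody expects a standard-layout set", call. = FALSE)
  }
  F <- length(std$fragment_labels)
  eps_total <- Reduce(`+`, std$components[intersect(
    c(LED_EPS_COMPONENTS, "solv"), names(std$components))])
  W <- fp_shares(diag(std$components$elprep), eps_total, scheme)
  M <- std$components
  for (cc in c("elprep", "elprep_ref", "elprep_corr")) {
    d <- diag(M[[cc]])
    P <- diag(d) %*% W          # P[x, y] = d_x * W[x, y]
    M[[cc]] <- P + t(P)
  }
  eps_names <- intersect(c(LED_EPS_COMPONENTS, "solv"), names(M))
  M$total <- M$elprep + Reduce(`+`, M[eps_names])
  diag(M$total) <- 0
  absent <- std$absent
  diag(absent) <- TRUE          # fp layout has no diagonal quantities
  new_matrix_set("fp", M, std$fragment_labels, std$subsystem_of,
                 std$bsse_corrected, std$body_order, absent,
                 scheme = scheme,
                 provenance = c(std$provenance,
                                sprintf("fp elprep partitioner: %s", scheme)))
}

#' Assemble the two-body LED matrix set
#'
#' Builds the two-body approximation of the many-body expansion from LED
#' calculations on each isolated fragment pair spanning different subsystems.
#' Electronic-preparation energies come from pair-record intra terms minus the
#' matching monomer intra terms; interfragment components come from the pair
#' records. Cells with no isolated-pair calculation (pairs within one
#' subsystem, and in the fp layout the diagonal) are flagged absent, not zero.
#'
#' @param pair_records named or unnamed list of `led_record`s, one per
#'   spanning pair (both fragments real).
#' @param monomer_records list of monomer `led_record`s: uncorrected, one per
#'   fragment; corrected, two per pair (each fragment real with its partner
#'   ghost).
#' @param subsystems list of [subsystem_spec()].
#' @param bsse logical: counterpoise-corrected convention for the monomers.
#' @param layout `"standard"` (diagonal elprep) or `"fp"` (pairwise elprep).
#' @param reference optional `led_record` whose labels define the fragment
#'   numbering (normally the supersystem output of the N-body analysis, so
#'   two-body labels inherit the N-body ones). When omitted, labels follow
#'   the order of the monomer record list.
#' @param tol alignment tolerance (Angstrom).
#' @return An `led_matrix_set` with `body_order == "twobody"`.
#' @export
assemble_twobody <- function(pair_records, monomer_records, subsystems,
                             bsse = FALSE, layout = c("standard", "fp"),
                             reference = NULL, tol = 1e-4) {
  layout <- match.arg(layout)
  if (length(pair_records) == 0) {
    stop("completeness error: empty pair record list", call. = FALSE)
  }
  if (is.null(reference)) {
    reference <- reference_from_monomers(monomer_records, tol)
  }
  labs <- real_labels(reference)
  F <- length(labs)
  check_fragment_cover(labs, subsystems)
  sub_of <- subsystem_of_map(subsystems, F)

  pair_records <- lapply(pair_records, function(r)
    relabel_record(r, align_labels(r, reference, tol)))
  monomer_records <- lapply(monomer_records, function(r)
    relabel_record(r, align_labels(r, reference, tol)))

  # index pair records by their real-fragment pair
  pkey <- vapply(pair_records, function(r)
    paste(sort(real_labels(r)), collapse = "-"), "")
  # monomer lookup: uncorrected by fragment; corrected by (real, ghost partner)
  mono_for <- function(f, partner) {
    for (m in monomer_records) {
      rl <- real_labels(m)
      if (length(rl) == 1 && rl == f) {
        gl <- setdiff(record_labels(m), rl)
        if (!bsse && length(gl) == 0) return(m)
        if (bsse && length(gl) == 1 && gl == partner) return(m)
      }
    }
    stop(sprintf("completeness error: missing %s monomer record for fragment %d%s",
                 if (bsse) "counterpoise" else "isolated", f,
                 if (bsse) sprintf(" (partner %d)", partner) else ""),
         call. = FALSE)
  }

  pairs <- spanning_pairs_by_map(sub_of)
  missing <- pairs[!vapply(pairs, function(p)
    paste(p, collapse = "-") %in% pkey, TRUE)]
  if (length(missing) > 0) {
    stop("completeness error: missing pair record(s): ",
         paste(vapply(missing, paste, "", collapse = "-"), collapse = ", "),
         call. = FALSE)
  }

  has_solv <- all(vapply(pair_records, function(r)
    all(!is.na(r$pairwise$solv)), TRUE))
  eps_names <- c(LED_EPS_COMPONENTS, if (has_solv) "solv")
  comps <- c("elprep", "elprep_ref", "elprep_corr", eps_names)
  M <- lapply(stats::setNames(comps, comps),
              function(...) matrix(0, F, F, dimnames = list(labs, labs)))
  absent <- matrix(TRUE, F, F, dimnames = list(labs, labs))

  for (p in pairs) {
    x <- p[1]; y <- p[2]
    rec <- pair_records[[match(paste(p, collapse = "-"), pkey)]]
    pr <- pair_row(rec, x, y)
    if (nrow(pr) == 0) {
      stop(sprintf("pair record %d-%d lacks its interaction block", x, y),
           call. = FALSE)
    }
    prep_ref <- prep_corr <- 0
    for (f in c(x, y)) {
      partner <- setdiff(c(x, y), f)
      ip <- intra_total(rec, f)
      im <- intra_total(mono_for(f, partner), f)
      dr <- ip$ref - im$ref
      dc <- ip$corr - im$corr
      if (layout == "standard") {
        M$elprep_ref[f, f] <- M$elprep_ref[f, f] + dr
        M$elprep_corr[f, f] <- M$elprep_corr[f, f] + dc
      }
      prep_ref <- prep_ref + dr
      prep_corr <- prep_corr + dc
    }
    if (layout == "fp") {
      M$elprep_ref[x, y] <- M$elprep_ref[y, x] <- prep_ref
      M$elprep_corr[x, y] <- M$elprep_corr[y, x] <- prep_corr
    }
    for (cc in eps_names) {
      v <- pr[[cc]][1]
      if (is.na(v)) v <- 0
      M[[cc]][x, y] <- M[[cc]][y, x] <- v
    }
    absent[x, y] <- absent[y, x] <- FALSE
  }
  if (layout == "standard") diag(absent) <- FALSE
  M$elprep <- M$elprep_ref + M$elprep_corr
  M <- lapply(M, function(m) m * HARTREE_TO_KCAL)
  M$total <- M$elprep + Reduce(`+`, M[eps_names])
  M <- M[c("total", "elprep", "elprep_ref", "elprep_corr", eps_names)]
  for (cc in names(M)) M[[cc]][absent] <- 0
  new_matrix_set(layout, M, labs, sub_of,
                 bsse_corrected = bsse, body_order = "twobody", absent,
                 provenance = sprintf("two-body assembly from %d pair records",
                                      length(pair_records)))
}

spanning_pairs_by_map <- function(sub_of) {
  F <- length(sub_of)
  out <- list()
  for (a in seq_len(F - 1)) {
    for (b in seq(a + 1, F)) {
      if (sub_of[a] != sub_of[b]) out[[length(out) + 1]] <- c(a, b)
    }
  }
  if (length(out) == 0) {
    stop("no fragment pairs span different subsystems", call. = FALSE)
  }
  out
}

# build a reference record covering all fragments from monomer outputs, in
# list order (used when no supersystem record is available)
reference_from_monomers <- function(monomer_records, tol = 1e-4) {
  atoms <- data.frame(fragment = integer(), element = character(),
                      x = numeric(), y = numeric(), z = numeric())
  intra <- data.frame(fragment = integer(), ref = numeric(), corr = numeric())
  nf <- 0L
  for (m in monomer_records) {
    rl <- real_labels(m)
    sel <- m$atoms$fragment %in% rl
    sig <- m$atoms[sel, ]
    dup <- FALSE
    if (nf > 0) {
      for (f in seq_len(nf)) {
        prev <- atoms[atoms$fragment == f, ]
        if (identical(prev$element, sig$element) &&
            nrow(prev) == nrow(sig) &&
            max(abs(as.matrix(prev[, c("x", "y", "z")]) -
                    as.matrix(sig[, c("x", "y", "z")]))) <= tol) {
          dup <- TRUE
          break
        }
      }
    }
    if (dup) next
    nf <- nf + 1L
    sig$fragment <- nf
    atoms <- rbind(atoms, sig)
    intra <- rbind(intra, data.frame(fragment = nf, ref = NA_real_,
                                     corr = NA_real_))
  }
  led_record(atoms = atoms, ghost = rep(FALSE, nf), intra = intra,
             pairwise = data.frame(f1 = integer(), f2 = integer()),
             method = monomer_records[[1]]$method,
             setting_label = monomer_records[[1]]$setting_label)
}

#' Cooperativity (many-body) matrix set
#'
#' Subtracts the two-body matrix set from the N-body set cellwise, isolating
#' environment-mediated many-body effects. Where the two-body cell is absent
#' (no isolated-pair calculation exists, e.g. same-subsystem differentials),
#' the cooperativity cell equals the N-body value and is flagged as fully
#' cooperative.
#'
#' @param nbody,twobody `led_matrix_set`s with matching fragment labels,
#'   layout and components.
#' @return An `led_matrix_set` with `body_order == "cooperativity"` and a
#'   `fully_coop` logical matrix.
#' @export
cooperativity <- function(nbody, twobody) {
  if (!identical(nbody$fragment_labels, twobody$fragment_labels)) {
    stop("alignment error: fragment labels differ", call. = FALSE)
  }
  if (!identical(nbody$layout, twobody$layout)) {
    stop("alignment error: layouts differ (convert both to the same layout)",
         call. = FALSE)
  }
  comps <- intersect(names(nbody$components), names(twobody$components))
  M <- list()
  for (cc in comps) {
    tb <- twobody$components[[cc]]
    tb[twobody$absent] <- 0
    M[[cc]] <- nbody$components[[cc]] - tb
    M[[cc]][nbody$absent] <- 0
  }
  fully <- twobody$absent & !nbody$absent
  new_matrix_set(nbody$layout, M, nbody$fragment_labels, nbody$subsystem_of,
                 nbody$bsse_corrected, "cooperativity",
                 absent = nbody$absent, fully_coop = fully,
                 provenance = c(nbody$provenance,
                                "cooperativity = nbody - twobody"))
}
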