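# Enumeration and rendering of every quantum-chemistry input required for
# N-body and two-body LED analyses, with and without counterpoise (BSSE)
# correction, across computational settings.

#' Define a subsystem
#'
#' A subsystem is a chemical entity within the supersystem (e.g. one strand of
#' a duplex); it owns one or more fragments. Subsystems must be disjoint and
#' jointly cover all fragments of the geometry.
#'
#' @param name subsystem name (used in filenames and reports).
#' @param fragment_ids integer vector of fragment ids belonging to it.
#' @export
subsystem_spec <- function(name, fragment_ids) {
  fragment_ids <- as.integer(fragment_ids)
  stopifnot(length(fragment_ids) > 0, !anyDuplicated(fragment_ids))
  structure(list(name = as.character(name), fragment_ids = fragment_ids),
            class = "led_subsystem")
}

check_subsystems <- function(geom, subsystems) {
  if (length(subsystems) == 0) {
    stop("configuration error: empty subsystem list", call. = FALSE)
  }
  all_ids <- unlist(lapply(subsystems, `[[`, "fragment_ids"))
  if (anyDuplicated(all_ids)) {
    stop("configuration error: subsystems are not disjoint", call. = FALSE)
  }
  if (!setequal(all_ids, seq_len(n_fragments(geom)))) {
    stop("configuration error: subsystems must cover all fragments exactly",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Define a computational setting
#'
#' @param label unique short label (used in filenames; e.g. `"TZ"` or
#'   `"PNO7"`).
#' @param method one of `"DLPNO-CCSD(T)"`, `"DLPNO-CCSD"`, `"HFLD"`.
#' @param basis basis-set keyword (e.g. `"aug-cc-pVTZ"`).
#' @param tcutpno_exponent optional positive integer X selecting the PNO
#'   truncation threshold T_CutPNO = 10^-X.
#' @param extra_keywords free-form extra keywords appended to the keyword line.
#' @export
calc_setting <- function(label, method = "DLPNO-CCSD(T)",
                         basis = "def2-TZVP", tcutpno_exponent = NULL,
                         extra_keywords = "") {
  method <- match.arg(method, c("DLPNO-CCSD(T)", "DLPNO-CCSD", "HFLD"))
  if (!is.null(tcutpno_exponent)) {
    stopifnot(tcutpno_exponent == round(tcutpno_exponent), tcutpno_exponent > 0)
  }
  structure(list(label = as.character(label), method = method, basis = basis,
                 tcutpno_exponent = tcutpno_exponent,
                 extra_keywords = extra_keywords),
            class = "led_setting")
}

frag_tag <- function(ids) paste0("F", paste(sort(ids), collapse = "-F"))

new_calcspec <- function(role, real, ghost, setting, bsse, filename) {
  stopifnot(length(intersect(real, ghost)) == 0)
  if (!bsse && length(ghost) > 0) {
    stop("uncorrected spec must have an empty ghost set", call. = FALSE)
  }
  structure(list(role = role,
                 real_fragments = sort(as.integer(real)),
                 ghost_fragments = sort(as.integer(ghost)),
                 setting = setting, bsse_corrected = bsse,
                 filename = filename),
            class = "led_calcspec")
}

#' @export
print.led_calcspec <- function(x, ...) {
  cat(sprintf("<led_calcspec> %s [%s] real={%s} ghost={%s} -> %s\n",
              x$role, if (x$bsse_corrected) "CP" else "no-CP",
              paste(x$real_fragments, collapse = ","),
              paste(x$ghost_fragments, collapse = ","), x$filename))
  invisible(x)
}

#' Enumerate N-body LED calculations
#'
#' One supersystem calculation (all fragments real) plus one per subsystem.
#' In the counterpoise-corrected setup each subsystem calculation carries all
#' other subsystems' fragments as ghost atoms, so every energy is evaluated in
#' the full supersystem basis.
#'
#' @param geom an `led_geometry` with fragments assigned.
#' @param subsystems list of [subsystem_spec()] covering all fragments.
#' @param setting a [calc_setting()].
#' @param bsse logical; counterpoise-corrected setup?
#' @return List of `led_calcspec`, length `1 + S`.
#' @export
enumerate_nbody <- function(geom, subsystems, setting, bsse = FALSE) {
  check_subsystems(geom, subsystems)
  mode <- if (bsse) "cp" else "nocp"
  all_ids <- seq_len(n_fragments(geom))
  specs <- list(new_calcspec(
    "supersystem", all_ids, integer(), setting, bsse,
    sprintf("%s_%s_supersystem.inp", setting$label, mode)))
  for (ss in subsystems) {
    ghost <- if (bsse) setdiff(all_ids, ss$fragment_ids) else integer()
    specs[[length(specs) + 1]] <- new_calcspec(
      "subsystem", ss$fragment_ids, ghost, setting, bsse,
      sprintf("%s_%s_subsystem-%s.inp", setting$label, mode, ss$name))
  }
  specs
}

spanning_pairs <- function(subsystems) {
  S <- length(subsystems)
  out <- list()
  for (a in seq_len(S - 1)) {
    for (b in seq(a + 1, S)) {
      for (x in subsystems[[a]]$fragment_ids) {
        for (y in subsystems[[b]]$fragment_ids) {
          out[[length(out) + 1]] <- sort(c(x, y))
        }
      }
    }
  }
  out
}

#' Enumerate two-body LED calculations
#'
#' One pair calculation per fragment pair spanning different subsystems
#' (P = sum over subsystem pairs of the product of their fragment counts),
#' plus monomer calculations: uncorrected, one per fragment (F total, no
#' ghosts); corrected, two per pair with ghost and real fragments exchanged
#' (2P total).
#'
#' @inheritParams enumerate_nbody
#' @return List of `led_calcspec` (pairs first, then monomers).
#' @export
enumerate_twobody <- function(geom, subsystems, setting, bsse = FALSE) {
  check_subsystems(geom, subsystems)
  if (length(subsystems) < 2) {
    stop("two-body enumeration needs at least 2 subsystems (no spanning pairs)",
         call. = FALSE)
  }
  mode <- if (bsse) "cp" else "nocp"
  pairs <- spanning_pairs(subsystems)
  specs <- lapply(pairs, function(p) {
    new_calcspec("pair", p, integer(), setting, bsse,
                 sprintf("%s_%s_pair-%s.inp", setting$label, mode, frag_tag(p)))
  })
  if (bsse) {
    for (p in pairs) {
      for (k in 1:2) {
        real <- p[k]; ghost <- p[-k]
        specs[[length(specs) + 1]] <- new_calcspec(
          "monomer", real, ghost, setting, TRUE,
          sprintf("%s_cp_monomer-F%d-in-%s.inp", setting$label, real,
                  frag_tag(p)))
      }
    }
  } else {
    for (f in seq_len(n_fragments(geom))) {
      specs[[length(specs) + 1]] <- new_calcspec(
        "monomer", f, integer(), setting, FALSE,
        sprintf("%s_nocp_monomer-F%d.inp", setting$label, f))
    }
  }
  specs
}

#' Enumerate a full calculation campaign
#'
#' Concatenates [enumerate_nbody()] (plus [enumerate_twobody()] when
#' requested) over all settings. Per setting the totals obey
#' `1 + S + P + F` (uncorrected) and `1 + S + 3P` (corrected) when two-body
#' analysis is included.
#'
#' @inheritParams enumerate_nbody
#' @param settings list of [calc_setting()] with unique labels.
#' @param include_twobody logical.
#' @return List of `led_calcspec` with unique filenames.
#' @export
enumerate_campaign <- function(geom, subsystems, settings, bsse = FALSE,
                               include_twobody = TRUE) {
  if (length(settings) == 0) {
    stop("configuration error: no settings", call. = FALSE)
  }
  labels <- vapply(settings, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("configuration error: duplicate setting labels", call. = FALSE)
  }
  specs <- list()
  for (st in settings) {
    specs <- c(specs, enumerate_nbody(geom, subsystems, st, bsse))
    if (include_twobody) {
      specs <- c(specs, enumerate_twobody(geom, subsystems, st, bsse))
    }
  }
  fn <- vapply(specs, `[[`, "", "filename")
  stopifnot(!anyDuplicated(fn))
  specs
}

#' Render a calculation input file
#'
#' Produces the input text for one `led_calcspec`: a keyword line (method,
#' basis, extra keywords), a `%mdci` block carrying the LED fragment-count
#' directive and, when set, the T_CutPNO threshold, and a coordinate block
#' listing every atom of the spec's real and ghost fragments. Each atom line
#' carries its fragment index in parentheses after the element symbol; ghost
#' atoms are marked by a colon after the element. Fragment indices are
#' renumbered contiguously from 1 within the file, real fragments first, in
#' supersystem order; the map back to supersystem labels is attached as the
#' `"fragment_map"` attribute.
#'
#' @param spec an `led_calcspec`.
#' @param geom the supersystem `led_geometry`.
#' @return Character scalar: the input-file text.
#' @export
render_input <- function(spec, geom) {
  ids <- c(spec$real_fragments, spec$ghost_fragments)
  if (any(!ids %in% seq_len(n_fragments(geom)))) {
    stop("consistency error: spec references unknown fragment id",
         call. = FALSE)
  }
  st <- spec$setting
  kw <- trimws(paste("!", st$method, st$basis, st$extra_keywords))
  # real fragments first, each keeping supersystem atom order internally
  order_ids <- c(sort(spec$real_fragments), sort(spec$ghost_fragments))
  local_of <- stats::setNames(seq_along(order_ids), order_ids)
  mdci <- c("%mdci", sprintf("  LED %d", length(order_ids)))
  if (!is.null(st$tcutpno_exponent)) {
    mdci <- c(mdci, sprintf("  TCutPNO 1e-%d", st$tcutpno_exponent))
  }
  mdci <- c(mdci, "end")
  lines <- c(kw, mdci, "* xyz 0 1")
  for (id in order_ids) {
    sel <- which(geom$fragment == id)
    ghost <- id %in% spec$ghost_fragments
    el <- paste0(geom$element[sel], if (ghost) ":" else "")
    lines <- c(lines, sprintf("  %s(%d) %14.8f %14.8f %14.8f",
                              sprintf("%-4s", paste0(el)),
                              local_of[as.character(id)],
                              geom$coords[sel, 1], geom$coords[sel, 2],
                              geom$coords[sel, 3]))
  }
  lines <- c(lines, "*")
  txt <- paste(lines, collapse = "\n")
  attr(txt, "fragment_map") <- stats::setNames(as.integer(names(local_of)),
                                               local_of)
  txt
}

#' Write a campaign to disk
#'
#' Renders every spec into `dir` and writes a manifest CSV describing the
#' campaign (filename, role, real/ghost fragments, setting label, bsse mode).
#'
#' @param specs list of `led_calcspec` from [enumerate_campaign()].
#' @param geom the supersystem geometry.
#' @param dir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_campaign <- function(specs, geom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in specs) {
    writeLines(render_input(sp, geom), file.path(dir, sp$filename))
  }
  manifest <- campaign_manifest(specs)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Campaign manifest as a data frame
#' @param specs list of `led_calcspec`.
#' @export
campaign_manifest <- function(specs) {
  data.frame(
    filename = vapply(specs, `[[`, "", "filename"),
    role = vapply(specs, `[[`, "", "role"),
    real_fragments = vapply(specs, function(s)
      paste(s$real_fragments, collapse = " "), ""),
    ghost_fragments = vapply(specs, function(s)
      paste(s$ghost_fragments, collapse = " "), ""),
    setting = vapply(specs, function(s) s$setting$label, ""),
    bsse_corrected = vapply(specs, `[[`, NA, "bsse_corrected"),
    stringsAsFactors = FALSE)
}
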