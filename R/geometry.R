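# Geometry container and XYZ I/O.
#
# A geometry is the atom list of a supersystem: element symbols, Cartesian
# coordinates (Angstrom), a per-atom ghost flag, and a per-atom fragment id.
# Fragment ids are 1-based integers forming a contiguous set 1..F.

#' Hartree to kcal/mol conversion factor
#'
#' CODATA-based factor used everywhere energies are reported: energies are
#' held in Hartree internally and converted to kcal/mol only at matrix
#' assembly and reporting time.
#'
#' @format A length-one numeric, 627.5094740631 kcal/mol per Hartree.
#' @export
HARTREE_TO_KCAL <- 627.5094740631

.ledkit_env <- new.env(parent = emptyenv())

#' Covalent radii table
#'
#' Single-bond covalent radii (Angstrom) per element symbol, from the
#' consensus table of Cordero et al. (2008), shipped as a CSV data file.
#' High-spin values are used where that reference distinguishes spin states.
#'
#' @return Named numeric vector of radii indexed by element symbol.
#' @export
covalent_radii <- function() {
  if (is.null(.ledkit_env$radii)) {
    path <- system.file("extdata", "covalent_radii.csv", package = "ledkit")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .ledkit_env$radii <- stats::setNames(tab$radius, tab$element)
  }
  .ledkit_env$radii
}

#' Construct a geometry
#'
#' @param element character vector of element symbols.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param fragment integer vector of 1-based fragment ids, one per atom.
#'   Defaults to all atoms in fragment 1 (the provisional assignment before
#'   [detect_fragments()] runs).
#' @param ghost logical vector of ghost flags (basis functions without nuclei
#'   or electrons, used for counterpoise corrections).
#' @param comment free-text comment carried through XYZ round trips.
#' @return An object of class `led_geometry`.
#' @export
geometry <- function(element, coords, fragment = NULL, ghost = NULL,
                     comment = "") {
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  n <- length(element)
  stopifnot(nrow(coords) == n)
  if (is.null(fragment)) fragment <- rep(1L, n)
  if (is.null(ghost)) ghost <- rep(FALSE, n)
  fragment <- as.integer(fragment)
  radii <- covalent_radii()
  unknown <- setdiff(unique(element), names(radii))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (length(fragment) != n || length(ghost) != n) {
    stop("fragment and ghost must have one entry per atom", call. = FALSE)
  }
  g <- structure(list(element = element, coords = coords,
                      fragment = fragment, ghost = ghost,
                      comment = as.character(comment)[1]),
                 class = "led_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  f <- sort(unique(g$fragment))
  if (!identical(f, seq_along(f))) {
    stop("fragment ids must form a contiguous set 1..F (got: ",
         paste(f, collapse = ","), ")", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.led_geometry <- function(x, ...) {
  cat(sprintf("<led_geometry> %d atoms, %d fragment(s)%s\n",
              n_atoms(x), n_fragments(x),
              if (any(x$ghost)) sprintf(", %d ghost atoms", sum(x$ghost)) else ""))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param geom an `led_geometry`.
#' @export
n_atoms <- function(geom) length(geom$element)

#' Number of fragments in a geometry
#' @param geom an `led_geometry`.
#' @export
n_fragments <- function(geom) if (n_atoms(geom) == 0) 0L else max(geom$fragment)

#' Extract the sub-geometry of selected fragments
#'
#' Atom order is preserved; fragment ids are kept (not renumbered).
#'
#' @param geom an `led_geometry`.
#' @param fragments integer vector of fragment ids to keep.
#' @export
subset_fragments <- function(geom, fragments) {
  keep <- geom$fragment %in% fragments
  structure(list(element = geom$element[keep],
                 coords = geom$coords[keep, , drop = FALSE],
                 fragment = geom$fragment[keep],
                 ghost = geom$ghost[keep],
                 comment = geom$comment),
            class = "led_geometry")
}

#' Read an XYZ file
#'
#' Standard XYZ: first line the atom count, second a comment, then one
#' `El x y z` line per atom. A labeled dialect is also accepted in which each
#' atom line carries a trailing integer fragment id; when labels are present
#' they populate the fragment assignment, otherwise all atoms are provisionally
#' placed in fragment 1 (run [detect_fragments()] to assign real fragments).
#'
#' @param path path to the XYZ file.
#' @return An `led_geometry`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("XYZ format error: file too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ format error: first line is not an atom count",
                     call. = FALSE)
  comment <- if (length(lines) >= 2) lines[2] else ""
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop(sprintf("XYZ format error: declared %d atoms but found %d lines",
                 n, length(body)), call. = FALSE)
  }
  body <- body[seq_len(n)]
  toks <- strsplit(trimws(body), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 4)) {
    stop("XYZ format error: atom line with fewer than 4 fields", call. = FALSE)
  }
  element <- vapply(toks, `[[`, "", 1)
  coords <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(!is.finite(coords))) {
    stop("XYZ format error: non-numeric coordinate", call. = FALSE)
  }
  labeled <- all(nf >= 5)
  fragment <- NULL
  if (labeled) {
    lab <- suppressWarnings(vapply(toks, function(tk) as.numeric(tk[5]),
                                   numeric(1)))
    if (all(is.finite(lab)) && all(lab == round(lab))) fragment <- as.integer(lab)
  }
  if (!is.null(fragment)) {
    # relabel to contiguous 1..F preserving the file's label order of first
    # appearance by lowest atom index
    fragment <- match(fragment, sort(unique(fragment)))
  }
  geometry(element, coords, fragment = fragment, comment = comment)
}

#' Write an XYZ file
#'
#' @param geom an `led_geometry`.
#' @param path output path.
#' @param labeled when `TRUE`, append each atom's fragment id as a trailing
#'   integer column (the labeled dialect read back by [read_xyz()]).
#' @param digits decimal places for coordinates.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path, labeled = FALSE, digits = 6) {
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6, digits, digits + 6, digits, digits + 6, digits)
  body <- sprintf(fmt, geom$element,
                  geom$coords[, 1], geom$coords[, 2], geom$coords[, 3])
  if (labeled) body <- sprintf("%s %d", body, geom$fragment)
  writeLines(c(as.character(n_atoms(geom)), geom$comment, body), path)
  invisible(path)
}
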