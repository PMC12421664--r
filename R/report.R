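# Reporting: CSV-workbook export of matrix sets, diverging heat maps with the
# standard overlay boxes, and the YAML-driven end-to-end pipeline.

#' Export a matrix set as a CSV workbook
#'
#' Writes one CSV per component (full precision) plus a `metadata.csv`
#' describing provenance (layout, body order, BSSE mode, partitioner scheme,
#' extrapolation history) into `dir`. Absent cells are written as empty cells,
#' never zeros, so downstream sums are unaffected. [read_matrix_set()]
#' reverses the export.
#'
#' @param ms an `led_matrix_set`.
#' @param dir output directory (created if needed).
#' @param components which components to write (default: all canonical ones
#'   present, plus the elprep ref/corr split).
#' @return Character vector of written file paths, invisibly.
#' @export
export_matrices <- function(ms, dir, components = names(ms$components)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cc in components) {
    m <- ms$components[[cc]]
    m[ms$absent] <- NA
    df <- as.data.frame(m)
    names(df) <- ms$fragment_labels
    out <- cbind(fragment = ms$fragment_labels, df)
    p <- file.path(dir, paste0(cc, ".csv"))
    utils::write.csv(out, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  meta <- data.frame(
    key = c("layout", "body_order", "bsse_corrected", "scheme", "unit",
            "fragment_labels", "subsystem_of", "provenance"),
    value = c(ms$layout, ms$body_order, as.character(ms$bsse_corrected),
              if (is.null(ms$scheme)) "" else ms$scheme, "kcal/mol",
              paste(ms$fragment_labels, collapse = " "),
              paste(ms$subsystem_of, collapse = " "),
              paste(ms$provenance, collapse = " | ")))
  mp <- file.path(dir, "metadata.csv")
  utils::write.csv(meta, mp, row.names = FALSE)
  invisible(c(paths, mp))
}

#' Read back a CSV-workbook matrix set
#'
#' @param dir directory written by [export_matrices()].
#' @return An `led_matrix_set` (empty cells become the absent mask).
#' @export
read_matrix_set <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  val <- stats::setNames(as.character(meta$value), meta$key)
  labs <- as.integer(strsplit(val["fragment_labels"], " ")[[1]])
  sub_of <- as.integer(strsplit(val["subsystem_of"], " ")[[1]])
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), "metadata.csv")
  comps <- list()
  absent <- NULL
  for (fn in files) {
    df <- utils::read.csv(file.path(dir, fn), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(labs, labs)
    if (is.null(absent)) absent <- is.na(m)
    m[is.na(m)] <- 0
    comps[[sub("\\.csv$", "", fn)]] <- m
  }
  order_known <- intersect(c("total", "elprep", "elprep_ref", "elprep_corr",
                             "elstat", "exch", "no_disp", "disp", "solv"),
                           names(comps))
  comps <- comps[c(order_known, setdiff(names(comps), order_known))]
  new_matrix_set(unname(val["layout"]), comps, labs, sub_of,
                 unname(as.logical(val["bsse_corrected"])),
                 unname(val["body_order"]), absent,
                 scheme = if (nzchar(val["scheme"])) unname(val["scheme"]),
                 provenance = unname(val["provenance"]))
}

#' Heat-map rendering options
#'
#' @param annotate_cells print the value inside each cell?
#' @param value_format decimal places for annotations (display default 2).
#' @param overlay_boxes draw the layout's overlay boxes? Turquoise outlines
#'   the diagonal electronic-preparation cells (standard layout only), green
#'   the same-subsystem differential blocks, black the inter-subsystem
#'   submatrices. Box geometry is derived from the subsystem assignment,
#'   never user-drawn.
#' @param title plot title.
#' @return Object of class `led_heatmap_spec`.
#' @export
heatmap_spec <- function(annotate_cells = TRUE, value_format = 2,
                         overlay_boxes = TRUE, title = NULL) {
  structure(list(annotate_cells = annotate_cells,
                 value_format = value_format,
                 overlay_boxes = overlay_boxes, title = title),
            class = "led_heatmap_spec")
}

#' Overlay-box geometry for a matrix set
#'
#' Computes the rectangles drawn on a heat map, in cell units over the
#' subsystem-grouped display order (cell k spans k-0.5..k+0.5): turquoise
#' boxes around each diagonal cell (standard layout), one green box per
#' multi-fragment subsystem's diagonal block, and one black box per
#' subsystem pair spanning its inter-subsystem submatrix.
#'
#' @param ms an `led_matrix_set`.
#' @return Data frame with columns `kind`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
overlay_boxes <- function(ms) {
  ord <- order(ms$subsystem_of, ms$fragment_labels)
  sub_disp <- ms$subsystem_of[ord]
  out <- data.frame(kind = character(), xmin = numeric(), xmax = numeric(),
                    ymin = numeric(), ymax = numeric())
  if (ms$layout == "standard") {
    F <- length(ord)
    out <- rbind(out, data.frame(kind = "turquoise",
                                 xmin = seq_len(F) - 0.5,
                                 xmax = seq_len(F) + 0.5,
                                 ymin = seq_len(F) - 0.5,
                                 ymax = seq_len(F) + 0.5))
  }
  for (s in unique(sub_disp)) {
    pos <- which(sub_disp == s)
    if (length(pos) > 1) {
      out <- rbind(out, data.frame(kind = "green",
                                   xmin = min(pos) - 0.5, xmax = max(pos) + 0.5,
                                   ymin = min(pos) - 0.5, ymax = max(pos) + 0.5))
    }
  }
  subs <- unique(sub_disp)
  if (length(subs) > 1) {
    for (i in seq_len(length(subs) - 1)) {
      for (j in seq(i + 1, length(subs))) {
        pi <- which(sub_disp == subs[i]); pj <- which(sub_disp == subs[j])
        out <- rbind(out, data.frame(kind = "black",
                                     xmin = min(pj) - 0.5, xmax = max(pj) + 0.5,
                                     ymin = min(pi) - 0.5, ymax = max(pi) + 0.5))
      }
    }
  }
  out
}

#' Render a component heat map
#'
#' F x F cell grid with a diverging colour scale centred at zero: red for
#' attraction (negative energies), blue for repulsion (positive), white at
#' zero. Absent cells are drawn grey. Overlay boxes follow the layout
#' semantics (see [overlay_boxes()]). Rows/columns are displayed grouped by
#' subsystem.
#'
#' @param ms an `led_matrix_set`.
#' @param component component name (e.g. `"total"`).
#' @param spec an [heatmap_spec()].
#' @param path optional output file (PNG/SVG/PDF by extension); when given the
#'   figure is saved there.
#' @param width,height device size in inches for saving.
#' @return The ggplot object, invisibly when saving.
#' @export
render_heatmap <- function(ms, component = "total", spec = heatmap_spec(),
                           path = NULL, width = 6, height = 5) {
  if (!component %in% names(ms$components)) {
    stop("configuration error: unknown component '", component, "'",
         call. = FALSE)
  }
  ord <- order(ms$subsystem_of, ms$fragment_labels)
  m <- ms$components[[component]][ord, ord, drop = FALSE]
  ab <- ms$absent[ord, ord, drop = FALSE]
  F <- length(ord)
  df <- expand.grid(col = seq_len(F), row = seq_len(F))
  df$value <- as.vector(t(m))  # row-major walk
  df$value[as.vector(t(ab))] <- NA
  labels <- sprintf("F%d", ms$fragment_labels[ord])
  lim <- max(abs(df$value), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                                  midpoint = 0, limits = c(-lim, lim),
                                  na.value = "grey85",
                                  name = "kcal/mol") +
    ggplot2::scale_x_continuous(breaks = seq_len(F), labels = labels,
                                expand = c(0, 0)) +
    ggplot2::scale_y_reverse(breaks = seq_len(F), labels = labels,
                             expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = if (is.null(spec$title)) {
                    sprintf("%s %s LED, %s", ms$body_order, ms$layout,
                            component)
                  } else spec$title) +
    ggplot2::theme_minimal()
  if (spec$annotate_cells) {
    df$lab <- ifelse(is.na(df$value), "",
                     sprintf(paste0("%.", spec$value_format, "f"), df$value))
    p <- p + ggplot2::geom_text(ggplot2::aes(label = lab), size = 2.6,
                                data = df, inherit.aes = TRUE)
  }
  if (spec$overlay_boxes) {
    boxes <- overlay_boxes(ms)
    cols <- c(turquoise = "turquoise3", green = "green4", black = "black")
    if (nrow(boxes) > 0) {
      p <- p + ggplot2::geom_rect(
        data = boxes,
        ggplot2::aes(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
        inherit.aes = FALSE, fill = NA,
        color = cols[boxes$kind], linewidth = 0.8)
    }
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

read_and_merge <- function(path, alt_path = NULL, method_filter = TRUE,
                           log = function(...) invisible()) {
  rec <- parse_led_output(path)
  if (!is.null(alt_path)) {
    alt <- parse_led_output(alt_path)
    rec <- merge_alternative(rec, alt)
    for (p in rec$provenance) log("merged: ", p)
  }
  if (method_filter && grepl("HFLD", rec$method, fixed = TRUE)) {
    rec <- exclude_redundant_hfld(rec)
    log("HFLD filter applied to ", path)
  }
  rec
}

#' Run the full LED analysis pipeline from a config file
#'
#' Executes parse -> align -> assemble (standard + fp) -> two-body ->
#' cooperativity -> extrapolation -> export + heat maps, driven by a single
#' YAML config (the script/batch replacement for an interactive workflow).
#' Cooperativity runs automatically whenever both N-body and two-body inputs
#' are configured. A log of merged fields, HFLD exclusions and scheme choices
#' is written alongside the outputs.
#'
#' Config keys (paths relative to the config file's directory):
#' \preformatted{
#' output_dir: out            # required
#' subsystems: {K: [1,2,3], L: [4,5,6]}
#' bsse_corrected: false
#' scheme: equal              # fp elprep partitioner
#' heatmaps: true
#' nbody:
#'   supersystem: super.out
#'   subsystems: [K.out, L.out]
#'   alternatives: {super.out: super_alt.out}   # optional
#' twobody:                   # optional
#'   pairs: [...]
#'   monomers: [...]
#' extrapolation:             # optional; needs nbody_y / twobody_y blocks
#'   kind: CBS                # or CPS
#'   x: 2
#'   y: 3
#' nbody_y: { ... same shape as nbody ... }
#' twobody_y: { ... }
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param base_dir directory against which relative paths resolve (defaults
#'   to the config file's directory).
#' @return Invisibly, a named list of the assembled `led_matrix_set`s.
#' @export
run_pipeline <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  } else if (is.null(base_dir)) {
    base_dir <- getwd()
  }
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  out_dir <- rel(config$output_dir)
  if (is.null(out_dir)) stop("config error: output_dir required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "ledkit.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }

  subsystems <- mapply(subsystem_spec, names(config$subsystems),
                       config$subsystems, SIMPLIFY = FALSE)
  bsse <- isTRUE(config$bsse_corrected)
  scheme <- if (is.null(config$scheme)) "equal" else config$scheme
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  load_nbody <- function(block) {
    alt <- block$alternatives
    alt_for <- function(p) {
      a <- alt[[p]]
      if (is.null(a)) a <- alt[[basename(p)]]
      a
    }
    super <- read_and_merge(rel(block$supersystem),
                            rel(alt_for(block$supersystem)), log = log)
    parts <- lapply(block$subsystems, function(p)
      read_and_merge(rel(p), rel(alt_for(p)), log = log))
    list(super = super, parts = parts)
  }
  load_twobody <- function(block) {
    list(pairs = lapply(block$pairs, function(p) read_and_merge(rel(p), log = log)),
         monomers = lapply(block$monomers, function(p)
           read_and_merge(rel(p), log = log)))
  }

  assemble_nbody_sets <- function(block, tag) {
    nb <- stage(paste0("parse-", tag), load_nbody(block))
    std <- stage(paste0("assemble-", tag),
                 assemble_standard_nbody(nb$super, nb$parts, subsystems))
    fp <- assemble_fp_nbody(std, scheme = scheme)
    log(sprintf("%s: standard + fp assembled (scheme %s)", tag, scheme))
    list(standard = std, fp = fp, super = nb$super)
  }
  assemble_twobody_sets <- function(block, tag, reference) {
    tb <- stage(paste0("parse-", tag), load_twobody(block))
    std <- stage(paste0("assemble-", tag),
                 assemble_twobody(tb$pairs, tb$monomers, subsystems,
                                  bsse = bsse, layout = "standard",
                                  reference = reference))
    fp <- stage(paste0("assemble-", tag),
                assemble_twobody(tb$pairs, tb$monomers, subsystems,
                                 bsse = bsse, layout = "fp",
                                 reference = reference))
    list(standard = std, fp = fp)
  }

  if (!is.null(config$nbody)) {
    nb <- assemble_nbody_sets(config$nbody, "nbody")
    results$nbody_standard <- nb$standard
    results$nbody_fp <- nb$fp
    if (!is.null(config$twobody)) {
      tb <- assemble_twobody_sets(config$twobody, "twobody", nb$super)
      results$twobody_standard <- tb$standard
      results$twobody_fp <- tb$fp
      results$coop_standard <- stage("cooperativity",
                                     cooperativity(nb$standard, tb$standard))
      results$coop_fp <- stage("cooperativity",
                               cooperativity(nb$fp, tb$fp))
      log("cooperativity analysis performed (nbody - twobody)")
    }
    if (!is.null(config$extrapolation)) {
      ex <- config$extrapolation
      params <- extrapolation_params(toupper(ex$kind), ex$x, ex$y,
                                     alpha = ex$alpha, beta = ex$beta,
                                     F = if (is.null(ex$f)) 1.5 else ex$f)
      nb_y <- assemble_nbody_sets(config$nbody_y, "nbody-y")
      results$nbody_standard_extrap <- stage("extrapolate",
        extrapolate_matrixset(nb$standard, nb_y$standard, params))
      results$nbody_fp_extrap <- stage("extrapolate",
        extrapolate_matrixset(nb$fp, nb_y$fp, params))
      log(sprintf("%s(%s/%s) extrapolation applied", params$kind,
                  params$X, params$Y))
    }
  }

  for (nm in names(results)) {
    export_matrices(results[[nm]], file.path(out_dir, nm))
    if (isTRUE(config$heatmaps)) {
      render_heatmap(results[[nm]], "total",
                     path = file.path(out_dir, paste0(nm, "_total.png")))
    }
  }
  log(sprintf("wrote %d matrix set(s) to %s", length(results), out_dir))
  invisible(results)
}
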