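# 2D depictions with per-atom strength highlights.
#
# Output is a standalone SVG document built deterministically from the
# record, its strengths and the depiction spec: donor hydrogens get a
# white-to-red highlight, acceptor atoms a white-to-blue one, with
# intensity monotone in strength and optional 2-decimal labels.

#' Depiction options
#'
#' @param mode Which strengths to highlight: `"donor"`, `"acceptor"` or
#'   `"both"`.
#' @param scale_max Strength mapped to full colour intensity. The default
#'   1.5 keeps the water reference (1.0) visibly below saturation; the
#'   scale is global so depictions of different molecules are comparable.
#' @param annotate Add numeric labels (2 decimals).
#' @return A list of class `depiction_spec`.
#' @export
depiction_spec <- function(mode = c("both", "donor", "acceptor"),
                           scale_max = 1.5, annotate = TRUE) {
  mode <- match.arg(mode)
  stopifnot(scale_max > 0)
  structure(list(mode = mode, scale_max = scale_max,
                 annotate = isTRUE(annotate)), class = "depiction_spec")
}

# monotone white -> (red | blue) gradient; strengths <= 0 stay white
strength_colour <- function(s, scale_max, hue = c("red", "blue")) {
  hue <- match.arg(hue)
  i <- pmin(pmax(s / scale_max, 0), 1)
  lo <- sprintf("%02x", round(255 * (1 - i)))
  if (hue == "red") paste0("#ff", lo, lo) else paste0("#", lo, lo, "ff")
}

#' Render a molecule with strength highlights as SVG
#'
#' Requires a record with 3D coordinates (the 2D layout is derived from
#' its connection table, preserving atom order). Identical inputs give
#' byte-identical documents.
#'
#' @param record A `mol_record` with coordinates.
#' @param strengths A `strength_set` for the record.
#' @param spec A [depiction_spec()].
#' @param path Output file; defaults to `<id>.svg` in the working
#'   directory.
#' @return The output path, invisibly.
#' @export
render_strengths <- function(record, strengths, spec = depiction_spec(),
                             path = paste0(record$id, ".svg")) {
  xy <- record$coords2d
  if (is.null(xy)) {
    if (is.null(record$coords)) {
      stop("depiction error: molecule '", record$id,
           "' has no coordinates to lay out", call. = FALSE)
    }
    res <- run_molprep(list(list(id = record$id,
                                 molblock = as_molblock(record))),
                       embed = FALSE, minimise = FALSE, preserve = TRUE,
                       layout2d = TRUE)[[1]]
    if (!isTRUE(res$ok)) {
      stop("depiction error for '", record$id, "': ", res$error,
           call. = FALSE)
    }
    xy <- do.call(rbind, lapply(res$coords2d, unlist))
  }
  w <- 500; h <- 400; margin <- 50
  rng_x <- range(xy[, 1]); rng_y <- range(xy[, 2])
  span <- max(diff(rng_x), diff(rng_y), 1e-6)
  sc <- (min(w, h) - 2 * margin) / span
  px <- (xy[, 1] - mean(rng_x)) * sc + w / 2
  py <- -(xy[, 2] - mean(rng_y)) * sc + h / 2

  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    w, h, w, h),
    '<rect width="100%" height="100%" fill="white"/>')

  # highlights first, under the skeleton
  hl <- character(0)
  if (spec$mode %in% c("donor", "both")) {
    for (k in seq_along(strengths$donor)) {
      i <- as.integer(names(strengths$donor))[k]
      s <- strengths$donor[[k]]
      hl <- c(hl, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="14" fill="%s" stroke="none"/>',
        px[i], py[i], strength_colour(s, spec$scale_max, "red")))
      if (spec$annotate) {
        hl <- c(hl, sprintf(
          '<text x="%.1f" y="%.1f" font-size="10" fill="#801010" text-anchor="middle">%.2f</text>',
          px[i], py[i] - 16, s))
      }
    }
  }
  if (spec$mode %in% c("acceptor", "both")) {
    for (k in seq_along(strengths$acceptor)) {
      i <- as.integer(names(strengths$acceptor))[k]
      s <- strengths$acceptor[[k]]
      hl <- c(hl, sprintf(
        '<circle cx="%.1f" cy="%.1f" r="14" fill="%s" stroke="none"/>',
        px[i], py[i], strength_colour(s, spec$scale_max, "blue")))
      if (spec$annotate) {
        hl <- c(hl, sprintf(
          '<text x="%.1f" y="%.1f" font-size="10" fill="#101080" text-anchor="middle">%.2f</text>',
          px[i], py[i] + 24, s))
      }
    }
  }
  svg <- c(svg, hl)
  for (k in seq_len(nrow(record$bonds))) {
    i <- record$bonds$i[k]; j <- record$bonds$j[k]
    svg <- c(svg, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#404040" stroke-width="1.5"/>',
      px[i], py[i], px[j], py[j]))
  }
  elem <- record$atoms$element
  lab <- which(elem != "C")
  for (i in lab) {
    svg <- c(svg, sprintf(
      '<circle cx="%.1f" cy="%.1f" r="8" fill="white"/>', px[i], py[i]),
      sprintf(
      '<text x="%.1f" y="%.1f" font-size="12" text-anchor="middle" dominant-baseline="middle">%s</text>',
      px[i], py[i], elem[i]))
  }
  svg <- c(svg, sprintf(
    '<text x="10" y="%d" font-size="11" fill="#606060">%s</text>', h - 10,
    record$id), "</svg>")
  writeLines(svg, path)
  invisible(path)
}

#' Batch depiction with an index page
#'
#' Renders one SVG per (record, strengths) pair into `dir` and writes an
#' `index.html` linking them.
#'
#' @param records List of `mol_record`.
#' @param strength_sets List of matching `strength_set`s.
#' @param dir Output directory, created if needed.
#' @param spec A [depiction_spec()].
#' @return Paths of the written SVGs, invisibly.
#' @export
render_strengths_batch <- function(records, strength_sets, dir,
                                   spec = depiction_spec()) {
  stopifnot(length(records) == length(strength_sets))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- mapply(function(r, s) {
    render_strengths(r, s, spec, file.path(dir, paste0(r$id, ".svg")))
  }, records, strength_sets)
  idx <- c("<html><body><h1>Strength depictions</h1><ul>",
           sprintf('<li><a href="%s.svg">%s</a></li>',
                   vapply(records, `[[`, character(1), "id"),
                   vapply(records, `[[`, character(1), "id")),
           "</ul></body></html>")
  writeLines(idx, file.path(dir, "index.html"))
  invisible(paths)
}
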