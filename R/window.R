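#' Transect observation window
#'
#' The observation region of a transect-based forest inventory: a union of
#' axis-aligned rectangles, one per transect, laid out in a common metric
#' frame. Transect `t` occupies `x` in `[0, lengths[t]]` (along-transect) and a
#' 50 m wide band in `y` (across-transect), with successive transect baselines
#' separated by `spacing` metres.
#'
#' @param lengths numeric vector of transect lengths in metres.
#' @param width transect width in metres (50 in the emulated survey design).
#' @param spacing distance between successive transect baselines in metres.
#' @param ids optional transect identifiers; default `T1, T2, ...`.
#' @return an object of class `transect_window`: a list with a `rectangles`
#'   data frame (`transect_id`, `xmin`, `xmax`, `ymin`, `ymax`), the window
#'   area in m^2 (`area_m2`) and hectares (`area_ha`).
#' @examples
#' w <- transect_window(c(1000, 1500))
#' window_area_ha(w)
#' @export
transect_window <- function(lengths, width = 50, spacing = 450,
                            ids = paste0("T", seq_along(lengths))) {
  stopifnot(length(lengths) >= 1, all(lengths > 0), width > 0, spacing >= width)
  y0 <- (seq_along(lengths) - 1) * spacing
  rect <- data.frame(
    transect_id = ids,
    xmin = 0, xmax = as.numeric(lengths),
    ymin = y0, ymax = y0 + width,
    stringsAsFactors = FALSE
  )
  area <- sum((rect$xmax - rect$xmin) * (rect$ymax - rect$ymin))
  structure(
    list(rectangles = rect, width = width, spacing = spacing,
         area_m2 = area, area_ha = area / 1e4),
    class = "transect_window"
  )
}

#' @export
print.transect_window <- function(x, ...) {
  cat(sprintf("Transect window: %d transect(s), width %g m, total area %.3f ha\n",
              nrow(x$rectangles), x$width, x$area_ha))
  cat(sprintf("  lengths (m): %s\n",
              paste(signif(x$rectangles$xmax - x$rectangles$xmin, 6), collapse = ", ")))
  invisible(x)
}

#' Default survey window: eight 5-8 km transects, 2005 subplots, 250.625 ha
#'
#' Eight parallel 50 m wide transects about 450 m apart whose lengths (all
#' between 5 and 8 km, multiples of 25 m) sum to 50,125 m, so the 25 m x 50 m
#' subplot grid has exactly 2005 cells and the window covers 250.625 ha.
#'
#' @return a [transect_window].
#' @export
yangambi_window <- function() {
  transect_window(c(5000, 5500, 6000, 6500, 7000, 7500, 6625, 6000))
}

#' Total window area in hectares
#' @param window a [transect_window].
#' @export
window_area_ha <- function(window) {
  stopifnot(inherits(window, "transect_window"))
  window$area_ha
}

#' Locate points in a transect window
#'
#' @param window a [transect_window].
#' @param x,y point coordinates (metres, global frame).
#' @return character vector of transect ids, `NA` for points outside every
#'   rectangle (closed boundaries).
#' @export
locate_transect <- function(window, x, y) {
  stopifnot(inherits(window, "transect_window"), length(x) == length(y))
  r <- window$rectangles
  out <- rep(NA_character_, length(x))
  for (k in seq_len(nrow(r))) {
    hit <- is.na(out) & x >= r$xmin[k] & x <= r$xmax[k] &
      y >= r$ymin[k] & y <= r$ymax[k]
    out[hit] <- r$transect_id[k]
  }
  out
}

#' Subplot grid of a transect window
#'
#' Divides each transect into full-width subplots of `length_m` metres along
#' the transect (25 m x 50 m = 0.125 ha in the emulated design). Subplot
#' membership of a stem uses half-open intervals `[lo, hi)` on both axes so a
#' boundary stem belongs to exactly one subplot.
#'
#' @param window a [transect_window].
#' @param length_m along-transect subplot length in metres.
#' @return data frame with columns `subplot_id`, `transect_id`, `cx`, `cy`
#'   (centre coordinates), `xmin`, `xmax`, `ymin`, `ymax`, `area_ha`.
#' @export
make_subplots <- function(window, length_m = 25) {
  stopifnot(inherits(window, "transect_window"), length_m > 0)
  r <- window$rectangles
  out <- vector("list", nrow(r))
  for (k in seq_len(nrow(r))) {
    n <- floor((r$xmax[k] - r$xmin[k]) / length_m + 1e-9)
    if (n < 1) stop("transect shorter than one subplot")
    x0 <- r$xmin[k] + (seq_len(n) - 1) * length_m
    out[[k]] <- data.frame(
      subplot_id = sprintf("%s_S%04d", r$transect_id[k], seq_len(n)),
      transect_id = r$transect_id[k],
      cx = x0 + length_m / 2,
      cy = (r$ymin[k] + r$ymax[k]) / 2,
      xmin = x0, xmax = x0 + length_m,
      ymin = r$ymin[k], ymax = r$ymax[k],
      area_ha = length_m * (r$ymax[k] - r$ymin[k]) / 1e4,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Assign stems to subplots
#'
#' @param stems a stem table (see [stem_table]).
#' @param subplots subplot grid from [make_subplots].
#' @return character vector of subplot ids, one per stem.
#' @export
assign_subplot <- function(stems, subplots) {
  out <- rep(NA_character_, nrow(stems))
  for (k in seq_len(nrow(subplots))) {
    hit <- is.na(out) &
      stems$x >= subplots$xmin[k] & stems$x < subplots$xmax[k] &
      stems$y >= subplots$ymin[k] & stems$y < subplots$ymax[k]
    out[hit] <- subplots$subplot_id[k]
  }
  if (anyNA(out)) {
    bad <- stems$tree_id[is.na(out)]
    stop("stems outside every subplot: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  }
  out
}
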