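# Pathway-names cloud: font size grows (monotonically) with the pathway
# representation score; the top-scoring pathways are highlighted and a
# fixed-size reference marker allows comparison across plots.

#' Cloud rendering specification
#'
#' @param size_map Monotone score-to-size map: `"sqrt"` (default; font size
#'   proportional to the square root of the score), `"log"` (log1p), or
#'   `"linear"`.
#' @param top_k_highlight How many top-scoring pathways to color. Default 5.
#' @param max_pt Font size (pt) of the top score. Default 44.
#' @param min_score Display floor: pathways at or below it are omitted.
#'   Default 0.
#' @param highlight_color,base_color Colors for highlighted / other entries.
#' @param width,height Canvas size in px.
#' @param ref_pt Constant size (pt) of the reference marker glyph. Default 14.
#' @return A list of class `ldt_cloud_spec`.
#' @export
cloud_spec <- function(size_map = c("sqrt", "log", "linear"),
                       top_k_highlight = 5L, max_pt = 44, min_score = 0,
                       highlight_color = "#c0392b", base_color = "#34495e",
                       width = 900L, height = 600L, ref_pt = 14) {
  structure(list(size_map = match.arg(size_map),
                 top_k_highlight = as.integer(top_k_highlight),
                 max_pt = max_pt, min_score = min_score,
                 highlight_color = highlight_color, base_color = base_color,
                 width = as.integer(width), height = as.integer(height),
                 ref_pt = ref_pt),
            class = "ldt_cloud_spec")
}

size_transform <- function(score, map) {
  switch(map, sqrt = sqrt(score), log = log1p(score), linear = score)
}

#' Font sizes for a set of scores
#'
#' Sizes are `max_pt * f(score) / f(max score)` with `f` the chosen monotone
#' map, so order is never inverted and equal scores get equal sizes.
#'
#' @param scores Non-negative finite scores.
#' @param spec An [cloud_spec()] object.
#' @return Numeric vector of font sizes (pt).
#' @export
cloud_font_sizes <- function(scores, spec = cloud_spec()) {
  stopifnot(all(is.finite(scores)), all(scores >= 0))
  f <- size_transform(scores, spec$size_map)
  top <- max(f)
  if (top <= 0) return(rep(0, length(scores)))
  spec$max_pt * f / top
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a pathway-names cloud as SVG
#'
#' Every pathway with a score above the display floor appears exactly once;
#' font size increases monotonically with the score; the `top_k_highlight`
#' highest-scoring pathways are colored; a fixed-size reference marker glyph
#' is drawn in the corner so clouds of different subjects can be compared.
#' Layout is a seeded spiral with bounding-box collision avoidance and is
#' deterministic given the seed.
#'
#' @param profile An `ldt_scores` data frame (columns `name`, `score`), or any
#'   data frame with those columns.
#' @param path Output SVG path.
#' @param spec An [cloud_spec()] object.
#' @param seed Layout seed. Default 1.
#' @return Invisibly, the placed entries: `name`, `score`, `font_size`,
#'   `color`, `x`, `y`.
#' @export
render_cloud <- function(profile, path, spec = cloud_spec(), seed = 1L) {
  stopifnot(all(c("name", "score") %in% names(profile)))
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  if (any(!is.finite(profile$score))) stop("scores must be finite", call. = FALSE)
  keep <- profile$score > spec$min_score
  w <- spec$width; h <- spec$height
  head_svg <- sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    w, h, w, h)
  if (!any(keep)) {
    writeLines(c(head_svg,
                 sprintf('<text x="%d" y="%d" font-size="18" text-anchor="middle" fill="#666">no overrepresented pathways</text>',
                         w %/% 2L, h %/% 2L),
                 reference_marker(spec), "</svg>"), path)
    return(invisible(data.frame(name = character(0), score = numeric(0),
                                font_size = numeric(0), color = character(0),
                                x = numeric(0), y = numeric(0))))
  }
  d <- profile[keep, c("name", "score")]
  d <- d[order(-d$score, d$name), , drop = FALSE]
  d$font_size <- cloud_font_sizes(d$score, spec)
  d$color <- c(rep(spec$highlight_color, min(spec$top_k_highlight, nrow(d))),
               rep(spec$base_color, max(0L, nrow(d) - spec$top_k_highlight)))
  placed <- withr_seed(seed, place_spiral(d$name, d$font_size, w, h))
  d$x <- placed$x; d$y <- placed$y
  body <- sprintf(
    '<text x="%.1f" y="%.1f" font-size="%.2f" font-family="sans-serif" text-anchor="middle" fill="%s">%s</text>',
    d$x, d$y, d$font_size, d$color, xml_escape(d$name))
  writeLines(c(head_svg, body, reference_marker(spec), "</svg>"), path)
  invisible(d)
}

reference_marker <- function(spec) {
  sprintf('<text x="12" y="%d" font-size="%.1f" font-family="sans-serif" fill="#000" data-role="reference-marker">[X]</text>',
          spec$height - 12L, spec$ref_pt)
}

# seeded Archimedean-spiral placement with rectangle collision checks
place_spiral <- function(labels, sizes, w, h) {
  n <- length(labels)
  boxes <- matrix(NA_real_, 0L, 4L)  # x0, y0, x1, y1
  x <- numeric(n); y <- numeric(n)
  for (i in seq_len(n)) {
    bw <- 0.62 * sizes[i] * nchar(labels[i])
    bh <- 1.05 * sizes[i]
    a0 <- stats::runif(1L, 0, 2 * pi)
    t <- 0
    repeat {
      cx <- w / 2 + 0.9 * t * cos(a0 + 0.35 * t)
      cy <- h / 2 + 0.6 * t * sin(a0 + 0.35 * t)
      box <- c(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
      ok_canvas <- box[1L] >= 0 && box[2L] >= 0 && box[3L] <= w && box[4L] <= h
      collide <- nrow(boxes) > 0L &&
        any(boxes[, 1L] < box[3L] & boxes[, 3L] > box[1L] &
              boxes[, 2L] < box[4L] & boxes[, 4L] > box[2L])
      if (ok_canvas && !collide) break
      t <- t + 2
      if (t > 4 * max(w, h)) break  # give up; overlap rather than drop
    }
    boxes <- rbind(boxes, box)
    x[i] <- (box[1L] + box[3L]) / 2
    y[i] <- (box[2L] + box[4L]) / 2 + bh * 0.35  # baseline adjustment
  }
  list(x = x, y = y)
}
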