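# Minimal hand-rolled SVG primitives for the static database: text-only
# output, no graphics device or cairo dependency, byte-stable across runs.

.svg_doc <- function(width, height, body) {
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', width,
         '" height="', height, '" viewBox="0 0 ', width, ' ', height, '">\n',
         body, '</svg>\n')
}

.svg_rect <- function(x, y, w, h, fill, title = NULL) {
  t <- if (is.null(title)) "" else paste0("<title>", title, "</title>")
  sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s">%s</rect>\n',
          x, y, w, h, fill, t)
}

.svg_text <- function(x, y, s, size = 11, anchor = "middle") {
  sprintf('<text x="%.2f" y="%.2f" font-size="%d" font-family="sans-serif" text-anchor="%s">%s</text>\n',
          x, y, size, anchor, s)
}

.svg_polyline <- function(xs, ys, stroke = "#2c6fbb") {
  pts <- paste(sprintf("%.2f,%.2f", xs, ys), collapse = " ")
  sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="1.5"/>\n',
          pts, stroke)
}

.svg_line <- function(x1, y1, x2, y2, stroke = "#999", dash = NULL) {
  d <- if (is.null(dash)) "" else sprintf(' stroke-dasharray="%s"', dash)
  sprintf('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s"%s/>\n',
          x1, y1, x2, y2, stroke, d)
}

# vertical bar chart from a named integer vector
.svg_barplot <- function(values, width = 420, height = 200, fill = "#2c6fbb",
                         title = "") {
  n <- length(values)
  if (n == 0 || all(values == 0))
    return(.svg_doc(width, height, .svg_text(width / 2, height / 2, "no data")))
  m <- max(values)
  pad <- 30
  bw <- (width - 2 * pad) / n
  body <- character(0)
  if (nzchar(title)) body <- .svg_text(width / 2, 14, title, size = 12)
  for (i in seq_len(n)) {
    h <- (height - 2 * pad) * values[i] / m
    x <- pad + (i - 1) * bw
    body <- c(body,
              .svg_rect(x + bw * 0.1, height - pad - h, bw * 0.8, h, fill,
                        title = sprintf("%s: %d", names(values)[i], values[i])),
              .svg_text(x + bw / 2, height - pad + 14, names(values)[i], size = 10),
              if (values[i] > 0)
                .svg_text(x + bw / 2, height - pad - h - 4, values[i], size = 10))
  }
  .svg_doc(width, height, paste(body, collapse = ""))
}

# per-window depth trace for one sample around a CNVR
.svg_depth_plot <- function(pos, depth, cnvr_start, cnvr_end, lambda,
                            gaps = NULL, width = 520, height = 180,
                            title = "") {
  pad <- 35
  xr <- range(pos)
  xmap <- function(p) pad + (p - xr[1]) / max(1, diff(xr)) * (width - 2 * pad)
  ymax <- max(depth, lambda * 2, 1)
  ymap <- function(v) height - pad - v / ymax * (height - 2 * pad)
  body <- character(0)
  if (!is.null(gaps) && nrow(gaps) > 0)
    for (k in seq_len(nrow(gaps)))
      body <- c(body, .svg_rect(xmap(max(gaps$start[k], xr[1])), pad,
                                max(1, xmap(min(gaps$end[k], xr[2])) -
                                      xmap(max(gaps$start[k], xr[1]))),
                                height - 2 * pad, "#ddd", title = "assembly gap"))
  body <- c(body,
            .svg_rect(xmap(cnvr_start), pad, xmap(cnvr_end) - xmap(cnvr_start),
                      height - 2 * pad, "#f6d5d5", title = "CNVR span"),
            .svg_line(pad, ymap(lambda), width - pad, ymap(lambda),
                      stroke = "#777", dash = "4,3"),
            .svg_polyline(xmap(pos), ymap(depth)),
            .svg_text(width / 2, 14, title, size = 12),
            .svg_text(pad - 4, ymap(lambda) + 4, "ref", size = 9, anchor = "end"),
            .svg_text(pad, height - 8, format(xr[1], big.mark = ","), size = 9,
                      anchor = "start"),
            .svg_text(width - pad, height - 8, format(xr[2], big.mark = ","),
                      size = 9, anchor = "end"))
  .svg_doc(width, height, paste(body, collapse = ""))
}
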