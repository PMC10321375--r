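# All report files use 1-based inclusive coordinates, tab separation,
# UTF-8, Unix newlines, "." for missing, and 6-decimal floats, so two
# runs on identical input are byte-identical.

#' Write the ranked guide table
#'
#' One row per guide in rank order. Uniqueness is printed as
#' `"yes"`/`"not_unique"`; a poly-T/A run of four or more is printed as
#' a literal `"!"`; coordinates are 1-based inclusive.
#'
#' @param design A `guide_design` (from [design_for_sequence()] etc.).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_guide_table <- function(design, path) {
  cols <- c("guide_id", "target_id", "start", "end", "strand", "spacer", "pam",
            "unique", "gc", "polyTA", "hairpin", "activity", "specificity",
            "n_offtargets")
  lines <- paste(cols, collapse = "\t")
  if (nrow(design) > 0) {
    rows <- vapply(seq_len(nrow(design)), function(i) {
      paste(c(design$guide_id[i],
              design$target_id[i],
              design$start[i] + 1L,
              design$end[i],
              design$strand[i],
              design$spacer[i],
              design$pam[i],
              if (design$is_unique[i]) "yes" else "not_unique",
              fmt_num(design$gc[i]),
              if (design$poly_ta[i]) "!" else "",
              if (design$hairpin[i]) "yes" else "no",
              fmt_num(design$activity[i]),
              fmt_num(design$specificity[i]),
              design$n_offtargets[i]),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, rows)
  }
  write_lines_lf(lines, path)
}

#' Write the off-target site table
#'
#' One row per (guide, off-target hit): site coordinates (1-based
#' inclusive), aligned site sequence and PAM, mismatch count,
#' per-position mismatch detail (`pos:guide>genome`, semicolon-joined)
#' and the CFD score; sorted by guide, then `(mismatch_count, -cfd)`.
#'
#' @inheritParams write_guide_table
#' @return `path`, invisibly.
#' @export
write_offtarget_table <- function(design, path) {
  cols <- c("guide_id", "record_id", "start", "end", "strand", "site_spacer",
            "site_pam", "mismatch_count", "mismatch_positions", "cfd")
  lines <- paste(cols, collapse = "\t")
  for (i in seq_len(nrow(design))) {
    hits <- design$hits[[i]]
    if (is.null(hits) || nrow(hits) == 0) next
    rows <- vapply(seq_len(nrow(hits)), function(j) {
      det <- hits$mismatch_detail[[j]]
      mmstr <- if (nrow(det) == 0) "." else {
        paste(sprintf("%d:%s>%s", det$position, det$guide_base, det$genome_base),
              collapse = ";")
      }
      paste(c(design$guide_id[i], hits$record_id[j],
              hits$start[j] + 1L, hits$end[j], hits$strand[j],
              hits$site_spacer[j], hits$site_pam[j], hits$mismatch_count[j],
              mmstr, fmt_num(hits$cfd[j])),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, rows)
  }
  write_lines_lf(lines, path)
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Render the guide position map
#'
#' Draws the target as a horizontal axis with one glyph per guide at
#' its coordinates: strand shown by arrow orientation, uniqueness by
#' fill (unique = filled, not unique = hollow). Output is deterministic
#' SVG text (byte-identical across runs on identical input); with
#' `format = "text"` a plain-text ruler fallback is written instead.
#'
#' @param design A `guide_design`.
#' @param path Output path.
#' @param format `"svg"` (default) or `"text"`.
#' @param width SVG width in pixels (default 900).
#' @return `path`, invisibly.
#' @export
render_position_map <- function(design, path, format = c("svg", "text"),
                                width = 900) {
  format <- match.arg(format)
  tlen <- attr(design, "target_length")
  tid <- attr(design, "target_id")
  if (nrow(design) > 0 &&
      (min(design$start) < 0 || max(design$end) > tlen)) {
    abort("guide coordinates fall outside the target")
  }
  if (format == "text") {
    return(write_lines_lf(position_map_text(design, tlen, tid), path))
  }
  write_lines_lf(position_map_svg(design, tlen, tid, width), path)
}

position_map_text <- function(design, tlen, tid, cols = 80) {
  scale <- cols / tlen
  lines <- c(sprintf("target %s (%d nt)", tid, tlen),
             paste0("0", strrep("-", cols - 2), sprintf("%d", tlen)))
  for (i in seq_len(nrow(design))) {
    a <- max(1, round(design$start[i] * scale))
    b <- max(a, round(design$end[i] * scale))
    glyph <- if (design$strand[i] == "+") ">" else "<"
    bar <- paste0(strrep(" ", a - 1), strrep(glyph, b - a + 1))
    lines <- c(lines, sprintf("%-*s %s%s", cols + 1, bar, design$guide_id[i],
                              if (!design$is_unique[i]) " [not_unique]" else ""))
  }
  lines
}

position_map_svg <- function(design, tlen, tid, width = 900) {
  pad <- 50
  row_h <- 18
  axis_y <- 40
  height <- axis_y + 30 + row_h * max(1, nrow(design))
  xmap <- function(pos) pad + (width - 2 * pad) * pos / tlen
  f1 <- function(x) sprintf("%.1f", x)
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('<text x="%s" y="20" font-family="monospace" font-size="13">%s (%d nt)</text>',
            f1(pad), tid, tlen),
    sprintf('<line x1="%s" y1="%d" x2="%s" y2="%d" stroke="black" stroke-width="1.5"/>',
            f1(xmap(0)), axis_y, f1(xmap(tlen)), axis_y),
    sprintf('<text x="%s" y="%d" font-family="monospace" font-size="10">0</text>',
            f1(xmap(0) - 4), axis_y - 6),
    sprintf('<text x="%s" y="%d" font-family="monospace" font-size="10">%d</text>',
            f1(xmap(tlen) - 12), axis_y - 6, tlen)
  )
  for (i in seq_len(nrow(design))) {
    y <- axis_y + 20 + (i - 1) * row_h
    x0 <- xmap(design$start[i]); x1 <- xmap(design$end[i])
    fill <- if (design$is_unique[i]) "#2b6cb0" else "none"
    if (design$strand[i] == "+") {
      pts <- sprintf("%s,%d %s,%d %s,%d %s,%d %s,%d",
                     f1(x0), y - 5, f1(x1 - 4), y - 5, f1(x1), y,
                     f1(x1 - 4), y + 5, f1(x0), y + 5)
    } else {
      pts <- sprintf("%s,%d %s,%d %s,%d %s,%d %s,%d",
                     f1(x1), y - 5, f1(x0 + 4), y - 5, f1(x0), y,
                     f1(x0 + 4), y + 5, f1(x1), y + 5)
    }
    svg <- c(svg,
      sprintf('<polygon points="%s" fill="%s" stroke="#2b6cb0" stroke-width="1"/>',
              pts, fill),
      sprintf('<text x="%s" y="%d" font-family="monospace" font-size="10">%s%s</text>',
              f1(xmap(tlen) + 6), y + 3, design$guide_id[i],
              if (!design$is_unique[i]) " [not_unique]" else ""))
  }
  c(svg, "</svg>")
}

#' Write the full report set for a design
#'
#' Convenience wrapper producing `<prefix>.guides.tsv`,
#' `<prefix>.offtargets.tsv` and `<prefix>.<target>.map.svg`.
#'
#' @param design A `guide_design`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_report_set <- function(design, prefix) {
  tid <- attr(design, "target_id")
  files <- c(
    guides = paste0(prefix, ".guides.tsv"),
    offtargets = paste0(prefix, ".offtargets.tsv"),
    map = sprintf("%s.%s.map.svg", prefix, tid)
  )
  write_guide_table(design, files[["guides"]])
  write_offtarget_table(design, files[["offtargets"]])
  render_position_map(design, files[["map"]])
  invisible(files)
}
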