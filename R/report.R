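# Report rendering: the multi-page printable profile. Page 1 map (location,
# catchment, optional comparator district), page 2 the 35-indicator boxplot
# panel grouped by domain, page 3 the results table (also emitted as a
# sidecar CSV with unrounded values), pages 4-5 indicator definitions.
# Rendering is a pure view: it never mutates the profile.

#' Report styling
#'
#' @param catchment_fill Fill colour of catchment municipalities on the map
#'   and of the catchment glyph (default ochre).
#' @param location_col Colour of the location marker (default black).
#' @param comparator_fill Fill colour of the comparator district (default
#'   green).
#' @param national_line Colour of the national reference line (default
#'   red).
#' @param catchment_glyph,comparator_glyph Plot characters: filled circle
#'   for the catchment value, filled square for the comparator value; must
#'   differ.
#' @param page_width,page_height Page size in inches (A4 portrait).
#' @param base_cex Base font scaling.
#' @return A \code{phc_style}.
#' @export
report_style <- function(catchment_fill = "#E0A526",
                         location_col = "black",
                         comparator_fill = "#3B8C4B",
                         national_line = "red",
                         catchment_glyph = 21,
                         comparator_glyph = 22,
                         page_width = 8.27, page_height = 11.69,
                         base_cex = 0.72) {
  for (col in c(catchment_fill, location_col, comparator_fill,
                national_line))
    grDevices::col2rgb(col)  # errors on invalid colour
  if (identical(catchment_glyph, comparator_glyph))
    stop("catchment and comparator glyphs must be distinct")
  structure(list(catchment_fill = catchment_fill,
                 location_col = location_col,
                 comparator_fill = comparator_fill,
                 national_line = national_line,
                 catchment_glyph = catchment_glyph,
                 comparator_glyph = comparator_glyph,
                 page_width = page_width, page_height = page_height,
                 base_cex = base_cex),
            class = "phc_style")
}

# Catalogue labels carry typographic characters (>=, dashes, quotes) that
# the base PDF fonts lack; map them to ASCII for drawing only.
ascii_label <- function(x) {
  x <- gsub("≥", ">=", x)
  x <- gsub("≤", "<=", x)
  x <- gsub("[–—]", "-", x)
  x <- gsub("[“”]", "\"", x)
  x <- gsub("[‘’]", "'", x)
  iconv(x, to = "ASCII", sub = "?")
}

# Display rounding for the PDF layer only (sidecar CSV keeps full values):
# times to whole minutes, counts to integers, percentages and the rest to
# one decimal.
display_value <- function(value, units) {
  if (is.na(value)) return("n/a")
  digits <- if (units %in% c("minutes")) 0
    else if (units %in% c("persons", "pharmacies", "EUR/year")) 0
    else 1
  formatC(round(value, digits), format = "f", digits = digits,
          big.mark = " ")
}

#' Lay out the 35-indicator boxplot panel
#'
#' Builds the panel geometry: one axis row per indicator in catalogue
#' order, grouped under the five domain headings, each row scaled to its
#' own value range. Whiskers span the full district range, the box the
#' 25-75\% quantiles with a median tick, a red line marks the national
#' value, a circle the catchment value and (when present) a square the
#' comparator district value. The returned object carries every glyph
#' position in data units and normalised axis units, so positions can be
#' inspected without a graphics device; \code{plot()} draws it.
#'
#' @param results The \code{results} data frame of a
#'   \code{\link{build_profile}} output (non-empty).
#' @param style A \code{\link{report_style}}.
#' @return A \code{phc_boxplot_panel} with a \code{rows} data frame
#'   (ranges, normalised box/glyph coordinates) and the style.
#' @export
render_boxplot_panel <- function(results, style = report_style()) {
  if (!nrow(results)) stop("results must be non-empty")
  rows <- results
  lo <- pmin(rows$minimum, rows$catchment_value, rows$national_value,
             rows$comparator_value, na.rm = TRUE)
  hi <- pmax(rows$maximum, rows$catchment_value, rows$national_value,
             rows$comparator_value, na.rm = TRUE)
  span <- hi - lo
  pad <- ifelse(is.finite(span) & span > 0, span * 0.05,
                pmax(abs(hi), 1) * 0.1)
  axis_lo <- lo - pad
  axis_hi <- hi + pad
  norm <- function(v) (v - axis_lo) / (axis_hi - axis_lo)
  panel_rows <- data.frame(
    indicator_id = rows$indicator_id, label = rows$label,
    domain = rows$domain, units = rows$units,
    axis_lo = axis_lo, axis_hi = axis_hi,
    minimum = rows$minimum, q25 = rows$q25, median = rows$median,
    q75 = rows$q75, maximum = rows$maximum,
    national_value = rows$national_value,
    circle_x = rows$catchment_value,
    square_x = rows$comparator_value,
    min_norm = norm(rows$minimum), q25_norm = norm(rows$q25),
    median_norm = norm(rows$median), q75_norm = norm(rows$q75),
    max_norm = norm(rows$maximum),
    national_norm = norm(rows$national_value),
    circle_norm = norm(rows$catchment_value),
    square_norm = norm(rows$comparator_value),
    stringsAsFactors = FALSE)
  structure(list(rows = panel_rows,
                 domain_order = unique(rows$domain), style = style),
            class = "phc_boxplot_panel")
}

#' @export
print.phc_boxplot_panel <- function(x, ...) {
  cat("Indicator boxplot panel:", nrow(x$rows), "indicator rows,",
      length(x$domain_order), "domain groups\n")
  invisible(x)
}

#' @export
plot.phc_boxplot_panel <- function(x, ...) {
  rows <- x$rows
  st <- x$style
  # vertical slots: one per indicator plus one header per domain group
  slots <- nrow(rows) + length(x$domain_order)
  graphics::par(mar = c(1.5, 16, 2.5, 5.5))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(slots + 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "", ...)
  y <- 0
  cex <- st$base_cex
  for (d in x$domain_order) {
    y <- y + 1
    graphics::mtext(d, side = 2, at = y, las = 1, line = 15,
                    adj = 0, cex = cex * 1.05, font = 2)
    idx <- which(rows$domain == d)
    for (i in idx) {
      y <- y + 1
      r <- rows[i, ]
      graphics::mtext(strtrim(ascii_label(r$label), 58), side = 2, at = y, las = 1,
                      line = 14.5, adj = 0, cex = cex * 0.82)
      graphics::segments(r$min_norm, y, r$max_norm, y, col = "grey30")
      graphics::rect(r$q25_norm, y - 0.3, r$q75_norm, y + 0.3,
                     col = "grey85", border = "grey30")
      graphics::segments(r$median_norm, y - 0.3, r$median_norm, y + 0.3,
                         lwd = 2, col = "grey10")
      if (!is.na(r$national_norm))
        graphics::segments(r$national_norm, y - 0.42, r$national_norm,
                           y + 0.42, col = st$national_line, lwd = 1.6)
      if (!is.na(r$square_norm))
        graphics::points(r$square_norm, y, pch = st$comparator_glyph,
                         bg = st$comparator_fill, cex = 1.0)
      if (!is.na(r$circle_norm))
        graphics::points(r$circle_norm, y, pch = st$catchment_glyph,
                         bg = st$catchment_fill, cex = 1.0)
      graphics::mtext(display_value(r$circle_x, r$units), side = 4,
                      at = y, las = 1, line = 0.3, cex = cex * 0.8)
    }
  }
  graphics::mtext("district distribution (range, quartiles, median) | red: national value | circle: catchment | square: comparator",
                  side = 1, line = 0.3, cex = cex * 0.8)
  invisible(x)
}

draw_map_page <- function(profile, country, style) {
  mun <- country$municipalities
  members <- names(profile$catchment$members)
  comp <- profile$request$comparator_district_id
  graphics::par(mar = c(2, 2, 3, 1))
  graphics::plot(mun$x / 1000, mun$y / 1000, pch = 16, cex = 0.3,
                 col = "grey70", asp = 1, xlab = "km", ylab = "km",
                 main = sprintf("Location %s and its %g-minute catchment area",
                                profile$request$location_id,
                                profile$request$cutoff_minutes))
  if (!is.null(comp)) {
    idx <- mun$district_id == comp
    graphics::points(mun$x[idx] / 1000, mun$y[idx] / 1000, pch = 16,
                     cex = 0.55, col = style$comparator_fill)
  }
  idx <- mun$municipality_id %in% members
  graphics::points(mun$x[idx] / 1000, mun$y[idx] / 1000, pch = 16,
                   cex = 0.7, col = style$catchment_fill)
  loc <- mun[mun$municipality_id == profile$request$location_id, ]
  graphics::points(loc$x / 1000, loc$y / 1000, pch = 16, cex = 1.2,
                   col = style$location_col)
  leg <- c("location", "catchment municipality")
  cols <- c(style$location_col, style$catchment_fill)
  if (!is.null(comp)) {
    leg <- c(leg, paste("comparator district", comp))
    cols <- c(cols, style$comparator_fill)
  }
  graphics::legend("topleft", legend = c(leg, "other municipality"),
                   col = c(cols, "grey70"), pch = 16, bty = "n",
                   cex = 0.8)
}

draw_table_page <- function(profile, style) {
  r <- profile$results
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(nrow(r) + 3, 0),
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Indicator results and absolute values for the catchment area")
  cex <- style$base_cex * 0.85
  cols <- c(label = 0.00, value = 0.56, absolute = 0.68, national = 0.80,
            rank = 0.89, comparator = 0.95)
  head <- c("Indicator", "Catchment", "Absolute", "National", "Rank",
            "Comparator")
  graphics::text(cols, 0, head, adj = c(0, 0.5), cex = cex, font = 2)
  graphics::segments(0, 0.5, 1, 0.5)
  for (i in seq_len(nrow(r))) {
    y <- i + 0.5
    absval <- if (!is.na(r$absolute_numerator[i]))
      formatC(round(r$absolute_numerator[i]), format = "d",
              big.mark = " ") else ""
    vals <- c(strtrim(ascii_label(r$label[i]), 72),
              display_value(r$catchment_value[i], r$units[i]),
              absval,
              display_value(r$national_value[i], r$units[i]),
              if (is.na(r$rank[i])) "n/a" else as.character(r$rank[i]),
              if (is.na(r$comparator_value[i])) "" else
                display_value(r$comparator_value[i], r$units[i]))
    graphics::text(cols, y, vals, adj = c(0, 0.5), cex = cex)
  }
  graphics::mtext(paste("Ranks are among the political districts; 1 = most favourable.",
                        "'n/a': value not computable for this region."),
                  side = 1, line = 0, cex = cex * 0.9)
}

draw_definition_pages <- function(profile, catalogue, style) {
  defs <- catalogue$definitions
  half <- ceiling(nrow(defs) / 2)
  chunks <- list(seq_len(half), seq(half + 1, nrow(defs)))
  for (chunk in chunks) {
    graphics::par(mar = c(1, 1, 3, 1))
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(1, 0), axes = FALSE,
                   xlab = "", ylab = "", main = "Indicator definitions")
    cex <- style$base_cex * 0.85
    y <- 0.01
    for (i in chunk) {
      graphics::text(0, y, sprintf("%d. %s [%s]", i,
                                   strtrim(ascii_label(defs$label[i]), 80),
                                   defs$units[i]),
                     adj = c(0, 1), cex = cex, font = 2)
      y <- y + 0.022
      for (line in strwrap(ascii_label(defs$definition_text[i]), width = 110)) {
        graphics::text(0.02, y, line, adj = c(0, 1), cex = cex * 0.92)
        y <- y + 0.018
      }
      y <- y + 0.008
    }
  }
}

#' Render a profile as a multi-page PDF report
#'
#' Writes the printable report: page 1 map (all municipalities, catchment
#' highlighted, location marked, comparator district shaded when
#' requested), page 2 the indicator boxplot panel, page 3 the results
#' table, pages 4-5 indicator definitions. The page-3 table is also
#' written as a sidecar CSV holding the exact (unrounded) profile values;
#' display rounding happens only in the PDF layer. Missing values render
#' as "n/a" and never abort rendering.
#'
#' @param profile A \code{phc_profile}.
#' @param style A \code{\link{report_style}}.
#' @param out Output PDF path.
#' @param country The \code{phc_country} the profile was built on (for the
#'   map page).
#' @param catalogue The catalogue (for the definition pages).
#' @param timestamp Optional \code{POSIXct}: stamped into the PDF metadata
#'   instead of the wall clock, making repeated renders byte-identical.
#' @return Invisibly, list with \code{pdf} and \code{csv} paths.
#' @export
render_pdf <- function(profile, style = report_style(), out, country,
                       catalogue, timestamp = NULL) {
  stopifnot(inherits(profile, "phc_profile"))
  dir <- dirname(out)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  grDevices::pdf(out, width = style$page_width, height = style$page_height,
                 onefile = TRUE, paper = "special", useDingbats = FALSE,
                 title = "Regional health care profile")
  ok <- FALSE
  tryCatch({
    draw_map_page(profile, country, style)
    plot(render_boxplot_panel(profile$results, style))
    graphics::mtext("Indicator values: catchment area vs. district distribution",
                    side = 3, line = 1, cex = 0.9, font = 2)
    draw_table_page(profile, style)
    draw_definition_pages(profile, catalogue, style)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) stop("report rendering failed")
  if (!is.null(timestamp)) normalize_pdf_dates(out, timestamp)
  csv <- sub("\\.pdf$", "", out)
  csv <- paste0(csv, "_table.csv")
  utils::write.csv(profile$results, csv, row.names = FALSE, na = "")
  invisible(list(pdf = out, csv = csv))
}

# Overwrite the device-written CreationDate/ModDate in place (same byte
# length) so renders with a frozen timestamp are byte-identical.
normalize_pdf_dates <- function(path, timestamp) {
  raw <- readBin(path, "raw", file.info(path)$size)
  stamp <- charToRaw(format(timestamp, "%Y%m%d%H%M%S"))
  for (key in c("/CreationDate (D:", "/ModDate (D:")) {
    pat <- charToRaw(key)
    starts <- which(raw == pat[1])
    for (s in starts) {
      if (s + length(pat) + 13 > length(raw)) next
      if (all(raw[s:(s + length(pat) - 1)] == pat)) {
        raw[(s + length(pat)):(s + length(pat) + 13)] <- stamp
      }
    }
  }
  writeBin(raw, path)
  invisible(path)
}

# Page count of a device-written PDF (counts page objects, not the
# /Pages tree node); scans raw bytes since streams are compressed.
pdf_page_count <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  length(grepRaw("/Type /Page[^s]", raw, all = TRUE))
}
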