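# Fixed-layout Sankey diagrams: unlike auto-optimized Sankey layouts, the
# horizontal axis is the day after admission at exactly equal intervals and
# the vertical axis is the fixed state order (scores descending, then the
# transfer and discharge labels). Link thickness encodes the per-day
# transition count.

#' Build a fixed-layout Sankey specification
#'
#' Nodes are (day, state) pairs with positive occupancy; their x position is
#' exactly `(day - 1) / (horizon - 1)` and, within a day, occupied states are
#' packed in display order with uniform gaps normalized to `[0, 1]`. Links
#' carry the per-day transition counts. An optional highlight rule marks
#' links: `"top2"` flags the links of the two largest named band categories
#' at `highlight_day`; `"bands"` annotates every link with its band path when
#' source and target share a band.
#'
#' @param counts_by_day List of `transition_counts` for consecutive days
#'   1, 2, ... from a single cohort.
#' @param highlight One of `"none"`, `"bands"`, `"top2"`.
#' @param highlight_day Day pair the `"top2"` rule applies to (default 3,
#'   the day pair used for cross-ward comparison).
#' @return An object of class `sankey_spec` with tibbles `nodes`
#'   (`day`, `state`, `x`, `y`, `occupancy`) and `links` (`day`, `source`,
#'   `target`, `value`, `highlighted`, `band_path`).
#' @export
build_sankey_spec <- function(counts_by_day,
                              highlight = c("none", "bands", "top2"),
                              highlight_day = 3L) {
  highlight <- match.arg(highlight)
  stopifnot(length(counts_by_day) >= 1,
            all(vapply(counts_by_day, inherits, logical(1), "transition_counts")))
  days <- vapply(counts_by_day, `[[`, integer(1), "day")
  if (!identical(days, seq_along(days))) {
    stop("counts must cover consecutive days starting at day 1")
  }
  totals <- vapply(counts_by_day, function(tc) sum(tc$counts), numeric(1))
  if (length(unique(totals)) != 1) {
    stop("counts do not come from a single cohort (totals differ)")
  }
  horizon <- length(days) + 1L

  occupancy <- function(d) {
    if (d <= length(days)) rowSums(counts_by_day[[d]]$counts)
    else colSums(counts_by_day[[length(days)]]$counts)
  }
  nodes <- do.call(rbind, lapply(seq_len(horizon), function(d) {
    occ <- occupancy(d)
    present <- which(occ > 0)  # already in display order
    k <- length(present)
    tibble::tibble(
      day = d,
      state = .states[present],
      x = (d - 1) / (horizon - 1),
      y = if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1),
      occupancy = as.integer(occ[present])
    )
  }))

  top2_cats <- character(0)
  if (highlight == "top2") {
    hd <- as.integer(highlight_day)
    if (hd < 1 || hd > length(days)) stop("highlight_day out of range")
    div <- diversity_from_counts(counts_by_day[[hd]]$counts,
                                 counts_by_day[[hd]]$n_cases, day = hd)
    top2_cats <- div$top2_categories
  }

  links <- do.call(rbind, lapply(seq_along(days), function(d) {
    M <- counts_by_day[[d]]$counts
    nz <- which(M > 0, arr.ind = TRUE)
    src <- .states[nz[, 1]]
    tgt <- .states[nz[, 2]]
    src_band <- classify_band(src)
    tgt_band <- classify_band(tgt)
    cat <- ifelse(src == "0" & tgt == "discharged", "zero_discharged",
           ifelse(src_band == tgt_band &
                  src_band %in% c("low", "medium", "high", "ultra_high"),
                  paste(src_band, tgt_band, sep = "_"), NA_character_))
    tibble::tibble(
      day = d,
      source = src,
      target = tgt,
      value = as.integer(M[nz]),
      highlighted = if (highlight == "top2") d == highlight_day &
                      !is.na(cat) & cat %in% top2_cats
                    else rep(FALSE, length(src)),
      band_path = if (highlight == "bands") cat else rep(NA_character_, length(src))
    )
  }))

  structure(
    list(nodes = nodes, links = links, highlight = highlight,
         horizon = horizon),
    class = "sankey_spec"
  )
}

#' @export
print.sankey_spec <- function(x, ...) {
  cat("<sankey_spec>", nrow(x$nodes), "nodes,", nrow(x$links), "links over",
      x$horizon, "days; highlight:", x$highlight, "\n")
  invisible(x)
}

#' Write a Sankey specification to disk
#'
#' `"json"` writes a lossless round-trippable serialization (see
#' [read_sankey()]). `"html"` writes a self-contained HTML page with an
#' inline SVG rendering of the fixed layout: node rectangles at the fixed
#' x/y positions with height proportional to occupancy, cubic-Bezier link
#' ribbons with thickness proportional to the transition count, highlighted
#' links in an emphasis colour, and native hover tooltips.
#'
#' @param spec A `sankey_spec`.
#' @param path Output file path.
#' @param format `"json"` or `"html"`.
#' @return `path`, invisibly.
#' @export
write_sankey <- function(spec, path, format = c("json", "html")) {
  stopifnot(inherits(spec, "sankey_spec"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      horizon = spec$horizon,
      highlight = spec$highlight,
      nodes = spec$nodes,
      links = spec$links
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  } else {
    writeLines(.sankey_html(spec), path)
  }
  invisible(path)
}

#' Read a Sankey specification written as JSON
#'
#' @param path JSON file path.
#' @return A `sankey_spec` identical to the one written.
#' @export
read_sankey <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tb <- function(x, template) {
    if (length(x) == 0 || (is.list(x) && all(lengths(x) == 0))) {
      return(template)
    }
    tibble::as_tibble(x)
  }
  nodes <- as_tb(obj$nodes, tibble::tibble(
    day = integer(0), state = character(0), x = numeric(0), y = numeric(0),
    occupancy = integer(0)))
  links <- as_tb(obj$links, tibble::tibble(
    day = integer(0), source = character(0), target = character(0),
    value = integer(0), highlighted = logical(0), band_path = character(0)))
  if (nrow(links) && is.null(links$band_path)) {
    links$band_path <- NA_character_
  }
  nodes$day <- as.integer(nodes$day)
  nodes$occupancy <- as.integer(nodes$occupancy)
  links$day <- as.integer(links$day)
  links$value <- as.integer(links$value)
  links$highlighted <- as.logical(links$highlighted)
  links$band_path <- as.character(links$band_path)
  structure(
    list(nodes = nodes, links = links, highlight = obj$highlight,
         horizon = as.integer(obj$horizon)),
    class = "sankey_spec"
  )
}

# display label for a node ("The others" per the figure convention)
.state_label <- function(s) {
  ifelse(s == "other", "The others", ifelse(s == "discharged", "discharged", s))
}

.sankey_html <- function(spec, width = 1000, height = 620) {
  margin <- 50
  iw <- width - 2 * margin
  ih <- height - 2 * margin
  total <- if (nrow(spec$links)) {
    sum(spec$links$value[spec$links$day == spec$links$day[1]])
  } else {
    1
  }
  px <- function(x) margin + x * iw
  py <- function(y) margin + y * ih
  node_h <- function(occ) pmax(2, occ / total * ih * 0.55)

  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="sans-serif" font-size="10">',
    width, height))

  if (nrow(spec$links)) {
    nd <- spec$nodes
    key <- paste(nd$day, nd$state)
    for (k in seq_len(nrow(spec$links))) {
      ln <- spec$links[k, ]
      i <- match(paste(ln$day, ln$source), key)
      j <- match(paste(ln$day + 1L, ln$target), key)
      x1 <- px(nd$x[i]); y1 <- py(nd$y[i])
      x2 <- px(nd$x[j]); y2 <- py(nd$y[j])
      xm <- (x1 + x2) / 2
      w <- max(0.5, ln$value / total * ih * 0.55)
      col <- if (isTRUE(ln$highlighted)) "#d62728" else
             switch(if (is.na(ln$band_path)) "none" else ln$band_path,
                    low_low = "#1f77b4", medium_medium = "#2ca02c",
                    high_high = "#d62728", ultra_high_ultra_high = "#9467bd",
                    zero_discharged = "#ff7f0e", "#9fb1c1")
      svg <- c(svg, sprintf(
        '<path d="M %.1f %.1f C %.1f %.1f, %.1f %.1f, %.1f %.1f" fill="none" stroke="%s" stroke-opacity="0.55" stroke-width="%.2f"><title>day %d: %s -> %s (n=%d)</title></path>',
        x1, y1, xm, y1, xm, y2, x2, y2, col, w,
        ln$day, .state_label(ln$source), .state_label(ln$target), ln$value))
    }
  }
  for (k in seq_len(nrow(spec$nodes))) {
    nd <- spec$nodes[k, ]
    h <- node_h(nd$occupancy)
    svg <- c(svg, sprintf(
      '<rect x="%.1f" y="%.1f" width="8" height="%.1f" fill="#34495e"><title>day %d, %s: %d cases</title></rect>',
      px(nd$x) - 4, py(nd$y) - h / 2, h, nd$day, .state_label(nd$state),
      nd$occupancy))
    if (nd$day == 1L || nd$day == spec$horizon) {
      svg <- c(svg, sprintf(
        '<text x="%.1f" y="%.1f" text-anchor="%s">%s</text>',
        px(nd$x) + if (nd$day == 1L) -8 else 8, py(nd$y) + 3,
        if (nd$day == 1L) "end" else "start", .state_label(nd$state)))
    }
  }
  for (d in seq_len(spec$horizon)) {
    svg <- c(svg, sprintf(
      '<text x="%.1f" y="%.1f" text-anchor="middle">%d</text>',
      px((d - 1) / (spec$horizon - 1)), height - margin / 2, d))
  }
  svg <- c(svg, "</svg>")
  c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    "<title>Nursing-demand trajectories</title></head><body>", svg,
    "</body></html>")
}
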