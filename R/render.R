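# Figure rendering. All drawing is base graphics; files are written through
# the svg() (default, deterministic bytes) or png() devices depending on the
# file extension.

open_device <- function(file, width, height) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         svg = grDevices::svg(file, width = width, height = height),
         png = grDevices::png(file, width = width * 96,
                              height = height * 96, res = 96),
         stop("unsupported output format: .", ext, " (use .svg or .png)"))
}

origin_palette <- function(origins) {
  stats::setNames(grDevices::hcl.colors(max(length(origins), 2L), "Dark 3"),
                  c(origins, if (length(origins) < 2L) "..unused.."))[origins]
}

#' Render the community-evolution timeline
#'
#' One circle per (time, branch) with area proportional to the community
#' size, dashed lines for all evolution segments, one colour per origin,
#' newborn origins labelled with their `NewC` identifiers, x axis `T1..TT`.
#'
#' @param geom A `timeline_geometry` from [assign_tracks()].
#' @param file Output path (`.svg` or `.png`), or `NULL` to draw on the
#'   current device.
#' @param main Plot title.
#' @param label_circles Draw the community label inside each circle?
#' @return The file path (invisibly), or `NULL` when drawing to the current
#'   device.
#' @export
render_timeline <- function(geom, file = NULL, main = "Community evolution",
                            label_circles = TRUE) {
  stopifnot(inherits(geom, "timeline_geometry"))
  if (nrow(geom$circles) == 0L) stop("empty geometry: nothing to draw")
  if (!is.null(file))
    open_device(file, width = 1.6 + 1.1 * geom$T,
                height = 1 + 0.55 * length(geom$ordering))
  op <- graphics::par(mar = c(3.5, 5, 2.5, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  pal <- origin_palette(geom$ordering)
  ymax <- length(geom$ordering) + BAND_HALF + 0.2
  plot(NA, xlim = c(0.7, geom$T + 0.3), ylim = c(ymax, 1 - BAND_HALF - 0.2),
       axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(geom$T), labels = paste0("T", seq_len(geom$T)),
                 lwd = 0, lwd.ticks = 1)
  graphics::axis(2, at = seq_along(geom$ordering), labels = geom$ordering,
                 las = 2, lwd = 0, lwd.ticks = 1)
  s <- geom$segments
  for (i in seq_len(nrow(s)))
    graphics::segments(s$interval[i], s$y0[i], s$interval[i] + 1L, s$y1[i],
                       lty = if (s$kind[i] == "merge-dash") 3 else 2,
                       col = pal[[s$origin0[i]]], lwd = 1.4)
  cc <- geom$circles
  graphics::symbols(cc$time, cc$y, circles = cc$radius, inches = FALSE,
                    add = TRUE, bg = grDevices::adjustcolor(pal[cc$origin], 0.85),
                    fg = pal[cc$origin])
  if (label_circles)
    graphics::text(cc$time, cc$y, cc$label, cex = 0.55, col = "white")
  invisible(file)
}

#' Render per-interval bipartite tracking maps as heatmap panels
#'
#' One matrix image per interval: rows are the communities at `t`, columns
#' the communities at `t + 1`, cell values the tracking edge weights in
#' `[0, 1]`. Edges into the dump sink are removed before plotting; a
#' community at `t` whose remaining outgoing weights sum to zero is relabelled
#' `Dump` on the axis, and newborn columns carry the `NewC` prefix.
#'
#' @param maps List of tracked (pruned, pseudo-attached) `bipartite_map`s.
#' @param file Output path (`.svg` / `.png`) or `NULL`.
#' @param panels_per_row Maximum panels per row (default 5).
#' @return The file path, invisibly.
#' @export
render_bipartite_heatmaps <- function(maps, file = NULL,
                                      panels_per_row = 5L) {
  stopifnot(length(maps) >= 1L, panels_per_row >= 1L)
  k <- length(maps)
  nr <- ceiling(k / panels_per_row)
  nc <- min(k, panels_per_row)
  if (!is.null(file)) open_device(file, width = 3.2 * nc, height = 3.2 * nr)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4.5, 4.5, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  for (m in maps) {
    A <- matrix(0, nrow = length(m$sources), ncol = length(m$targets),
                dimnames = list(m$sources, m$targets))
    if (nrow(m$edges))
      A[cbind(m$edges$source, m$edges$target)] <- m$edges$weight
    rn <- rownames(A)
    dead <- rowSums(A) == 0
    rn[dead] <- DUMP_LABEL
    cn <- colnames(A)
    if (!is.null(m$pseudo)) {
      born <- m$pseudo$target[m$pseudo$kind == "birth"]
      cn[colnames(A) %in% born] <- paste0("NewC:", cn[colnames(A) %in% born])
    }
    graphics::image(seq_len(ncol(A)), seq_len(nrow(A)), t(A)[, rev(seq_len(nrow(A))), drop = FALSE],
                    zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = paste0("clusters at T", m$t + 1L),
                    ylab = paste0("clusters at T", m$t),
                    main = sprintf("W %d->%d  (theta = %.2f)", m$t, m$t + 1L,
                                   m$theta_applied))
    graphics::axis(1, at = seq_len(ncol(A)), labels = cn, las = 2,
                   cex.axis = 0.7, lwd = 0)
    graphics::axis(2, at = rev(seq_len(nrow(A))), labels = rn, las = 2,
                   cex.axis = 0.7, lwd = 0)
    graphics::box()
  }
  invisible(file)
}

#' Render per-snapshot network-configuration panels
#'
#' One panel per snapshot (at most `panels_per_row` per row): communities are
#' drawn as discs with area proportional to node count, connected by lines
#' whose grey level encodes the inter-community edge flow normalised by the
#' busiest pair at that snapshot (darker = closer to 1).
#'
#' @param dp A [dynamic_partition()].
#' @param es An `edge_series` (one entry per snapshot; `NULL` entries are
#'   skipped with a warning).
#' @param file Output path (`.svg` / `.png`) or `NULL`.
#' @param panels_per_row Maximum panels per row (default 5).
#' @return The file path, invisibly.
#' @export
render_network_panels <- function(dp, es, file = NULL, panels_per_row = 5L) {
  dp <- as.dynamic_partition(dp)
  stopifnot(panels_per_row >= 1L)
  have <- !vapply(seq_len(dp$T), function(i)
    i > length(es) || is.null(es[[i]]), logical(1L))
  if (any(!have))
    warning("no edge data for snapshot(s) ",
            paste(which(!have), collapse = ", "), "; panel(s) skipped")
  k <- sum(have)
  if (k == 0L) stop("no snapshots with edge data")
  nr <- ceiling(k / panels_per_row)
  nc <- min(k, panels_per_row)
  if (!is.null(file)) open_device(file, width = 3 * nc, height = 3 * nr)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  for (t in which(have)) {
    s <- dp$snapshots[[t]]
    flows <- community_flows(s, es[[t]])
    n <- s$n
    ang <- if (n > 1L) 2 * pi * (seq_len(n) - 1L) / n else 0
    x <- cos(ang); y <- sin(ang)
    names(x) <- names(y) <- names(s$clusters)
    plot(NA, xlim = c(-1.6, 1.6), ylim = c(-1.6, 1.6), axes = FALSE,
         xlab = "", ylab = "", asp = 1, main = paste0("T", t))
    if (nrow(flows))
      for (i in seq_len(nrow(flows)))
        graphics::segments(x[flows$a[i]], y[flows$a[i]],
                           x[flows$b[i]], y[flows$b[i]],
                           col = grDevices::gray(1 - flows$w[i]),
                           lwd = 0.5 + 2.5 * flows$w[i])
    rad <- sqrt(lengths(s$clusters))
    rad <- rad / max(rad) * 0.3
    graphics::symbols(x, y, circles = rad, inches = FALSE, add = TRUE,
                      bg = if (n == 1L) "steelblue" else
                        grDevices::adjustcolor(
                          origin_palette(names(s$clusters)), 0.9))
    graphics::text(x * 1.35, y * 1.35, names(s$clusters), cex = 0.7)
  }
  invisible(file)
}

# inter-community edge flow at one snapshot, normalised by the busiest pair
community_flows <- function(s, edges) {
  empty <- data.frame(a = character(), b = character(), w = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) return(empty)
  memb <- rep(names(s$clusters), lengths(s$clusters))
  names(memb) <- unlist(s$clusters, use.names = FALSE)
  ca <- memb[edges$src]; cb <- memb[edges$dst]
  keep <- !is.na(ca) & !is.na(cb) & ca != cb
  if (!any(keep)) return(empty)
  a <- pmin(ca[keep], cb[keep]); b <- pmax(ca[keep], cb[keep])
  agg <- stats::aggregate(count ~ a + b,
                          data = data.frame(a = a, b = b,
                                            count = edges$count[keep],
                                            stringsAsFactors = FALSE),
                          FUN = sum)
  agg$w <- agg$count / max(agg$count)
  agg[order(agg$a, agg$b), c("a", "b", "w"), drop = FALSE]
}
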