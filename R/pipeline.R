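# End-to-end pipeline runners behind the command-line interface. Each takes
# a plain config list so the CLI stays a thin flag-to-list adapter.

#' Run the simulation pipeline
#'
#' Generates a planted benchmark (preset or random schedule), writes the
#' membership table, optional edge snapshots and the ground-truth event log
#' into `out_dir`.
#'
#' @param cfg List with fields: `out_dir`; `preset` (one of `"birthdeath"`,
#'   `"hide"`, `"mergesplit"`, `"random"`); `seed` (default 1); optional
#'   `edges` (logical; also sample planted-partition edge lists), `p_in`,
#'   `p_out`.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(cfg) {
  out_dir <- cfg$out_dir %||chr% stop("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  preset <- cfg$preset %||chr% "random"
  sched <- switch(preset,
                  birthdeath = schedule_birthdeath(seed),
                  hide = schedule_hide(seed),
                  mergesplit = schedule_mergesplit(seed),
                  random = random_schedule(seed),
                  stop("unknown preset: ", preset))
  sim <- generate_dynamic_partition(sched)
  paths <- list(memberships = file.path(out_dir, "memberships.tsv"),
                truth = file.path(out_dir, "events_truth.tsv"))
  write_memberships(sim$partition, paths$memberships)
  write_events(sim$truth, paths$truth)
  if (isTRUE(cfg$edges)) {
    es <- generate_edges(sim$partition, p_in = cfg$p_in %||% 0.3,
                         p_out = cfg$p_out %||% 0.01, seed = seed)
    paths$edges <- file.path(out_dir,
                             sprintf("edges_t%d.tsv", seq_len(sim$partition$T)))
    write_edge_snapshots(es, paths$edges)
  }
  invisible(paths)
}

#' Run the tracking pipeline
#'
#' Reads a membership table, tracks all intervals and writes the per-interval
#' edge tables (source, target, weight, retained, theta), the threshold
#' report (per-interval theta, applied theta, mu_theta) and the event log.
#'
#' @param cfg List with fields: `memberships` (path), `out_dir`; optional
#'   `rho`, `nu` (default 0.1), `growth_frac` (default 0.2), `sep`.
#' @return Invisibly, the `track_all()` result.
#' @export
run_track <- function(cfg) {
  out_dir <- cfg$out_dir %||chr% stop("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dp <- read_memberships(cfg$memberships %||chr% stop("config needs 'memberships'"),
                         sep = cfg$sep %||chr% "\t")
  tr <- track_all(dp, rho = cfg$rho, nu = cfg$nu %||% 0.1,
                  growth_frac = cfg$growth_frac %||% 0.2)
  w <- do.call(rbind, lapply(tr$maps, map_edge_table))
  utils::write.table(w[, c("t", "source", "target", "weight", "retained",
                           "theta")],
                     file.path(out_dir, "bipartite_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  thr <- data.frame(interval = seq_along(tr$thetas), theta = tr$thetas,
                    theta_applied = tr$thetas_applied,
                    mu_theta = tr$mu_theta, overridden = tr$overridden)
  utils::write.table(thr, file.path(out_dir, "thresholds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_events(tr$events, file.path(out_dir, "events.tsv"))
  invisible(tr)
}

#' Run the visualization pipeline
#'
#' From a membership table (full pipeline: tracking, lineage, layout,
#' figures) or from an existing lineage table (replay: layout and timeline
#' only), writes the lineage table, the timeline figure, the bipartite
#' heatmaps, optional network-configuration panels and a crossing report for
#' the initial and final orderings.
#'
#' @param cfg List with fields: `out_dir`; one of `memberships` or `lineage`
#'   (paths); optional `edges` (character vector of per-snapshot edge files),
#'   `rho`, `nu`, `growth_frac`, `order` (given/greedy/bruteforce; default
#'   greedy), `survivors` (named vector for [resolve_merges()]), `format`
#'   (svg/png, default svg), `panels_per_row` (default 5).
#' @return Invisibly, a list with the fit/threads, orderings and crossing
#'   counts.
#' @export
run_visualize <- function(cfg) {
  out_dir <- cfg$out_dir %||chr% stop("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- cfg$format %||chr% "svg"
  mode <- cfg$order %||chr% "greedy"
  ppr <- as.integer(cfg$panels_per_row %||% 5L)
  fp <- function(name) file.path(out_dir, paste0(name, ".", fmt))
  if (!is.null(cfg$memberships)) {
    fit <- commtrace(cfg$memberships, rho = cfg$rho, nu = cfg$nu %||% 0.1,
                     growth_frac = cfg$growth_frac %||% 0.2,
                     ordering = mode, survivor_policy = cfg$survivors)
    write_lineage_table(fit$db, file.path(out_dir, "lineage.tsv"))
    write_events(fit$events, file.path(out_dir, "events.tsv"))
    render_timeline(fit$geometry, fp("timeline"))
    render_bipartite_heatmaps(fit$maps, fp("heatmaps"),
                              panels_per_row = ppr)
    if (!is.null(cfg$edges)) {
      es <- read_edge_snapshots(cfg$edges, dp = fit$partition)
      render_network_panels(fit$partition, es, fp("network_panels"),
                            panels_per_row = ppr)
    }
    init <- fit$ordering_initial; final <- fit$ordering_final
    cr <- c(fit$crossings_initial, fit$crossings_final)
    out <- list(fit = fit)
  } else if (!is.null(cfg$lineage)) {
    db <- read_lineage_table(cfg$lineage)
    threads <- extract_threads(db)
    init <- threads$origins
    resolution <- resolve_merges(threads, init, cfg$survivors)
    final <- switch(mode,
      given = init,
      greedy = greedy_reorder(threads, init, cfg$survivors),
      bruteforce = brute_force_order(threads, init, cfg$survivors)$ordering,
      stop("unknown ordering mode: ", mode))
    geom <- assign_tracks(threads, final, resolution = resolution)
    cr <- c(count_crossovers(assign_tracks(threads, init,
                                           resolution = resolution)),
            count_crossovers(geom))
    write_lineage_table(db, file.path(out_dir, "lineage.tsv"))
    render_timeline(geom, fp("timeline"))
    out <- list(threads = threads, geometry = geom)
  } else stop("config needs 'memberships' or 'lineage'")
  report <- c(sprintf("ordering_mode\t%s", mode),
              sprintf("ordering_initial\t%s", paste(init, collapse = ",")),
              sprintf("ordering_final\t%s", paste(final, collapse = ",")),
              sprintf("crossings_initial\t%d", cr[1L]),
              sprintf("crossings_final\t%d", cr[2L]))
  writeLines(report, file.path(out_dir, "crossings.txt"))
  out$ordering_initial <- init
  out$ordering_final <- final
  out$crossings_initial <- cr[1L]
  out$crossings_final <- cr[2L]
  invisible(out)
}
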