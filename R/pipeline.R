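# Pipeline entry points tying the stages together: simulation, the
# polarity analysis, the flow analysis, and the cohort statistic. Each
# run writes its artifacts plus a manifest (config, seed, package
# version), so any run is reproducible from its manifest.

write_manifest <- function(out_dir, command, config, seed) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package = "ependyflow",
    version = as.character(utils::packageVersion("ependyflow"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Simulate a scene and/or flow video and write the artifacts
#'
#' Writes, under `out_dir`: `label.tif`, `points.csv`,
#' `truth_cells.csv`, `truth_bbs.csv` for the mosaic;
#' `flow_<regime>.tif` and `truth_flow_<regime>.csv` for each flow
#' video; `manifest.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param scene a [scene_config()], a preset name (`"wildtype"`,
#'   `"mutant"`), or NULL to skip the mosaic.
#' @param flow a [flow_config()], a regime name (`"coherent"`,
#'   `"disorganized"`), a list of either, or NULL to skip.
#' @param seed integer seed applied to configs built from preset
#'   names.
#' @return invisibly, a list of the generated objects.
#' @export
run_simulate <- function(out_dir, scene = "wildtype", flow = NULL,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  if (!is.null(scene)) {
    if (is.character(scene)) scene <- scene_preset(scene, seed = seed)
    mos <- generate_mosaic(scene)
    write_label_tiff(mos$label, file.path(out_dir, "label.tif"))
    write_points_csv(mos$points, file.path(out_dir, "points.csv"))
    utils::write.csv(mos$truth$cells,
                     file.path(out_dir, "truth_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(mos$truth$bbs,
                     file.path(out_dir, "truth_bbs.csv"),
                     row.names = FALSE)
    out$scene <- mos
  }
  if (!is.null(flow)) {
    if (is.character(flow)) flow <- as.list(flow)
    if (inherits(flow, "flow_config")) flow <- list(flow)
    out$flow <- lapply(flow, function(fc) {
      if (is.character(fc)) fc <- flow_config(regime = fc, seed = seed)
      vid <- generate_flow_video(fc)
      tag <- fc$regime
      write_stack_tiff(vid$frames,
                       file.path(out_dir, paste0("flow_", tag, ".tif")))
      utils::write.csv(vid$truth$positions,
                       file.path(out_dir,
                                 paste0("truth_flow_", tag, ".csv")),
                       row.names = FALSE)
      vid
    })
  }
  strip_cfg <- function(x) if (is.null(x)) NULL else unclass(x)
  write_manifest(out_dir, "simulate",
                 list(scene = strip_cfg(if (is.null(out$scene)) NULL
                                        else out$scene$config),
                      flow = lapply(out$flow %||% list(),
                                    function(v) unclass(v$config))),
                 seed)
  invisible(out)
}

#' Run the polarity analysis on one or two groups
#'
#' Each group is a list with `label` (path to a label TIFF or a label
#' matrix) or `polygons` (polygons CSV path or data frame), plus
#' `points` (CSV path or data frame) and `name`. Writes
#' `measurements.csv`, `summary.csv`, `td_hist.csv`, `ta_bins.csv`,
#' `fa_bins.csv`, `rose_ta.png`, `rose_fa.png` and `manifest.json`
#' under `out_dir`.
#'
#' @param groups list of one or two group descriptors.
#' @param out_dir output directory.
#' @param n_bins bins for the circular bar plots.
#' @param include_border include border-touching cells in summaries.
#' @return list with `measurements`, `summary`, `t_test`.
#' @export
run_polarity <- function(groups, out_dir = NULL, n_bins = 24,
                         include_border = FALSE) {
  meas <- lapply(groups, function(g) {
    cells <- if (!is.null(g$label)) {
      lab <- if (is.character(g$label)) read_label_tiff(g$label) else g$label
      cells_from_label(lab)
    } else if (!is.null(g$polygons)) {
      polys <- if (is.character(g$polygons)) utils::read.csv(g$polygons)
               else g$polygons
      cells_from_polygons(polys)
    } else stop("group needs `label` or `polygons`")
    points <- if (is.character(g$points)) read_points_csv(g$points)
              else g$points
    if (nrow(points) == 0) {
      stop("empty point table",
           if (is.character(g$points)) paste0(": ", g$points) else "")
    }
    extra <- setdiff(unique(points$cell_id), cells$cell_id)
    if (length(extra)) {
      stop("point table has cell_ids absent from the cell set: ",
           paste(utils::head(extra, 10), collapse = ", "))
    }
    m <- measure_polarity(cells, points)
    m$group <- g$name %||% "group"
    m
  })
  measurements <- do.call(rbind, meas)
  summ <- summarize_cells(measurements, include_border = include_border)
  if (length(groups) < 2) {
    warning("single group: no between-group test performed")
  }
  keep <- measurements[!measurements$border | include_border, ]
  ta <- angle_sample(keep$TA[!is.na(keep$TA)], 360)
  fa <- angle_sample(keep$FA[!is.na(keep$FA)], 180)
  out <- list(measurements = measurements, summary = summ$summary,
              t_test = summ$t_test,
              td_hist = td_histogram(keep$TD),
              ta_bins = bin_angles(ta, n_bins),
              # axial plot keeps the same bin width, so half the bins
              fa_bins = bin_angles(fa, if (180 %% n_bins == 0) n_bins
                                       else n_bins %/% 2))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(measurements,
                     file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$td_hist, file.path(out_dir, "td_hist.csv"),
                     row.names = FALSE)
    utils::write.csv(out$ta_bins, file.path(out_dir, "ta_bins.csv"),
                     row.names = FALSE)
    utils::write.csv(out$fa_bins, file.path(out_dir, "fa_bins.csv"),
                     row.names = FALSE)
    if (!is.null(summ$t_test)) {
      jsonlite::write_json(summ$t_test,
                           file.path(out_dir, "t_test.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    grDevices::png(file.path(out_dir, "rose_ta.png"), 480, 480)
    rose_plot(ta, n_bins, main = "BB patch angle (TA)")
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "rose_fa.png"), 480, 480)
    rose_plot(fa, if (180 %% n_bins == 0) n_bins else n_bins %/% 2,
              main = "Feret's angle (FA)")
    grDevices::dev.off()
    write_manifest(out_dir, "polarity",
                   list(n_groups = length(groups), n_bins = n_bins,
                        include_border = include_border), NA)
  }
  out
}

#' Run the flow analysis on one or two groups
#'
#' Each group is a list with `stack` (multi-page TIFF path or a list
#' of frame matrices) or `detections` (CSV path or data frame
#' `frame, x, y`), plus `name`. With two groups, their per-track
#' movement directions are compared by Watson's two-sample U2 test.
#'
#' @param groups list of one or two group descriptors.
#' @param out_dir optional output directory (tracks and direction CSVs
#'   per group, comparison JSON, rose-plot bins).
#' @param sigma,threshold detection parameters (see
#'   [detect_particles()]).
#' @param max_disp,max_gap linking parameters (see
#'   [link_trajectories()]).
#' @param min_disp minimum net displacement for a track to contribute
#'   a direction.
#' @param method,n_permutations,seed Watson test parameters.
#' @return list with per-group `tracks` and `directions`
#'   ([angle_sample]s), and `watson` (NULL for a single group).
#' @export
run_flow <- function(groups, out_dir = NULL, sigma = 1.5,
                     threshold = 0.2, max_disp = NULL, max_gap = 0,
                     min_disp = 2,
                     method = c("permutation", "asymptotic"),
                     n_permutations = 999, seed = 1L) {
  res <- lapply(groups, function(g) {
    det <- if (!is.null(g$stack)) {
      frames <- if (is.character(g$stack)) {
        if (!file.exists(g$stack)) stop("cannot read stack: ", g$stack)
        read_stack_tiff(g$stack)
      } else g$stack
      detect_stack(frames, sigma, threshold)
    } else if (!is.null(g$detections)) {
      if (is.character(g$detections)) utils::read.csv(g$detections)
      else g$detections
    } else stop("group needs `stack` or `detections`")
    tracks <- link_trajectories(det, max_disp = max_disp,
                                max_gap = max_gap)
    list(name = g$name %||% "group", tracks = tracks,
         directions = direction_sample(tracks, min_disp,
                                       label = g$name %||% "group"))
  })
  watson <- NULL
  if (length(res) == 2) {
    watson <- compare_flow(res[[1]]$directions, res[[2]]$directions,
                           method = method,
                           n_permutations = n_permutations, seed = seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in res) {
      utils::write.csv(r$tracks,
                       file.path(out_dir,
                                 paste0("tracks_", r$name, ".csv")),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(label = r$name, angle_deg = r$directions$angles),
        file.path(out_dir, paste0("directions_", r$name, ".csv")),
        row.names = FALSE)
      utils::write.csv(bin_angles(r$directions, 24),
                       file.path(out_dir,
                                 paste0("rose_", r$name, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(watson)) {
      jsonlite::write_json(
        list(U2 = watson$U2, n = watson$n, m = watson$m,
             p_value = watson$p_value, method = watson$method,
             n_permutations = watson$n_permutations,
             seed = watson$seed),
        file.path(out_dir, "watson.json"), auto_unbox = TRUE,
        digits = NA)
    }
    write_manifest(out_dir, "flow",
                   list(sigma = sigma, threshold = threshold,
                        max_gap = max_gap, min_disp = min_disp),
                   seed)
  }
  list(groups = res, watson = watson)
}

#' Cohort allele-frequency report
#'
#' Computes the cohort minor allele frequency and the 2x2 Yates
#' chi-square against a comparison cohort.
#'
#' @param table 2x2 counts `(variant, reference)` by cohort, as a
#'   matrix or `c(a, b, c, d)` row-wise.
#' @param out optional JSON output path.
#' @return list with `chi2`, `df`, `p`, and per-cohort allele
#'   frequencies.
#' @export
run_cohort <- function(table, out = NULL) {
  x <- if (is.matrix(table)) as.numeric(t(table)) else as.numeric(table)
  chi <- yates_chi2(table)
  res <- list(chi2 = chi$chi2, df = chi$df, p = chi$p,
              af_cohort1 = x[1] / (x[1] + x[2]),
              af_cohort2 = x[3] / (x[3] + x[4]))
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
  }
  res
}
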