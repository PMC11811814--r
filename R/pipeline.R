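#' Default pipeline configuration
#'
#' A fully-specified configuration for [run_pipeline()]: a trace-level
#' simulated experiment with three replicate chambers ("mice") per
#' condition, a ROS-scavenger control condition with NOX activity
#' abolished, the fixed 10.3% classification threshold, and a small
#' gated transcriptome. Any YAML file with the same structure can be
#' loaded with [read_pipeline_config()].
#'
#' @param outdir Output directory of the run.
#' @param seed Base integer seed; per-replicate seeds are derived from it.
#' @return A nested configuration list (class `pipeline_config`).
#' @export
default_pipeline_config <- function(outdir = tempfile("dropnox_run_"),
                                    seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    image_level = FALSE,
    chamber = list(n_droplets = 2000L, droplet_volume = 5e-11,
                   droplet_radius_px = 10L, tile_grid = c(10L, 10L),
                   lambda_occupancy = 0.3),
    acquisition = list(n_frames = 6L, interval_s = 600, noise_sd = 5),
    conditions = list(
      list(name = "control", n_replicates = 3L, nox_fraction = 0.3),
      list(name = "NAC", n_replicates = 3L, nox_fraction = 0.3)),
    threshold = list(mode = "fixed", threshold_pct = 10.3,
                     n_control = 2000L),
    constants = list(igg_upper = 285),
    rna = list(enabled = TRUE, n_cells = 1000L,
               nox_positive_fraction = 0.25, noise_sd = 0.3),
    make_figures = TRUE
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_pipeline_config()] values.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_pipeline_config())
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && !is.null(base[[nm]]) && is.list(base[[nm]]) &&
          !is.null(names(upd[[nm]])))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_into(cfg, user), class = "pipeline_config")
}

derive_seed <- function(seed, i) (as.integer(seed) %% 1000000L) * 1000L + i

pipeline_stages <- c("simulate", "segment", "extract", "classify",
                     "quantify", "gate", "report")

run_path <- function(cfg, ...) file.path(cfg$outdir, paste0(...))

need_file <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing '", basename(path), "': rerun stage '", produced_by, "'",
         call. = FALSE)
  path
}

read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)

cfg_chamber <- function(cfg)
  chamber_spec(cfg$chamber$n_droplets, cfg$chamber$droplet_volume,
               cfg$chamber$droplet_radius_px, unlist(cfg$chamber$tile_grid),
               cfg$chamber$lambda_occupancy)

cfg_acq <- function(cfg)
  acquisition_spec(cfg$acquisition$n_frames, cfg$acquisition$interval_s,
                   noise_sd = cfg$acquisition$noise_sd)

cfg_constants <- function(cfg) {
  args <- cfg$constants
  args$droplet_volume <- cfg$chamber$droplet_volume
  do.call(assay_constants, args)
}

# condition x replicate grid of a config
replicate_grid <- function(cfg) {
  do.call(rbind, lapply(cfg$conditions, function(cc)
    data.frame(condition = cc$name, replicate = seq_len(cc$n_replicates),
               nox_fraction = cc$nox_fraction, stringsAsFactors = FALSE)))
}

stage_simulate <- function(cfg) {
  grid <- replicate_grid(cfg)
  chamber <- cfg_chamber(cfg); acq <- cfg_acq(cfg)
  for (i in seq_len(nrow(grid))) {
    s <- derive_seed(cfg$seed, i)
    ph <- sample_phenotypes(chamber$n_droplets, chamber$lambda_occupancy,
                            nox_fraction = grid$nox_fraction[i],
                            condition = grid$condition[i], seed = s)
    ts <- generate_trace_set(chamber, acq, ph, seed = s)
    tag <- paste0(grid$condition[i], "_", grid$replicate[i])
    write_tsv(ts$traces, run_path(cfg, "traces_", tag, ".tsv"))
    write_tsv(ts$truth, run_path(cfg, "truth_", tag, ".tsv"))
    if (isTRUE(cfg$image_level))
      generate_image_series(ts, seed = s,
                            dir = run_path(cfg, "images_", tag))
  }
  if (isTRUE(cfg$rna$enabled)) {
    rna <- generate_rna_matrix(n_cells = cfg$rna$n_cells,
                               nox_positive_fraction =
                                 cfg$rna$nox_positive_fraction,
                               noise_sd = cfg$rna$noise_sd,
                               seed = derive_seed(cfg$seed, 999L))
    utils::write.csv(rna$matrix, run_path(cfg, "rna_matrix.csv"))
    write_tsv(rna$truth, run_path(cfg, "rna_truth.tsv"))
  }
  invisible(NULL)
}

stage_segment_extract <- function(cfg) {
  grid <- replicate_grid(cfg)
  acq <- cfg_acq(cfg)
  for (i in seq_len(nrow(grid))) {
    tag <- paste0(grid$condition[i], "_", grid$replicate[i])
    if (isTRUE(cfg$image_level)) {
      imgdir <- need_file(run_path(cfg, "images_", tag), "simulate")
      imgs <- read_image_series(imgdir)
      regs <- lapply(imgs$frames, function(fr)
        segment_droplets(fr$a647,
                         radius_range = cfg$chamber$droplet_radius_px *
                           c(0.6, 1.4),
                         tile_grid = unlist(imgs$layout_json$tile_grid)))
      trk <- track_droplets(regs)
      tr <- extract_traces(trk, regs, imgs$frames, acq)
      tr$condition <- grid$condition[i]
    } else {
      tr <- read_tsv(need_file(run_path(cfg, "traces_", tag, ".tsv"),
                               "simulate"))
    }
    write_tsv(tr, run_path(cfg, "extracted_", tag, ".tsv"))
  }
  invisible(NULL)
}

resolve_threshold <- function(cfg) {
  if (identical(cfg$threshold$mode, "fixed"))
    return(fixed_threshold(cfg$threshold$threshold_pct))
  # control-derived: fit on an independently simulated probe-only chamber
  chamber <- cfg_chamber(cfg); acq <- cfg_acq(cfg)
  s <- derive_seed(cfg$seed, 998L)
  ph <- sample_phenotypes(cfg$threshold$n_control, chamber$lambda_occupancy,
                          nox_fraction = 0, igg_secretor_fraction = 0,
                          condition = "probe_only", seed = s)
  ctrl_chamber <- chamber_spec(cfg$threshold$n_control,
                               chamber$droplet_volume,
                               chamber$droplet_radius_px, chamber$tile_grid,
                               chamber$lambda_occupancy)
  ts <- generate_trace_set(ctrl_chamber, acq, ph, seed = s)
  losses <- signal_loss_table(ts$traces)
  keep <- ts$truth$droplet_id[ts$truth$n_cells >= 1]
  fit_threshold(losses[losses$droplet_id %in% keep, ])
}

stage_classify <- function(cfg) {
  grid <- replicate_grid(cfg)
  model <- resolve_threshold(cfg)
  jsonlite::write_json(unclass(model), run_path(cfg, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_len(nrow(grid))) {
    tag <- paste0(grid$condition[i], "_", grid$replicate[i])
    tr <- read_tsv(need_file(run_path(cfg, "extracted_", tag, ".tsv"),
                             "extract"))
    calls <- classify_nox(signal_loss_table(tr), model)
    info <- tr[tr$channel == "a647" & tr$frame == 1,
               c("droplet_id", "n_cells", "track_quality", "condition")]
    calls <- merge(calls, info, by = "droplet_id")
    write_tsv(calls, run_path(cfg, "calls_", tag, ".tsv"))
  }
  invisible(NULL)
}

stage_quantify <- function(cfg) {
  grid <- replicate_grid(cfg)
  constants <- cfg_constants(cfg)
  for (i in seq_len(nrow(grid))) {
    tag <- paste0(grid$condition[i], "_", grid$replicate[i])
    tr <- read_tsv(need_file(run_path(cfg, "extracted_", tag, ".tsv"),
                             "extract"))
    calls <- read_tsv(need_file(run_path(cfg, "calls_", tag, ".tsv"),
                                "classify"))
    igg <- igg_secretion_rate(tr, constants = constants, nox_calls = calls)
    lac <- lactate_secretion_rate(tr, constants = constants)
    ros <- ros_slope_table(tr, constants = constants)
    joint <- joint_phenotype_table(calls, igg, lac, ros)
    write_tsv(joint, run_path(cfg, "estimates_", tag, ".tsv"))
  }
  invisible(NULL)
}

stage_gate <- function(cfg) {
  if (!isTRUE(cfg$rna$enabled)) return(invisible(NULL))
  m <- as.matrix(utils::read.csv(
    need_file(run_path(cfg, "rna_matrix.csv"), "simulate"),
    row.names = 1, check.names = FALSE))
  ann <- annotate_cells(m)
  write_tsv(ann, run_path(cfg, "annotations.tsv"))
  rep_ <- composition_report(ann)
  for (nm in names(rep_))
    utils::write.csv(rep_[[nm]],
                     run_path(cfg, "composition_", nm, ".csv"),
                     row.names = FALSE)
  hk <- housekeeping_check(m)
  jsonlite::write_json(list(pass = hk$pass, failed = hk$failed,
                            table = hk$table),
                       run_path(cfg, "housekeeping.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_report <- function(cfg) {
  grid <- replicate_grid(cfg)
  rows <- list()
  per_cell <- list()
  for (i in seq_len(nrow(grid))) {
    tag <- paste0(grid$condition[i], "_", grid$replicate[i])
    est <- read_tsv(need_file(run_path(cfg, "estimates_", tag, ".tsv"),
                              "quantify"))
    cell <- est[est$n_cells >= 1, ]
    freq <- nox_frequency(est, est)
    sc <- cell$igg_rate[!is.na(cell$igg_rate) &
                          cell$igg_gate %in% c("igg_sc", "above_range")]
    lac <- cell$lactate_rate[!is.na(cell$lactate_rate)]
    rows[[i]] <- data.frame(
      condition = grid$condition[i], replicate = grid$replicate[i],
      n_cell_droplets = nrow(cell),
      pct_nox_pos = freq$pct_pos[freq$condition == grid$condition[i]],
      n_igg_sc = length(sc),
      median_igg_rate = if (length(sc)) stats::median(sc) else NA_real_,
      median_lactate_rate = if (length(lac)) stats::median(lac) else NA_real_,
      pct_lactate_above = if (length(lac))
        100 * mean(lac >= cfg_constants(cfg)$lactate_range[2]) else NA_real_,
      median_ros_slope = stats::median(cell$ros_slope, na.rm = TRUE),
      stringsAsFactors = FALSE)
    cell$condition <- grid$condition[i]
    per_cell[[i]] <- cell
  }
  summary <- do.call(rbind, rows)
  write_tsv(summary, run_path(cfg, "summary.csv"))

  allcells <- do.call(rbind, per_cell)
  stats_out <- list()
  if (length(unique(summary$condition)) >= 2 &&
      all(table(summary$condition) >= 2)) {
    ct <- condition_contrast(summary, value = "pct_nox_pos")
    stats_out$nox_frequency_contrast <-
      list(test = ct$test, statistic = ct$statistic, p = ct$p,
           star = ct$star)
  }
  pos <- allcells[allcells$label == "NOX_drop_pos", ]
  neg <- allcells[allcells$label == "NOX_drop_neg", ]
  if (sum(!is.na(pos$lactate_rate)) >= 2 && sum(!is.na(neg$lactate_rate)) >= 2) {
    ks <- compare_distributions(pos$lactate_rate[!is.na(pos$lactate_rate)],
                                neg$lactate_rate[!is.na(neg$lactate_rate)])
    stats_out$lactate_by_nox <- list(test = ks$test, D = ks$statistic,
                                     p = ks$p, star = ks$star)
  }
  if (sum(!is.na(pos$ros_slope)) >= 2 && sum(!is.na(neg$ros_slope)) >= 2) {
    ks <- compare_distributions(pos$ros_slope[!is.na(pos$ros_slope)],
                                neg$ros_slope[!is.na(neg$ros_slope)])
    stats_out$ros_by_nox <- list(test = ks$test, D = ks$statistic,
                                 p = ks$p, star = ks$star)
  }
  jsonlite::write_json(stats_out, run_path(cfg, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(cfg$make_figures)) {
    # every figure writes its underlying table alongside
    grDevices::pdf(run_path(cfg, "figures.pdf"), width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::boxplot(pct_nox_pos ~ condition, data = summary,
                      ylab = "% NOX-active droplets", xlab = "")
    if (any(!is.na(allcells$lactate_rate)))
      graphics::boxplot(lactate_rate ~ label, data = allcells,
                        ylab = "lactate secretion rate [amol/s]", xlab = "")
    utils::write.csv(allcells, run_path(cfg, "figure_cells.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dropnox")),
    seed = cfg$seed,
    n_replicates = nrow(grid),
    rows_summary = nrow(summary),
    files = sort(list.files(cfg$outdir)))
  jsonlite::write_json(manifest, run_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Run the droplet-assay analysis pipeline
#'
#' Chains the stages simulate, segment, extract, classify, quantify, gate
#' and report. Each stage reads its inputs from, and writes its outputs
#' to, the configured output directory, so a run can be resumed from any
#' stage; a missing upstream file stops with a message naming the stage
#' to rerun. The resolved configuration is written next to the outputs.
#'
#' @param config A `pipeline_config` list ([default_pipeline_config()]),
#'   or a path to a YAML file ([read_pipeline_config()]).
#' @param stages Stages to run, a contiguous subset of
#'   `c("simulate","segment","extract","classify","quantify","gate","report")`.
#' @param dry_run Print the stage plan and output directory without
#'   running or writing anything.
#' @return Invisibly, the summary table (when `report` ran) or `NULL`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = pipeline_stages, dry_run = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  stopifnot(inherits(cfg, "pipeline_config") || is.list(cfg))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  if (all(c("segment", "extract") %in% stages))
    stages <- setdiff(stages, "segment")  # one shared pass
  if (dry_run) {
    cat("dropnox pipeline plan (dry run):\n")
    cat("  outdir:", cfg$outdir, "\n")
    cat("  stages:", paste(stages, collapse = " -> "), "\n")
    return(invisible(NULL))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), run_path(cfg, "resolved_config.yaml"))
  out <- NULL
  for (st in stages) {
    out <- switch(st,
      simulate = stage_simulate(cfg),
      segment = ,  # segmentation and extraction share one pass
      extract = stage_segment_extract(cfg),
      classify = stage_classify(cfg),
      quantify = stage_quantify(cfg),
      gate = stage_gate(cfg),
      report = stage_report(cfg))
  }
  invisible(out)
}
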