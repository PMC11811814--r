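# shared helper: split one channel of a long trace table into per-droplet
# frame-ordered chunks (droplets with track_quality != "ok" dropped)
channel_by_droplet <- function(traces, channel) {
  x <- traces[traces$channel == channel, ]
  if (nrow(x) == 0) stop("traces contain no '", channel, "' channel")
  if (!is.null(x$track_quality)) x <- x[x$track_quality == "ok", ]
  x <- x[order(x$droplet_id, x$frame), ]
  split(x, x$droplet_id)
}

#' IgG secretion rates from bead-relocation traces
#'
#' Per frame, the relocation ratio (beadline mean over whole-droplet mean
#' in the IgG probe channel) is inverted through the calibration curve to
#' an IgG concentration, converted to molecules (`c * V * N_A`), and the
#' rate is the mean of the per-interval increases `d(molecules)/dt`.
#' Negative per-interval rates are retained before averaging; only the
#' final estimate clamps at 0.
#'
#' Gating: rate at or above the limit of detection gates `igg_sc`
#' (IgG-secreting cell, boundary included), at or above the upper
#' quantitative bound `above_range`, otherwise `below_lod`. Droplets
#' classified NOX-active in the same run get `igg_uninterpretable` and no
#' rate, since the probe's fluorophore itself is destroyed by the
#' NOX-derived oxidation. Instead of visual verification, automated flags
#' record the monotone fraction of the relocation trace and its net
#' change.
#'
#' @param traces Long trace data frame (needs the `a647` channel with
#'   `beadline_mean`); only droplets with `n_cells >= 1` and
#'   `track_quality == "ok"` are evaluated.
#' @param curve IgG relocation [calibration_curve()].
#' @param constants [assay_constants()].
#' @param nox_calls Optional data frame with `droplet_id`, `label` from
#'   [classify_nox()].
#' @return Data frame per droplet: `droplet_id`, `rate` (molecules/s; NA
#'   when uninterpretable), `in_quant_range`, `gate`, `monotone_fraction`,
#'   `relocation_change`, `n_cells`.
#' @export
igg_secretion_rate <- function(traces, curve = default_igg_calibration(),
                               constants = assay_constants(),
                               nox_calls = NULL) {
  stopifnot(inherits(curve, "calibration_curve"),
            curve$kind == "igg_relocation",
            inherits(constants, "assay_constants"))
  chunks <- channel_by_droplet(traces, "a647")
  pos_ids <- if (is.null(nox_calls)) integer(0) else
    nox_calls$droplet_id[nox_calls$label == "NOX_drop_pos"]
  V <- constants$droplet_volume
  out <- lapply(chunks, function(d) {
    if (d$n_cells[1] < 1) return(NULL)
    id <- d$droplet_id[1]
    if (any(d$droplet_mean == 0))
      return(data.frame(droplet_id = id, rate = NA_real_,
                        in_quant_range = FALSE, gate = "error_zero_signal",
                        monotone_fraction = NA_real_,
                        relocation_change = NA_real_, n_cells = d$n_cells[1]))
    reloc <- d$beadline_mean / d$droplet_mean
    if (id %in% pos_ids)
      return(data.frame(droplet_id = id, rate = NA_real_,
                        in_quant_range = FALSE, gate = "igg_uninterpretable",
                        monotone_fraction = mean(diff(reloc) > 0),
                        relocation_change = reloc[length(reloc)] - reloc[1],
                        n_cells = d$n_cells[1]))
    conc <- concentration(curve, reloc)
    molecules <- as.numeric(conc) * V * constants$avogadro
    rates <- diff(molecules) / diff(d$time_s)
    rate <- max(mean(rates), 0)
    gate <- if (rate >= constants$igg_upper) "above_range"
            else if (rate >= constants$igg_lod) "igg_sc" else "below_lod"
    data.frame(droplet_id = id, rate = rate,
               in_quant_range = rate >= constants$igg_lod &&
                 rate < constants$igg_upper,
               gate = gate,
               monotone_fraction = mean(diff(reloc) > 0),
               relocation_change = reloc[length(reloc)] - reloc[1],
               n_cells = d$n_cells[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lactate secretion rates from droplet probe traces
#'
#' Per frame, the whole-droplet lactate-probe intensity is inverted
#' through the linear calibration to a concentration, converted to an
#' amount in attomoles (`c * V`), and the rate is the mean per-interval
#' increase in amol/s (final estimate clamped at 0). Droplets with more
#' than one cell are excluded (`excluded_multicell`, no rate); rates are
#' gated against the quantitative range, with the above-range flag at the
#' upper bound (boundary included).
#'
#' @param traces Long trace data frame (needs the `lactate_probe` channel).
#' @param curve Linear lactate [calibration_curve()] (concentration in uM).
#' @param constants [assay_constants()].
#' @return Data frame per cell-containing droplet: `droplet_id`, `rate`
#'   (amol/s), `in_quant_range`, `gate` in `below_lod` / `in_range` /
#'   `above_range` / `excluded_multicell`, `n_cells`.
#' @export
lactate_secretion_rate <- function(traces,
                                   curve = default_lactate_calibration(),
                                   constants = assay_constants()) {
  stopifnot(inherits(curve, "calibration_curve"),
            curve$kind == "lactate_linear",
            inherits(constants, "assay_constants"))
  chunks <- channel_by_droplet(traces, "lactate_probe")
  V <- constants$droplet_volume
  lo <- constants$lactate_range[1]
  hi <- constants$lactate_range[2]
  out <- lapply(chunks, function(d) {
    nc <- d$n_cells[1]
    if (nc < 1) return(NULL)
    id <- d$droplet_id[1]
    if (nc > 1)
      return(data.frame(droplet_id = id, rate = NA_real_,
                        in_quant_range = FALSE, gate = "excluded_multicell",
                        n_cells = nc))
    if (any(d$droplet_mean == 0))
      return(data.frame(droplet_id = id, rate = NA_real_,
                        in_quant_range = FALSE, gate = "error_zero_signal",
                        n_cells = nc))
    conc_uM <- as.numeric(concentration(curve, d$droplet_mean))
    amol <- conc_uM * 1e-6 * V * 1e18
    rates <- diff(amol) / diff(d$time_s)
    rate <- max(mean(rates), 0)
    gate <- if (rate >= hi) "above_range"
            else if (rate < lo) "below_lod" else "in_range"
    data.frame(droplet_id = id, rate = rate,
               in_quant_range = rate >= lo && rate < hi,
               gate = gate, n_cells = nc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intracellular ROS slope of a single cell trace
#'
#' The ROS-sensitive dye signal of a cell rises while ROS are produced.
#' The slope is the average of the per-interval signal increases from the
#' first frame up to the frame where the cell signal is maximal (later
#' intervals are ignored), rescaled to a.u. per 10 min window. A maximum
#' at the first frame gives slope 0.
#'
#' @param trace Numeric cell-signal vector over >= 2 frames.
#' @param interval_s Frame interval in seconds.
#' @param window_s Reporting window in seconds (default 600 = 10 min).
#' @return Slope in a.u. per `window_s`.
#' @examples
#' ros_slope(c(100, 130, 160, 190, 220, 250), 600)  # 30 a.u./10 min
#' @export
ros_slope <- function(trace, interval_s = 600, window_s = 600) {
  trace <- as.numeric(trace)
  if (length(trace) < 2) stop("ros_slope needs >= 2 frames")
  m <- which.max(trace)
  if (m == 1) return(0)
  incr <- diff(trace[seq_len(m)]) / interval_s
  mean(incr) * window_s
}

#' ROS slopes for every cell-containing droplet of a trace table
#'
#' @param traces Long trace data frame (needs the `ros_probe` channel with
#'   `cell_mean`).
#' @param constants [assay_constants()] (supplies the reporting window).
#' @return Data frame: `droplet_id`, `ros_slope` (a.u. per window),
#'   `n_cells`.
#' @export
ros_slope_table <- function(traces, constants = assay_constants()) {
  chunks <- channel_by_droplet(traces, "ros_probe")
  out <- lapply(chunks, function(d) {
    if (d$n_cells[1] < 1 || anyNA(d$cell_mean)) return(NULL)
    dt <- diff(d$time_s)
    data.frame(droplet_id = d$droplet_id[1],
               ros_slope = ros_slope(d$cell_mean, interval_s = dt[1],
                                     window_s = constants$ros_window),
               n_cells = d$n_cells[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge per-droplet phenotypes into one table
#'
#' Joins NOX calls, IgG and lactate secretion estimates and ROS slopes on
#' `droplet_id`, carrying condition labels when present. Disjoint id sets
#' produce an empty join with a warning; partially missing ids are
#' reported via NA.
#'
#' @param nox_calls Data frame from [classify_nox()] (`droplet_id`,
#'   `x_pct`, `label`, optionally `condition`).
#' @param igg Data frame from [igg_secretion_rate()] or NULL.
#' @param lactate Data frame from [lactate_secretion_rate()] or NULL.
#' @param ros Data frame from [ros_slope_table()] or NULL.
#' @return One row per droplet present in `nox_calls`.
#' @export
joint_phenotype_table <- function(nox_calls, igg = NULL, lactate = NULL,
                                  ros = NULL) {
  out <- nox_calls
  add <- function(base, tbl, cols, suffix) {
    if (is.null(tbl)) return(base)
    keep <- tbl[, c("droplet_id", cols)]
    names(keep)[-1] <- paste0(suffix, "_", cols)
    if (length(intersect(base$droplet_id, keep$droplet_id)) == 0)
      warning("no shared droplet ids with ", suffix, " table")
    merge(base, keep, by = "droplet_id", all.x = TRUE)
  }
  out <- add(out, igg, c("rate", "gate"), "igg")
  out <- add(out, lactate, c("rate", "gate"), "lactate")
  out <- add(out, ros, "ros_slope", "ros")
  names(out)[names(out) == "ros_ros_slope"] <- "ros_slope"
  out[order(out$droplet_id), ]
}
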