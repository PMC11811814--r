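#' Sample per-droplet ground-truth phenotypes
#'
#' Draws the hidden per-droplet state that the forward trace model renders:
#' Poisson cell occupancy, NOX activity with a terminal percent loss of the
#' oxidation-sensitive dye, IgG and lactate secretion rates and an
#' intracellular ROS slope. Only cell-containing droplets can be NOX-active
#' or secrete. The `"NAC"` condition (ROS scavenger control) forces NOX
#' activity off in every droplet; other condition strings are labels only.
#'
#' Defaults describe a responding B-cell sample: about 30% of cells
#' NOX-active with a mean terminal dye loss of 20%, roughly a third of
#' cells secreting IgG at rates across the quantitative range, lactate
#' rates spread over 0.1-0.8 amol/s, and ROS slopes higher in NOX-active
#' cells.
#'
#' @param n Number of droplets.
#' @param lambda_occupancy Mean cells per droplet (Poisson).
#' @param nox_fraction Probability that a cell-containing droplet is
#'   NOX-active.
#' @param terminal_loss_mean,terminal_loss_sd Gaussian parameters (percent,
#'   truncated to `[5, 95]`) of the terminal dye loss of NOX-active
#'   droplets.
#' @param igg_secretor_fraction Probability that a cell secretes IgG.
#' @param igg_range Uniform range of IgG secretion rates (molecules/s) for
#'   secreting cells.
#' @param lactate_range Uniform range of lactate secretion rates (amol/s).
#' @param ros_range_neg,ros_range_pos Uniform ROS-slope ranges
#'   (a.u. per 10 min) for NOX-inactive and NOX-active cells.
#' @param condition Condition label; `"NAC"` disables all NOX activity.
#' @param seed Integer seed; the draw is fully determined by it.
#' @return A data frame with one row per droplet: `n_cells`, `nox_active`,
#'   `terminal_loss_pct`, `igg_rate`, `lactate_rate`, `ros_slope`,
#'   `condition`.
#' @export
sample_phenotypes <- function(n,
                              lambda_occupancy = 0.3,
                              nox_fraction = 0.3,
                              terminal_loss_mean = 20,
                              terminal_loss_sd = 5,
                              igg_secretor_fraction = 0.3,
                              igg_range = c(9, 285),
                              lactate_range = c(0.1, 0.8),
                              ros_range_neg = c(5, 20),
                              ros_range_pos = c(20, 60),
                              condition = "control",
                              seed = 1L) {
  stopifnot(n > 0, lambda_occupancy >= 0,
            nox_fraction >= 0, nox_fraction <= 1)
  set.seed(seed)
  n_cells <- stats::rpois(n, lambda_occupancy)
  has_cell <- n_cells >= 1
  nox <- has_cell & stats::runif(n) < nox_fraction
  if (identical(condition, "NAC")) nox[] <- FALSE
  loss <- numeric(n)
  loss[nox] <- pmin(pmax(stats::rnorm(sum(nox), terminal_loss_mean,
                                      terminal_loss_sd), 5), 95)
  secretes <- has_cell & stats::runif(n) < igg_secretor_fraction
  igg <- numeric(n)
  igg[secretes] <- stats::runif(sum(secretes), igg_range[1], igg_range[2])
  lactate <- numeric(n)
  lactate[has_cell] <- stats::runif(sum(has_cell),
                                    lactate_range[1], lactate_range[2])
  ros <- numeric(n)
  ros[has_cell & !nox] <- stats::runif(sum(has_cell & !nox),
                                       ros_range_neg[1], ros_range_neg[2])
  ros[nox] <- stats::runif(sum(nox), ros_range_pos[1], ros_range_pos[2])
  data.frame(n_cells = n_cells, nox_active = nox, terminal_loss_pct = loss,
             igg_rate = igg, lactate_rate = lactate, ros_slope = ros,
             condition = condition, stringsAsFactors = FALSE)
}

# droplet centres on a jittered grid spanning the tile array; returns the
# layout table plus canvas geometry as attributes. Consumes RNG (jitter).
chamber_layout <- function(chamber) {
  n <- chamber$n_droplets
  r <- chamber$droplet_radius_px
  gap <- max(4L, r)
  spacing <- 2L * r + gap
  jmax <- max(0L, gap %/% 2L - 1L)
  ncol_d <- ceiling(sqrt(n))
  nrow_d <- ceiling(n / ncol_d)
  height <- nrow_d * spacing + gap
  width <- ncol_d * spacing + gap
  idx <- seq_len(n) - 1L
  gr <- idx %/% ncol_d
  gc <- idx %% ncol_d
  jr <- if (jmax > 0) stats::runif(n, -jmax, jmax) else numeric(n)
  jc <- if (jmax > 0) stats::runif(n, -jmax, jmax) else numeric(n)
  # 0-based pixel coordinates of droplet centres
  row <- gap + r + gr * spacing + jr
  col <- gap + r + gc * spacing + jc
  seams_r <- (seq_len(chamber$tile_grid[1] - 1) / chamber$tile_grid[1]) * height
  seams_c <- (seq_len(chamber$tile_grid[2] - 1) / chamber$tile_grid[2]) * width
  near <- function(x, seams) {
    if (length(seams) == 0) return(rep(FALSE, length(x)))
    sapply(x, function(v) any(abs(v - seams) <= r + 1))
  }
  edge <- row < r + 1 | col < r + 1 | row > height - r - 2 | col > width - r - 2 |
    near(row, seams_r) | near(col, seams_c)
  out <- data.frame(droplet_id = seq_len(n), row = row, col = col,
                    radius_px = r, edge = edge)
  attr(out, "canvas") <- c(height = height, width = width)
  attr(out, "tile_grid") <- chamber$tile_grid
  out
}

#' Generate a synthetic droplet trace set with ground truth
#'
#' Forward model of the droplet assay at the trace level. Per droplet and
#' frame it produces mean intensities for four channels:
#'
#' * `a647`: the oxidation-sensitive dye / IgG probe. NOX-active droplets
#'   decay exponentially, `S(t) = S0 * exp(-k t)` with `k` chosen so the
#'   loss from the first to the last frame equals the planted terminal
#'   loss percentage; inactive droplets stay at `S0`. The beadline mean is
#'   `relocation(t) * S(t)` where the relocation ratio follows the IgG
#'   calibration curve evaluated at the accumulated secreted IgG
#'   concentration.
#' * `lactate_probe`: the linear lactate calibration evaluated at the
#'   accumulated lactate concentration.
#' * `ros_probe`: the cell-region signal rises linearly at the planted ROS
#'   slope (a.u. per 10 min).
#' * `cell_stain`: a constant per-cell stain signal.
#'
#' Every reported mean receives additive Gaussian noise of the per-channel
#' SD in `acq`. Identical `(chamber, acq, phenotypes, seed)` give
#' bit-identical output.
#'
#' @param chamber A [chamber_spec()].
#' @param acq An [acquisition_spec()].
#' @param phenotypes A phenotype data frame as from [sample_phenotypes()]
#'   with exactly `chamber$n_droplets` rows, or `NULL` to sample defaults.
#' @param seed Integer seed controlling occupancy, jitter and noise.
#' @param igg_curve,lactate_curve Forward [calibration_curve()]s.
#' @param s0_a647 First-frame A647 droplet mean (a.u.).
#' @param ros_baseline Cell ROS signal at the first frame (a.u.).
#' @param stain_level Cell-stain blob signal (a.u.).
#' @return A list of class `droplet_trace_set`:
#'   `traces` (long data frame: `droplet_id`, `frame`, `time_s`, `channel`,
#'   `droplet_mean`, `beadline_mean`, `cell_mean`, `n_cells`, `condition`,
#'   `track_quality`), `truth` (phenotypes joined to droplet ids, centroids
#'   and edge flags), `chamber`, `acq`, and the curves used.
#' @examples
#' ts <- generate_trace_set(chamber_spec(50), acquisition_spec(), seed = 7)
#' head(ts$traces)
#' @export
generate_trace_set <- function(chamber, acq, phenotypes = NULL, seed = 1L,
                               igg_curve = default_igg_calibration(),
                               lactate_curve = default_lactate_calibration(),
                               s0_a647 = 500,
                               ros_baseline = 200,
                               stain_level = 3000) {
  stopifnot(inherits(chamber, "chamber_spec"),
            inherits(acq, "acquisition_spec"))
  if (acq$n_frames < 2) stop("n_frames must be >= 2")
  n <- chamber$n_droplets
  if (is.null(phenotypes)) {
    phenotypes <- sample_phenotypes(n, chamber$lambda_occupancy, seed = seed)
  }
  stopifnot(is.data.frame(phenotypes), nrow(phenotypes) == n)
  if (any(phenotypes$igg_rate < 0) || any(phenotypes$lactate_rate < 0) ||
      any(phenotypes$ros_slope < 0))
    stop("phenotype rates must be >= 0")
  if (any(phenotypes$terminal_loss_pct < 0 |
          phenotypes$terminal_loss_pct > 100))
    stop("terminal_loss_pct must lie in [0, 100]")
  if (any(!phenotypes$nox_active & phenotypes$terminal_loss_pct != 0))
    stop("NOX-inactive droplets must have terminal_loss_pct = 0")
  if (is.null(phenotypes$condition)) phenotypes$condition <- "control"

  set.seed(seed)
  layout <- chamber_layout(chamber)
  times <- frame_times(acq)
  t_last <- times[length(times)]
  nf <- acq$n_frames
  V <- chamber$droplet_volume
  NA_CONST <- 6.02214076e23

  # per droplet x frame matrices, droplets in rows
  tt <- matrix(times, nrow = n, ncol = nf, byrow = TRUE)
  ncells <- phenotypes$n_cells

  # a647 dye decay
  k <- ifelse(phenotypes$nox_active & phenotypes$terminal_loss_pct > 0,
              -log(1 - phenotypes$terminal_loss_pct / 100) / t_last, 0)
  a647 <- s0_a647 * exp(-k * tt)
  # IgG relocation from accumulated molecules
  molecules <- ncells * phenotypes$igg_rate * tt
  reloc <- matrix(predict(igg_curve, as.vector(molecules) / (V * NA_CONST)),
                  nrow = n)
  beadline <- reloc * a647
  # lactate readout from accumulated amount (amol -> uM)
  amol <- ncells * phenotypes$lactate_rate * tt
  lact <- matrix(predict(lactate_curve, as.vector(amol) * 1e-12 / V), nrow = n)
  # ROS cell signal, linear rise per 600 s
  ros_cell <- ros_baseline + (phenotypes$ros_slope / 600) * tt
  ros_cell[ncells == 0, ] <- NA_real_
  stain_cell <- matrix(ifelse(ncells >= 1, stain_level, NA_real_),
                       nrow = n, ncol = nf)

  noisy <- function(m, channel) {
    sd <- acq$noise_sd[[channel]]
    if (sd > 0) {
      e <- matrix(stats::rnorm(length(m), 0, sd), nrow = nrow(m))
      e[is.na(m)] <- NA
      m <- m + e
    }
    pmax(m, 0)
  }
  a647_n <- noisy(a647, "a647")
  bead_n <- noisy(beadline, "a647")
  lact_n <- noisy(lact, "lactate_probe")
  ros_n <- noisy(ros_cell, "ros_probe")
  ros_drop <- noisy(matrix(150, n, nf), "ros_probe")
  stain_n <- noisy(stain_cell, "cell_stain")
  stain_drop <- noisy(matrix(20 + 30 * ncells, n, nf), "cell_stain")

  block <- function(channel, droplet_mean, beadline_mean = NULL,
                    cell_mean = NULL) {
    data.frame(
      droplet_id = rep(seq_len(n), nf),
      frame = rep(seq_len(nf), each = n),
      time_s = rep(times, each = n),
      channel = channel,
      droplet_mean = as.vector(droplet_mean),
      beadline_mean = if (is.null(beadline_mean)) NA_real_
                      else as.vector(beadline_mean),
      cell_mean = if (is.null(cell_mean)) NA_real_ else as.vector(cell_mean),
      n_cells = rep(ncells, nf),
      condition = rep(phenotypes$condition, nf),
      track_quality = "ok",
      stringsAsFactors = FALSE)
  }
  traces <- rbind(
    block("cell_stain", stain_drop, cell_mean = stain_n),
    block("lactate_probe", lact_n),
    block("ros_probe", ros_drop, cell_mean = ros_n),
    block("a647", a647_n, beadline_mean = bead_n))
  traces <- traces[order(traces$droplet_id, traces$frame), ]
  rownames(traces) <- NULL

  truth <- cbind(layout, phenotypes)
  attr(truth, "canvas") <- attr(layout, "canvas")
  attr(truth, "tile_grid") <- attr(layout, "tile_grid")

  structure(list(traces = traces, truth = truth, chamber = chamber,
                 acq = acq, igg_curve = igg_curve,
                 lactate_curve = lactate_curve,
                 render = list(s0_a647 = s0_a647, ros_baseline = ros_baseline,
                               stain_level = stain_level)),
            class = "droplet_trace_set")
}

#' @export
print.droplet_trace_set <- function(x, ...) {
  cat("Synthetic droplet trace set:", x$chamber$n_droplets, "droplets x",
      x$acq$n_frames, "frames,", length(x$acq$channels), "channels\n")
  cat("  cell-containing:", sum(x$truth$n_cells >= 1),
      "| NOX-active:", sum(x$truth$nox_active), "\n")
  invisible(x)
}

#' Generate calibration standards from a known curve
#'
#' Forward-evaluates a calibration curve at the given concentrations and
#' adds replicate Gaussian readout noise, producing the standards table a
#' calibration experiment would yield.
#'
#' @param curve A [calibration_curve()].
#' @param concentrations Standard concentrations (unit of the curve);
#'   must be non-empty and non-negative.
#' @param replicates Replicate measurements per concentration.
#' @param noise_sd Gaussian readout noise SD.
#' @param seed Integer seed.
#' @return Data frame with columns `concentration`, `readout`, `replicate`.
#' @export
generate_calibration_standards <- function(curve, concentrations,
                                           replicates = 3L, noise_sd = 0,
                                           seed = 1L) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (length(concentrations) == 0) stop("concentrations must be non-empty")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  stopifnot(replicates >= 1)
  set.seed(seed)
  conc <- rep(concentrations, each = replicates)
  readout <- predict(curve, conc) +
    stats::rnorm(length(conc), 0, noise_sd)
  data.frame(concentration = conc, readout = readout,
             replicate = rep(seq_len(replicates), length(concentrations)))
}
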