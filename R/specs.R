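#' Chamber geometry and droplet-loading specification
#'
#' Describes one 2D droplet observation chamber: how many droplets it holds,
#' their volume, their rendered radius, the image tile layout and the mean
#' Poisson cell occupancy. Defaults mirror a typical picoliter-droplet
#' chamber: 50 pL droplets imaged as a 10 x 10 tile array with a mean
#' occupancy of 0.3 cells per droplet.
#'
#' @param n_droplets Number of droplets in the chamber (> 0).
#' @param droplet_volume Droplet volume in liters. Default `5e-11` (50 pL).
#' @param droplet_radius_px Rendered droplet radius in pixels (image-level
#'   generation only).
#' @param tile_grid Integer vector `c(rows, cols)` of the image tile array.
#' @param lambda_occupancy Mean cells per droplet under Poisson loading
#'   (cell suspensions are typically loaded at lambda between 0.2 and 0.5).
#' @return An object of class `chamber_spec`.
#' @examples
#' chamber_spec(n_droplets = 1000)
#' @export
chamber_spec <- function(n_droplets,
                         droplet_volume = 5e-11,
                         droplet_radius_px = 10L,
                         tile_grid = c(10L, 10L),
                         lambda_occupancy = 0.3) {
  stopifnot(length(n_droplets) == 1, is.finite(n_droplets), n_droplets > 0)
  stopifnot(droplet_volume > 0, droplet_radius_px >= 2)
  stopifnot(length(tile_grid) == 2, all(tile_grid >= 1))
  if (lambda_occupancy < 0) stop("lambda_occupancy must be >= 0")
  structure(list(
    n_droplets = as.integer(n_droplets),
    droplet_volume = droplet_volume,
    droplet_radius_px = as.integer(droplet_radius_px),
    tile_grid = as.integer(tile_grid),
    lambda_occupancy = lambda_occupancy
  ), class = "chamber_spec")
}

#' Time-lapse acquisition specification
#'
#' Frame count, frame interval and channel layout of a time-lapse
#' acquisition, plus the additive Gaussian intensity noise applied per
#' frame by the synthetic generator. The default is six frames at a 10 min
#' interval (a 50 min series); a five-frame / 12 min variant is obtained by
#' setting `n_frames = 5, interval_s = 720`.
#'
#' @param n_frames Number of frames (>= 2).
#' @param interval_s Frame interval in seconds (> 0). Default 600 (10 min).
#' @param channels Ordered channel names. The `a647` channel carries both
#'   the oxidation-sensitive dye signal and the bead-relocation immunoassay.
#' @param noise_sd Additive Gaussian noise SD in intensity units, recycled
#'   over channels. Default 5 a.u. per channel.
#' @param bit_depth Integer bit depth used when rendering images.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_frames = 6L,
                             interval_s = 600,
                             channels = c("cell_stain", "lactate_probe",
                                          "ros_probe", "a647"),
                             noise_sd = 5,
                             bit_depth = 16L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (interval_s <= 0) stop("interval_s must be > 0")
  noise_sd <- rep_len(noise_sd, length(channels))
  names(noise_sd) <- channels
  structure(list(
    n_frames = as.integer(n_frames),
    interval_s = interval_s,
    channels = channels,
    noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth)
  ), class = "acquisition_spec")
}

#' Assay constants: volumes, detection limits and quantitative ranges
#'
#' Physical constants and gate boundaries used when converting fluorescence
#' traces into secretion rates. The IgG upper quantitative bound is
#' configurable because the source assay literature prints both 258 and
#' 285 IgG/s for the same range; 285 is the default.
#'
#' @param droplet_volume Droplet volume in liters (default 50 pL).
#' @param avogadro Avogadro constant, per mole.
#' @param igg_lod Lower limit of detection of the IgG assay, molecules/s.
#'   Cells at or above this rate gate as IgG-secreting cells (IgG-SCs).
#' @param igg_upper Upper bound of the IgG quantitative range, molecules/s.
#' @param lactate_range Numeric length-2, lactate quantitative range in
#'   amol/s.
#' @param ros_window Reference window for the ROS slope in seconds
#'   (slopes are reported per 10 min = 600 s).
#' @return An object of class `assay_constants`.
#' @examples
#' assay_constants()
#' assay_constants(igg_upper = 258)  # alternate printed bound
#' @export
assay_constants <- function(droplet_volume = 5e-11,
                            avogadro = 6.02214076e23,
                            igg_lod = 9,
                            igg_upper = 285,
                            lactate_range = c(0.1, 0.8),
                            ros_window = 600) {
  stopifnot(droplet_volume > 0, avogadro > 0, igg_lod > 0,
            igg_upper > igg_lod, length(lactate_range) == 2,
            all(lactate_range > 0), lactate_range[1] < lactate_range[2],
            ros_window > 0)
  structure(list(
    droplet_volume = droplet_volume,
    avogadro = avogadro,
    igg_lod = igg_lod,
    igg_upper = igg_upper,
    lactate_range = lactate_range,
    ros_window = ros_window
  ), class = "assay_constants")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat("Droplet chamber:", x$n_droplets, "droplets,",
      format(x$droplet_volume * 1e12), "pL,",
      paste(x$tile_grid, collapse = " x "), "tiles, lambda =",
      x$lambda_occupancy, "\n")
  invisible(x)
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat("Acquisition:", x$n_frames, "frames every", x$interval_s, "s; channels:",
      paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.assay_constants <- function(x, ...) {
  cat("Assay constants\n")
  cat("  droplet volume :", format(x$droplet_volume * 1e12), "pL\n")
  cat("  IgG gate       : >=", x$igg_lod, "IgG/s (LoD), upper",
      x$igg_upper, "IgG/s\n")
  cat("  lactate range  :", x$lactate_range[1], "-", x$lactate_range[2],
      "amol/s\n")
  invisible(x)
}

# frame times in seconds from the first frame
frame_times <- function(acq) (seq_len(acq$n_frames) - 1) * acq$interval_s
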