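# 1-based matrix indices of a filled disk at 0-based centre (row, col)
disk_pixels <- function(row, col, r, H, W) {
  rr <- max(0, floor(row - r)):min(H - 1, ceiling(row + r))
  cc <- max(0, floor(col - r)):min(W - 1, ceiling(col + r))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - row)^2 + (g$c - col)^2 <= r^2
  cbind(g$r[keep] + 1L, g$c[keep] + 1L)
}

# beadline footprint: a 2 px tall horizontal bar through the droplet centre
beadline_pixels <- function(row, col, r, H, W) {
  half <- max(2L, floor(r / 2))
  rr <- round(row):(round(row) + 1)
  cc <- (round(col) - half):(round(col) + half)
  g <- expand.grid(r = rr, c = cc)
  keep <- g$r >= 0 & g$r < H & g$c >= 0 & g$c < W &
    (g$r - row)^2 + (g$c - col)^2 <= (r - 1)^2
  cbind(g$r[keep] + 1L, g$c[keep] + 1L)
}

#' Render a trace set into multi-channel image frames
#'
#' Draws each droplet as a filled disk at its jittered grid position on a
#' single stitched canvas, per channel and frame. Within the `a647` disk a
#' short bright bar at the droplet centre carries the beadline intensity;
#' within `cell_stain` and `ros_probe`, small uniform disk blobs at fixed
#' per-cell positions carry the cell signal. Non-feature disk pixels are
#' compensated so that the disk-mean of every rendered channel equals the
#' input trace value exactly before quantization; images are then rounded
#' to the acquisition bit depth. A ground-truth label image maps pixels to
#' droplet ids.
#'
#' @param trace_set A `droplet_trace_set` from [generate_trace_set()].
#' @param seed Integer seed (cell blob placement).
#' @param channels Channels to render (default all in the acquisition).
#' @param dir Optional directory; when given, one 16-bit TIFF per channel
#'   per frame (`<channel>_t<frame>.tif`) plus `stitch_layout.json` and
#'   the ground truth TSV are written there.
#' @param cell_radius_px Radius of the rendered cell blobs.
#' @return List of class `droplet_image_series`: `frames` (list per frame
#'   of named channel matrices), `labels` (integer droplet-id label
#'   matrix), `layout` (truth table with centroids and edge flags),
#'   `cells` (per-cell blob positions), `acq`, `chamber`.
#' @export
generate_image_series <- function(trace_set, seed = 1L, channels = NULL,
                                  dir = NULL, cell_radius_px = 2L) {
  stopifnot(inherits(trace_set, "droplet_trace_set"))
  truth <- trace_set$truth
  acq <- trace_set$acq
  if (is.null(channels)) channels <- acq$channels
  canvas <- attr(truth, "canvas")
  H <- ceiling(canvas[["height"]]); W <- ceiling(canvas[["width"]])
  r <- trace_set$chamber$droplet_radius_px
  n <- nrow(truth)
  if (cell_radius_px >= r - 2)
    stop("cell blobs must be smaller than the droplet")
  dmin <- if (n >= 2) min(stats::dist(cbind(truth$row, truth$col))) else Inf
  if (dmin <= 2 * r) {
    bad <- sum(stats::dist(cbind(truth$row, truth$col)) <= 2 * r)
    stop(bad, " droplet pair(s) cannot be placed without overlap")
  }

  set.seed(seed)
  labels <- matrix(0L, H, W)
  disks <- vector("list", n)
  beads <- vector("list", n)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    disks[[i]] <- disk_pixels(truth$row[i], truth$col[i], r, H, W)
    labels[disks[[i]]] <- truth$droplet_id[i]
    beads[[i]] <- beadline_pixels(truth$row[i], truth$col[i], r, H, W)
    nc <- truth$n_cells[i]
    if (nc > 0) {
      # rejection-sample well-separated cell centres inside the droplet,
      # restarting the whole set when a partial placement dead-ends
      sep <- 2 * cell_radius_px + 1
      pts <- NULL
      for (restart in 1:200) {
        pts <- matrix(numeric(0), 0, 2)
        for (tries in 1:100) {
          a <- stats::runif(1, 0, 2 * pi)
          d <- sqrt(stats::runif(1)) * (r - cell_radius_px - 2)
          cand <- c(truth$row[i] + d * sin(a), truth$col[i] + d * cos(a))
          if (nrow(pts) == 0 ||
              min(sqrt(rowSums(sweep(pts, 2, cand)^2))) > sep)
            pts <- rbind(pts, cand)
          if (nrow(pts) == nc) break
        }
        if (nrow(pts) == nc) break
      }
      if (nrow(pts) < nc)
        stop("could not place ", nc, " cells in droplet ", i)
      cells[[i]] <- pts
    }
  }

  tr <- trace_set$traces
  maxval <- 2^acq$bit_depth - 1
  frames <- vector("list", acq$n_frames)
  for (f in seq_len(acq$n_frames)) {
    chmats <- list()
    trf <- tr[tr$frame == f, ]
    for (ch in channels) {
      v <- trf[trf$channel == ch, ]
      v <- v[order(v$droplet_id), ]
      img <- matrix(0, H, W)
      for (i in seq_len(n)) {
        dpx <- disks[[i]]
        nd <- nrow(dpx)
        dm <- v$droplet_mean[i]
        if (ch == "a647") {
          bpx <- beads[[i]]
          bm <- v$beadline_mean[i]
          nb <- nrow(bpx)
          rest <- (nd * dm - nb * bm) / (nd - nb)
          img[dpx] <- rest
          img[bpx] <- bm
        } else if (ch %in% c("cell_stain", "ros_probe") &&
                   truth$n_cells[i] > 0 && !is.na(v$cell_mean[i])) {
          cpx <- do.call(rbind, lapply(seq_len(nrow(cells[[i]])), function(j)
            disk_pixels(cells[[i]][j, 1], cells[[i]][j, 2], cell_radius_px,
                        H, W)))
          cm <- v$cell_mean[i]
          ncp <- nrow(cpx)
          rest <- (nd * dm - ncp * cm) / (nd - ncp)
          img[dpx] <- max(rest, 0)
          img[cpx] <- cm
        } else {
          img[dpx] <- dm
        }
      }
      chmats[[ch]] <- pmin(pmax(round(img), 0), maxval)
    }
    frames[[f]] <- chmats
  }

  out <- structure(list(frames = frames, labels = labels, layout = truth,
                        cells = cells, acq = acq,
                        chamber = trace_set$chamber),
                   class = "droplet_image_series")
  if (!is.null(dir)) write_image_series(out, dir)
  out
}

#' Write an image series to disk as 16-bit TIFFs plus layout JSON
#'
#' @param series A `droplet_image_series`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_image_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^series$acq$bit_depth - 1
  for (f in seq_along(series$frames)) {
    for (ch in names(series$frames[[f]])) {
      tiff::writeTIFF(series$frames[[f]][[ch]] / maxval,
                      file.path(dir, sprintf("%s_t%02d.tif", ch, f)),
                      bits.per.sample = 16L)
    }
  }
  canvas <- dim(series$labels)
  jsonlite::write_json(
    list(canvas_height = canvas[1], canvas_width = canvas[2],
         tile_grid = attr(series$layout, "tile_grid"),
         droplet_radius_px = series$chamber$droplet_radius_px,
         n_frames = length(series$frames),
         interval_s = series$acq$interval_s,
         channels = names(series$frames[[1]])),
    file.path(dir, "stitch_layout.json"), auto_unbox = TRUE)
  truth <- series$layout
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an image series written by [write_image_series()]
#'
#' @param dir Directory with `<channel>_t<frame>.tif` files and
#'   `stitch_layout.json`.
#' @return List: `frames` (per frame, named channel matrices, intensity
#'   units), `layout_json`.
#' @export
read_image_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stitch_layout.json"),
                              simplifyVector = TRUE)
  maxval <- 65535
  frames <- lapply(seq_len(meta$n_frames), function(f) {
    out <- lapply(meta$channels, function(ch)
      round(tiff::readTIFF(file.path(dir, sprintf("%s_t%02d.tif", ch, f))) *
              maxval))
    names(out) <- meta$channels
    out
  })
  list(frames = frames, layout_json = meta)
}
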