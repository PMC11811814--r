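#' Segment droplets in a single-channel frame
#'
#' Threshold-and-label segmentation: pixels above the intensity floor are
#' connected-component labelled (EBImage), and components are kept when
#' their equivalent radius lies in the configured range and their
#' circularity `4*pi*A/P^2` reaches the minimum. Components touching the
#' image border are flagged `edge`; with a tile grid given, components
#' whose centroid lies within one radius of an internal tile seam are
#' flagged `stitch_suspect` (stitching artifacts are a known
#' false-positive source for loss-based classification).
#'
#' @param img Numeric matrix (single channel frame; rows x cols).
#' @param radius_range Numeric length-2 accepted radius range in pixels.
#' @param intensity_floor Threshold separating droplets from background.
#' @param min_circularity Minimum circularity (default 0.6; digital
#'   perimeters make perfect disks score around 1 with some bias).
#' @param tile_grid Optional integer `c(rows, cols)` of the stitched tile
#'   layout.
#' @return Data frame of regions: `region_id`, `row`, `col` (0-based
#'   centroid), `radius_px`, `area`, `edge_flag`, `stitch_suspect`; the
#'   relabelled component image is attached as attribute `"labels"`
#'   (values = `region_id`). A blank frame yields zero rows.
#' @export
segment_droplets <- function(img, radius_range = c(3, 50),
                             intensity_floor = 50,
                             min_circularity = 0.6,
                             tile_grid = NULL) {
  stopifnot(is.matrix(img))
  bw <- EBImage::bwlabel(img > intensity_floor)
  nlab <- max(bw)
  empty <- data.frame(region_id = integer(0), row = numeric(0),
                      col = numeric(0), radius_px = numeric(0),
                      area = numeric(0), edge_flag = logical(0),
                      stitch_suspect = logical(0))
  if (nlab == 0) {
    attr(empty, "labels") <- matrix(0L, nrow(img), ncol(img))
    return(empty)
  }
  shp <- EBImage::computeFeatures.shape(bw)
  area <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1)
  circ <- 4 * pi * area / perim^2
  radius <- sqrt(area / pi)
  # centroids (0-based row/col) from the label image
  px <- which(bw > 0)
  lab <- as.integer(bw)[px]
  rows <- (px - 1) %% nrow(img)
  cols <- (px - 1) %/% nrow(img)
  crow <- rowsum(rows, lab)[, 1] / as.vector(table(lab))
  ccol <- rowsum(cols, lab)[, 1] / as.vector(table(lab))
  # border contact per label
  on_border <- rows == 0 | rows == nrow(img) - 1 |
    cols == 0 | cols == ncol(img) - 1
  edge <- rowsum(as.numeric(on_border), lab)[, 1] > 0

  keep <- radius >= radius_range[1] & radius <= radius_range[2] &
    circ >= min_circularity
  ids <- which(keep)
  out <- data.frame(region_id = seq_along(ids), row = crow[ids],
                    col = ccol[ids], radius_px = radius[ids],
                    area = area[ids], edge_flag = unname(edge[ids]),
                    stitch_suspect = FALSE)
  if (!is.null(tile_grid)) {
    seams_r <- (seq_len(tile_grid[1] - 1) / tile_grid[1]) * nrow(img)
    seams_c <- (seq_len(tile_grid[2] - 1) / tile_grid[2]) * ncol(img)
    near <- function(x, seams, r) {
      if (!length(seams)) return(rep(FALSE, length(x)))
      vapply(seq_along(x), function(i) any(abs(x[i] - seams) <= r[i] + 1),
             logical(1))
    }
    out$stitch_suspect <- near(out$row, seams_r, out$radius_px) |
      near(out$col, seams_c, out$radius_px)
  }
  # relabel image to region ids
  remap <- integer(nlab)
  remap[ids] <- seq_along(ids)
  labmat <- matrix(0L, nrow(img), ncol(img))
  sel <- lab %in% ids
  labmat[px[sel]] <- remap[lab[sel]]
  attr(out, "labels") <- labmat
  out
}

#' Track droplets across frames by nearest centroids
#'
#' Droplets in a 2D observation chamber are almost static; tracks are
#' built from the first frame's regions by greedy nearest-centroid
#' matching (closest pairs assigned first, one-to-one). A match is valid
#' only when the displacement is at most `max_disp_frac` times the
#' droplet radius. A track unmatched in any frame is flagged
#' `tracking_failed` and must be excluded from downstream statistics; a
#' track whose region is edge-flagged in any frame is flagged `edge`, and
#' `stitch_suspect` likewise.
#'
#' @param regions_by_frame List of region data frames from
#'   [segment_droplets()], one per frame (>= 2).
#' @param max_disp_frac Maximum allowed displacement as a fraction of the
#'   droplet radius (default 0.5).
#' @return List: `tracks` (data frame `droplet_id`, `track_quality`, plus
#'   one centroid pair per frame), `assignment` (matrix of region ids,
#'   droplets x frames, NA where unmatched).
#' @export
track_droplets <- function(regions_by_frame, max_disp_frac = 0.5) {
  stopifnot(is.list(regions_by_frame), length(regions_by_frame) >= 2)
  ref <- regions_by_frame[[1]]
  n <- nrow(ref)
  nf <- length(regions_by_frame)
  assign_mat <- matrix(NA_integer_, n, nf)
  assign_mat[, 1] <- ref$region_id
  cur_row <- ref$row; cur_col <- ref$col
  failed <- rep(FALSE, n)
  for (f in 2:nf) {
    rg <- regions_by_frame[[f]]
    if (nrow(rg) == 0) { failed[] <- TRUE; next }
    # all candidate pairs within the gate, assigned greedily by distance
    d2 <- outer(cur_row, rg$row, "-")^2 + outer(cur_col, rg$col, "-")^2
    gate <- (max_disp_frac * ref$radius_px)^2
    cand <- which(d2 <= gate, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d2[cand])
      used_t <- rep(FALSE, n); used_r <- rep(FALSE, nrow(rg))
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_t[i] && !used_r[j]) {
          used_t[i] <- TRUE; used_r[j] <- TRUE
          assign_mat[i, f] <- rg$region_id[j]
        }
      }
    }
    miss <- is.na(assign_mat[, f])
    failed <- failed | miss
    ok <- !miss
    cur_row[ok] <- rg$row[match(assign_mat[ok, f], rg$region_id)]
    cur_col[ok] <- rg$col[match(assign_mat[ok, f], rg$region_id)]
  }
  edge <- rep(FALSE, n); stitch <- rep(FALSE, n)
  for (f in seq_len(nf)) {
    rg <- regions_by_frame[[f]]
    idx <- match(assign_mat[, f], rg$region_id)
    edge <- edge | (!is.na(idx) & rg$edge_flag[idx])
    stitch <- stitch | (!is.na(idx) & rg$stitch_suspect[idx])
  }
  quality <- ifelse(failed, "tracking_failed",
                    ifelse(edge, "edge",
                           ifelse(stitch, "stitch_suspect", "ok")))
  tracks <- data.frame(droplet_id = seq_len(n), track_quality = quality,
                       row = ref$row, col = ref$col,
                       radius_px = ref$radius_px)
  list(tracks = tracks, assignment = assign_mat)
}

# count distinct above-floor blobs of `stain` inside the given pixel set
count_blobs_in <- function(stain, pixels, floor) {
  if (length(pixels) == 0) return(0L)
  v <- stain[pixels] > floor
  if (!any(v)) return(0L)
  # label blobs on a local window to stay cheap
  rows <- (pixels - 1) %% nrow(stain) + 1
  cols <- (pixels - 1) %/% nrow(stain) + 1
  r0 <- min(rows); c0 <- min(cols)
  sub <- matrix(FALSE, max(rows) - r0 + 1, max(cols) - c0 + 1)
  sub[cbind(rows - r0 + 1, cols - c0 + 1)] <- v
  max(EBImage::bwlabel(sub))
}

#' Count cells inside a droplet mask
#'
#' Counts distinct above-threshold blobs of the cell-stain channel inside
#' the droplet mask, maximized over frames (cells may photobleach, so the
#' conservative count for multi-cell exclusion is the max).
#'
#' @param pixels_by_frame List (one element per frame) of linear pixel
#'   indices of the droplet mask.
#' @param stain_by_frame List of cell-stain channel matrices, same length.
#' @param floor Blob detection threshold (a.u.).
#' @return Integer cell count.
#' @export
count_cells <- function(pixels_by_frame, stain_by_frame, floor = 150) {
  stopifnot(length(pixels_by_frame) == length(stain_by_frame),
            length(pixels_by_frame) >= 1)
  if (any(lengths(pixels_by_frame) == 0)) stop("droplet mask is empty")
  max(vapply(seq_along(pixels_by_frame), function(f)
    count_blobs_in(stain_by_frame[[f]], pixels_by_frame[[f]], floor),
    integer(1)))
}

# beadline estimator: brightest compact cluster, else top-quantile fallback
beadline_mean_of <- function(vals, q = 0.02) {
  med <- stats::median(vals)
  thr <- (max(vals) + med) / 2
  cl <- vals[vals > thr]
  if (max(vals) > 1.1 * med && length(cl) >= 4)
    list(mean = mean(cl), fallback = FALSE)
  else
    list(mean = mean(vals[vals >= stats::quantile(vals, 1 - q)]),
         fallback = TRUE)
}

#' Extract per-droplet traces from tracked image frames
#'
#' For every cleanly tracked droplet and frame this computes the
#' whole-droplet mean per channel, the beadline mean in the `a647`
#' channel (brightest compact cluster inside the droplet; when no cluster
#' stands out, the mean of the top intensity quantile is used and the
#' droplet is flagged `beadline_fallback`), the mean over detected cell
#' blobs in the cell channels, and the cell count (max over frames).
#'
#' @param tracking Result of [track_droplets()].
#' @param regions_by_frame The region data frames (with `"labels"`
#'   attributes) used for tracking.
#' @param frames List per frame of named channel matrices.
#' @param acq An [acquisition_spec()] providing frame times.
#' @param cell_floor Cell blob detection threshold.
#' @param quantile_q Top-quantile used by the beadline fallback.
#' @return Long trace data frame with the same schema as
#'   [generate_trace_set()] (`droplet_id`, `frame`, `time_s`, `channel`,
#'   `droplet_mean`, `beadline_mean`, `cell_mean`, `n_cells`,
#'   `track_quality`) plus `beadline_fallback`.
#' @export
extract_traces <- function(tracking, regions_by_frame, frames, acq,
                           cell_floor = 150, quantile_q = 0.02) {
  stopifnot(length(frames) == length(regions_by_frame))
  shapes <- unique(t(vapply(frames, function(f) dim(f[[1]]), integer(2))))
  if (nrow(shapes) != 1) stop("inconsistent image shapes across frames")
  times <- frame_times(acq)
  tracks <- tracking$tracks
  nf <- length(frames)
  channels <- names(frames[[1]])
  ok_ids <- tracks$droplet_id[tracks$track_quality %in%
                                c("ok", "edge", "stitch_suspect")]
  # pixel sets per droplet per frame
  pix <- lapply(seq_len(nf), function(f) {
    labmat <- attr(regions_by_frame[[f]], "labels")
    sp <- split(which(labmat > 0), labmat[labmat > 0])
    lapply(tracks$droplet_id, function(d) {
      rid <- tracking$assignment[d, f]
      if (is.na(rid)) integer(0) else sp[[as.character(rid)]]
    })
  })
  has_stain <- "cell_stain" %in% channels
  # global cell-blob label image per frame (cheap: one bwlabel per frame)
  cell_lab <- if (has_stain)
    lapply(seq_len(nf), function(f)
      EBImage::bwlabel(frames[[f]]$cell_stain > cell_floor)) else NULL

  keep <- tracks$droplet_id[tracks$track_quality != "tracking_failed"]
  nd <- length(keep)
  ntot <- nd * nf * length(channels)
  col_id <- integer(ntot); col_frame <- integer(ntot)
  col_ch <- character(ntot); col_dm <- numeric(ntot)
  col_bm <- rep(NA_real_, ntot); col_cm <- rep(NA_real_, ntot)
  col_nc <- integer(ntot); col_fb <- rep(NA, ntot)
  used <- logical(ntot)
  k <- 0L
  ncells_of <- integer(max(tracks$droplet_id))
  for (d in keep) {
    ncells_of[d] <- if (has_stain)
      max(vapply(seq_len(nf), function(f) {
        p <- pix[[f]][[d]]
        if (!length(p)) 0L else {
          l <- cell_lab[[f]][p]
          length(unique(l[l > 0]))
        }
      }, integer(1))) else 0L
  }
  for (f in seq_len(nf)) {
    for (d in keep) {
      p <- pix[[f]][[d]]
      if (!length(p)) next
      cellpix <- if (has_stain && ncells_of[d] > 0)
        p[cell_lab[[f]][p] > 0] else integer(0)
      for (ch in channels) {
        img <- frames[[f]][[ch]]
        k <- k + 1L
        used[k] <- TRUE
        col_id[k] <- d; col_frame[k] <- f; col_ch[k] <- ch
        col_dm[k] <- mean(img[p])
        col_nc[k] <- ncells_of[d]
        if (ch == "a647") {
          be <- beadline_mean_of(img[p], q = quantile_q)
          col_bm[k] <- be$mean; col_fb[k] <- be$fallback
        }
        if (ch %in% c("cell_stain", "ros_probe") && length(cellpix))
          col_cm[k] <- mean(img[cellpix])
      }
    }
  }
  idx <- which(used)
  out <- data.frame(
    droplet_id = col_id[idx], frame = col_frame[idx],
    time_s = times[col_frame[idx]], channel = col_ch[idx],
    droplet_mean = col_dm[idx], beadline_mean = col_bm[idx],
    cell_mean = col_cm[idx], n_cells = col_nc[idx],
    track_quality = tracks$track_quality[match(col_id[idx],
                                               tracks$droplet_id)],
    beadline_fallback = col_fb[idx], stringsAsFactors = FALSE)
  # droplets missing in some frame keep their rows but are flagged
  per_drop <- table(out$droplet_id[out$channel == channels[1]])
  incomplete <- as.integer(names(per_drop)[per_drop < nf])
  if (length(incomplete))
    out$track_quality[out$droplet_id %in% incomplete] <- "tracking_failed"
  out <- out[order(out$droplet_id, out$frame, out$channel), ]
  rownames(out) <- NULL
  out
}
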