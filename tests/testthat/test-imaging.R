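# small rendered chamber reused across imaging tests
make_render <- function(n = 60, seed = 3, noise_sd = 0, radius = 8) {
  ch <- chamber_spec(n, droplet_radius_px = radius, tile_grid = c(2, 2))
  acq <- acquisition_spec(noise_sd = noise_sd)
  ph <- sample_phenotypes(n, 0.3, seed = seed)
  ts <- generate_trace_set(ch, acq, ph, seed = seed)
  im <- generate_image_series(ts, seed = seed)
  list(ts = ts, im = im, acq = acq)
}

test_that("a blank frame segments to zero regions", {
  out <- segment_droplets(matrix(0, 64, 64))
  expect_equal(nrow(out), 0)
  expect_true(all(attr(out, "labels") == 0))
})

test_that("every requested droplet is rendered as a disjoint labelled disk", {
  x <- make_render(n = 60)
  ids <- setdiff(unique(as.integer(x$im$labels)), 0L)
  expect_length(ids, 60)
  # disk means in the label image match truth ids one-to-one
  expect_setequal(ids, x$ts$truth$droplet_id)
})

test_that("segmentation recovers droplets with sub-pixel centroids", {
  x <- make_render(n = 60)
  reg <- segment_droplets(x$im$frames[[1]]$a647, radius_range = c(5, 12))
  expect_gte(nrow(reg), 59)
  d2 <- outer(reg$row, x$ts$truth$row, "-")^2 +
    outer(reg$col, x$ts$truth$col, "-")^2
  expect_lt(max(sqrt(apply(d2, 1, min))), 1)
})

test_that("droplets touching the canvas border are edge-flagged", {
  x <- make_render(n = 9)
  truth <- x$ts$truth
  # move one droplet onto the border and re-render
  truth$row[1] <- truth$radius_px[1] - 2
  ts2 <- x$ts; ts2$truth <- truth
  im2 <- generate_image_series(ts2, seed = 1)
  reg <- segment_droplets(im2$frames[[1]]$a647, radius_range = c(4, 12),
                          min_circularity = 0.3)
  hit <- which.min((reg$row - truth$row[1])^2 + (reg$col - truth$col[1])^2)
  expect_true(reg$edge_flag[hit])
  expect_false(any(reg$edge_flag[-hit]))
})

test_that("static droplets track perfectly and swaps beyond the gate flag", {
  x <- make_render(n = 40)
  regs <- lapply(x$im$frames, function(fr)
    segment_droplets(fr$a647, radius_range = c(5, 12)))
  trk <- track_droplets(regs)
  expect_true(all(trk$tracks$track_quality == "ok"))
  expect_true(all(!is.na(trk$assignment)))

  # displace one droplet by two radii in frame 3 -> its track fails
  regs2 <- regs
  regs2[[3]]$row[5] <- regs2[[3]]$row[5] + 2 * regs2[[3]]$radius_px[5]
  trk2 <- track_droplets(regs2)
  expect_identical(trk2$tracks$track_quality[5], "tracking_failed")
  expect_true(all(trk2$tracks$track_quality[-5] == "ok"))

  # two droplets moved beyond the gate from every prior centroid:
  # both are flagged, neither is silently reassigned
  regs3 <- regs
  shift <- 3 * regs3[[2]]$radius_px[1]
  regs3[[2]]$row[1] <- regs3[[2]]$row[1] + shift
  regs3[[2]]$row[2] <- regs3[[2]]$row[2] - shift
  trk3 <- track_droplets(regs3)
  expect_true(all(trk3$tracks$track_quality[1:2] == "tracking_failed"))
})

test_that("cell counts match the planted occupancy on clean renders", {
  x <- make_render(n = 60)
  regs <- lapply(x$im$frames, function(fr)
    segment_droplets(fr$a647, radius_range = c(5, 12)))
  trk <- track_droplets(regs)
  tr <- extract_traces(trk, regs, x$im$frames, x$acq)
  ref <- trk$tracks
  idx <- vapply(seq_len(nrow(ref)), function(i)
    which.min((x$ts$truth$row - ref$row[i])^2 +
                (x$ts$truth$col - ref$col[i])^2), integer(1))
  got <- vapply(ref$droplet_id, function(d)
    tr$n_cells[tr$droplet_id == d][1], integer(1))
  expect_identical(got, x$ts$truth$n_cells[idx])
})

test_that("extracted means reproduce the generated traces within a quantum", {
  x <- make_render(n = 60)
  regs <- lapply(x$im$frames, function(fr)
    segment_droplets(fr$a647, radius_range = c(5, 12)))
  trk <- track_droplets(regs)
  tr <- extract_traces(trk, regs, x$im$frames, x$acq)
  ref <- trk$tracks
  idx <- vapply(seq_len(nrow(ref)), function(i)
    which.min((x$ts$truth$row - ref$row[i])^2 +
                (x$ts$truth$col - ref$col[i])^2), integer(1))
  for (ch in c("a647", "lactate_probe")) {
    gen <- x$ts$traces[x$ts$traces$channel == ch, ]
    ext <- tr[tr$channel == ch, ]
    for (d in ref$droplet_id) {
      g <- gen$droplet_mean[gen$droplet_id == idx[d]]
      e <- ext$droplet_mean[ext$droplet_id == d]
      expect_lt(max(abs(sort(g) - sort(e))), 1)
    }
  }
})

test_that("beadline extraction recovers strong relocation within 5 percent", {
  ph <- one_droplet(igg = 200)  # relocation well above 1 by the last frame
  ch <- chamber_spec(1, droplet_radius_px = 10)
  acq <- acquisition_spec(noise_sd = 0)
  ts <- generate_trace_set(ch, acq, ph, seed = 2)
  im <- generate_image_series(ts, seed = 2)
  regs <- lapply(im$frames, function(fr)
    segment_droplets(fr$a647, radius_range = c(6, 14)))
  trk <- track_droplets(regs)
  tr <- extract_traces(trk, regs, im$frames, acq)
  gen <- ts$traces[ts$traces$channel == "a647", ]
  ext <- tr[tr$channel == "a647", ]
  reloc_gen <- gen$beadline_mean / gen$droplet_mean
  reloc_ext <- ext$beadline_mean / ext$droplet_mean
  late <- reloc_gen > 1.2
  expect_true(all(abs(reloc_ext[late] - reloc_gen[late]) /
                    reloc_gen[late] < 0.05))
})

test_that("droplets without a visible beadline fall back to the quantile", {
  ph <- one_droplet(igg = 0)  # relocation stays at baseline 1
  ts <- generate_trace_set(chamber_spec(1, droplet_radius_px = 10),
                           acquisition_spec(noise_sd = 0), ph, seed = 2)
  im <- generate_image_series(ts, seed = 2)
  regs <- lapply(im$frames, function(fr)
    segment_droplets(fr$a647, radius_range = c(6, 14)))
  trk <- track_droplets(regs)
  tr <- extract_traces(trk, regs, im$frames, acquisition_spec(noise_sd = 0))
  a <- tr[tr$channel == "a647", ]
  expect_true(all(a$beadline_fallback))
  expect_equal(a$beadline_mean / a$droplet_mean, rep(1, 6), tolerance = 0.01)
})

test_that("TIFF write/read round trip preserves rendered intensities", {
  x <- make_render(n = 9)
  dir <- tempfile("imgio_")
  write_image_series(x$im, dir)
  back <- read_image_series(dir)
  expect_equal(back$frames[[1]]$a647, x$im$frames[[1]]$a647)
  expect_equal(back$layout_json$tile_grid, c(2, 2))
  unlink(dir, recursive = TRUE)
})
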