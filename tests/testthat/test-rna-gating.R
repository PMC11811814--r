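nox_row <- function(...) {
  v <- stats::setNames(rep(0, length(nox_gene_set())), nox_gene_set())
  upd <- list(...)
  v[names(upd)] <- unlist(upd)
  matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
}

test_that("NOX mRNA rule: any set gene above zero is positive", {
  expect_identical(classify_nox_mrna(nox_row()), "neg")  # all exactly 0
  expect_identical(classify_nox_mrna(nox_row(NOX2 = 0.5)), "pos")
  expect_identical(classify_nox_mrna(nox_row(NOX1 = 0.4, NOX2 = -0.2)), "pos")
  expect_identical(classify_nox_mrna(nox_row(NOX1 = -1, CYBB = -0.1)), "neg")
  expect_error(classify_nox_mrna(nox_row(), gene_set = character(0)),
               "non-empty")
})

test_that("mean aggregation mode is available behind the mode switch", {
  m <- nox_row(NOX1 = 0.4)  # mean over 15 genes is positive but small
  expect_identical(classify_nox_mrna(m, mode = "mean"), "pos")
  m2 <- nox_row(NOX1 = 0.4, NOX2 = -1)
  expect_identical(classify_nox_mrna(m2, mode = "mean"), "neg")
  expect_identical(classify_nox_mrna(m2, mode = "any"), "pos")
})

test_that("raising a NOX-set value never flips a positive call negative", {
  set.seed(9)
  for (i in 1:20) {
    m <- nox_row()
    m[1, ] <- rnorm(ncol(m), -0.2, 0.5)
    before <- classify_nox_mrna(m)
    g <- sample(ncol(m), 1)
    m[1, g] <- m[1, g] + runif(1, 0, 2)
    after <- classify_nox_mrna(m)
    if (before == "pos") expect_identical(after, "pos")
  }
})

test_that("missing set genes warn and are treated as zero", {
  m <- matrix(c(0.5, -1), 1, dimnames = list(NULL, c("NOX2", "CYBB")))
  expect_warning(lab <- classify_nox_mrna(m), "missing")
  expect_identical(lab, "pos")
})

test_that("subset assignment takes the argmax of mean marker scores", {
  cfg <- default_marker_config()$subsets
  genes <- unique(unlist(cfg))
  cell <- stats::setNames(rep(0, length(genes)), genes)
  m0 <- matrix(cell, 1, dimnames = list(NULL, genes))
  expect_identical(assign_subset(m0, cfg), "unassigned")  # all zero

  m1 <- m0; m1[1, cfg$gcbc] <- 2
  expect_identical(assign_subset(m1, cfg), "gcbc")

  # exact two-way tie
  m2 <- m0; m2[1, cfg$gcbc] <- 1; m2[1, cfg$mbc] <- 1
  expect_identical(assign_subset(m2, cfg), "unassigned")
})

test_that("deg_test is calibrated under the null and powered under shift", {
  set.seed(12)
  ngenes <- 400
  ref <- matrix(rnorm(400 * ngenes), 400,
                dimnames = list(NULL, paste0("g", 1:ngenes)))
  grp <- matrix(rnorm(200 * ngenes), 200,
                dimnames = list(NULL, paste0("g", 1:ngenes)))
  null_res <- deg_test(grp, ref)
  frac <- mean(null_res$p < 0.05)
  se <- sqrt(0.05 * 0.95 / ngenes)
  expect_lt(abs(frac - 0.05), 3 * se)
  expect_lt(max(abs(null_res$log2fc)), 0.5)

  planted <- paste0("g", 1:50)
  grp2 <- grp; grp2[, planted] <- grp2[, planted] + 1
  shift_res <- deg_test(grp2, ref)
  expect_gte(mean(shift_res$p[shift_res$gene %in% planted] < 0.05), 0.9)
  expect_equal(mean(shift_res$log2fc[shift_res$gene %in% planted]), 1,
               tolerance = 0.1)
})

test_that("deg_test handles constant genes and rejects empty groups", {
  ref <- matrix(1, 10, 2, dimnames = list(NULL, c("a", "b")))
  grp <- matrix(1, 5, 2, dimnames = list(NULL, c("a", "b")))
  res <- deg_test(grp, ref)
  expect_equal(res$p, c(1, 1))
  expect_error(deg_test(grp[0, , drop = FALSE], ref), "non-empty")
})

test_that("pathway modulation scores the mean log2FC of significant genes", {
  deg <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1, 1, -1, 5), p = c(0.01, 0.02, 0.01, 0.8))
  up <- pathway_modulation(deg, c("a", "b"))
  expect_equal(up$score, 1)
  expect_identical(up$direction, "positive")
  mix <- pathway_modulation(deg, c("a", "c"))
  expect_equal(mix$score, 0)
  expect_identical(mix$direction, "none")
  # gene d is in the set but not significant; nothing remains
  none <- pathway_modulation(deg, "d")
  expect_identical(none$direction, "no call")
})

test_that("a planted pathway up-shift is recovered end to end", {
  set.seed(23)
  ngenes <- 300
  genes <- paste0("g", 1:ngenes)
  ref <- matrix(rnorm(300 * ngenes), 300, dimnames = list(NULL, genes))
  grp <- matrix(rnorm(150 * ngenes), 150, dimnames = list(NULL, genes))
  path <- paste0("g", 1:30)
  grp[, path] <- grp[, path] + 0.5
  res <- pathway_modulation(deg_test(grp, ref), path)
  expect_identical(res$direction, "positive")
  expect_equal(res$score, 0.5, tolerance = 0.2)
})

test_that("gating is deterministic and exact on noise-free planted data", {
  g <- generate_rna_matrix(n_cells = 600, seed = 14, noise_sd = 0)
  a1 <- annotate_cells(g$matrix)
  a2 <- annotate_cells(g$matrix)
  expect_identical(a1, a2)
  expect_identical(a1$subset, g$truth$subset)
  expect_identical(a1$nox_mrna, g$truth$nox_mrna)
  gc <- g$truth$subset == "gcbc"
  expect_identical(a1$zone[gc], g$truth$zone[gc])
  pc <- g$truth$subset == "pc"
  expect_identical(a1$pc_state[pc], g$truth$pc_state[pc])
  expect_identical(a1$ighg_expresser, g$truth$ighg_expresser)
})

test_that("composition report recovers planted fractions with denominators", {
  g <- generate_rna_matrix(n_cells = 4000, seed = 15)
  rep_ <- composition_report(annotate_cells(g$matrix))
  gcbc <- rep_$subsets[rep_$subsets$subset == "gcbc", ]
  se <- sqrt(0.34 * 0.66 / 4000)
  expect_lt(abs(gcbc$fraction - 0.34), 3 * se)
  expect_equal(gcbc$n_total, 4000)
  # no NOX-positive cells planted -> all NOX fractions zero
  g0 <- generate_rna_matrix(nox_positive_fraction = 0, n_cells = 500,
                            seed = 16)
  r0 <- composition_report(annotate_cells(g0$matrix))
  expect_true(all(r0$nox_by_subset$fraction == 0))
  expect_equal(nrow(r0$zones_nox_pos), 0)
})

test_that("housekeeping check passes on null data and names violations", {
  g <- generate_rna_matrix(n_cells = 1500, seed = 18)
  hk <- housekeeping_check(g$matrix)
  expect_true(hk$pass)
  m2 <- g$matrix
  m2[, "HPRT"] <- m2[, "HPRT"] + 1
  hk2 <- housekeeping_check(m2)
  expect_false(hk2$pass)
  expect_true("HPRT" %in% hk2$failed)
  expect_error(housekeeping_check(matrix(numeric(0), 0, 0)), "empty")
})

test_that("marker configs round trip through YAML", {
  cfg <- default_marker_config()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  back <- read_marker_config(path)
  expect_identical(back$subsets, cfg$subsets)
  unlink(path)
})
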