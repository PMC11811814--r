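# return the submatrix for `genes`, padding missing genes with zeros
# (with a single warning naming them)
gene_submatrix <- function(m, genes, what = "gene") {
  missing <- setdiff(genes, colnames(m))
  if (length(missing))
    warning("missing ", what, "(s) treated as 0: ",
            paste(missing, collapse = ", "))
  out <- matrix(0, nrow(m), length(genes),
                dimnames = list(rownames(m), genes))
  present <- intersect(genes, colnames(m))
  out[, present] <- m[, present, drop = FALSE]
  out
}

#' Classify cells as NOX-expressing from log2 fold changes
#'
#' A cell is `pos` when its NOX gene-set expression exceeds 0 (log2FC)
#' and `neg` otherwise (values at exactly 0 are negative). Under the
#' default `"any"` mode a single set gene above 0 suffices, matching the
#' observation that cells express individual isoforms (either NOX1 or
#' NOX2) rather than the whole set; `"mean"` mode aggregates the set mean
#' before thresholding.
#'
#' @param m Cells-by-genes log2FC matrix (or a named per-cell vector).
#' @param gene_set NOX gene symbols (default [nox_gene_set()]); missing
#'   genes are treated as 0 with a warning.
#' @param mode `"any"` (default) or `"mean"`.
#' @return Character vector `"pos"` / `"neg"`, one per cell.
#' @export
classify_nox_mrna <- function(m, gene_set = nox_gene_set(),
                              mode = c("any", "mean")) {
  mode <- match.arg(mode)
  if (length(gene_set) == 0) stop("gene_set must be non-empty")
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  sub <- gene_submatrix(m, gene_set, "NOX set gene")
  score <- if (mode == "any") apply(sub, 1, max) else rowMeans(sub)
  unname(ifelse(score > 0, "pos", "neg"))
}

#' Assign each cell to a subset by mean marker expression
#'
#' Each subset is scored as the mean log2FC over its marker genes; the
#' cell takes the highest-scoring subset. An exact tie at the top, or all
#' scores at or below 0, gives `"unassigned"`.
#'
#' @param m Cells-by-genes log2FC matrix.
#' @param markers Named list subset -> marker gene vector (e.g.
#'   `default_marker_config()$subsets`); missing markers are treated as 0
#'   with a warning.
#' @return Character vector of subset labels.
#' @export
assign_subset <- function(m, markers) {
  stopifnot(is.list(markers), length(markers) >= 1,
            all(lengths(markers) >= 1))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(m)))
  scores <- sapply(names(markers), function(s)
    rowMeans(gene_submatrix(m, markers[[s]], "marker")))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1,
                                             dimnames = list(NULL, names(markers)))
  apply(scores, 1, function(v) {
    top <- max(v)
    if (top <= 0 || sum(v == top) > 1) "unassigned"
    else names(markers)[which.max(v)]
  })
}

#' Per-gene differential expression against a pooled reference
#'
#' For each gene, the log2 fold change is the difference of group means
#' (values are already on the log2 scale) and the p-value comes from a
#' two-sided Wilcoxon rank-sum test of the group against the reference
#' cells. No multiplicity adjustment is applied here (downstream pathway
#' scoring filters at raw p < 0.05); [stats::p.adjust()] can be applied by
#' the caller.
#'
#' @param group Cells-by-genes matrix of the group of interest.
#' @param reference Cells-by-genes matrix of the pooled reference; genes
#'   are matched by column name.
#' @return Data frame: `gene`, `log2fc`, `p`.
#' @export
deg_test <- function(group, reference) {
  if (is.null(dim(group)) || nrow(group) == 0 ||
      is.null(dim(reference)) || nrow(reference) == 0)
    stop("both group and reference must be non-empty matrices")
  genes <- intersect(colnames(group), colnames(reference))
  if (length(genes) == 0) stop("no shared genes")
  p <- vapply(genes, function(g) {
    a <- group[, g]; b <- reference[, g]
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  data.frame(gene = genes,
             log2fc = colMeans(group[, genes, drop = FALSE]) -
               colMeans(reference[, genes, drop = FALSE]),
             p = unname(p), row.names = NULL)
}

#' Pathway modulation score from a filtered DEG table
#'
#' The score is the mean log2 fold change over the differentially
#' expressed genes (p < cutoff) that belong to the pathway gene set; its
#' sign gives the modulation direction. An empty intersection returns a
#' `"no call"`.
#'
#' @param deg Data frame from [deg_test()] (`gene`, `log2fc`, `p`).
#' @param pathway_genes Character vector of pathway gene symbols.
#' @param p_cutoff Raw p-value filter (default 0.05).
#' @return List: `score`, `direction` (`"positive"`, `"negative"`,
#'   `"none"` at exactly 0, or `"no call"`), `n_genes` used.
#' @export
pathway_modulation <- function(deg, pathway_genes, p_cutoff = 0.05) {
  stopifnot(all(c("gene", "log2fc", "p") %in% names(deg)))
  hit <- deg[deg$p < p_cutoff & deg$gene %in% pathway_genes, ]
  if (nrow(hit) == 0)
    return(list(score = NA_real_, direction = "no call", n_genes = 0L))
  s <- mean(hit$log2fc)
  list(score = s,
       direction = if (s > 0) "positive" else if (s < 0) "negative" else "none",
       n_genes = nrow(hit))
}

#' Annotate every cell: subset, NOX expression, zone/state, IgG isotype
#'
#' Runs the full gating chain on a log2FC matrix: subset assignment,
#' NOX-expression classification, dark/light-zone gating within GC cells,
#' maturation-state gating within plasma cells, and the IGHG-expresser
#' flag (any IGHG isotype gene > 0) for plasma cells.
#'
#' @param m Cells-by-genes log2FC matrix.
#' @param marker_config Marker config list (see [default_marker_config()]).
#' @param gene_set NOX gene set.
#' @param mode NOX aggregation mode passed to [classify_nox_mrna()].
#' @param day Day/condition label attached to all cells.
#' @return Data frame: `cell_id`, `subset`, `zone`, `pc_state`,
#'   `nox_mrna`, `ighg_expresser`, `day`.
#' @export
annotate_cells <- function(m, marker_config = default_marker_config(),
                           gene_set = nox_gene_set(), mode = "any",
                           day = 0) {
  subset <- assign_subset(m, marker_config$subsets)
  nox <- classify_nox_mrna(m, gene_set, mode = mode)
  zone <- rep(NA_character_, nrow(m))
  if (!is.null(marker_config$gc_zones)) {
    gc <- subset == "gcbc"
    if (any(gc)) zone[gc] <- assign_subset(m[gc, , drop = FALSE],
                                           marker_config$gc_zones)
  }
  pc_state <- rep(NA_character_, nrow(m))
  if (!is.null(marker_config$pc_states)) {
    pc <- subset == "pc"
    if (any(pc)) pc_state[pc] <- assign_subset(m[pc, , drop = FALSE],
                                               marker_config$pc_states)
  }
  ighg_cols <- grep("^IGHG", colnames(m), value = TRUE)
  ighg <- if (length(ighg_cols))
    apply(m[, ighg_cols, drop = FALSE], 1, max) > 0 else rep(FALSE, nrow(m))
  data.frame(cell_id = seq_len(nrow(m)), subset = subset, zone = zone,
             pc_state = pc_state, nox_mrna = nox,
             ighg_expresser = unname(ighg) & subset == "pc", day = day,
             stringsAsFactors = FALSE)
}

# fraction table helper with explicit numerator/denominator
frac_table <- function(num, den, labels) {
  den <- rep_len(den, length(num))
  data.frame(labels, n = num, n_total = den,
             fraction = ifelse(den == 0, NA_real_, num / den),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Composition and NOX-expression frequency report
#'
#' Summarizes an annotation table into the frequency tables a composition
#' figure needs: subset fractions per day, NOX-expressing fraction per
#' subset and day, dark/light-zone split among NOX-expressing GC cells,
#' plasma-cell state split, and IGHG-expresser fractions among plasma
#' cells. All fractions report explicit numerators and denominators;
#' empty denominators give `NA`.
#'
#' @param ann Annotation data frame from [annotate_cells()] (or the truth
#'   table of [generate_rna_matrix()]).
#' @return List of data frames: `subsets`, `nox_by_subset`,
#'   `zones_nox_pos`, `pc_states`, `ighg`.
#' @export
composition_report <- function(ann) {
  stopifnot(all(c("subset", "nox_mrna", "day") %in% names(ann)))
  days <- unique(ann$day)
  per_day <- function(f) do.call(rbind, lapply(days, f))

  subsets <- per_day(function(d) {
    a <- ann[ann$day == d, ]
    tb <- table(a$subset)
    cbind(day = d, frac_table(as.integer(tb), nrow(a),
                              data.frame(subset = names(tb))))
  })
  nox_by_subset <- per_day(function(d) {
    a <- ann[ann$day == d, ]
    sp <- split(a$nox_mrna, a$subset)
    cbind(day = d, frac_table(vapply(sp, function(v) sum(v == "pos"), 0L),
                              lengths(sp),
                              data.frame(subset = names(sp))))
  })
  zones_nox_pos <- per_day(function(d) {
    a <- ann[ann$day == d & ann$subset == "gcbc" & ann$nox_mrna == "pos", ]
    if (nrow(a) == 0)
      return(data.frame(day = numeric(0), zone = character(0),
                        n = integer(0), n_total = integer(0),
                        fraction = numeric(0)))
    tb <- table(factor(a$zone, levels = c("dz", "lz")))
    cbind(day = d, frac_table(as.integer(tb), nrow(a),
                              data.frame(zone = names(tb))))
  })
  pc_states <- per_day(function(d) {
    a <- ann[ann$day == d & ann$subset == "pc", ]
    tb <- table(a$pc_state)
    cbind(day = d, frac_table(as.integer(tb), nrow(a),
                              data.frame(pc_state = names(tb))))
  })
  ighg <- per_day(function(d) {
    a <- ann[ann$day == d & ann$subset == "pc", ]
    cbind(day = d, frac_table(sum(a$ighg_expresser), nrow(a),
                              data.frame(group = "pc")))
  })
  list(subsets = subsets, nox_by_subset = nox_by_subset,
       zones_nox_pos = zones_nox_pos, pc_states = pc_states, ighg = ighg)
}

#' Housekeeping-gene bias check
#'
#' Internal control for fold-change-based analyses: the mean log2FC of
#' each housekeeping gene must stay within a tolerance of zero, and no
#' housekeeping gene may be significantly shifted (one-sample Wilcoxon
#' signed-rank test against 0, BH-adjusted across the control genes, at
#' 0.05).
#'
#' @param m Cells-by-genes log2FC matrix (non-empty).
#' @param genes Housekeeping gene symbols (default [housekeeping_genes()]);
#'   genes absent from the matrix are listed in the output and skipped.
#' @param tolerance Maximum tolerated absolute mean log2FC (default 0.25).
#' @return List: `pass` (logical), `table` (gene, mean_log2fc, p, p_adj,
#'   ok), `missing`, `failed` (offending gene names).
#' @export
housekeeping_check <- function(m, genes = housekeeping_genes(),
                               tolerance = 0.25) {
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0)
    stop("expression matrix is empty")
  missing <- setdiff(genes, colnames(m))
  present <- intersect(genes, colnames(m))
  if (length(present) == 0) stop("no housekeeping genes present")
  mean_fc <- colMeans(m[, present, drop = FALSE])
  p <- vapply(present, function(g) {
    v <- m[, g]
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = 0, exact = FALSE)$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  ok <- abs(mean_fc) < tolerance & p_adj >= 0.05
  tab <- data.frame(gene = present, mean_log2fc = unname(mean_fc),
                    p = unname(p), p_adj = unname(p_adj), ok = unname(ok),
                    row.names = NULL)
  list(pass = all(ok), table = tab, missing = missing,
       failed = present[!ok])
}
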