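#' Default NOX gene set
#'
#' Isoforms NOX1-4 and DUOX1-2, the regulators NOXO1 and NOXA1, and the
#' complex-component genes CYBA, CYBB, NCF1/2/4 and DUOXA1/2. A cell is
#' NOX-expressing when any gene of this set has a positive log2 fold
#' change.
#'
#' @return Character vector of 15 gene symbols.
#' @export
nox_gene_set <- function() {
  c("NOX1", "NOX2", "NOX3", "NOX4", "DUOX1", "DUOX2",
    "NOXO1", "NOXA1", "CYBA", "CYBB", "NCF1", "NCF2", "NCF4",
    "DUOXA1", "DUOXA2")
}

#' Default housekeeping control genes
#'
#' Constitutively expressed genes used as internal controls: their mean
#' log2 fold change should sit near zero in an unbiased experiment.
#'
#' @return Character vector of 10 gene symbols.
#' @export
housekeeping_genes <- function() {
  c("ATF1", "ATF2", "ATF4", "ATF6", "ATF7", "BTF3", "E2F4", "JUND",
    "HPRT", "RPL3")
}

#' Default marker configuration for B-cell subset gating
#'
#' Literature-typical marker panels for murine splenic B-cell subsets,
#' germinal-center dark/light zones and plasma-cell states. These are
#' synthetic defaults for testing the gating machinery; real analyses
#' should supply their own validated panels via [read_marker_config()].
#'
#' @return Nested list: `subsets`, `gc_zones`, `pc_states` (each subset
#'   name -> character vector of marker genes).
#' @export
default_marker_config <- function() {
  list(
    subsets = list(
      immature_b  = c("CD24A", "VPREB3"),
      naive_b     = c("IGHD", "FCER2A", "SELL"),
      activated_b = c("CD69", "CD83", "NR4A1"),
      gcbc        = c("AICDA", "BCL6", "S1PR2"),
      mbc         = c("CCR6", "ZEB2", "CD38"),
      pc          = c("PRDM1", "XBP1", "SDC1", "IRF4"),
      other       = c("CD3E", "NKG7")
    ),
    gc_zones = list(
      dz = c("CXCR4", "MKI67", "AURKB"),
      lz = c("CD83", "CD86", "CXCR5")
    ),
    pc_states = list(
      plasmablast  = c("MKI67", "TIGIT"),
      immature_pc  = c("TNFRSF13B", "BCL2L11"),
      mature_pc    = c("SLAMF7", "CD93"),
      apoptotic_pc = c("CASP3", "BAX")
    )
  )
}

#' Read a marker configuration from YAML
#'
#' @param path YAML file with top-level blocks `subsets`, and optionally
#'   `gc_zones` and `pc_states`, each mapping subset name to a marker
#'   gene list.
#' @return Marker config list as in [default_marker_config()].
#' @export
read_marker_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$subsets) || !length(cfg$subsets))
    stop("marker config needs a non-empty 'subsets' block")
  lapply(cfg, lapply, as.character)
}

# default day-0-like splenic composition; germinal-center fraction 0.34
default_composition <- function() {
  c(immature_b = 0.09, naive_b = 0.02, activated_b = 0.11, gcbc = 0.34,
    mbc = 0.09, pc = 0.09, other = 0.26)
}

#' Generate a synthetic log2-fold-change expression matrix with truth
#'
#' Plants a cells-by-genes log2FC matrix in which each cell's true-subset
#' markers are shifted positive, off-subset markers sit at zero, NOX gene
#' values are strictly positive for planted NOX-expressing cells (one or
#' two of NOX1/NOX2, mirroring the isoform usage of splenic B cells) and
#' non-positive otherwise, housekeeping genes have mean zero, and
#' IGHG/IGHM isotype genes mark a fraction of plasma cells as IgG
#' expressers. GC cells additionally carry dark/light-zone markers and PCs
#' a maturation-state marker shift so zone and state gating are testable.
#' With `noise_sd = 0` all planted labels are exactly recoverable.
#'
#' @param composition Named subset -> fraction map (must sum to 1); names
#'   must exist in `marker_config$subsets`.
#' @param marker_config Marker config (see [default_marker_config()]).
#' @param nox_positive_fraction Scalar or named-per-subset probability
#'   that a cell is NOX-expressing.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param marker_mean Planted log2FC of a cell's own markers.
#' @param noise_sd Gaussian SD added to every entry's planted mean.
#' @param n_extra_genes Unstructured null genes appended to the matrix.
#' @param ighg_fraction Probability a PC expresses IGHG.
#' @param day Day label attached to all cells.
#' @return List: `matrix` (cells x genes), `truth` (cell_id, subset, zone,
#'   pc_state, nox_mrna, ighg_expresser, day), `marker_config`,
#'   `nox_genes`.
#' @export
generate_rna_matrix <- function(composition = default_composition(),
                                marker_config = default_marker_config(),
                                nox_positive_fraction = 0.25,
                                n_cells = 1000,
                                seed = 1L,
                                marker_mean = 2,
                                noise_sd = 0.3,
                                n_extra_genes = 100,
                                ighg_fraction = 0.6,
                                day = 0) {
  stopifnot(abs(sum(composition) - 1) < 1e-9)
  subsets <- names(marker_config$subsets)
  unknown <- setdiff(names(composition), subsets)
  if (length(unknown))
    stop("unknown subset in composition: ", paste(unknown, collapse = ", "))
  set.seed(seed)

  subset <- sample(names(composition), n_cells, replace = TRUE,
                   prob = composition)
  nfrac <- if (length(nox_positive_fraction) == 1)
    stats::setNames(rep(nox_positive_fraction, length(composition)),
                    names(composition))
  else nox_positive_fraction
  nox_pos <- stats::runif(n_cells) < nfrac[subset]

  nox_genes <- nox_gene_set()
  hk <- housekeeping_genes()
  isotype <- c("IGHG1", "IGHG2B", "IGHG3", "IGHM")
  extra <- if (n_extra_genes > 0) sprintf("GENE%04d", seq_len(n_extra_genes))
           else character(0)
  genes <- unique(c(unlist(marker_config$subsets),
                    unlist(marker_config$gc_zones),
                    unlist(marker_config$pc_states),
                    nox_genes, hk, isotype, extra))
  mu <- matrix(0, n_cells, length(genes), dimnames = list(NULL, genes))

  for (s in subsets) {
    idx <- subset == s
    if (any(idx)) mu[idx, marker_config$subsets[[s]]] <- marker_mean
  }

  # GC zone and PC state sub-labels
  zone <- rep(NA_character_, n_cells)
  is_gc <- subset == "gcbc"
  if (any(is_gc) && length(marker_config$gc_zones)) {
    zone[is_gc] <- sample(names(marker_config$gc_zones), sum(is_gc),
                          replace = TRUE, prob = c(0.6, 0.4))
    for (z in names(marker_config$gc_zones)) {
      idx <- !is.na(zone) & zone == z
      if (any(idx)) mu[idx, marker_config$gc_zones[[z]]] <-
          mu[idx, marker_config$gc_zones[[z]]] + marker_mean
    }
  }
  pc_state <- rep(NA_character_, n_cells)
  is_pc <- subset == "pc"
  if (any(is_pc) && length(marker_config$pc_states)) {
    pc_state[is_pc] <- sample(names(marker_config$pc_states), sum(is_pc),
                              replace = TRUE,
                              prob = c(0.10, 0.15, 0.40, 0.35))
    for (st in names(marker_config$pc_states)) {
      idx <- !is.na(pc_state) & pc_state == st
      if (any(idx)) mu[idx, marker_config$pc_states[[st]]] <-
          mu[idx, marker_config$pc_states[[st]]] + marker_mean
    }
  }

  # NOX genes: positive cells express NOX1 and/or NOX2; every other set
  # gene (and all set genes of negative cells) sits at or below zero
  mu[, nox_genes] <- -0.3
  if (any(nox_pos)) {
    which_iso <- sample(c("NOX1", "NOX2", "both"), sum(nox_pos),
                        replace = TRUE, prob = c(0.35, 0.50, 0.15))
    pos_idx <- which(nox_pos)
    mu[pos_idx[which_iso != "NOX2"], "NOX1"] <- 1
    mu[pos_idx[which_iso != "NOX1"], "NOX2"] <- 1
  }

  # isotype genes: a fraction of PCs expresses IGHG, the rest IGHM
  mu[, isotype] <- -0.2
  ighg <- rep(FALSE, n_cells)
  if (any(is_pc)) ighg[is_pc] <- stats::runif(sum(is_pc)) < ighg_fraction

  m <- mu + if (noise_sd > 0)
    matrix(stats::rnorm(length(mu), 0, noise_sd), nrow = n_cells) else 0

  # enforce the planted sign structure exactly (gating truth must hold
  # even under noise): NOX set and isotype values are sign-constrained
  m[, nox_genes] <- pmin(m[, nox_genes], 0)
  pos_cells <- which(nox_pos)
  if (length(pos_cells)) {
    for (gidx in c("NOX1", "NOX2")) {
      planted <- pos_cells[mu[pos_cells, gidx] == 1]
      m[planted, gidx] <- pmax(1 + stats::rnorm(length(planted), 0, noise_sd),
                               0.05)
    }
  }
  m[, isotype] <- pmin(m[, isotype], 0)
  if (any(ighg)) {
    g_pick <- sample(c("IGHG1", "IGHG2B", "IGHG3"), sum(ighg), replace = TRUE)
    m[cbind(which(ighg), match(g_pick, genes))] <-
      pmax(marker_mean + stats::rnorm(sum(ighg), 0, noise_sd), 0.05)
  }
  if (any(is_pc & !ighg))
    m[cbind(which(is_pc & !ighg), match("IGHM", genes))] <-
      pmax(marker_mean + stats::rnorm(sum(is_pc & !ighg), 0, noise_sd), 0.05)

  truth <- data.frame(cell_id = seq_len(n_cells), subset = subset,
                      zone = zone, pc_state = pc_state,
                      nox_mrna = ifelse(nox_pos, "pos", "neg"),
                      ighg_expresser = ighg, day = day,
                      stringsAsFactors = FALSE)
  rownames(m) <- sprintf("cell%05d", seq_len(n_cells))
  list(matrix = m, truth = truth, marker_config = marker_config,
       nox_genes = nox_genes)
}
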