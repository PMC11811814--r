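#' Two-sample Kolmogorov-Smirnov comparison of distributions
#'
#' Used to compare per-cell secretion-rate or ROS-slope distributions
#' between droplet classes (e.g. NOX-active vs inactive cells).
#'
#' @param a,b Numeric samples with >= 2 values each.
#' @return A `stats_result` (test name, D statistic, p, group sizes, star
#'   label).
#' @export
compare_distributions <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need >= 2 values")
  ks <- suppressWarnings(stats::ks.test(a, b))
  structure(list(test = "Two-sample Kolmogorov-Smirnov",
                 statistic = unname(ks$statistic), p = ks$p.value,
                 group_sizes = c(length(a), length(b)),
                 star = star_label(ks$p.value)),
            class = "stats_result")
}

#' Significance star label for a p-value
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, `****` for
#' p < 0.0001, `"ns"` otherwise.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' star_label(c(0.04, 0.0005, 0.5))
#' @export
star_label <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
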