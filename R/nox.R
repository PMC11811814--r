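#' Percent signal loss of an oxidation-sensitive dye trace
#'
#' The per-droplet NOX-activity statistic: with `signal_t1` the intensity
#' at the first time point and `signal_lowest` the minimum intensity over
#' the second to last time points,
#' `x = 100 * (signal_t1 - signal_lowest) / signal_t1`.
#' Negative values (the signal rose) are retained without clamping; they
#' can only ever classify negative and keep control distributions honest.
#'
#' @param trace Numeric vector of A647 droplet means over >= 2 frames, in
#'   acquisition order.
#' @return A one-row data frame (`x_pct`, `signal_t1`, `signal_lowest`).
#' @examples
#' signal_loss(c(200, 190, 170, 180, 185, 190))  # x_pct = 15
#' @export
signal_loss <- function(trace) {
  trace <- as.numeric(trace)
  if (length(trace) < 2) stop("signal_loss needs >= 2 frames")
  if (anyNA(trace)) stop("trace contains missing values")
  s1 <- trace[1]
  if (s1 <= 0) stop("first-frame signal must be > 0")
  lowest <- min(trace[-1])
  data.frame(x_pct = 100 * (s1 - lowest) / s1,
             signal_t1 = s1, signal_lowest = lowest)
}

#' Signal loss for every droplet in a trace table
#'
#' Applies [signal_loss()] to the `a647` channel of a long trace table
#' (as produced by [generate_trace_set()] or [extract_traces()]).
#'
#' @param traces Long trace data frame with columns `droplet_id`, `frame`,
#'   `channel`, `droplet_mean`.
#' @return Data frame with one row per droplet: `droplet_id`, `x_pct`,
#'   `signal_t1`, `signal_lowest`.
#' @export
signal_loss_table <- function(traces) {
  a <- traces[traces$channel == "a647", ]
  if (nrow(a) == 0) stop("traces contain no a647 channel")
  a <- a[order(a$droplet_id, a$frame), ]
  sp <- split(a$droplet_mean, a$droplet_id)
  out <- do.call(rbind, lapply(sp, signal_loss))
  out <- cbind(droplet_id = as.integer(names(sp)), out)
  rownames(out) <- NULL
  out[order(out$droplet_id), ]
}

#' Fit the control-derived NOX classification threshold
#'
#' The classification threshold is the median plus `k` (default 3) sample
#' standard deviations of the percent signal loss observed in control
#' droplets that contain the dye-labelled probe but no NOX activity:
#' `threshold = median(x) + k * SD(x)`.
#'
#' @param control_losses Numeric vector of control `x_pct` values, or a
#'   data frame with an `x_pct` column. At least 2 values.
#' @param k SD multiplier (default 3).
#' @return An object of class `nox_threshold` with fields `source`
#'   (`"control_derived"`), `median_pct`, `sd_pct`, `k`, `threshold_pct`.
#' @examples
#' fit_threshold(c(1, 2, 3))  # median 2 + 3*1 = 5
#' @export
fit_threshold <- function(control_losses, k = 3) {
  if (is.data.frame(control_losses)) control_losses <- control_losses$x_pct
  control_losses <- as.numeric(control_losses)
  if (length(control_losses) < 2)
    stop("need >= 2 control droplets; with no controls use fixed_threshold()")
  m <- stats::median(control_losses)
  s <- stats::sd(control_losses)
  structure(list(source = "control_derived", median_pct = m, sd_pct = s,
                 k = k, threshold_pct = m + k * s),
            class = "nox_threshold")
}

#' Fixed NOX classification threshold
#'
#' The default operating threshold of 10.3% signal loss, as established on
#' probe-only control droplets.
#'
#' @param threshold_pct Threshold in percent signal loss.
#' @return An object of class `nox_threshold` with `source = "fixed"`.
#' @export
fixed_threshold <- function(threshold_pct = 10.3) {
  structure(list(source = "fixed", median_pct = NA_real_, sd_pct = NA_real_,
                 k = NA_real_, threshold_pct = threshold_pct),
            class = "nox_threshold")
}

#' @export
print.nox_threshold <- function(x, ...) {
  cat("NOX signal-loss threshold:", format(x$threshold_pct, digits = 4),
      "% (", x$source, ")\n", sep = "")
  if (x$source == "control_derived")
    cat("  median ", format(x$median_pct, digits = 4), "% + ", x$k, " x SD ",
        format(x$sd_pct, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' @export
coef.nox_threshold <- function(object, ...) {
  c(median_pct = object$median_pct, sd_pct = object$sd_pct, k = object$k,
    threshold_pct = object$threshold_pct)
}

#' Classify droplets as NOX-active by signal loss
#'
#' A droplet is `NOX_drop_pos` when its percent signal loss is strictly
#' greater than the threshold; a loss exactly at the threshold classifies
#' negative.
#'
#' @param x Numeric `x_pct` values or a data frame with `x_pct` (and
#'   optionally `droplet_id`).
#' @param model A `nox_threshold` from [fit_threshold()] or
#'   [fixed_threshold()] (default).
#' @return If `x` is a data frame: the data frame with `threshold_pct` and
#'   `label` columns appended. Otherwise a character vector of labels
#'   (`"NOX_drop_pos"` / `"NOX_drop_neg"`).
#' @export
classify_nox <- function(x, model = fixed_threshold()) {
  stopifnot(inherits(model, "nox_threshold"),
            is.finite(model$threshold_pct))
  vals <- if (is.data.frame(x)) x$x_pct else as.numeric(x)
  label <- ifelse(vals > model$threshold_pct, "NOX_drop_pos", "NOX_drop_neg")
  if (is.data.frame(x)) {
    x$threshold_pct <- model$threshold_pct
    x$label <- label
    x
  } else label
}

#' Frequency of NOX-active droplets among analyzable cell droplets
#'
#' The denominator counts droplets that contain at least one cell and
#' tracked cleanly (`track_quality == "ok"`); everything else is excluded.
#' Zero denominators report `NA` (undefined), never 0.
#'
#' @param calls Data frame from [classify_nox()] with `droplet_id`, `label`.
#' @param droplets Data frame with `droplet_id`, `n_cells` and optionally
#'   `track_quality` and `condition` (e.g. a truth table or an extracted
#'   trace table collapsed to one row per droplet).
#' @return Data frame per condition: `condition`, `n_pos`, `n_total`,
#'   `pct_pos`.
#' @export
nox_frequency <- function(calls, droplets) {
  d <- droplets[!duplicated(droplets$droplet_id),
                intersect(c("droplet_id", "n_cells", "track_quality",
                            "condition"), names(droplets))]
  if (is.null(d$track_quality)) d$track_quality <- "ok"
  if (is.null(d$condition)) d$condition <- "all"
  m <- merge(calls[, c("droplet_id", "label")], d, by = "droplet_id")
  m <- m[m$n_cells >= 1 & m$track_quality == "ok", ]
  conds <- unique(d$condition)
  out <- do.call(rbind, lapply(conds, function(cc) {
    g <- m[m$condition == cc, ]
    n_tot <- nrow(g)
    n_pos <- sum(g$label == "NOX_drop_pos")
    data.frame(condition = cc, n_pos = n_pos, n_total = n_tot,
               pct_pos = if (n_tot == 0) NA_real_ else 100 * n_pos / n_tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Brown-Forsythe test for equality of means (F* statistic with
# Satterthwaite-type denominator df), as reported alongside Welch's ANOVA
# by common statistics packages. Not the Levene/Brown-Forsythe variance
# test.
brown_forsythe_anova <- function(values, groups) {
  groups <- factor(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  vi <- tapply(values, groups, stats::var)
  N <- sum(ni)
  grand <- sum(ni * mi) / N
  num <- sum(ni * (mi - grand)^2)
  ci <- (1 - ni / N) * vi
  den <- sum(ci)
  Fstar <- num / den
  df1 <- length(ni) - 1
  df2 <- den^2 / sum(ci^2 / (ni - 1))
  p <- stats::pf(Fstar, df1, df2, lower.tail = FALSE)
  list(statistic = Fstar, df1 = df1, df2 = df2, p.value = p)
}

#' Compare NOX-frequency (or any per-replicate metric) across conditions
#'
#' Two conditions are compared with Welch's t-test; more than two with
#' Welch's ANOVA together with the Brown-Forsythe test for means (both are
#' reported; the Welch p-value drives the star label). With a single
#' replicate per condition only descriptive output is returned, no p.
#'
#' @param freqs Data frame with columns `condition` and a numeric value
#'   column (default `pct_pos`), one row per replicate.
#' @param value Name of the value column.
#' @return An object of class `stats_result` (test name, statistic, p,
#'   group sizes, star label) or, when inference is impossible, a
#'   descriptive list with `p = NA`.
#' @export
condition_contrast <- function(freqs, value = "pct_pos") {
  stopifnot(is.data.frame(freqs), value %in% names(freqs),
            "condition" %in% names(freqs))
  v <- freqs[[value]]
  g <- factor(freqs$condition)
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need >= 2 conditions")
  if (any(sizes < 2)) {
    return(structure(list(test = "descriptive", statistic = NA_real_,
                          p = NA_real_, group_sizes = as.integer(sizes),
                          star = NA_character_,
                          means = tapply(v, g, mean)),
                     class = "stats_result"))
  }
  if (nlevels(g) == 2) {
    tt <- stats::t.test(v ~ g)  # Welch by default
    res <- list(test = "Welch t-test", statistic = unname(tt$statistic),
                p = tt$p.value, group_sizes = as.integer(sizes),
                star = star_label(tt$p.value), means = tapply(v, g, mean))
  } else {
    w <- stats::oneway.test(v ~ g, var.equal = FALSE)
    bf <- brown_forsythe_anova(v, g)
    res <- list(test = "Brown-Forsythe and Welch ANOVA",
                statistic = unname(w$statistic), p = w$p.value,
                brown_forsythe = bf, group_sizes = as.integer(sizes),
                star = star_label(w$p.value), means = tapply(v, g, mean))
  }
  structure(res, class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(x$test, "\n")
  if (!is.na(x$p))
    cat("  statistic =", format(x$statistic, digits = 4),
        " p =", format.pval(x$p, digits = 3), paste0("(", x$star, ")"), "\n")
  cat("  group sizes:", paste(x$group_sizes, collapse = ", "), "\n")
  invisible(x)
}
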