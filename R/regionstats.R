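#' Per-region summaries of a relaxometry map
#'
#' Mean and sample (n-1) standard deviation of the masked map values in
#' each labelled region. Regions without masked voxels are reported with
#' `NA` and flagged.
#'
#' @param values numeric array (or vector) of map values.
#' @param labels integer array of region labels (0 = unlabelled).
#' @param mask optional logical array; defaults to `labels > 0`.
#' @return data.frame with columns `label`, `n`, `mean`, `sd`, `empty`.
#' @export
region_summaries <- function(values, labels, mask = NULL) {
  if (length(values) != length(labels))
    stop("values and labels geometry mismatch")
  if (is.null(mask)) mask <- labels > 0
  if (length(mask) != length(values))
    stop("mask geometry mismatch")
  keep <- as.logical(mask) & labels > 0
  v <- as.numeric(values)[keep]
  l <- as.integer(labels)[keep]
  all_labels <- sort(unique(as.integer(labels[labels > 0])))
  out <- data.frame(label = all_labels, n = 0L, mean = NA_real_,
                    sd = NA_real_, empty = TRUE)
  if (length(l)) {
    agg_n <- tapply(v, l, length)
    agg_m <- tapply(v, l, mean)
    agg_s <- tapply(v, l, stats::sd)
    idx <- match(as.integer(names(agg_n)), out$label)
    out$n[idx] <- as.integer(agg_n)
    out$mean[idx] <- as.numeric(agg_m)
    out$sd[idx] <- as.numeric(agg_s)
    out$empty[idx] <- FALSE
  }
  out
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, measuring agreement with the identity line:
#' it penalizes both scatter around the best-fit line and systematic
#' location/scale shifts, and equals 1 only for exact elementwise
#' equality.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return scalar in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least two pairs")
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  den <- sx2 + sy2 + (mx - my)^2
  if (den == 0) {
    if (all(x == y)) return(1)
    stop("degenerate input: zero variance and equal means")
  }
  2 * sxy / den
}

#' Paired regional data for agreement analysis
#'
#' @param subject cluster identifiers (one per observation).
#' @param region region identifiers.
#' @param true,dl paired measurements (e.g. acquired vs. synthesized T1
#'   per subject and region).
#' @return data.frame of class `paired_region_data`.
#' @export
paired_region_data <- function(subject, region, true, dl) {
  n <- length(true)
  stopifnot(length(dl) == n, length(subject) == n, length(region) == n)
  structure(data.frame(subject = subject, region = region,
                       true = as.numeric(true), dl = as.numeric(dl)),
            class = c("paired_region_data", "data.frame"))
}

#' Clustered bootstrap of a paired statistic
#'
#' Resamples subject clusters with replacement (all of a sampled
#' subject's regions enter together, preserving the within-subject
#' correlation structure), recomputes the statistic on each replicate and
#' reports the percentile confidence interval. The point estimate is the
#' statistic on the original data. With every cluster of size one this
#' reduces to the ordinary iid bootstrap.
#'
#' @param data a [paired_region_data()] (or data.frame with columns
#'   `subject`, `true`, `dl`).
#' @param statistic function of two vectors `(true, dl) -> scalar`, e.g.
#'   [ccc()] or `function(x, y) mean(x - y)`.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95, percentile method).
#' @return list with `estimate`, `ci` (length 2), `replicates`,
#'   `n_boot`.
#' @export
clustered_bootstrap <- function(data, statistic, n_boot = 10000, seed = 0,
                                conf = 0.95) {
  stopifnot(is.data.frame(data), n_boot >= 1)
  subjects <- unique(data$subject)
  ns <- length(subjects)
  if (ns < 1) stop("need at least one cluster")
  est <- statistic(data$true, data$dl)
  idx_by_subject <- lapply(subjects, function(s) which(data$subject == s))
  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    pick <- sample.int(ns, ns, replace = TRUE)
    rows <- unlist(idx_by_subject[pick], use.names = FALSE)
    reps[b] <- tryCatch(
      statistic(data$true[rows], data$dl[rows]),
      error = function(e) stop(sprintf(
        "statistic failed on bootstrap replicate %d: %s", b,
        conditionMessage(e)), call. = FALSE))
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  list(estimate = est, ci = ci, replicates = reps, n_boot = n_boot)
}

#' Read the packaged regional relaxometry table
#'
#' A 47-region table of acquired ("true") versus network-synthesized
#' ("DL") T1 and T2 means and standard deviations (ms), averaged over a
#' five-subject test cohort; the packaged copy ships with an integrity
#' checksum.
#'
#' @param path optional path to a compatible tab-delimited file; defaults
#'   to the packaged fixture.
#' @return data.frame of class `region_stats_table`.
#' @export
read_region_stats <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "regional_relaxometry.tsv",
                        package = "mrfsynth", mustWork = TRUE)
    sum_ <- unname(tools::md5sum(path))
    if (!identical(sum_, "2fb938e942d753edbecc4619eee1b828"))
      stop("packaged regional table failed its integrity checksum")
  }
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("region", "t1_true_mean", "t1_true_sd", "t1_dl_mean",
            "t1_dl_sd", "t2_true_mean", "t2_true_sd", "t2_dl_mean",
            "t2_dl_sd")
  if (!all(need %in% names(tab))) stop("missing columns in region table")
  if (anyNA(tab[need[-1]])) stop("missing cells in region table")
  if (any(tab$t1_true_mean <= 0 | tab$t2_true_mean <= 0 |
          tab$t1_dl_mean <= 0 | tab$t2_dl_mean <= 0))
    stop("region means must be positive")
  structure(tab, class = c("region_stats_table", "data.frame"))
}

#' Agreement report from a regional statistics table
#'
#' Computes, for T1 and T2 separately: the average over regions of
#' (true mean - DL mean); the per-region coefficient of variation
#' (SD / mean) of each column with its minimum, maximum and mean; and
#' Lin's CCC between the paired region-mean columns. All quantities are
#' exact deterministic functions of the table.
#'
#' @param table a [read_region_stats()] table.
#' @return list with elements `t1`, `t2`, each containing
#'   `mean_difference`, `ccc_of_means`, and `cov` (a data.frame with one
#'   row per column: `column`, `min`, `max`, `mean`), plus `n_regions`.
#' @export
table_report <- function(table = read_region_stats()) {
  stopifnot(inherits(table, "region_stats_table"))
  cov_summary <- function(sd, mean) {
    cv <- sd / mean
    c(min = min(cv), max = max(cv), mean = mean(cv))
  }
  per <- function(p) {
    tm <- table[[paste0(p, "_true_mean")]]
    dm <- table[[paste0(p, "_dl_mean")]]
    covs <- rbind(
      true = cov_summary(table[[paste0(p, "_true_sd")]], tm),
      dl = cov_summary(table[[paste0(p, "_dl_sd")]], dm))
    list(mean_difference = mean(tm - dm),
         ccc_of_means = ccc(tm, dm),
         cov = data.frame(column = rownames(covs), covs,
                          row.names = NULL))
  }
  list(t1 = per("t1"), t2 = per("t2"), n_regions = nrow(table))
}

#' Regional agreement between two maps
#'
#' Convenience wrapper: per-region means of a true and a synthesized map
#' under shared labels, assembled into paired data with one cluster per
#' supplied subject id.
#' @param true_map,dl_map numeric arrays.
#' @param labels integer label array.
#' @param subject cluster id attached to these volumes (default 1).
#' @param mask optional logical array.
#' @return a [paired_region_data()].
#' @export
regional_pairs <- function(true_map, dl_map, labels, subject = 1,
                           mask = NULL) {
  st <- region_summaries(true_map, labels, mask)
  sd_ <- region_summaries(dl_map, labels, mask)
  keep <- !st$empty & !sd_$empty
  paired_region_data(subject = rep(subject, sum(keep)),
                     region = st$label[keep],
                     true = st$mean[keep], dl = sd_$mean[keep])
}
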