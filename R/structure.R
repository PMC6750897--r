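#' C-alpha RMSD after optimal rigid superposition
#'
#' Kabsch superposition: both coordinate sets are centered, the optimal
#' rotation is obtained from the singular value decomposition of the
#' cross-covariance matrix (with the reflection guard on the determinant),
#' and the root mean square deviation of the superposed coordinates is
#' returned.
#'
#' @param coords_a,coords_b Numeric matrices of matched coordinates,
#'   `n x 3` with `n >= 3` and equal `n` (the correspondence is given, as
#'   from a precomputed structural alignment).
#' @return RMSD in the coordinate units (Angstrom for PDB input). A
#'   degenerate (collinear or coincident) point set triggers a warning; the
#'   superposition itself is still well defined.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch_rmsd(x, x) # 0
#' @export
kabsch_rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 3 || ncol(b) != 3 ||
      nrow(a) != nrow(b)) {
    abort("Coordinate sets must be numeric n x 3 matrices of equal length.",
          class = "divlimit_invalid_input")
  }
  if (nrow(a) < 3) {
    abort("Need at least 3 matched points.", class = "divlimit_invalid_input")
  }
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  H <- crossprod(a0, b0)
  s <- svd(H)
  if (s$d[2] < 1e-10 * max(s$d[1], 1)) {
    warn("Degenerate (collinear) coordinate set; rotation is not unique.")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diff <- b0 - a0 %*% t(R)
  sqrt(mean(rowSums(diff^2)))
}

#' Filter structure pairs by alignment coverage
#'
#' Drops ortholog pairs for which more than `max_unaligned` of the shorter
#' protein's residues could not be structurally aligned (default: more
#' than 70% unaligned, i.e. coverage below 0.3). When a logical `flexible`
#' column is present (from a flexible-alignment screen), flexible pairs
#' are dropped too.
#'
#' @param records Data frame with a `coverage` column in (0, 1].
#' @param max_unaligned Maximum unaligned fraction of the shorter protein.
#' @return The filtered tibble.
#' @export
coverage_filter <- function(records, max_unaligned = 0.7) {
  records <- tibble::as_tibble(records)
  stopifnot("coverage" %in% names(records))
  keep <- records$coverage >= (1 - max_unaligned) - 1e-9
  if ("flexible" %in% names(records)) {
    keep <- keep & !(records$flexible %in% TRUE)
  }
  records[keep, , drop = FALSE]
}

#' Structural divergence as a function of time
#'
#' Summarizes RMSD-versus-divergence-time records: rank-based Spearman
#' correlation, per-time-bin percentile boxes (median, 25-75 and 5-95
#' percentiles), and a centered moving average over the time-sorted
#' records.
#'
#' @param records Data frame with columns `time` (Gy) and `rmsd`
#'   (Angstrom); >= 3 records with non-constant times.
#' @param bin_edges Time-bin break points (left-closed, right-open);
#'   default: 0.5-Gy bins spanning the data.
#' @param ma_window Moving-average window in records (odd; default 51,
#'   truncated to the data size).
#' @return List with `spearman` (one-row tibble: `rho`, `p.value`, `n`),
#'   `bins` (per-bin percentiles) and `moving_average` (tibble `time`,
#'   `rmsd_ma`).
#' @export
rmsd_time_trend <- function(records, bin_edges = NULL, ma_window = 51L) {
  d <- tibble::as_tibble(records)
  stopifnot(all(c("time", "rmsd") %in% names(d)))
  d <- d[complete.cases(d[c("time", "rmsd")]), ]
  if (nrow(d) < 3) {
    abort("Need at least 3 records.", class = "divlimit_insufficient_data")
  }
  if (length(unique(d$time)) < 2) {
    abort("All divergence times tied; Spearman correlation undefined.",
          class = "divlimit_invalid_input")
  }
  ct <- suppressWarnings(cor.test(d$time, d$rmsd, method = "spearman",
                                  exact = FALSE))
  if (is.null(bin_edges)) {
    bin_edges <- seq(floor(min(d$time) / 0.5) * 0.5,
                     ceiling(max(d$time) / 0.5) * 0.5 + 0.5, by = 0.5)
  }
  d$time_bin <- cut(d$time, breaks = bin_edges, right = FALSE,
                    include.lowest = TRUE)
  bins <- dplyr::summarise(
    dplyr::group_by(d, .data$time_bin),
    median = median(.data$rmsd),
    q25 = quantile(.data$rmsd, 0.25), q75 = quantile(.data$rmsd, 0.75),
    q05 = quantile(.data$rmsd, 0.05), q95 = quantile(.data$rmsd, 0.95),
    n = dplyr::n(), .groups = "drop"
  )
  dd <- dplyr::arrange(d, .data$time)
  w <- min(ma_window, nrow(dd))
  if (w %% 2 == 0) w <- w - 1
  ma <- as.numeric(stats::filter(dd$rmsd, rep(1 / w, w), sides = 2))
  list(
    spearman = tibble::tibble(rho = unname(ct$estimate),
                              p.value = ct$p.value, n = nrow(d)),
    bins = bins,
    moving_average = tibble::tibble(time = dd$time, rmsd_ma = ma)
  )
}

#' Compare a divergence metric across functional-specificity groups
#'
#' Per-group summaries and pairwise two-sided Mann-Whitney (Wilcoxon
#' rank-sum) tests for a metric such as long-term percent identity or
#' C-alpha RMSD across groups of ortholog pairs with different degrees of
#' functional conservation (full EC match, 3-digit EC match, same fold
#' only). Optionally restricts to pairs with divergence time above
#' `min_time` (the long-term subset).
#'
#' @param records Data frame; must contain the `value` and `group` columns
#'   and, when `min_time` is used, a `time` column.
#' @param value,group Column names (tidy-eval) of the metric and the group
#'   label.
#' @param min_time Keep records with `time > min_time` (default `NULL`: no
#'   filter).
#' @return List with `summary` (per group: `n`, `mean`, `median`) and
#'   `tests` (pairwise: `group1`, `group2`, `statistic`, `p.value`).
#'   Singleton groups are excluded with a warning.
#' @export
functional_group_comparison <- function(records, value, group,
                                        min_time = NULL) {
  d <- tibble::as_tibble(records)
  vals <- dplyr::pull(d, {{ value }})
  grps <- as.character(dplyr::pull(d, {{ group }}))
  if (!is.null(min_time)) {
    keep <- d$time > min_time
    vals <- vals[keep]; grps <- grps[keep]
  }
  ok <- !is.na(vals) & !is.na(grps)
  vals <- vals[ok]; grps <- grps[ok]
  sizes <- table(grps)
  if (any(sizes < 2)) {
    warn(paste0("Excluding singleton group(s): ",
                paste(names(sizes)[sizes < 2], collapse = ", ")))
    keep <- grps %in% names(sizes)[sizes >= 2]
    vals <- vals[keep]; grps <- grps[keep]
  }
  gl <- sort(unique(grps))
  if (length(gl) < 2) {
    abort("Need at least 2 groups with >= 2 values each.",
          class = "divlimit_insufficient_data")
  }
  summary <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(value = vals, group = grps), .data$group),
    n = dplyr::n(), mean = mean(.data$value), median = median(.data$value),
    .groups = "drop"
  )
  combos <- utils::combn(gl, 2)
  tests <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    wt <- suppressWarnings(wilcox.test(vals[grps == g1], vals[grps == g2],
                                       alternative = "two.sided"))
    tibble::tibble(group1 = g1, group2 = g2,
                   statistic = unname(wt$statistic), p.value = wt$p.value)
  })
  list(summary = summary, tests = tests)
}

#' Sequence identity compared across groups within structural-similarity bins
#'
#' Bins ortholog pairs by RMSD (left-closed, right-open bins) and, within
#' each bin, compares percent identity across functional-specificity
#' groups — asking whether functional conservation constrains sequence
#' beyond what maintaining the structure requires.
#'
#' @param records Data frame with columns `identity`, `rmsd` and `group`.
#' @param rmsd_bin_edges Break points in Angstrom (default 0.5-Angstrom
#'   bins spanning the data).
#' @return List with `summary` (per bin x group: `n`, `mean`, `median`)
#'   and `tests` (per bin pairwise Mann-Whitney); bins with fewer than two
#'   usable groups appear in `summary` only.
#' @export
identity_by_structure_bins <- function(records, rmsd_bin_edges = NULL) {
  d <- tibble::as_tibble(records)
  stopifnot(all(c("identity", "rmsd", "group") %in% names(d)))
  if (is.null(rmsd_bin_edges)) {
    rmsd_bin_edges <- seq(floor(min(d$rmsd) / 0.5) * 0.5,
                          ceiling(max(d$rmsd) / 0.5) * 0.5 + 0.5, by = 0.5)
  }
  d$rmsd_bin <- cut(d$rmsd, breaks = rmsd_bin_edges, right = FALSE,
                    include.lowest = TRUE)
  d <- d[!is.na(d$rmsd_bin), ]
  summary <- dplyr::summarise(
    dplyr::group_by(d, .data$rmsd_bin, .data$group),
    n = dplyr::n(), mean = mean(.data$identity),
    median = median(.data$identity), .groups = "drop"
  )
  tests <- purrr::map_dfr(split(d, d$rmsd_bin, drop = TRUE), function(bin) {
    enough <- names(which(table(bin$group) >= 2))
    if (length(enough) < 2) return(NULL)
    res <- suppressWarnings(
      functional_group_comparison(bin[bin$group %in% enough, ],
                                  value = "identity", group = "group")
    )
    dplyr::mutate(res$tests, rmsd_bin = unique(bin$rmsd_bin), .before = 1)
  })
  list(summary = summary, tests = tests)
}
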