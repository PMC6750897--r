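#' @name mage-fitness
#' @title Growth-rate estimation from pooled competition read counts
#' @description
#' Functions to estimate per-mutant relative growth rates and per-site
#' average fitness effects from amplicon read counts of a pooled
#' turbidostat competition (a MAGE-style deep mutational scan). The count
#' table is a wide tibble: one row per mutant plus a `WT` row, identifier
#' columns `mutant_id`, `position`, `codon`, `aa`, `wt_aa`, `batch`, and
#' one numeric column per sampling time whose name is the time in hours
#' (`"0"`, `"2"`, ...). In exponential growth the log ratio of mutant to WT
#' reads is linear in time with slope equal to the growth-rate difference;
#' dividing that slope by the turbidostat dilution rate (e-folds per hour)
#' gives the relative growth-rate difference.
NULL

time_columns <- function(counts) {
  nm <- names(counts)
  tc <- nm[suppressWarnings(!is.na(as.numeric(nm)))]
  if (length(tc) < 2) {
    abort("Count table needs >= 2 numeric-named time-point columns (hours).",
          class = "divlimit_invalid_input")
  }
  tc[order(as.numeric(tc))]
}

wt_row_index <- function(counts) {
  i <- which(toupper(counts$mutant_id) == "WT")
  if (length(i) != 1) {
    abort("Count table must contain exactly one `WT` row.",
          class = "divlimit_invalid_input")
  }
  i
}

#' Median-normalize counts across mutagenesis batches
#'
#' Mutagenesis was performed in batches of 10 codons, which introduces
#' batch-level abundance noise. Within each time point, every batch's
#' counts are divided by the batch median; the resulting values at that
#' time point are then rescaled by a common factor so that the total
#' (non-WT) count is preserved. A single-batch table is therefore returned
#' unchanged. Batches with a zero median are flagged and left
#' unnormalized. The WT row is untouched.
#'
#' @param counts A MAGE count table (see [mage-fitness]).
#' @return The normalized table; batches with zero medians are listed in
#'   the `"flagged_batches"` attribute.
#' @export
median_normalize <- function(counts) {
  counts <- tibble::as_tibble(counts)
  tc <- time_columns(counts)
  wt <- wt_row_index(counts)
  flagged <- character(0)
  for (tp in tc) {
    v <- counts[[tp]]
    scaled <- v
    for (b in unique(counts$batch[-wt])) {
      rows <- setdiff(which(counts$batch == b), wt)
      if (length(rows) == 0) next
      med <- median(v[rows])
      if (!is.finite(med) || med == 0) {
        flagged <- union(flagged, as.character(b))
        next
      }
      scaled[rows] <- v[rows] / med
    }
    tot_old <- sum(v[-wt])
    tot_new <- sum(scaled[-wt])
    if (tot_new > 0) {
      scaled[-wt] <- scaled[-wt] * tot_old / tot_new
    }
    counts[[tp]] <- scaled
  }
  attr(counts, "flagged_batches") <- flagged
  counts
}

#' Per-mutant relative growth rates from competition counts
#'
#' For each mutant, an ordinary least-squares slope of
#' `ln(count_mutant / count_WT)` against time, over the time points where
#' the mutant has at least `min_reads` reads (and WT is non-zero; time
#' points with zero WT reads are dropped for all mutants). Mutants with
#' fewer than `min_points` qualifying time points are flagged as filtered
#' and carry no estimate. The relative growth-rate difference is the slope
#' divided by the turbidostat dilution rate: a slope of -0.137/h at
#' dilution 1.37/h means 10% slower growth than WT.
#'
#' @param counts A MAGE count table (see [mage-fitness]).
#' @param dilution Turbidostat dilution rate in e-folds per hour
#'   (default 1.37).
#' @param min_points Minimum number of qualifying time points (default 5).
#' @param min_reads Minimum mutant reads for a time point to qualify
#'   (default 20).
#' @return Tibble: identifier columns plus `slope` (per hour),
#'   `rel_growth` (slope / dilution), `n_usable`, `filtered`.
#' @export
relative_growth_rates <- function(counts, dilution = 1.37,
                                  min_points = 5L, min_reads = 20L) {
  counts <- tibble::as_tibble(counts)
  tc <- time_columns(counts)
  wt <- wt_row_index(counts)
  times <- as.numeric(tc)
  wt_counts <- as.numeric(unlist(counts[wt, tc]))
  if (all(wt_counts <= 0)) {
    abort("WT has no positive counts.", class = "divlimit_invalid_input")
  }
  keep_tp <- wt_counts > 0
  mut <- counts[-wt, , drop = FALSE]
  M <- as.matrix(mut[tc])

  est <- purrr::map_dfr(seq_len(nrow(mut)), function(i) {
    usable <- keep_tp & M[i, ] >= min_reads
    n_usable <- sum(usable)
    if (n_usable < min_points) {
      return(tibble::tibble(slope = NA_real_, rel_growth = NA_real_,
                            n_usable = n_usable, filtered = TRUE))
    }
    lr <- log(M[i, usable] / wt_counts[usable])
    tt <- times[usable]
    slope <- sum((tt - mean(tt)) * (lr - mean(lr))) / sum((tt - mean(tt))^2)
    tibble::tibble(slope = slope, rel_growth = slope / dilution,
                   n_usable = n_usable, filtered = FALSE)
  })
  dplyr::bind_cols(mut[setdiff(names(mut), tc)], est)
}

#' Per-site average fitness effects
#'
#' Collapses per-mutant growth estimates to a single value per protein
#' site in two stages: codon-level estimates for the same amino-acid
#' change are averaged first, then the site mean is taken over the
#' available amino-acid substitutions (up to 20). Synonymous changes
#' (`aa == wt_aa`) are excluded from site means by default and reported
#' separately; nonsense substitutions (`aa == "*"`) are retained and
#' flagged.
#'
#' @param growth Output of [relative_growth_rates()] (filtered mutants are
#'   ignored).
#' @param include_synonymous Include synonymous substitutions in the site
#'   mean (default `FALSE`).
#' @return Tibble: `position`, `mean_fitness` (mean relative growth-rate
#'   difference across substitutions), `n_subs` (amino-acid changes
#'   contributing); sites with no estimated substitutions are absent.
#' @export
site_fitness_profile <- function(growth, include_synonymous = FALSE) {
  g <- tibble::as_tibble(growth)
  stopifnot(all(c("position", "codon", "aa", "rel_growth") %in% names(g)))
  g <- g[!is.na(g$rel_growth), ]
  if (!include_synonymous && "wt_aa" %in% names(g)) {
    g <- g[is.na(g$wt_aa) | g$aa != g$wt_aa, ]
  }
  by_aa <- dplyr::summarise(
    dplyr::group_by(g, .data$position, .data$aa),
    rel_growth = mean(.data$rel_growth), .groups = "drop"
  )
  dplyr::summarise(
    dplyr::group_by(by_aa, .data$position),
    mean_fitness = mean(.data$rel_growth),
    n_subs = dplyr::n(), .groups = "drop"
  )
}

ALL_CODONS <- as.vector(outer(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0)),
                              c("A","C","G","T"), paste0))

#' Split-half consistency of the site fitness profile
#'
#' Randomly partitions the 64 codons into two 32-codon halves, computes the
#' per-site fitness profile from each half independently, and returns the
#' Pearson correlation across sites — a measure of how robust the site
#' profile is to sequencing and sampling noise.
#'
#' @param counts A MAGE count table.
#' @param seed RNG seed for the codon partition.
#' @param ... Passed to [relative_growth_rates()].
#' @return One-row tibble: `correlation`, `n_sites`.
#' @export
split_half_consistency <- function(counts, seed = 0L, ...) {
  counts <- tibble::as_tibble(counts)
  half1 <- with_seed_if(seed, sample(ALL_CODONS, 32))
  wt <- wt_row_index(counts)
  keep1 <- counts$mutant_id == counts$mutant_id[wt] | counts$codon %in% half1
  keep2 <- counts$mutant_id == counts$mutant_id[wt] | !(counts$codon %in% half1)
  prof <- function(keep) {
    site_fitness_profile(relative_growth_rates(counts[keep, , drop = FALSE], ...))
  }
  p1 <- prof(keep1); p2 <- prof(keep2)
  m <- dplyr::inner_join(p1, p2, by = "position", suffix = c("_1", "_2"))
  if (nrow(m) < 3) {
    abort("Fewer than 3 sites with both half-profiles defined.",
          class = "divlimit_insufficient_data")
  }
  tibble::tibble(correlation = cor(m$mean_fitness_1, m$mean_fitness_2),
                 n_sites = nrow(m))
}
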