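#' @name site-divergence
#' @title Per-site conservation and stratified divergence curves
#' @description
#' These functions dissect which protein sites carry the long-term identity
#' between orthologs: per-site conservation across phylogenetically
#' independent ortholog pairs, the fraction of universally conserved sites,
#' and identity-versus-time curves for groups of sites stratified by
#' experimentally measured fitness effects or by distance from the active
#' site. All site indices are 1-based positions of the ungapped designated
#' reference sequence; alignment columns where the reference is gapped are
#' dropped, and a pair with a gap at a column is excluded from that site's
#' denominator.
NULL

# coerce an MSA (named character vector, AAStringSet, AAMultipleAlignment,
# or character matrix) into a character matrix: sequences x columns
as_aln_matrix <- function(msa) {
  if (is.matrix(msa) && is.character(msa)) return(msa)
  if (methods::is(msa, "AAMultipleAlignment")) {
    msa <- methods::as(msa, "AAStringSet")
  }
  if (methods::is(msa, "XStringSet")) {
    msa <- setNames(as.character(msa), names(msa))
  }
  if (!is.character(msa) || is.null(names(msa))) {
    abort("MSA must be a named character vector (or Biostrings alignment).",
          class = "divlimit_invalid_input")
  }
  lens <- nchar(msa)
  if (length(unique(lens)) != 1) {
    abort("Aligned sequences must all have equal length.",
          class = "divlimit_invalid_input")
  }
  m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

# map reference sites (1-based, ungapped) to alignment columns
reference_columns <- function(aln, reference_id) {
  if (!reference_id %in% rownames(aln)) {
    abort(sprintf("Reference `%s` not in the alignment.", reference_id),
          class = "divlimit_invalid_input")
  }
  which(aln[reference_id, ] != "-")
}

#' Per-site conservation profile across independent ortholog pairs
#'
#' For every site of the reference sequence, the fraction of
#' phylogenetically independent ortholog pairs in which the two orthologs
#' carry the identical residue at that site. Pairs with a gap in either
#' member at a column are excluded from that site's denominator.
#'
#' @param msa Multiple sequence alignment: named character vector of
#'   equal-length gapped sequences (Biostrings objects accepted).
#' @param pairs Data frame with columns `a` and `b` naming alignment
#'   members (e.g. from [select_independent_pairs()]); must be non-empty.
#' @param reference_id Name of the reference sequence in the MSA.
#' @return Tibble of class `"site_profile"`: `site` (1-based reference
#'   coordinate), `column` (alignment column), `ref_aa`, `fraction`,
#'   `n_pairs` (site-specific denominator).
#' @export
site_identity_profile <- function(msa, pairs, reference_id) {
  aln <- as_aln_matrix(msa)
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    abort("Pair set is empty.", class = "divlimit_invalid_input")
  }
  missing <- setdiff(unique(c(pairs$a, pairs$b)), rownames(aln))
  if (length(missing) > 0) {
    abort(paste0("Pair members absent from the MSA: ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "divlimit_invalid_input")
  }
  cols <- reference_columns(aln, reference_id)
  A <- aln[pairs$a, cols, drop = FALSE]
  B <- aln[pairs$b, cols, drop = FALSE]
  usable <- A != "-" & B != "-"
  ident <- usable & (A == B)
  n_pairs <- colSums(usable)
  frac <- ifelse(n_pairs > 0, colSums(ident) / n_pairs, NA_real_)
  structure(tibble::tibble(site = seq_along(cols), column = cols,
                           ref_aa = aln[reference_id, cols],
                           fraction = frac, n_pairs = n_pairs),
            class = c("site_profile", class(tibble::tibble())))
}

#' Fraction of universally conserved sites
#'
#' The fraction of reference sites whose conservation probability across
#' independent ortholog pairs is at least `threshold` (sites identical in
#' >= 90% of pairs, by default).
#'
#' @param profile A [site_identity_profile()] result.
#' @param threshold Conservation threshold (default 0.9).
#' @return A single fraction in `[0, 1]`.
#' @export
universal_site_fraction <- function(profile, threshold = 0.9) {
  if (nrow(profile) == 0) {
    abort("Empty site profile.", class = "divlimit_invalid_input")
  }
  mean(profile$fraction >= threshold, na.rm = TRUE)
}

#' Share of observed long-term identity due to universally conserved sites
#'
#' Expresses the universal-site fraction as a percentage of the observed
#' long-term sequence identity: with ~14% of sites universally conserved
#' and ~40% long-term identity, universal sites account for only ~35% of
#' the conserved residues — most of the divergence limit is carried by
#' different sites in different lineages.
#'
#' @param universal_fraction Fraction of sites universally conserved
#'   (0 to 1).
#' @param long_term_identity Observed long-term identity in percent, `> 0`.
#' @return Share in percent.
#' @export
conserved_identity_share <- function(universal_fraction, long_term_identity) {
  if (any(long_term_identity <= 0)) {
    abort("Long-term identity must be positive.", class = "divlimit_invalid_input")
  }
  100 * universal_fraction / (long_term_identity / 100)
}

# shared engine: identity per ortholog pair restricted to site groups,
# then aggregated over time bins
grouped_site_divergence <- function(msa, pair_times, site_groups,
                                    bin_edges_time, reference_id) {
  aln <- as_aln_matrix(msa)
  pair_times <- tibble::as_tibble(pair_times)
  stopifnot(all(c("a", "b", "time") %in% names(pair_times)))
  cols <- reference_columns(aln, reference_id)
  site_groups <- tibble::as_tibble(site_groups)
  stopifnot(all(c("site", "group") %in% names(site_groups)))
  bad <- setdiff(site_groups$site, seq_along(cols))
  if (length(bad) > 0) {
    abort("Site groups reference sites outside the reference coordinate range.",
          class = "divlimit_invalid_input")
  }

  A <- aln[pair_times$a, cols, drop = FALSE]
  B <- aln[pair_times$b, cols, drop = FALSE]
  usable <- A != "-" & B != "-"
  ident <- usable & (A == B)

  per_pair <- purrr::map_dfr(split(site_groups$site, site_groups$group), function(sites) {
    u <- usable[, sites, drop = FALSE]
    id <- ident[, sites, drop = FALSE]
    n <- unname(rowSums(u))
    tibble::tibble(pair = seq_len(nrow(pair_times)),
                   time = pair_times$time,
                   identity = unname(ifelse(n > 0, 100 * rowSums(id) / n, NA_real_)),
                   n_sites = n)
  }, .id = "group")

  per_pair$time_bin <- cut(per_pair$time, breaks = bin_edges_time,
                           right = FALSE, include.lowest = TRUE)
  binned <- dplyr::summarise(
    dplyr::group_by(per_pair[!is.na(per_pair$identity), ],
                    .data$group, .data$time_bin, .drop = FALSE),
    mean_identity = mean(.data$identity),
    sd_identity = sd(.data$identity),
    sem_identity = sd(.data$identity) / sqrt(dplyr::n()),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )
  binned$mean_identity[binned$n_pairs == 0] <- NA_real_
  list(per_pair = tibble::as_tibble(per_pair), binned = binned)
}

#' Identity-versus-time curves for fitness-stratified site groups
#'
#' Sorts reference sites into groups by their experimentally measured
#' average fitness effect of mutations, then computes, per ortholog pair,
#' the percent identity over each group's sites only, and aggregates into
#' divergence-time bins (mean, SD, SEM). Identity is averaged per pair
#' first and then per bin.
#'
#' @inheritParams site_identity_profile
#' @param pair_times Data frame with columns `a`, `b` (MSA members) and
#'   `time` (Gy).
#' @param site_fitness Data frame with columns `site` and `fitness`
#'   (relative growth-rate effect; more negative = more deleterious).
#' @param bin_edges_fitness Numeric break points for the fitness groups;
#'   `NULL` (default) uses quartiles of the site-fitness distribution.
#' @param bin_edges_time Numeric break points for divergence-time bins
#'   (left-closed, right-open).
#' @return List with `per_pair` (pair-level identities per group) and
#'   `binned` (group x time-bin tibble: `mean_identity`, `sd_identity`,
#'   `sem_identity`, `n_pairs`; empty bins are `NA`, not an error).
#' @export
fitness_binned_divergence <- function(msa, pair_times, site_fitness,
                                      bin_edges_time,
                                      bin_edges_fitness = NULL,
                                      reference_id) {
  site_fitness <- tibble::as_tibble(site_fitness)
  stopifnot(all(c("site", "fitness") %in% names(site_fitness)))
  if (is.null(bin_edges_fitness)) {
    bin_edges_fitness <- unique(quantile(site_fitness$fitness,
                                         probs = seq(0, 1, 0.25), na.rm = TRUE))
  }
  grp <- cut(site_fitness$fitness, breaks = bin_edges_fitness,
             include.lowest = TRUE)
  groups <- tibble::tibble(site = site_fitness$site, group = as.character(grp))
  groups <- groups[!is.na(groups$group), ]
  grouped_site_divergence(msa, pair_times, groups, bin_edges_time, reference_id)
}

#' Site conservation probability as a function of fitness effect
#'
#' Bins the per-site conservation probabilities of a
#' [site_identity_profile()] (computed from pairs within a long-divergence
#' window, e.g. 2 +/- 0.25 Gy) by the sites' average fitness effects, and
#' reports the mean probability with its SEM across sites per bin.
#'
#' @param profile A [site_identity_profile()] result.
#' @param site_fitness Data frame with columns `site`, `fitness`.
#' @param bin_edges_fitness Break points for fitness bins; `NULL` uses
#'   quartiles.
#' @return Tibble: `fitness_bin`, `mean_fitness`, `probability`, `sem`,
#'   `n_sites` (empty bins yield `NA`).
#' @export
identity_prob_vs_fitness <- function(profile, site_fitness,
                                     bin_edges_fitness = NULL) {
  d <- dplyr::inner_join(tibble::as_tibble(profile),
                         tibble::as_tibble(site_fitness), by = "site")
  if (is.null(bin_edges_fitness)) {
    bin_edges_fitness <- unique(quantile(d$fitness, probs = seq(0, 1, 0.25),
                                         na.rm = TRUE))
  }
  d$fitness_bin <- cut(d$fitness, breaks = bin_edges_fitness, include.lowest = TRUE)
  out <- dplyr::summarise(
    dplyr::group_by(d[!is.na(d$fraction) & !is.na(d$fitness_bin), ],
                    .data$fitness_bin, .drop = FALSE),
    mean_fitness = mean(.data$fitness),
    probability = mean(.data$fraction),
    sem = sd(.data$fraction) / sqrt(dplyr::n()),
    n_sites = dplyr::n(),
    .groups = "drop"
  )
  out$probability[out$n_sites == 0] <- NA_real_
  out
}

#' Assign reference sites to distance shells around the active site
#'
#' Computes the centroid of the active-site residues' C-alpha coordinates
#' and stratifies every site by the Euclidean distance of its C-alpha to
#' that centroid: `shell = floor(distance / shell_width)`.
#'
#' @param ca_coords C-alpha coordinates: data frame with columns `site`,
#'   `x`, `y`, `z`, or a numeric matrix with 3 columns and sites as
#'   rownames. Sites with missing coordinates are skipped with a warning.
#' @param active_site_indices Reference positions of active-site residues
#'   (>= 1 required).
#' @param shell_width Shell width in Angstrom (default 5).
#' @return Tibble: `site`, `distance` (Angstrom), `shell` (0-based index).
#' @export
assign_distance_shells <- function(ca_coords, active_site_indices,
                                   shell_width = 5) {
  if (is.matrix(ca_coords)) {
    ca_coords <- tibble::tibble(site = as.integer(rownames(ca_coords) %||%
                                                    seq_len(nrow(ca_coords))),
                                x = ca_coords[, 1], y = ca_coords[, 2],
                                z = ca_coords[, 3])
  }
  ca_coords <- tibble::as_tibble(ca_coords)
  stopifnot(all(c("site", "x", "y", "z") %in% names(ca_coords)),
            shell_width > 0)
  if (length(active_site_indices) < 1) {
    abort("Need at least one active-site residue.", class = "divlimit_invalid_input")
  }
  ok <- complete.cases(ca_coords[c("x", "y", "z")])
  if (any(!ok)) {
    warn(sprintf("%d site(s) without coordinates skipped.", sum(!ok)))
    ca_coords <- ca_coords[ok, ]
  }
  act <- ca_coords[ca_coords$site %in% active_site_indices, ]
  if (nrow(act) == 0) {
    abort("No coordinates available for the active-site residues.",
          class = "divlimit_invalid_input")
  }
  centroid <- colMeans(as.matrix(act[c("x", "y", "z")]))
  dxyz <- sweep(as.matrix(ca_coords[c("x", "y", "z")]), 2, centroid)
  dist <- sqrt(rowSums(dxyz^2))
  tibble::tibble(site = ca_coords$site, distance = dist,
                 shell = floor(dist / shell_width))
}

#' Identity-versus-time curves per active-site distance shell
#'
#' Same aggregation as [fitness_binned_divergence()], with distance shells
#' (from [assign_distance_shells()]) as the site groups.
#'
#' @inheritParams fitness_binned_divergence
#' @param shell_map Tibble with columns `site` and `shell`.
#' @return List with `per_pair` and `binned` (see
#'   [fitness_binned_divergence()]); the binned table reports SEM across
#'   ortholog pairs.
#' @export
shell_divergence <- function(msa, pair_times, shell_map, bin_edges_time,
                             reference_id) {
  shell_map <- tibble::as_tibble(shell_map)
  stopifnot(all(c("site", "shell") %in% names(shell_map)))
  groups <- tibble::tibble(site = shell_map$site,
                           group = sprintf("shell_%d", shell_map$shell))
  grouped_site_divergence(msa, pair_times, groups, bin_edges_time, reference_id)
}
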