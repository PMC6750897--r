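#' Assign a divergence time to a species pair
#'
#' Looks up literature divergence times for pairs of species, applying the
#' deep-time override rules used throughout the analysis: any
#' bacteria-archaea or prokaryote-eukaryote pair is set to 4 Gy (the
#' estimated age of their last common ancestor), except that taxa flagged
#' as TACK-superphylum archaea paired with eukaryotes are set to 2.7 Gy
#' (the estimated age of the TACK clade). Identical species get 0.
#'
#' @param species_a,species_b Character vectors of species identifiers
#'   (recycled to common length).
#' @param time_table Data frame with columns `species_a`, `species_b`,
#'   `time_gy` (and optionally `time_min`, `time_max`); when a pair occurs
#'   in several rows (several studies) the mean time is used. Unordered
#'   lookup.
#' @param domain_labels Data frame with columns `species`, `domain` (one of
#'   `"bacteria"`, `"archaea"`, `"eukaryote"`) and optionally a logical
#'   `tack` column.
#' @return Numeric vector of divergence times in Gy.
#' @export
assign_divergence_time <- function(species_a, species_b, time_table = NULL,
                                   domain_labels = NULL) {
  n <- max(length(species_a), length(species_b))
  species_a <- rep_len(as.character(species_a), n)
  species_b <- rep_len(as.character(species_b), n)

  dom <- function(sp) {
    if (is.null(domain_labels)) return(rep(NA_character_, length(sp)))
    domain_labels$domain[match(sp, domain_labels$species)]
  }
  tack <- function(sp) {
    if (is.null(domain_labels) || !"tack" %in% names(domain_labels)) {
      return(rep(FALSE, length(sp)))
    }
    out <- domain_labels$tack[match(sp, domain_labels$species)]
    !is.na(out) & out
  }
  da <- dom(species_a); db <- dom(species_b)
  ta <- tack(species_a); tb <- tack(species_b)

  out <- rep(NA_real_, n)
  out[species_a == species_b] <- 0

  is_prok <- function(d) d %in% c("bacteria", "archaea")
  is_euk <- function(d) !is.na(d) & d == "eukaryote"
  cross_domain <- (is_prok(da) & is_euk(db)) | (is_euk(da) & is_prok(db)) |
    (!is.na(da) & !is.na(db) & ((da == "bacteria" & db == "archaea") |
                                (da == "archaea" & db == "bacteria")))
  tack_euk <- (ta & is_euk(db)) | (tb & is_euk(da))
  out[is.na(out) & tack_euk] <- 2.7
  out[is.na(out) & cross_domain] <- 4.0

  need <- which(is.na(out))
  if (length(need) > 0) {
    if (is.null(time_table)) {
      abort("No time table supplied for within-domain pairs.",
            class = "divlimit_lookup_error")
    }
    key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
    tab <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(time_table),
                      pair_key = key(.data$species_a, .data$species_b)),
      time_gy = mean(.data$time_gy), .groups = "drop"
    )
    hit <- match(key(species_a[need], species_b[need]), tab$pair_key)
    if (anyNA(hit)) {
      missing <- unique(paste(species_a[need], species_b[need], sep = " / ")[is.na(hit)])
      abort(paste0("No divergence time for pair(s): ",
                   paste(utils::head(missing, 5), collapse = "; ")),
            class = "divlimit_lookup_error")
    }
    out[need] <- tab$time_gy[hit]
  }
  out
}

#' Calibrate a genetic-distance to divergence-time map
#'
#' Ordinary least-squares regression of literature divergence times on
#' genetic distances (e.g. 16S rRNA distances); predictions are clamped at
#' zero.
#'
#' @param calibration Data frame with columns `distance` and `time`
#'   (>= 2 points with distinct distances).
#' @return An object of class `"time_calibration"` with `intercept`,
#'   `slope`, `r.squared`; use [predict()] to map new distances to times.
#' @export
calibrate_distance_time <- function(calibration) {
  d <- tibble::as_tibble(calibration)
  if (!all(c("distance", "time") %in% names(d))) {
    abort("Calibration needs `distance` and `time` columns.",
          class = "divlimit_calibration_error")
  }
  d <- d[complete.cases(d[c("distance", "time")]), ]
  if (nrow(d) < 2 || length(unique(d$distance)) < 2) {
    abort("Need >= 2 calibration points with distinct distances.",
          class = "divlimit_calibration_error")
  }
  fit <- lm(time ~ distance, data = d)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r.squared = summary(fit)$r.squared,
                 n = nrow(d)),
            class = "time_calibration")
}

#' @export
print.time_calibration <- function(x, ...) {
  cat(sprintf("<time_calibration: time = %.4g + %.4g * distance (R^2 = %.3f, n = %d)>\n",
              x$intercept, x$slope, x$r.squared, x$n))
  invisible(x)
}

#' @export
predict.time_calibration <- function(object, distance, ...) {
  pmax(object$intercept + object$slope * distance, 0)
}

# nontrivial bipartitions of the leaf set, as canonical strings (each split
# keyed by the smaller side, labels sorted)
tree_splits <- function(tree) {
  tree <- ape::unroot(ape::multi2di(tree, random = FALSE))
  labs <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (part in pp) {
    side <- sort(attr(pp, "labels")[part])
    if (length(side) <= 1 || length(side) >= length(labs) - 1) next
    other <- setdiff(labs, side)
    keyside <- if (length(side) < length(other) ||
                   (length(side) == length(other) &&
                    paste(side, collapse = ",") < paste(other, collapse = ","))) side else other
    out <- c(out, paste(keyside, collapse = ","))
  }
  unique(out)
}

#' Screen a gene tree for horizontal gene transfer
#'
#' Automated proxy for the manual tree-topology curation used to exclude
#' HGT candidates: the Robinson-Foulds distance between the gene tree and
#' the species tree on their shared leaves, normalized by the number of
#' resolvable (nontrivial) splits in the two trees. Families whose
#' normalized distance exceeds `threshold` are flagged.
#'
#' @param gene_tree,species_tree `phylo` objects; leaf sets must overlap on
#'   at least 4 taxa.
#' @param threshold Normalized RF distance above which the family is
#'   flagged (default 0.2).
#' @return One-row tibble: `rf`, `n_splits`, `rf_normalized`, `n_shared`,
#'   `flag`.
#' @export
flag_hgt <- function(gene_tree, species_tree, threshold = 0.2) {
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4) {
    abort("Trees share fewer than 4 taxa.", class = "divlimit_insufficient_overlap")
  }
  g <- ape::keep.tip(gene_tree, shared)
  s <- ape::keep.tip(species_tree, shared)
  sg <- tree_splits(g)
  ss <- tree_splits(s)
  rf <- length(setdiff(sg, ss)) + length(setdiff(ss, sg))
  denom <- length(sg) + length(ss)
  rfn <- if (denom == 0) 0 else rf / denom
  tibble::tibble(rf = rf, n_splits = denom, rf_normalized = rfn,
                 n_shared = length(shared), flag = rfn > threshold)
}

#' Flag families with ancient gene duplications
#'
#' A duplication node is an internal node whose child subtrees share at
#' least one species; the duplication is *ancient* when that node is
#' ancestral to 3 or more distinct species. Families containing such a node
#' are flagged and excluded from divergence-time analyses, because their
#' within-family divergences predate the species divergences.
#'
#' @param gene_tree A `phylo` object, possibly with several leaves per
#'   species.
#' @param species_map Data frame with columns `leaf` and `species`; by
#'   default each leaf label is its own species (no duplications possible).
#' @return `TRUE` if an ancient duplication is present.
#' @export
flag_ancient_duplication <- function(gene_tree, species_map = NULL) {
  labs <- gene_tree$tip.label
  sp <- if (is.null(species_map)) {
    setNames(labs, labs)
  } else {
    setNames(as.character(species_map$species), species_map$leaf)[labs]
  }
  tr <- stats::reorder(gene_tree, "postorder")
  ntip <- length(labs)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  species_below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) species_below[[i]] <- sp[[i]]
  # parents in postorder of first appearance: children are always complete
  for (node in unique(tr$edge[, 1])) {
    sets <- lapply(children[[as.character(node)]], function(k) species_below[[k]])
    species_below[[node]] <- unique(unlist(sets))
    if (length(sets) >= 2 && length(species_below[[node]]) >= 3) {
      for (x in seq_along(sets)) for (y in seq_along(sets)) {
        if (x < y && length(intersect(sets[[x]], sets[[y]])) > 0) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# edges on the path between two leaves, as "parent-child" keys
path_edges <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  nodes <- ape::nodepath(tree, ia, ib)
  paste(pmin(nodes[-length(nodes)], nodes[-1]),
        pmax(nodes[-length(nodes)], nodes[-1]), sep = "-")
}

#' Select a maximum set of edge-disjoint (phylogenetically independent) pairs
#'
#' Finds the largest set of leaf pairs whose connecting tree paths share no
#' branch and whose divergence times fall within a window — pairs of
#' lineages that constitute independent evolutionary replicates. Exact
#' search (branch and bound over the pair-conflict graph) is used for trees
#' with at most `exact_max_leaves` leaves; larger trees fall back to a
#' greedy heuristic that prefers pairs with short tree paths.
#'
#' @param tree A `phylo` object with unique leaf labels.
#' @param window Numeric length-2 vector `(t_lo, t_hi)` in Gy; use
#'   `c(2, Inf)` for a one-sided "diverged more than 2 Gy ago" window.
#' @param times Divergence times between leaves: a symmetric matrix with
#'   leaf-label dimnames, or `NULL` to use half the patristic distance
#'   (appropriate for clock-like trees in time units).
#' @param min_pairs Minimum number of pairs required for downstream use;
#'   shortfalls are reported in the result, not raised.
#' @param exact_max_leaves Leaf-count limit for the exact search.
#' @return A tibble of class `"independent_pairs"` with columns `a`, `b`,
#'   `time`, ordered lexicographically; attributes `window` and
#'   `min_pairs_met`.
#' @export
select_independent_pairs <- function(tree, window, times = NULL,
                                     min_pairs = 0L, exact_max_leaves = 12L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(window) != 2 || window[1] > window[2]) {
    abort("`window` must be c(t_lo, t_hi) with t_lo <= t_hi.",
          class = "divlimit_invalid_input")
  }
  labs <- tree$tip.label
  if (anyDuplicated(labs)) {
    abort("Leaf labels must be unique.", class = "divlimit_invalid_input")
  }
  if (is.null(times)) times <- ape::cophenetic.phylo(tree) / 2
  times <- times[labs, labs, drop = FALSE]

  cand <- which(upper.tri(times) & times >= window[1] & times <= window[2],
                arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(empty_pair_set(window, min_pairs))
  }
  cand_pairs <- lapply(seq_len(nrow(cand)), function(k) {
    a <- labs[cand[k, 1]]; b <- labs[cand[k, 2]]
    list(a = min(a, b), b = max(a, b),
         time = times[cand[k, 1], cand[k, 2]],
         edges = path_edges(tree, a, b))
  })
  # conflict graph: pairs sharing any edge
  m <- length(cand_pairs)
  conflict <- matrix(FALSE, m, m)
  for (x in seq_len(m)) for (y in seq_len(m)) {
    if (x < y && length(intersect(cand_pairs[[x]]$edges, cand_pairs[[y]]$edges)) > 0) {
      conflict[x, y] <- conflict[y, x] <- TRUE
    }
  }

  chosen <- if (length(labs) <= exact_max_leaves) {
    max_independent_set(conflict)
  } else {
    greedy_independent_set(conflict, order(purrr::map_int(cand_pairs, ~ length(.x$edges))))
  }

  out <- purrr::map_dfr(cand_pairs[chosen], ~ tibble::tibble(a = .x$a, b = .x$b, time = .x$time))
  out <- dplyr::arrange(out, .data$a, .data$b)
  # post-hoc edge-disjointness assertion (always on)
  stopifnot(pairs_edge_disjoint(tree, out))
  structure(out,
            class = c("independent_pairs", class(out)),
            window = window,
            min_pairs_met = nrow(out) >= min_pairs)
}

empty_pair_set <- function(window, min_pairs) {
  structure(tibble::tibble(a = character(), b = character(), time = numeric()),
            class = c("independent_pairs", class(tibble::tibble())),
            window = window, min_pairs_met = 0 >= min_pairs)
}

# exact maximum independent set by branch and bound
max_independent_set <- function(conflict) {
  m <- nrow(conflict)
  if (m == 0) return(integer(0))
  best <- integer(0)
  recurse <- function(chosen, remaining) {
    if (length(chosen) + length(remaining) <= length(best)) return()
    if (length(remaining) == 0) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    v <- remaining[1]
    # include v
    keep <- remaining[-1]
    recurse(c(chosen, v), keep[!conflict[v, keep]])
    # exclude v
    recurse(chosen, remaining[-1])
  }
  recurse(integer(0), seq_len(m))
  best
}

greedy_independent_set <- function(conflict, order_idx) {
  chosen <- integer(0)
  for (v in order_idx) {
    if (!any(conflict[v, chosen])) chosen <- c(chosen, v)
  }
  sort(chosen)
}

#' Verify that a pair set is edge-disjoint
#'
#' Marks the tree edges used by each pair's path and checks that no edge is
#' used twice.
#'
#' @param tree A `phylo` object.
#' @param pairs Data frame with columns `a`, `b`.
#' @return `TRUE` if all paths are pairwise edge-disjoint.
#' @export
pairs_edge_disjoint <- function(tree, pairs) {
  if (nrow(pairs) == 0) return(TRUE)
  used <- unlist(lapply(seq_len(nrow(pairs)),
                        function(i) path_edges(tree, pairs$a[i], pairs$b[i])))
  !anyDuplicated(used)
}
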