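#' Ground-truth site profile for sequence-evolution simulation
#'
#' Draws, per site, the allowed amino-acid set (of size `a_i`, always
#' containing the ancestral residue) and a per-site substitution rate
#' `lambda_i`, emulating the finite-alphabet divergence model with
#' gamma-distributed rate variation across sites.
#'
#' @param L Number of sites, `>= 1`.
#' @param alphabet_size Per-site allowed-set sizes: a single integer
#'   (constant), an integer vector of length `L`, or a function `n ->
#'   integer vector` for random draws. Sizes are clamped to `[1, 20]`.
#' @param rate_shape,rate_mean Shape and mean of the gamma distribution of
#'   per-site rates (per Gy); `rate_shape = Inf` gives the constant rate
#'   `rate_mean`.
#' @param group Optional per-site group labels (length `L`), carried into
#'   the profile for stratified analyses.
#' @param seed RNG seed.
#' @return Tibble of class `"site_profile_truth"`: `site`, `ancestral`,
#'   `allowed` (list column of character vectors), `a`, `lambda`,
#'   and `group` if given.
#' @export
make_site_profile <- function(L, alphabet_size = 4, rate_shape = Inf,
                              rate_mean = 1, group = NULL, seed = 0L) {
  stopifnot(L >= 1, rate_mean > 0, rate_shape > 0)
  with_seed_if(seed, {
    a <- if (is.function(alphabet_size)) alphabet_size(L) else rep_len(alphabet_size, L)
    if (any(!is.finite(a)) || any(a < 1)) {
      abort("Alphabet sizes must be >= 1.", class = "divlimit_invalid_param")
    }
    a <- pmin(as.integer(round(a)), length(AA_STANDARD))
    lambda <- if (is.infinite(rate_shape)) rep(rate_mean, L) else
      rgamma(L, shape = rate_shape, rate = rate_shape / rate_mean)
    ancestral <- sample(AA_STANDARD, L, replace = TRUE)
    allowed <- lapply(seq_len(L), function(i) {
      if (a[i] == 1) return(ancestral[i])
      c(ancestral[i], sample(setdiff(AA_STANDARD, ancestral[i]), a[i] - 1))
    })
    out <- tibble::tibble(site = seq_len(L), ancestral = ancestral,
                          allowed = allowed, a = a, lambda = lambda)
    if (!is.null(group)) out$group <- rep_len(group, L)
    structure(out, class = c("site_profile_truth", class(out)))
  })
}

# one lineage evolved for time t from the profile's ancestral sequence:
# exact endpoint sampling of the per-site uniform-exchange CTMC on the
# allowed set (back substitutions included), under which
# P(descendant = ancestor) = 1/a + (1 - 1/a) exp(-a lambda t / (a - 1))
evolve_lineage <- function(profile, t) {
  L <- nrow(profile)
  a <- profile$a
  stay_p <- ifelse(a == 1, 1,
                   1 / a + (1 - 1 / a) * exp(-a * profile$lambda * t / (a - 1)))
  stay <- runif(L) < stay_p
  out <- profile$ancestral
  jump <- which(!stay)
  if (length(jump) > 0) {
    # allowed[[i]] stores the ancestral residue first; pick uniformly
    # among the other a - 1
    pick <- 2L + as.integer(floor(runif(length(jump)) * (a[jump] - 1L)))
    out[jump] <- vapply(seq_along(jump),
                        function(k) profile$allowed[[jump[k]]][pick[k]],
                        character(1))
  }
  out
}

#' Evolve an ortholog pair from a common ancestor
#'
#' Two lineages evolve independently for time `t` from the profile's
#' ancestral sequence, each site following a continuous-time Markov
#' process with uniform exchange over its allowed set at total rate
#' `lambda_i` (back substitutions allowed). Site endpoints are sampled
#' from the exact CTMC transition distribution, so the finite-alphabet
#' closed form is the exact expectation of pairwise identity.
#'
#' @param profile A [make_site_profile()] result.
#' @param t Divergence time in Gy (each branch has length `t`).
#' @param seed RNG seed.
#' @return Named character vector of two sequences, `seq_a` and `seq_b`.
#' @export
evolve_pair <- function(profile, t, seed = NULL) {
  stopifnot(inherits(profile, "site_profile_truth") || is.data.frame(profile))
  check_time(t)
  with_seed_if(seed, {
    c(seq_a = paste(evolve_lineage(profile, t), collapse = ""),
      seq_b = paste(evolve_lineage(profile, t), collapse = ""))
  })
}

#' Evolve many independent ortholog pairs
#'
#' Convenience wrapper around [evolve_pair()]: `n` independent pairs from
#' the same ancestor, returned with their pairwise (ungapped) identities.
#'
#' @inheritParams evolve_pair
#' @param n Number of independent pairs.
#' @return Tibble: `pair`, `seq_a`, `seq_b`, `identity` (percent).
#' @export
evolve_pairs <- function(profile, t, n, seed = 0L) {
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      p <- evolve_pair(profile, t)
      tibble::tibble(pair = i, seq_a = p[["seq_a"]], seq_b = p[["seq_b"]],
                     identity = sequence_identity(p[["seq_a"]], p[["seq_b"]]))
    })
  })
}

#' Simulate identity-versus-time observations
#'
#' Draws observations from a divergence model plus Gaussian noise, clamped
#' to `[0, 100]` — the harness for testing model fitting.
#'
#' @param params A [model_params()] object.
#' @param times Divergence times (Gy), non-empty.
#' @param noise_sd Gaussian noise SD in identity percent.
#' @param n_per_time Observations per time value.
#' @param seed RNG seed.
#' @param family_id Family label carried into the output.
#' @return Tibble: `pair_id`, `family_id`, `identity`, `time`.
#' @export
simulate_observations <- function(params, times, noise_sd = 5,
                                  n_per_time = 1L, seed = 0L,
                                  family_id = "sim") {
  stopifnot(length(times) > 0, noise_sd >= 0, n_per_time >= 1)
  p <- as_model_params(params)
  tt <- rep(times, each = n_per_time)
  with_seed_if(seed, {
    y <- evaluate_model(p, tt) + rnorm(length(tt), 0, noise_sd)
    tibble::tibble(pair_id = sprintf("pair%03d", seq_along(tt)),
                   family_id = family_id,
                   identity = pmin(pmax(y, 0), 100),
                   time = tt)
  })
}

#' Simulate a pooled-competition count table
#'
#' Deterministic exponential abundance trajectories per mutant (growth-rate
#' difference to WT `delta_m`, per hour), observed through multinomial read
#' sampling at a fixed depth per time point — the generative model behind
#' the turbidostat competition read counts.
#'
#' @param true_effects Data frame with columns `mutant_id`, `position`,
#'   `codon`, `aa`, `delta_m` (per hour); optional `wt_aa`. Batches of 10
#'   consecutive codon positions are labelled automatically.
#' @param times Sampling times in hours, strictly increasing.
#' @param depth Reads per time point (`>= 1`).
#' @param wt_share Initial abundance share of the WT strain (default 0.2,
#'   the remainder split equally among mutants).
#' @param sampling `"multinomial"` for read sampling, `"expected"` for the
#'   infinite-depth limit (expected counts, not integral).
#' @param seed RNG seed.
#' @return A MAGE count table (see [mage-fitness]) with a `WT` row.
#' @export
simulate_mage <- function(true_effects, times, depth = 1e5, wt_share = 0.2,
                          sampling = c("multinomial", "expected"), seed = 0L) {
  sampling <- match.arg(sampling)
  te <- tibble::as_tibble(true_effects)
  stopifnot(all(c("mutant_id", "position", "codon", "aa", "delta_m") %in% names(te)),
            all(diff(times) > 0), depth >= 1, wt_share > 0, wt_share < 1)
  n_mut <- nrow(te)
  init <- c((1 - wt_share) / n_mut * rep(1, n_mut), wt_share)
  rates <- c(te$delta_m, 0)
  counts <- with_seed_if(seed, {
    sapply(times, function(tt) {
      w <- init * exp(rates * tt)
      p <- w / sum(w)
      if (sampling == "multinomial") {
        as.numeric(stats::rmultinom(1, size = depth, prob = p))
      } else {
        depth * p
      }
    })
  })
  colnames(counts) <- as.character(times)
  ids <- tibble::tibble(
    mutant_id = c(te$mutant_id, "WT"),
    position = c(te$position, NA_integer_),
    codon = c(te$codon, NA_character_),
    aa = c(te$aa, NA_character_),
    wt_aa = if ("wt_aa" %in% names(te)) c(te$wt_aa, NA_character_) else NA_character_,
    batch = c((te$position - 1) %/% 10 + 1, NA_integer_)
  )
  dplyr::bind_cols(ids, tibble::as_tibble(counts))
}

#' Simulate a clock-like random tree
#'
#' A random coalescent-style rooted ultrametric tree with branch lengths
#' scaled by `clock_rate` — input material for independent-pair selection.
#'
#' @param n_leaves Number of leaves (`>= 2`).
#' @param clock_rate Multiplier applied to all branch lengths.
#' @param seed RNG seed.
#' @return An ultrametric `phylo` object with leaves `t1 ... tn`.
#' @export
simulate_tree <- function(n_leaves, clock_rate = 1, seed = 0L) {
  stopifnot(n_leaves >= 2, clock_rate > 0)
  with_seed_if(seed, {
    tr <- ape::rcoal(n_leaves)
    tr$edge.length <- tr$edge.length * clock_rate
    tr
  })
}

#' Simulate an aligned set of independent ortholog pairs
#'
#' Builds a gap-free MSA containing the ancestral reference plus `n`
#' independent ortholog pairs evolved to the given times — input material
#' for the site-level divergence analyses, with the generating site
#' profile as ground truth.
#'
#' @param profile A [make_site_profile()] result.
#' @param pair_times Numeric vector: divergence time of each pair.
#' @param seed RNG seed.
#' @return List with `msa` (named character vector; reference `"ref"`,
#'   pair members `"p<i>_a"` / `"p<i>_b"`) and `pairs` (tibble `a`, `b`,
#'   `time`).
#' @export
simulate_ortholog_msa <- function(profile, pair_times, seed = 0L) {
  with_seed_if(seed, {
    seqs <- c(ref = paste(profile$ancestral, collapse = ""))
    pairs <- purrr::map_dfr(seq_along(pair_times), function(i) {
      p <- evolve_pair(profile, pair_times[i])
      seqs[[sprintf("p%d_a", i)]] <<- p[["seq_a"]]
      seqs[[sprintf("p%d_b", i)]] <<- p[["seq_b"]]
      tibble::tibble(a = sprintf("p%d_a", i), b = sprintf("p%d_b", i),
                     time = pair_times[i])
    })
    list(msa = seqs, pairs = pairs)
  })
}
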