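toy_sites <- function() {
  # reference has a gap at column 3; pair2 has gaps over reference sites
  msa <- toy_msa(
    ref = "AC-DEF",
    p1a = "ACQDEF",
    p1b = "ACQDEY",
    p2a = "AC-D-F",
    p2b = "ACQDEF"
  )
  pairs <- tibble::tibble(a = c("p1a", "p2a"), b = c("p1b", "p2b"))
  list(msa = msa, pairs = pairs)
}

test_that("site profile counts identities per reference site, skipping gaps", {
  ts <- toy_sites()
  prof <- site_identity_profile(ts$msa, ts$pairs, "ref")
  # reference is 5 ungapped sites over columns 1,2,4,5,6
  expect_equal(prof$site, 1:5)
  expect_equal(prof$column, c(1, 2, 4, 5, 6))
  expect_equal(prof$ref_aa, c("A", "C", "D", "E", "F"))
  # column 5 (site 4): pair2 has a gap, denominator drops to 1
  expect_equal(prof$n_pairs, c(2, 2, 2, 1, 2))
  # site 5 (column 6): pair1 mismatch F/Y, pair2 match
  expect_equal(prof$fraction, c(1, 1, 1, 1, 0.5))
  # oracle re-count
  expect_equal(prof$fraction, oracle_site_profile(ts$msa, ts$pairs, "ref"))
  expect_error(site_identity_profile(ts$msa, ts$pairs[0, ], "ref"),
               class = "divlimit_invalid_input")
  expect_error(site_identity_profile(ts$msa, tibble::tibble(a = "zz", b = "p1b"), "ref"),
               class = "divlimit_invalid_input")
})

test_that("universal fraction and conserved-identity share follow their definitions", {
  prof <- tibble::tibble(fraction = c(0.95, 0.85, 0.91, 0.5))
  expect_equal(universal_site_fraction(prof), 0.5)
  expect_equal(universal_site_fraction(prof, threshold = 0.8), 0.75)
  # 14% of sites universal, 40% long-term identity -> 35% of conserved residues
  expect_equal(conserved_identity_share(0.14, 40), 35)
  expect_error(conserved_identity_share(0.14, 0), class = "divlimit_invalid_input")
})

test_that("grouped divergence averages per pair first, then per time bin", {
  ts <- toy_sites()
  pt <- tibble::tibble(a = c("p1a", "p2a"), b = c("p1b", "p2b"),
                       time = c(0.5, 0.5))
  fitness <- tibble::tibble(site = 1:5, fitness = c(-1, -1, -1, 0, 0))
  res <- fitness_binned_divergence(ts$msa, pt, fitness,
                                   bin_edges_time = c(0, 1),
                                   bin_edges_fitness = c(-2, -0.5, 1),
                                   reference_id = "ref")
  pp <- res$per_pair
  # deleterious group = sites 1:3 (all identical in both pairs)
  del <- pp[pp$group == "[-2,-0.5]", ]
  expect_equal(sort(del$identity), c(100, 100))
  # neutral group = sites 4:5: pair1 -> 50% (E match, F/Y mismatch),
  # pair2 -> 100% over its single usable site
  neu <- pp[pp$group == "(-0.5,1]", ]
  expect_equal(sort(neu$identity), c(50, 100))
  binned <- res$binned
  expect_equal(binned$mean_identity[binned$group == "(-0.5,1]"], 75)
  expect_equal(binned$n_pairs, c(2L, 2L))
})

test_that("a single all-site group reproduces plain pairwise identity", {
  prof <- make_site_profile(60, alphabet_size = 4, seed = 3)
  sim <- simulate_ortholog_msa(prof, pair_times = c(0.5, 1, 2, 3), seed = 4)
  groups <- tibble::tibble(site = 1:60, fitness = 0)
  res <- fitness_binned_divergence(sim$msa, sim$pairs, groups,
                                   bin_edges_time = c(0, 5),
                                   bin_edges_fitness = c(-1, 1),
                                   reference_id = "ref")
  direct <- purrr::map_dbl(seq_len(nrow(sim$pairs)), function(i) {
    sequence_identity(sim$msa[[sim$pairs$a[i]]], sim$msa[[sim$pairs$b[i]]])
  })
  expect_equal(sort(res$per_pair$identity), sort(direct), tolerance = 1e-12)
})

test_that("group identities recombine to the global identity when weighted by site counts", {
  prof <- make_site_profile(80, alphabet_size = 3, seed = 8)
  sim <- simulate_ortholog_msa(prof, pair_times = c(1, 1, 2), seed = 9)
  groups <- tibble::tibble(site = 1:80,
                           group = rep(c("g1", "g2", "g3"), length.out = 80))
  res <- divlimit:::grouped_site_divergence(sim$msa, sim$pairs, groups,
                                            bin_edges_time = c(0, 3),
                                            reference_id = "ref")
  pp <- res$per_pair
  for (i in unique(pp$pair)) {
    d <- pp[pp$pair == i, ]
    pooled <- sum(d$identity * d$n_sites) / sum(d$n_sites)
    direct <- sequence_identity(sim$msa[[sim$pairs$a[i]]], sim$msa[[sim$pairs$b[i]]])
    expect_equal(pooled, direct, tolerance = 1e-9)
  }
})

test_that("fitness-stratified simulation shows higher identity for constrained sites", {
  # constrained sites: tiny alphabet (a=2); permissive sites: a=12
  prof <- make_site_profile(400, alphabet_size = function(n) rep(c(2, 12), n / 2),
                            seed = 10)
  sim <- simulate_ortholog_msa(prof, pair_times = rep(3, 20), seed = 11)
  fitness <- tibble::tibble(site = prof$site,
                            fitness = ifelse(prof$a == 2, -0.3, -0.01))
  res <- fitness_binned_divergence(sim$msa, sim$pairs, fitness,
                                   bin_edges_time = c(0, 5),
                                   bin_edges_fitness = c(-1, -0.1, 0),
                                   reference_id = "ref")
  b <- res$binned
  constrained <- b$mean_identity[b$group == "[-1,-0.1]"]
  permissive <- b$mean_identity[b$group == "(-0.1,0]"]
  expect_gt(constrained, permissive + 20)
})

test_that("conservation probability decreases with milder fitness effects", {
  prof <- make_site_profile(300, alphabet_size = function(n) rep(c(2, 16), n / 2),
                            seed = 12)
  sim <- simulate_ortholog_msa(prof, pair_times = rep(2, 30), seed = 13)
  sp <- site_identity_profile(sim$msa, sim$pairs, "ref")
  fitness <- tibble::tibble(site = prof$site,
                            fitness = ifelse(prof$a == 2, -0.4, -0.02))
  out <- identity_prob_vs_fitness(sp, fitness,
                                  bin_edges_fitness = c(-1, -0.1, 0))
  expect_gt(out$probability[out$fitness_bin == "[-1,-0.1]"],
            out$probability[out$fitness_bin == "(-0.1,0]"])
  expect_true(all(out$n_sites == 150))
})

test_that("distance shells follow the floor(distance / width) rule", {
  coords <- tibble::tibble(site = 1:4,
                           x = c(0, 3, 7, 12), y = 0, z = 0)
  shells <- assign_distance_shells(coords, active_site_indices = 1,
                                   shell_width = 5)
  expect_equal(shells$distance, c(0, 3, 7, 12))
  expect_equal(shells$shell, c(0, 0, 1, 2))
  # centroid of two active residues
  sh2 <- assign_distance_shells(coords, active_site_indices = c(1, 2),
                                shell_width = 5)
  expect_equal(sh2$distance[1], 1.5)
  # missing coordinates are skipped with a warning
  coords$x[3] <- NA
  expect_warning(sh3 <- assign_distance_shells(coords, 1), "skipped")
  expect_equal(nrow(sh3), 3)
  expect_error(assign_distance_shells(coords, active_site_indices = integer(0)),
               class = "divlimit_invalid_input")
})

test_that("divergence increases with distance from the active site when rates do", {
  # shell structure built into the simulation: inner sites slow, outer fast
  L <- 300
  shell <- rep(0:2, each = L / 3)
  prof <- make_site_profile(L, alphabet_size = 18, rate_shape = Inf,
                            rate_mean = 1, seed = 14)
  prof$lambda <- c(0.1, 0.6, 2.5)[shell + 1]
  sim <- simulate_ortholog_msa(prof, pair_times = rep(1.5, 25), seed = 15)
  res <- shell_divergence(sim$msa, sim$pairs,
                          shell_map = tibble::tibble(site = 1:L, shell = shell),
                          bin_edges_time = c(0, 3), reference_id = "ref")
  b <- res$binned
  m <- setNames(b$mean_identity, b$group)
  expect_gt(m[["shell_0"]], m[["shell_1"]])
  expect_gt(m[["shell_1"]], m[["shell_2"]])
})
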