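rotation_matrix <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

test_that("RMSD is zero for identical sets and invariant under rigid motion", {
  set.seed(1)
  x <- matrix(rnorm(60), ncol = 3)
  expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-10)
  R <- rotation_matrix(0.3, -1.1, 2.2)
  y <- x %*% t(R) + matrix(rep(c(5, -3, 11), each = nrow(x)), ncol = 3)
  expect_equal(kabsch_rmsd(x, y), 0, tolerance = 1e-9)
  # known displacement after superposition: translate one point only
  y2 <- x
  y2[1, ] <- y2[1, ] + c(3, 0, 0)
  expect_gt(kabsch_rmsd(x, y2), 0)
  expect_error(kabsch_rmsd(x, x[1:10, ]), class = "divlimit_invalid_input")
  expect_error(kabsch_rmsd(x[1:2, ], x[1:2, ]), class = "divlimit_invalid_input")
})

test_that("RMSD matches the bio3d superposition oracle", {
  skip_if_not_installed("bio3d")
  set.seed(2)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    a <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    b <- a + matrix(rnorm(3 * n, sd = 0.8), ncol = 3)
    av <- as.vector(t(a)); bv <- as.vector(t(b))
    fitted <- bio3d::fit.xyz(fixed = av, mobile = bv)
    oracle <- sqrt(mean(colSums(matrix((fitted - av)^2, nrow = 3))))
    expect_equal(kabsch_rmsd(a, b), oracle, tolerance = 1e-6)
  }
})

test_that("reflection is never used to superpose mirror images", {
  set.seed(3)
  x <- matrix(rnorm(45, sd = 3), ncol = 3)
  mirror <- x %*% diag(c(-1, 1, 1))
  # a proper rotation cannot undo a reflection: RMSD stays positive
  expect_gt(kabsch_rmsd(x, mirror), 0.1)
})

test_that("jittered coordinates give the expected RMSD scale", {
  set.seed(4)
  sigma <- 0.5
  vals <- replicate(20, {
    x <- matrix(rnorm(3 * 500, sd = 10), ncol = 3)
    kabsch_rmsd(x, x + matrix(rnorm(3 * 500, sd = sigma), ncol = 3))
  })
  # isotropic jitter of sd sigma -> RMSD ~= sigma * sqrt(3)
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.05)
})

test_that("degenerate collinear coordinates warn but still return", {
  line <- cbind(1:5, 0, 0)
  expect_warning(r <- kabsch_rmsd(line, line), "Degenerate")
  expect_equal(r, 0, tolerance = 1e-10)
})

test_that("coverage filter keeps the boundary and drops flexible pairs", {
  rec <- tibble::tibble(pair = 1:4,
                        coverage = c(0.29, 0.30, 0.31, 0.95),
                        flexible = c(FALSE, FALSE, TRUE, FALSE))
  out <- coverage_filter(rec, max_unaligned = 0.7)
  # coverage exactly at 0.30 is kept; 0.29 dropped; flexible dropped
  expect_equal(out$pair, c(2L, 4L))
  out2 <- coverage_filter(rec[, c("pair", "coverage")], max_unaligned = 0.7)
  expect_equal(out2$pair, c(2L, 3L, 4L))
})

test_that("a monotone structural trend yields Spearman rho of one", {
  rec <- tibble::tibble(time = seq(0.1, 4, length.out = 50),
                        rmsd = seq(0.5, 3, length.out = 50))
  tr <- rmsd_time_trend(rec, ma_window = 5)
  expect_equal(tr$spearman$rho, 1)
  expect_lt(tr$spearman$p.value, 1e-10)
  expect_equal(tr$spearman$n, 50)
  # per-bin medians are monotone too
  med <- tr$bins$median[!is.na(tr$bins$median)]
  expect_true(all(diff(med) > 0))
  # moving average has NA pad at the edges and matches a manual mean inside
  ma <- tr$moving_average
  expect_true(all(is.na(ma$rmsd_ma[1:2])))
  expect_equal(ma$rmsd_ma[3], mean(rec$rmsd[1:5]))
  expect_error(rmsd_time_trend(rec[1:2, ]), class = "divlimit_insufficient_data")
  expect_error(rmsd_time_trend(tibble::tibble(time = c(1, 1, 1),
                                              rmsd = c(1, 2, 3))),
               class = "divlimit_invalid_input")
})

test_that("independent time and RMSD give a near-zero correlation", {
  set.seed(6)
  rec <- tibble::tibble(time = runif(1000, 0, 4), rmsd = runif(1000, 0, 3))
  tr <- rmsd_time_trend(rec)
  expect_lt(abs(tr$spearman$rho), 0.06)
  expect_gt(tr$spearman$p.value, 0.05)
})

test_that("group comparison reproduces hand-computed Mann-Whitney results", {
  rec <- tibble::tibble(value = c(1, 2, 3, 4, 5, 6),
                        group = rep(c("ec4", "ec3"), each = 3))
  res <- functional_group_comparison(rec, value, group)
  expect_equal(sort(res$summary$n), c(3L, 3L))
  # exact two-sided p for {1,2,3} vs {4,5,6} with no ties is 0.1
  expect_equal(res$tests$p.value, 0.1)
  expect_equal(res$tests$p.value,
               oracle_mann_whitney_p(c(4, 5, 6), c(1, 2, 3)))
})

test_that("group comparison matches exact enumeration on random small groups", {
  set.seed(7)
  for (i in 1:10) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    vals <- sample(seq(1, 100), nx + ny)  # distinct -> no ties
    rec <- tibble::tibble(value = vals,
                          group = rep(c("g1", "g2"), c(nx, ny)))
    res <- functional_group_comparison(rec, value, group)
    expect_equal(res$tests$p.value,
                 oracle_mann_whitney_p(vals[1:nx], vals[-(1:nx)]),
                 tolerance = 1e-12)
  }
})

test_that("group comparison handles filters, singletons and degenerate input", {
  rec <- tibble::tibble(value = c(1, 2, 3, 4, 10, 5),
                        group = c("a", "a", "b", "b", "c", "a"),
                        time = c(3, 3, 3, 3, 3, 0.5))
  expect_warning(res <- functional_group_comparison(rec, value, group),
                 "singleton")
  expect_equal(sort(unique(c(res$tests$group1, res$tests$group2))), c("a", "b"))
  # min_time filter drops the short-divergence record
  expect_warning(res2 <- functional_group_comparison(rec, value, group,
                                                     min_time = 1))
  expect_equal(res2$summary$n[res2$summary$group == "a"], 2L)
  expect_error(suppressWarnings(
    functional_group_comparison(rec[1:3, ], value, group)),
    class = "divlimit_insufficient_data")
  # three groups -> three pairwise tests
  rec3 <- tibble::tibble(value = rnorm(12), group = rep(c("a", "b", "c"), 4))
  expect_equal(nrow(functional_group_comparison(rec3, value, group)$tests), 3)
})

test_that("identity differences across groups persist within RMSD bins", {
  set.seed(8)
  n <- 120
  rec <- tibble::tibble(
    rmsd = runif(n, 0, 2),
    group = rep(c("same_ec", "ec3_only"), each = n / 2)
  )
  rec$identity <- ifelse(rec$group == "same_ec", 40, 27) + rnorm(n, 0, 2)
  res <- identity_by_structure_bins(rec, rmsd_bin_edges = c(0, 1, 2))
  expect_equal(nrow(res$summary), 4)
  expect_true(all(res$tests$p.value < 0.01))
  # the same comparison without binning agrees with the direct test
  direct <- functional_group_comparison(rec, identity, group)
  one_bin <- identity_by_structure_bins(rec, rmsd_bin_edges = c(0, 2))
  expect_equal(one_bin$tests$p.value, direct$tests$p.value)
  # bins are left-closed: a value exactly at an inner edge joins the upper bin
  rec2 <- tibble::tibble(identity = c(10, 20, 30, 40),
                         rmsd = c(0.2, 1.0, 1.2, 1.6),
                         group = c("a", "a", "b", "b"))
  s <- identity_by_structure_bins(rec2, rmsd_bin_edges = c(0, 1, 2))$summary
  expect_equal(s$n[as.character(s$rmsd_bin) == "[0,1)"], 1L)
})
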