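test_that("relative quantities follow q = E^-dCt with per-gene max of 1", {
  ct <- rbind(A = c(20, 21, 22, 23), B = c(25, 25, 25, 25))
  colnames(ct) <- paste0("s", 1:4)
  m <- ct_matrix(ct)
  q <- relative_quantities(m)$q
  expect_equal(unname(q["A", ]), c(1, 0.5, 0.25, 0.125))
  expect_equal(unname(q["B", ]), rep(1, 4))
  q19 <- relative_quantities(m, efficiency_base = 1.9)$q
  expect_equal(unname(q19["A", 1:2]), c(1, 1 / 1.9))
  expect_true(all(q > 0 & q <= 1))
  expect_equal(unname(apply(q, 1, max)), c(1, 1))
  expect_error(relative_quantities(m, efficiency_base = 1), "> 1")
})

test_that("delta-Ct stability reproduces hand-computed toy values", {
  tab <- delta_ct_stability(toy_ct_matrix())
  expect_equal(tab$stability, c(0.47871, 0.47871, 0.95743), tolerance = 1e-5)
  expect_equal(tab$rank, c(1L, 2L, 3L))
  # identical genes score 0 against each other
  ct <- rbind(A = c(20, 21, 22), B = c(20, 21, 22))
  colnames(ct) <- paste0("s", 1:3)
  expect_equal(delta_ct_stability(ct_matrix(ct))$stability, c(0, 0))
})

test_that("delta-Ct stability matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:20) {
    m <- random_ct_matrix(sample(2:8, 1), sample(3:12, 1))
    expect_equal(delta_ct_stability(m)$stability,
                 unname(brute_delta_ct(m$ct)), tolerance = 1e-12)
  }
})

test_that("GeNorm reproduces the hand-computed toy example", {
  g <- genorm(toy_ct_matrix())
  expect_equal(unname(g$initial_m), c(0.47871, 0.47871, 0.95743),
               tolerance = 1e-5)
  expect_equal(g$exclusion_order, "C")
  expect_equal(sort(g$final_pair), c("A", "B"))
  # final pair shares M = 0 (constant log ratio)
  expect_equal(g$stability$stability[1:2], c(0, 0))
  expect_equal(unname(g$pairwise_variation$v), 0.31914, tolerance = 1e-5)
})

test_that("initial GeNorm M equals the brute-force q-matrix computation", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_ct_matrix(sample(3:8, 1), sample(3:10, 1))
    base <- sample(c(1.9, 2, 2.1), 1)
    expect_equal(unname(genorm(m, efficiency_base = base)$initial_m),
                 unname(brute_genorm_m(m$ct, base)), tolerance = 1e-9)
  }
})

test_that("GeNorm M is invariant to per-gene and per-sample Ct shifts", {
  set.seed(21)
  m <- random_ct_matrix(6, 10)
  shifted <- m$ct + stats::runif(6, -3, 3) +
    rep(stats::runif(10, -2, 2), each = 6)
  m2 <- ct_matrix(shifted, group = m$group)
  expect_equal(genorm(m2)$initial_m, genorm(m)$initial_m, tolerance = 1e-9)
})

test_that("proportional genes have zero pairwise variation and zero M", {
  ct <- rbind(A = c(20, 21, 22), B = c(23, 24, 25))
  colnames(ct) <- paste0("s", 1:3)
  expect_equal(unname(genorm(ct_matrix(ct))$initial_m), c(0, 0))
})

test_that("GeNorm flags genes with M above the threshold as unsuitable", {
  set.seed(5)
  ct <- rbind(A = c(20, 21, 22, 23, 24),
              B = c(20.1, 21, 22.1, 23, 24.1),
              C = c(20, 26, 19, 27, 21))  # wildly unstable
  colnames(ct) <- paste0("s", 1:5)
  g <- genorm(ct_matrix(ct))
  expect_true(g$initial_m[["C"]] > 1.5)
  expect_equal(g$unsuitable, "C")
  expect_length(genorm(ct_matrix(ct), m_threshold = 100)$unsuitable, 0)
})

test_that("optimal reference count takes the smallest n under the cutoff", {
  mk <- function(v, n) structure(list(v = v, n = n, v_threshold = 0.15),
                                 class = "pairwise_variation")
  expect_equal(optimal_reference_count(mk(c(0.123, 0.2), 2:3))$n, 2)
  # strict inequality at the boundary
  opt <- optimal_reference_count(mk(c(0.149999), 2L))
  expect_equal(opt$n, 2)
  expect_true(opt$cutoff_met)
  expect_false(optimal_reference_count(mk(c(0.15), 2L))$cutoff_met)
  # no n below the cutoff: all k genes, flag unset
  opt2 <- optimal_reference_count(mk(c(0.3, 0.2), 2:3))
  expect_equal(opt2$n, 4)
  expect_false(opt2$cutoff_met)
})

test_that("ungrouped NormFinder reproduces the toy and the oracle", {
  nf <- normfinder(toy_ct_matrix(), use_groups = FALSE)
  expect_equal(nf$stability$stability, c(0, 0, 0.95743), tolerance = 1e-5)
  set.seed(33)
  for (i in 1:15) {
    m <- random_ct_matrix(sample(3:9, 1), sample(3:12, 1))
    expect_equal(normfinder(m, use_groups = FALSE)$stability$stability,
                 unname(brute_normfinder_ungrouped(m$ct)), tolerance = 1e-12)
  }
})

test_that("NormFinder SV is invariant to per-gene and per-sample shifts", {
  set.seed(40)
  m <- random_ct_matrix(5, 8)
  shifted <- m$ct + stats::runif(5, -4, 4) +
    rep(stats::runif(8, -2, 2), each = 5)
  m2 <- ct_matrix(shifted, group = m$group)
  expect_equal(normfinder(m2, use_groups = FALSE)$stability$stability,
               normfinder(m, use_groups = FALSE)$stability$stability,
               tolerance = 1e-9)
})

test_that("grouped NormFinder matches the brute-force oracle", {
  set.seed(55)
  for (i in 1:10) {
    m <- random_ct_matrix(sample(3:8, 1), 2 * sample(2:6, 1), groups = 2)
    nf <- normfinder(m, use_groups = TRUE)
    expect_true(nf$grouped)
    expect_equal(nf$stability$stability,
                 unname(brute_normfinder_grouped(m$ct, m$group)),
                 tolerance = 1e-12)
  }
})

test_that("grouped NormFinder demotes a gene with a group-mean shift", {
  set.seed(9)
  sp <- simulation_spec(k = 6, groups = 2, n_per_group = 8,
                        loading_sd = 0.2,
                        delta = {
                          d <- matrix(0, 6, 2)
                          d[6, 2] <- 2  # +2 cycles in group 2
                          d
                        },
                        noise_sd = 0.1)
  sim <- simulate_ct(sp, seed = 9)
  nf <- normfinder(sim$ct, use_groups = TRUE)
  expect_equal(nf$stability$rank[6], 6L)
})

test_that("NormFinder rejects degenerate inputs", {
  ct <- rbind(A = c(20, 21, 22), B = c(25, 26, 27))
  colnames(ct) <- paste0("s", 1:3)
  expect_error(normfinder(ct_matrix(ct)), "at least 3 genes")
  ct3 <- rbind(A = c(20, 21, 22), B = c(25, 26, 27), C = c(18, 19, 20))
  colnames(ct3) <- paste0("s", 1:3)
  m <- ct_matrix(ct3, group = c("a", "b", "b"))
  expect_error(normfinder(m, use_groups = TRUE), "singleton")
})

test_that("constant matrices give zero stability in every method", {
  ct <- matrix(c(20, 25, 30), 3, 4,
               dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  m <- ct_matrix(ct)
  expect_equal(delta_ct_stability(m)$stability, rep(0, 3))
  expect_equal(unname(genorm(m)$initial_m), rep(0, 3))
  expect_equal(normfinder(m, use_groups = FALSE)$stability$stability,
               rep(0, 3))
  expect_equal(bestkeeper(m)$sd, rep(0, 3))
})

test_that("BestKeeper descriptives match hand computation", {
  ct <- rbind(X = c(20, 20.5, 21), Y = c(30, 31, 35))
  colnames(ct) <- paste0("s", 1:3)
  bk <- bestkeeper(ct_matrix(ct))
  expect_equal(bk$mean_ct[1], 20.5)
  expect_equal(bk$sd[1], 1 / 3, tolerance = 1e-9)
  expect_equal(bk$cv[1], 100 * (1 / 3) / 20.5, tolerance = 1e-9)
  expect_equal(bk$rank, c(1L, 2L))
  expect_true(all(bk$min_ct <= bk$mean_ct & bk$mean_ct <= bk$max_ct))
  expect_true(all(bk$min_ct <= bk$geo_mean_ct & bk$geo_mean_ct <= bk$max_ct))
  # n-1 SD variant
  bk2 <- bestkeeper(ct_matrix(ct), sd_type = "sd")
  expect_equal(bk2$sd[1], sd(c(20, 20.5, 21)))
})

test_that("BestKeeper SD is permutation-invariant and scales linearly", {
  set.seed(77)
  m <- random_ct_matrix(4, 9)
  perm <- sample(9)
  m2 <- ct_matrix(m$ct[, perm], group = m$group[perm])
  expect_equal(bestkeeper(m2)$sd, bestkeeper(m)$sd, tolerance = 1e-12)
  a <- 2.5
  m3 <- ct_matrix(a * m$ct, group = m$group)
  expect_equal(bestkeeper(m3)$sd, a * bestkeeper(m)$sd, tolerance = 1e-9)
})

test_that("stability tables export as TSV with a method column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stability_table(delta_ct_stability(toy_ct_matrix()), f)
  tab <- read.delim(f)
  expect_equal(names(tab), c("method", "gene", "stability", "rank"))
  expect_equal(unique(tab$method), "delta_ct")
})
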