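test_that("TMM factors: symmetry, depth invariance, inflation direction", {
  cnt <- matrix(rpois(600, 50), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  # two identical columns -> both factors 1
  two <- cnt[, c(1, 1)]
  colnames(two) <- c("a", "b")
  f <- tmm_factors(two)
  expect_equal(unname(f$factors), c(1, 1), tolerance = 1e-12)
  # a pure depth doubling is absorbed by the library size
  two2 <- cbind(a = cnt[, 1], b = 2L * cnt[, 1])
  f2 <- tmm_factors(two2)
  expect_equal(unname(f2$factors), c(1, 1), tolerance = 1e-12)

  # inflating one sample's top-5% genes composition-biases it: its factor
  # must drop below 1, and below the untrimmed-mean oracle factor
  set.seed(1)
  mu <- exp(rnorm(2000, 5, 1))
  cnt4 <- matrix(rnbinom(2000 * 4, mu = rep(mu, 4), size = 10), 2000, 4,
                 dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:4)))
  top <- order(mu, decreasing = TRUE)[1:100]
  cnt4[top, 4] <- cnt4[top, 4] * 8L
  f4 <- tmm_factors(cnt4)
  expect_lt(f4$factors[["s4"]], 1)
  # untrimmed oracle: plain mean of M against sample 1
  keep <- cnt4[, 4] > 0 & cnt4[, 1] > 0
  m_or <- log2((cnt4[keep, 4] / sum(cnt4[, 4])) /
                 (cnt4[keep, 1] / sum(cnt4[, 1])))
  expect_lt(log2(f4$factors[["s4"]] / f4$factors[["s1"]]), mean(m_or))
})

test_that("dispersion estimation: Poisson limit, recovery, shrinkage limit", {
  x <- make_two_group_counts(2000, n = 5, phi = 1e-8, seed = 2)
  nf <- tmm_factors(x)
  d0 <- suppressWarnings(
    estimate_dispersion(x, x$samples$group, nf))
  expect_lt(d0$common_phi, 0.01)

  x2 <- make_two_group_counts(2000, n = 5, phi = 0.2, seed = 3)
  nf2 <- tmm_factors(x2)
  d2 <- estimate_dispersion(x2, x2$samples$group, nf2)
  expect_gt(d2$common_phi, 0.15)
  expect_lt(d2$common_phi, 0.25)
  # tagwise values are shrunk toward the common estimate
  expect_lt(sd(log(d2$tagwise_phi)),
            sd(log(pmax(
              estimate_dispersion(x2, x2$samples$group, nf2,
                                  prior_df = 0.1)$tagwise_phi, 1e-6))))
  # prior_df -> Inf collapses tagwise onto common
  dinf <- estimate_dispersion(x2, x2$samples$group, nf2, prior_df = Inf)
  expect_true(all(dinf$tagwise_phi == dinf$common_phi))
})

test_that("exact test: symmetry, antisymmetry, zero totals", {
  cnt <- matrix(c(10L, 12L, 8L, 10L, 12L, 8L,    # balanced gene
                  5L, 6L, 7L, 50L, 60L, 70L,     # shifted gene
                  0L, 0L, 0L, 0L, 0L, 0L),       # all-zero gene
                nrow = 3, byrow = TRUE,
                dimnames = list(c("bal", "up", "zero"), paste0("s", 1:6)))
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        group = rep(c("AC", "CS"), each = 3),
                        time_label = "9mo")
  x <- count_matrix(cnt, samples)
  nf <- structure(list(factors = setNames(rep(1, 6), paste0("s", 1:6)),
                       lib_sizes = setNames(rep(100, 6), paste0("s", 1:6)),
                       effective = setNames(rep(100, 6), paste0("s", 1:6))),
                  class = "norm_factors")
  disp <- structure(list(common_phi = 0.1,
                         tagwise_phi = setNames(rep(0.1, 3),
                                                rownames(cnt))),
                    class = "dispersion_estimates")
  g <- factor(samples$group, levels = c("AC", "CS"))
  res <- exact_test(x, g, nf, disp)
  expect_equal(res$p_value[res$gene == "bal"], 1)
  expect_equal(res$log2_fc[res$gene == "bal"], 0)
  expect_equal(res$p_value[res$gene == "zero"], 1)
  expect_equal(res$log2_fc[res$gene == "zero"], 0)
  # swapping group labels: identical p, negated log2FC
  res_sw <- exact_test(x, factor(samples$group, levels = c("CS", "AC")),
                       nf, disp)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res_sw$log2_fc, -res$log2_fc, tolerance = 1e-12)
})

test_that("exact test matches the brute-force enumeration oracle", {
  # the spec's worked fixture: n=3+3, equalized totals (10,12,8) vs
  # (40,38,44), phi = 0.1
  p_impl <- smokecourse:::exact_nb_pvals(30L, 122L, 3, 3, 0.1)
  p_or <- oracle_exact_p(30, 122, 3, 3, 0.1)
  expect_equal(p_impl, p_or, tolerance = 1e-10)

  set.seed(4)
  for (phi in c(0.01, 0.1, 0.5)) {
    t <- sample(0:200, 60, replace = TRUE)
    z1 <- vapply(t, function(tt) sample(0:tt, 1), 0L)
    for (n in list(c(3, 3), c(5, 5), c(4, 6))) {
      p_impl <- smokecourse:::exact_nb_pvals(as.integer(z1),
                                             as.integer(t - z1),
                                             n[1], n[2],
                                             rep(phi, length(t)))
      p_or <- mapply(oracle_exact_p, z1, t - z1,
                     MoreArgs = list(n1 = n[1], n2 = n[2], phi = phi))
      expect_equal(p_impl, unname(p_or), tolerance = 1e-10)
    }
  }
})

test_that("bh_adjust: closed forms and the naive O(m^2) oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(6)
  p <- runif(1000)^2
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  # monotone in rank
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-12))
})

test_that("independent filtering: identity at theta 0, gains on filterable data", {
  # null data: chosen theta arbitrary, discoveries near zero
  x0 <- make_two_group_counts(3000, n = 5, phi = 0.1, seed = 7)
  nf0 <- tmm_factors(x0)
  disp0 <- estimate_dispersion(x0, x0$samples$group, nf0)
  res0 <- exact_test(x0, factor(x0$samples$group,
                                levels = c("AC", "CS")), nf0, disp0)
  fil0 <- independent_filter(res0, x0, nf0)
  expect_lte(fil0$n_sig, 10)
  expect_equal(fil0$scan$n_sig[fil0$scan$theta == 0],
               sum(bh_adjust(res0$p_value) <= 0.1))

  # 10% strongly DE genes at high expression + 50% near-zero genes:
  # the scan must do at least as well as plain BH
  G <- 2000
  mu <- c(exp(rnorm(G / 2, 6, 0.8)), rep(0.3, G / 2))
  lfc <- c(rep(1.5, G * 0.1), rep(0, G * 0.9))
  xf <- make_two_group_counts(G, n = 5, mu = mu, phi = 0.1, lfc = lfc,
                              seed = 8)
  nff <- tmm_factors(xf)
  dispf <- estimate_dispersion(xf, xf$samples$group, nff)
  resf <- exact_test(xf, factor(xf$samples$group,
                                levels = c("AC", "CS")), nff, dispf)
  filf <- independent_filter(resf, xf, nff)
  expect_gte(filf$n_sig, filf$scan$n_sig[filf$scan$theta == 0])
  expect_gt(filf$n_sig, 0)
})

test_that("de_test wires the significance flag exactly", {
  spec <- null_spec(1500, phi = 0.1, seed = 9)
  spec$planted_pattern_table$persistent <- list(n = 60, lfc = 2,
                                                prop_up = 0.5)
  sim <- simulate_counts(spec)
  res <- de_test(sim$counts, c("CS", "AC"), "9mo")
  expect_true(all(res$significant ==
                    (res$q_value <= 0.10 &
                       abs(res$log2_fc) >= log2(1.5))))
  expect_equal(attr(res, "contrast"), c("CS", "AC"))
  # planted persistent genes are overwhelmingly discovered
  hits <- res$gene[res$significant]
  planted <- sim$truth$gene_patterns$gene[
    sim$truth$gene_patterns$label == "persistent"]
  expect_gt(mean(planted %in% hits), 0.85)
})
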