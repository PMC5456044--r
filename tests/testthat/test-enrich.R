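unit_nf <- function(n, lib = 1e6) {
  structure(list(factors = setNames(rep(1, n), paste0("s", 1:n)),
                 lib_sizes = setNames(rep(lib, n), paste0("s", 1:n)),
                 effective = setNames(rep(lib, n), paste0("s", 1:n))),
            class = "norm_factors")
}

test_that("gene-level stats: zeros on identical samples, hand fixture, depth invariance", {
  cnt <- matrix(c(100L, 10L, 100L, 10L,   # ctl1, ctl2 identical to trt1/2
                  200L, 40L, 200L, 40L),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        group = c("AC", "AC", "CS", "CS"),
                        time_label = "1d")
  x <- count_matrix(cnt, samples)
  g <- factor(samples$group, levels = c("AC", "CS"))
  st <- gene_level_stats(x, g, unit_nf(4), moderation = 1)
  expect_equal(dim(st), c(2L, 4L))
  # trt s3 vs ctl s1 are byte-identical columns -> stat 0
  expect_equal(unname(st[, "s3|s1"]), c(0, 0))
  # hand computation for the (s4, s1) pair on the CPM scale
  cpm4 <- cnt[, 4] / 1e6 * 1e6
  cpm1 <- cnt[, 1] / 1e6 * 1e6
  expect_equal(unname(st[, "s4|s1"]),
               unname(log2((cpm4 + 1) / (cpm1 + 1))))

  # doubling a treatment sample's depth (counts and library) changes nothing
  cnt2 <- cnt
  cnt2[, 3] <- cnt2[, 3] * 2L
  x2 <- count_matrix(cnt2, samples)
  nf2 <- unit_nf(4)
  nf2$lib_sizes["s3"] <- nf2$effective["s3"] <- 2e6
  st2 <- gene_level_stats(x2, g, nf2, moderation = 1)
  expect_equal(st2, st, ignore_attr = TRUE)
})

test_that("set containing all genes scores zero with p one half", {
  x <- make_two_group_counts(300, n = 3, phi = 0.1, seed = 11)
  nf <- tmm_factors(x)
  st <- gene_level_stats(x, factor(x$samples$group,
                                   levels = c("AC", "CS")), nf)
  res <- set_test(st, rownames(x$counts), "up")
  expect_equal(res$set_stat, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 0.5, tolerance = 1e-12)
})

test_that("small sets are skipped, not scored", {
  x <- make_two_group_counts(100, n = 3, phi = 0.1, seed = 12)
  nf <- tmm_factors(x)
  st <- gene_level_stats(x, factor(x$samples$group,
                                   levels = c("AC", "CS")), nf)
  res <- set_test(st, rownames(x$counts)[1:3], "up")
  expect_true(is.na(res$p_value))
  expect_equal(res$n_genes, 3L)
})

test_that("null random-set p-values are roughly uniform", {
  x <- make_two_group_counts(3000, n = 5, phi = 0.1, seed = 13)
  nf <- tmm_factors(x)
  st <- gene_level_stats(x, factor(x$samples$group,
                                   levels = c("AC", "CS")), nf)
  set.seed(14)
  p <- replicate(300, set_test(st, sample(rownames(x$counts), 20),
                               "up")$p_value)
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.60)
})

test_that("core genes: planted recovery, null expectation, sign filter", {
  G <- 1500
  lfc <- numeric(G)
  lfc[1] <- 3        # one strong gene inside the set
  lfc[2] <- -3       # one strong opposite-direction gene inside the set
  x <- make_two_group_counts(G, n = 5, phi = 0.05, lfc = lfc, seed = 15)
  nf <- tmm_factors(x)
  st <- gene_level_stats(x, factor(x$samples$group,
                                   levels = c("AC", "CS")), nf)
  set <- rownames(x$counts)[1:20]
  core_up <- core_genes(st, set, "up", sd_mult = 1)
  expect_true(rownames(x$counts)[1] %in% core_up)
  expect_false(rownames(x$counts)[2] %in% core_up)   # sign constraint
  # an all-null set contributes at most a few genes beyond 1 SD
  null_set <- rownames(x$counts)[100:119]
  expect_lte(length(core_genes(st, null_set, "up")), 6)
})

test_that("stronger planted effects never weaken one-sided significance", {
  ps <- vapply(c(0.5, 1, 2), function(eff) {
    lfc <- c(rep(eff, 20), rep(0, 980))
    x <- make_two_group_counts(1000, n = 5, phi = 0.1, lfc = lfc,
                               seed = 16)   # paired seeds: same noise
    nf <- tmm_factors(x)
    st <- gene_level_stats(x, factor(x$samples$group,
                                     levels = c("AC", "CS")), nf)
    set_test(st, rownames(x$counts)[1:20], "up")$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("enrich_all recovers a planted direction flip across time points", {
  spec <- null_spec(1200, phi = 0.1, seed = 17)
  spec$geneset_spec <- list(n_sets = 20, size_range = c(15, 25),
                            n_enriched = 0, n_recurrent = 0, effect = 1.2,
                            prop_up = 0.5, persist = 0)
  sim <- simulate_counts(spec)
  # plant the flip by hand: set 1 up at 1d, down at 7d
  genes <- match(sim$sets[[1]], rownames(sim$counts$counts))
  s <- sim$counts$samples
  cnt <- sim$counts$counts
  i1 <- s$group == "CS" & s$time_label == "1d"
  i7 <- s$group == "CS" & s$time_label == "7d"
  cnt[genes, i1] <- cnt[genes, i1] * 2L
  cnt[genes, i7] <- as.integer(round(cnt[genes, i7] / 2))
  x <- count_matrix(cnt, s)
  enr <- enrich_all(x, sim$sets, times = c("1d", "7d"))
  expect_equal(unname(enr$grid["SET001", c("1d", "7d")]),
               c("up", "down"))
  # q-values per direction equal bh_adjust of that direction's p list
  for (t in c("1d", "7d")) for (d in c("up", "down")) {
    sub <- enr$table[enr$table$time == t & enr$table$direction == d, ]
    ok <- !is.na(sub$p_value)
    expect_equal(sub$q_value[ok], bh_adjust(sub$p_value[ok]))
  }
  # direction exclusivity under coherent effects
  sub1 <- enr$table[enr$table$time == "1d" & enr$table$set == "SET001", ]
  expect_false(all(sub1$significant))
})
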