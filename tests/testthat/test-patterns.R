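test_that("classifier equals the exhaustive truth-table oracle", {
  mags <- c(0.7, 1.0, 2.1)     # distinct magnitudes exercise tie-breaks
  cases <- expand.grid(s1 = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                       s3 = c(TRUE, FALSE),
                       g1 = c(-1, 0, 1), g2 = c(-1, 0, 1),
                       g3 = c(-1, 0, 1),
                       m1 = mags, m2 = mags, m3 = mags)
  # sign = 0 iff log2FC = 0
  f1 <- cases$g1 * cases$m1
  f2 <- cases$g2 * cases$m2
  f3 <- cases$g3 * cases$m3
  tri <- data.frame(gene = sprintf("c%05d", seq_len(nrow(cases))),
                    sig_CSvAC = cases$s1, lfc_CSvAC = f1,
                    sig_SSvCS = cases$s2, lfc_SSvCS = f2,
                    sig_SSvAC = cases$s3, lfc_SSvAC = f3)
  got <- classify_patterns(tri)
  want <- mapply(oracle_pattern, cases$s1, f1, cases$s2, f2, cases$s3, f3)
  expect_identical(got$label, unname(want))
  # exhaustive + exclusive: every case got exactly one defined label
  expect_true(all(got$label %in% PATTERN_LEVELS))
})

test_that("published pattern branch examples classify as stated", {
  # up in CS, significantly reversed after cessation, back at AC level
  expect_equal(classify_gene(c(TRUE, TRUE, FALSE), c(2, -2, 0)),
               list(label = "reversible", direction = "up"))
  # the fully persistent case: down in CS, unchanged by cessation,
  # still down vs AC
  expect_equal(classify_gene(c(TRUE, FALSE, TRUE), c(-1.5, 0, -1.4)),
               list(label = "persistent", direction = "down"))
  # partial return, closer to AC than to CS
  expect_equal(classify_gene(c(TRUE, TRUE, TRUE), c(2, -1.2, 0.8))$label,
               "semi_reversible")
  # partial return, closer to CS: the lysosome-like case
  expect_equal(classify_gene(c(TRUE, TRUE, TRUE), c(2, -0.8, 1.2))$label,
               "semi_persistent")
  # amplification after cessation
  expect_equal(classify_gene(c(TRUE, TRUE, TRUE), c(1, 1, 2.5))$label,
               "continuing")
  # cessation-only response
  expect_equal(classify_gene(c(FALSE, TRUE, FALSE), c(0, 1.5, 0)),
               list(label = "recovery", direction = "up"))
})

test_that("summary arithmetic reproduces the published table layout", {
  s <- pattern_summary_from_counts(up = c(278, 134, 0, 1, 0),
                                   down = c(269, 198, 1, 1, 0))
  expect_equal(s$total, 882)
  expect_equal(unname(s$percent["semi_reversible"]), 37.64)
  expect_equal(unname(s$percent["persistent"]), 0.11)
  expect_equal(unname(s$percent["semi_persistent"]), 0.23)
  expect_equal(s$percent_reversible_any, 99.7)
  expect_equal(sum(s$counts["Up", ]) + sum(s$counts["Down", ]), 882)
  expect_equal(sum(s$counts[, "persistent"]), 1)   # one persistent gene

  sp <- pattern_summary_from_counts(up = c(18, 5, 0, 1, 0),
                                    down = c(38, 1, 0, 0, 0))
  expect_equal(sp$total, 63)
  expect_equal(unname(sp$percent["reversible"]), 88.89)
  expect_equal(sp$percent_reversible_any, 98.4)

  empty <- summarize_patterns(data.frame(gene = character(0),
                                         label = character(0),
                                         direction = character(0)))
  expect_equal(empty$total, 0)
  expect_true(all(empty$percent == 0))
})

test_that("recovery gene finder applies uniqueness rules", {
  mk <- function(genes, sig) data.frame(gene = genes, significant = sig)
  sscs <- mk(c("a", "b", "c"), c(TRUE, TRUE, FALSE))
  csac9 <- mk(c("a", "b", "c"), c(FALSE, TRUE, FALSE))
  expect_equal(find_recovery_genes(sscs, csac9), "a")
  # all-time-point uniqueness removes genes hit at any earlier time
  csac1 <- mk(c("a", "b", "c"), c(TRUE, FALSE, FALSE))
  expect_equal(find_recovery_genes(sscs, list(csac9, csac1)),
               character(0))
  # optional SSvAC exclusion
  ssac <- mk(c("a", "b", "c"), c(TRUE, FALSE, FALSE))
  expect_equal(find_recovery_genes(sscs, csac9, ssac), character(0))
})

test_that("planted recovery genes are found with high sensitivity", {
  spec <- null_spec(1500, phi = 0.1, seed = 31)
  spec$planted_pattern_table$recovery <- list(n = 40, lfc = 2,
                                              prop_up = 0.5)
  sim <- simulate_counts(spec)
  m9 <- month9_contrasts(sim$counts)
  rec <- find_recovery_genes(m9$SSvCS, m9$CSvAC)
  planted <- sim$truth$gene_patterns$gene[
    sim$truth$gene_patterns$label == "recovery"]
  expect_gte(mean(planted %in% rec), 0.9)
})

test_that("pathway-level classification mirrors the gene rules", {
  mk_enr <- function(sets, dir, stat, q) {
    data.frame(set = sets, time = "9mo", direction = dir,
               set_stat = stat, p_value = q, q_value = q,
               significant = q <= 0.10, n_genes = 20,
               core_genes = "", stringsAsFactors = FALSE)
  }
  sets <- c("pwA", "pwB")
  # pwA: up in CS, reversed significantly, not DE in SSvAC -> reversible
  # pwB: up in CS, partial move back, still up vs AC (|stat| closer to
  # CS) -> semi_persistent, the lysosome-like call
  csac <- rbind(mk_enr(sets, "up", c(5, 5), c(0.01, 0.01)),
                mk_enr(sets, "down", c(-1, -1), c(0.9, 0.9)))
  sscs <- rbind(mk_enr(sets, "up", c(1, 1), c(0.9, 0.9)),
                mk_enr(sets, "down", c(-4, -2), c(0.02, 0.05)))
  ssac <- rbind(mk_enr(sets, "up", c(1, 3), c(0.8, 0.03)),
                mk_enr(sets, "down", c(-0.5, -0.5), c(0.9, 0.9)))
  out <- classify_pathways(csac, sscs, ssac)
  expect_equal(out$calls$label[out$calls$set == "pwA"], "reversible")
  expect_equal(out$calls$label[out$calls$set == "pwB"],
               "semi_persistent")

  # a single reversible pathway summarizes to 100%
  one <- classify_pathways(csac[c(1, 3), ], sscs[c(1, 3), ],
                           ssac[c(1, 3), ])
  expect_equal(unname(one$summary$percent["reversible"]), 100)
})
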