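mini_series <- function() {
  # one series, 6 samples, 3 genes: a constant gene, a deviating gene and
  # a mirrored partner
  m <- rbind(const = rep(5, 6),
             dev = c(0, 0, 0, 0, 0, 3),
             mirror = c(0, 0, 0, 0, 0, -3))
  colnames(m) <- paste0("s", 1:6)
  list(ser1 = m)
}

test_that("deviation calls flag samples beyond z_dev series SDs", {
  calls <- call_deviations(mini_series(), z_dev = 2)
  cm <- calls$calls
  expect_true(all(cm["const", ] == 0))
  # the single spiked sample deviates by sqrt(5/6)/sd ~ +2.04 SDs
  expect_equal(unname(cm["dev", ]), c(0, 0, 0, 0, 0, 1))
  expect_equal(unname(cm["mirror", ]), c(0, 0, 0, 0, 0, -1))
  small <- list(s = mini_series()$ser1[, 1:3])
  expect_error(call_deviations(small), "fewer than 4")
  expect_error(call_deviations(mini_series(), z_dev = -1), "positive")
})

test_that("calls are invariant to sample order within a series", {
  set.seed(61)
  m <- matrix(rnorm(20 * 10), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  c1 <- call_deviations(list(a = m))
  perm <- sample(10)
  c2 <- call_deviations(list(a = m[, perm]))
  expect_equal(unname(c1$calls[, perm]), unname(c2$calls))
})

test_that("pair co-expression is symmetric and directional", {
  set.seed(67)
  n <- 40
  base <- sample(c(-1, 0, 1), n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  calls <- structure(list(
    calls = rbind(a = base, b = base, c = -base,
                  d = sample(c(-1, 0, 1), n, replace = TRUE,
                             prob = c(0.2, 0.6, 0.2))),
    series = factor(rep("s", n)), z_dev = 2),
    class = "deviation_calls")
  ab <- coexpress_pair("a", "b", calls)
  expect_equal(ab$direction, "positive")
  ac <- coexpress_pair("a", "c", calls)
  expect_equal(ac$direction, "negative")
  expect_equal(ab$p, ac$p)
  # symmetry
  ba <- coexpress_pair("b", "a", calls)
  expect_equal(ab$p, ba$p)
  # identical vectors beat an unrelated pair
  ad <- coexpress_pair("a", "d", calls)
  expect_lte(ab$p, ad$p)
  # too few joint samples
  sparse <- structure(list(
    calls = rbind(a = c(1, rep(0, 9)), b = c(1, rep(0, 9))),
    series = factor(rep("s", 10)), z_dev = 2),
    class = "deviation_calls")
  expect_equal(coexpress_pair("a", "b", sparse)$direction, "none")
  expect_equal(coexpress_pair("a", "b", sparse)$p, 1)
})

test_that("planted module pairs are strongly co-expressed", {
  cfg <- demo_config(seed = 71)
  comp <- generate_coexpression_compendium(cfg)
  calls <- call_deviations(comp)
  tf <- names(cfg$planted_tf_modules)[1]
  signs <- attr(comp, "module_signs")[[tf]]
  pos_gene <- names(signs)[signs > 0][1]
  neg_gene <- names(signs)[signs < 0][1]
  pp <- coexpress_pair(tf, pos_gene, calls)
  expect_equal(pp$direction, "positive")
  # significant at the bank's partner threshold
  expect_lt(pp$p, 0.05)
  # the p matches an exact hypergeometric oracle on the joint-call table
  ct <- calls$calls[tf, ]
  cp <- calls$calls[pos_gene, ]
  joint <- !is.na(ct) & !is.na(cp) & ct != 0 & cp != 0
  UU <- sum(ct[joint] > 0 & cp[joint] > 0)
  UD <- sum(ct[joint] > 0 & cp[joint] < 0)
  DU <- sum(ct[joint] < 0 & cp[joint] > 0)
  DD <- sum(ct[joint] < 0 & cp[joint] < 0)
  conc <- sum(dhyper(UU:min(UU + UD, UU + DU), UU + DU, UD + DD, UU + UD))
  expect_equal(pp$p, conc)
  pn <- coexpress_pair(tf, neg_gene, calls)
  expect_equal(pn$direction, "negative")
  # a positively loaded module gene tracks its TF within each series
  m <- comp[[1]]
  expect_gt(cor(m[tf, ], m[pos_gene, ]), 0.9)
  expect_lt(cor(m[tf, ], m[neg_gene, ]), -0.9)
  # non-module genes are independent of the TF within a series
  expect_lt(abs(cor(m[tf, ], m["g1999", ])), 0.3)
  # the concordance p depends on how the latent factor's excursions split
  # between up and down calls; across a batch of generator seeds the planted
  # pair is overwhelmingly strong in most runs
  ps <- vapply(1:10, function(s) {
    cfg_s <- demo_config(seed = s)
    comp_s <- generate_coexpression_compendium(cfg_s)
    calls_s <- call_deviations(comp_s)
    tf_s <- names(cfg_s$planted_tf_modules)[1]
    pos_s <- names(attr(comp_s, "module_signs")[[tf_s]])[1]
    coexpress_pair(tf_s, pos_s, calls_s)$p
  }, numeric(1))
  expect_gte(mean(ps < 1e-4), 0.7)
  expect_true(all(ps < 0.05))
})

test_that("the TFCEP bank recovers planted modules and skips absent TFs", {
  cfg <- demo_config(seed = 73)
  comp <- generate_coexpression_compendium(cfg)
  calls <- call_deviations(comp)
  tfs <- names(cfg$planted_tf_modules)
  expect_message(bank <- build_tfcep_bank(calls, c(tfs, "nosuchgene"),
                                          k = 500),
                 "absent")
  expect_length(bank, length(tfs))
  signs <- attr(comp, "module_signs")[[tfs[1]]]
  sig <- bank[[tfs[1]]]
  # planted partners appear in the matching direction
  expect_gte(mean(names(signs)[signs > 0] %in% sig$up), 0.8)
  expect_gte(mean(names(signs)[signs < 0] %in% sig$down), 0.8)
  # no padding: far fewer partners than k survive the significance cut
  expect_lt(length(sig$up), 500)
  # unrelated TFs share few partners
  other <- bank[[tfs[2]]]
  expect_lte(length(intersect(sig$up, other$up)), 3)
})

test_that("querying TFCEPs recovers the planted TF with the right sign", {
  cfg <- demo_config(seed = 79)
  comp <- generate_coexpression_compendium(cfg)
  calls <- call_deviations(comp)
  tfs <- names(cfg$planted_tf_modules)
  bank <- build_tfcep_bank(calls, tfs, k = 500)
  tf <- tfs[1]
  signs <- attr(comp, "module_signs")[[tf]]
  q <- signed_signature(up = names(signs)[signs > 0],
                        down = names(signs)[signs < 0])
  res <- query_tfcep(q, bank)
  expect_equal(res$name[1], tf)
  expect_gt(res$score[1], 2)
  # a TF's own signature ranks it first
  res_self <- query_tfcep(bank[[tf]], bank)
  expect_equal(res_self$name[1], tf)
  # sign-swapped query still singles the TF out, with negative score
  swap <- signed_signature(up = q$down, down = q$up)
  res_sw <- query_tfcep(swap, bank)
  expect_equal(res_sw$name[length(tfs)], tf)
  expect_lt(res_sw$score[length(tfs)], -2)
})
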