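make_profile <- function(keys, z, log2fc = z) {
  p <- data.frame(key = keys, z = z, log2fc = log2fc,
                  stringsAsFactors = FALSE)
  attr(p, "level") <- "gene"
  p
}

test_that("the differential Z is the pooled two-group statistic", {
  m <- rbind(p1 = c(0, 1, 0, 1, 2, 3, 2, 3),
             p2 = c(1, 1, 1, 1, 1, 1, 1, 1))
  colnames(m) <- c(paste0("c", 1:4), paste0("t", 1:4))
  de <- differential_profile(m, paste0("c", 1:4), paste0("t", 1:4))
  expect_equal(de$log2fc[1], 2)
  expect_equal(de$z[1], 2 / sqrt((1 / 3) * (1 / 4 + 1 / 4)))
  # identical arms
  expect_equal(de$z[2], 0)
  expect_equal(de$log2fc[2], 0)
  expect_error(differential_profile(m, "c1", paste0("t", 1:4)),
               "at least 2")
})

test_that("zero within-arm variance with a difference hits the z cap", {
  m <- rbind(p1 = c(0, 0, 5, 5))
  colnames(m) <- c("c1", "c2", "t1", "t2")
  de <- differential_profile(m, c("c1", "c2"), c("t1", "t2"))
  expect_equal(de$z, 40)
  de2 <- differential_profile(m, c("t1", "t2"), c("c1", "c2"))
  expect_equal(de2$z, -40)
})

test_that("swapping arm labels negates z and log2fc", {
  set.seed(21)
  m <- matrix(rnorm(200 * 8, 8, 1), nrow = 200,
              dimnames = list(sprintf("p%03d", 1:200),
                              c(paste0("c", 1:4), paste0("t", 1:4))))
  a <- differential_profile(m, paste0("c", 1:4), paste0("t", 1:4))
  b <- differential_profile(m, paste0("t", 1:4), paste0("c", 1:4))
  expect_equal(a$z, -b$z)
  expect_equal(a$log2fc, -b$log2fc)
})

test_that("probe-to-gene collapse keeps the maximal-magnitude Z with ties to positive", {
  prof <- data.frame(key = c("p1", "p2", "p3", "p4", "p5"),
                     z = c(2.0, -3.5, 2.0, -2.0, 1.1),
                     log2fc = c(0.5, -1.2, 0.6, -0.6, 0.2),
                     stringsAsFactors = FALSE)
  map <- data.frame(probe = c("p1", "p2", "p3", "p4", "p5"),
                    gene = c("gA", "gA", "gB", "gB", "gC"))
  g <- collapse_probes(prof, map)
  expect_equal(g$z[g$key == "gA"], -3.5)
  expect_equal(g$log2fc[g$key == "gA"], -1.2)
  expect_equal(g$z[g$key == "gB"], 2.0)   # tie -> positive
  expect_equal(g$z[g$key == "gC"], 1.1)   # single probe is identity
  expect_equal(attr(g, "level"), "gene")
})

test_that("fold-change counts threshold on |log2fc| >= log2(fold)", {
  p <- make_profile(c("a", "b", "c"), z = c(1, -1, 0),
                    log2fc = c(1.5, -1.0, -0.5))
  expect_equal(fold_change_counts(p, 2), c(n_up = 1, n_down = 1))
  # all-zero profile has no regulated genes at fold 2
  expect_equal(fold_change_counts(make_profile("a", 0, 0), 2),
               c(n_up = 0, n_down = 0))
  # fold 1 counts every gene on the side of its sign
  expect_equal(fold_change_counts(p, 1), c(n_up = 1, n_down = 2))
  expect_error(fold_change_counts(p, 0.5), ">= 1")
})

test_that("signature thresholding splits by signed z cut", {
  p <- make_profile(c("a", "b", "c"), z = c(3.2, -3.1, 2.9))
  s <- threshold_signature(p, 3)
  expect_equal(s$up, "a")
  expect_equal(s$down, "b")
  s2 <- threshold_signature(p, 10)
  expect_length(s2$up, 0)
  expect_length(s2$down, 0)
  expect_error(threshold_signature(p, 0), "positive")
  expect_error(signed_signature(c("a", "b"), c("b")), "disjoint")
})

test_that("planted effects at 2 log2 units are recovered with high sensitivity", {
  cfg <- demo_config(seed = 31)
  exp <- generate_experiment(cfg)
  de <- collapse_probes(
    differential_profile(exp$exprs, arm_samples(exp, "core_vehicle"),
                         arm_samples(exp, "core_treated")), exp$map)
  sig <- threshold_signature(de, 3)
  truth <- exp$truth$planted_de
  hits <- (truth$gene %in% sig$up & truth$direction == "up") |
    (truth$gene %in% sig$down & truth$direction == "down")
  expect_gte(mean(hits), 0.9)
})

test_that("overlap_fisher restricts, tabulates signs and matches the hypergeometric tail", {
  a <- make_profile(c("a", "b", "c", "d", "e"),
                    z = c(4, -4, 4, -1, 5))
  b <- make_profile(c("a", "b", "c", "d", "f"),
                    z = c(3.5, 3.2, -4, 9, -9))
  ov <- overlap_fisher(a, b, 3)
  # shared keys above cut in both: a (UU), b (DU), c (UD)
  expect_equal(c(ov$UU, ov$UD, ov$DU, ov$DD), c(1, 1, 1, 0))
  # no overlap at a high cut
  ov2 <- overlap_fisher(a, b, 20)
  expect_equal(ov2$p, 1)
  expect_equal(ov2$direction, "none")
  # perfectly concordant 10+10 table: single-term tail
  t3 <- overlap_table(10, 0, 0, 10)
  expect_equal(t3$p, 1 / choose(20, 10))
  expect_equal(t3$direction, "concordant")
})

test_that("overlap p equals explicit hypergeometric sums and fisher.test on random tables", {
  set.seed(13)
  hyper_sum <- function(UU, UD, DU, DD) {
    m <- UU + DU; n <- UD + DD; k <- UU + UD
    x <- UU:min(m, k)
    sum(dhyper(x, m, n, k))
  }
  for (i in 1:50) {
    cells <- rpois(4, 6)
    if (sum(cells) == 0) next
    tab <- overlap_table(cells[1], cells[2], cells[3], cells[4])
    expect_equal(tab$p, hyper_sum(cells[1], cells[2], cells[3], cells[4]))
    ft <- fisher.test(matrix(cells, 2, byrow = TRUE),
                      alternative = "greater")
    expect_equal(tab$p, ft$p.value, tolerance = 1e-10)
  }
})

test_that("Stouffer combination is (za+zb)/sqrt(2) over shared keys", {
  a <- make_profile(c("x", "y", "z"), z = c(5, 3, 3))
  b <- make_profile(c("x", "y", "z"), z = c(5, -3, 3))
  cb <- stouffer_combine(a, b)
  expect_equal(cb$z[cb$key == "x"], 10 / sqrt(2))
  expect_equal(cb$z[cb$key == "y"], 0)
  expect_equal(cb$z[cb$key == "z"], 6 / sqrt(2))
  # self-combination scales by sqrt(2) exactly
  self <- stouffer_combine(a, a)
  expect_equal(self$z, a$z[match(self$key, a$key)] * sqrt(2))
  expect_error(stouffer_combine(a, make_profile("q", 1)), "no keys")
})

test_that("null differential z is near-calibrated at 4v4", {
  cfg <- sim_config(n_genes = 4000, seed = 17)
  exp <- generate_experiment(cfg)
  de <- differential_profile(exp$exprs, arm_samples(exp, "core_vehicle"),
                             arm_samples(exp, "core_treated"))
  expect_gte(nrow(de), 5000)
  expect_lt(abs(mean(de$z)), 0.1)
  # uncorrected pooled-t at df 6 has SD sqrt(6/4) ~ 1.22
  expect_gt(sd(de$z), 0.85)
  expect_lt(sd(de$z), 1.3)
  # gene-level collapse selects the max-|z| probe, which inflates the SD
  # beyond the probe level; compare against a direct Monte-Carlo oracle of
  # the max-|t6| mixture using the map's actual probes-per-gene counts
  g <- collapse_probes(de, exp$map)
  expect_lt(abs(mean(g$z)), 0.1)
  k <- table(exp$map$gene)
  set.seed(18)
  oracle <- vapply(rep(as.integer(k), 25), function(kk) {
    t <- rt(kk, 6)
    t[which.max(abs(t))]
  }, numeric(1))
  expect_gt(sd(g$z), sd(de$z))
  expect_equal(sd(g$z), sd(oracle), tolerance = 0.05)
})
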