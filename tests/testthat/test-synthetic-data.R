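test_that("the generator is deterministic given the configuration", {
  cfg <- demo_config(seed = 5)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1, e2)
  b1 <- generate_background_compendium(cfg)
  b2 <- generate_background_compendium(cfg)
  expect_identical(b1, b2)
  c1 <- generate_coexpression_compendium(cfg)
  expect_identical(c1, generate_coexpression_compendium(cfg))
  # serialized artifacts are byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_matrix(e1$exprs, f1)
  write_matrix(e2$exprs, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(planted_de = data.frame(gene = "nope",
                                                  effect = 1)),
               "absent from the gene universe")
  expect_error(sim_config(planted_drugs = data.frame(drug = "d",
                                                     concordance = 1.5)),
               "\\[0, 1\\]")
  expect_error(sim_config(probes_per_gene = c("1" = 0.5)), "probabilities")
  genes <- sprintf("g%04d", 1:2000)
  expect_error(sim_config(planted_tf_modules = stats::setNames(
    list(genes[2:3], genes[3:4]), genes[10:11])), "disjoint")
  cfg <- sim_config(n_background_series = 1)
  expect_error(generate_background_compendium(cfg), "at least 2")
  expect_error(generate_panel(sim_config(panel_entities = 1),
                              setNames(0.1, "g0001")), "at least 2")
})

test_that("with no planted effects the arms differ only by noise", {
  cfg <- sim_config(n_genes = 500, seed = 13)
  exp <- generate_experiment(cfg)
  de <- differential_profile(exp$exprs, arm_samples(exp, "core_vehicle"),
                             arm_samples(exp, "core_treated"))
  expect_lt(abs(mean(de$log2fc)), 0.05)
  expect_lt(max(abs(de$log2fc)), 6 * cfg$noise_sd)
})

test_that("planted log2 effects are reproduced on average across simulations", {
  fc <- vapply(1:100, function(i) {
    cfg <- sim_config(n_genes = 50, seed = 1000 + i,
                      planted_de = data.frame(gene = "g0001", effect = 2))
    exp <- generate_experiment(cfg)
    probes <- exp$map$probe[exp$map$gene == "g0001"]
    de <- differential_profile(exp$exprs,
                               arm_samples(exp, "core_vehicle"),
                               arm_samples(exp, "core_treated"))
    mean(de$log2fc[de$key %in% probes])
  }, numeric(1))
  expect_lt(abs(mean(fc) - 2), 0.2)
})

test_that("the background compendium has shared probes and constitutive extremes", {
  cfg <- sim_config(n_genes = 500, n_background_series = 5,
                    samples_per_series = 10, seed = 3)
  bg <- generate_background_compendium(cfg)
  expect_length(bg, 5)
  expect_true(all(vapply(bg, ncol, integer(1)) == 10))
  rn <- rownames(bg[[1]])
  expect_true(all(vapply(bg, function(m) identical(rownames(m), rn),
                         logical(1))))
  r0 <- rowMeans(vapply(bg, scaled_ranks, numeric(nrow(bg[[1]]))))
  const <- attr(bg, "constitutive")
  # a +6 offset over N(0, 2) baselines leaves a constitutive-high probe
  # below a given other probe with probability pnorm(-6/(2*sqrt(2))) ~ 0.017,
  # so mean r0 sits near 0 while single probes can drift to ~0.1-0.2
  expect_lt(mean(r0[const$high]), 0.05)
  expect_gt(mean(r0[const$low]), 0.95)
  expect_lt(max(r0[const$high]), 0.25)
  expect_gt(min(r0[const$low]), 0.75)
  # constitutive extremes separate cleanly from the bulk
  bulk <- r0[setdiff(names(r0), c(const$high, const$low))]
  expect_lt(max(r0[const$high]), min(bulk))
  expect_gt(min(r0[const$low]), max(bulk))
})

test_that("the panel contains one twin and otherwise independent profiles", {
  cfg <- sim_config(n_genes = 5000, twin_noise = 0, seed = 29)
  set.seed(29)
  grp <- setNames(runif(5000, -1, 1), cfg$genes)
  panel <- generate_panel(cfg, grp)
  expect_length(panel, 17)
  twin <- attr(panel, "twin")
  expect_equal(compare_rank_profiles(grp, panel[[twin]])$rho, 1)
  others <- setdiff(names(panel), twin)
  rhos <- vapply(others, function(nm)
    compare_rank_profiles(grp, panel[[nm]])$rho, numeric(1))
  # null Spearman SD is ~1/sqrt(n-1) ~ 0.014 at n = 5000
  expect_lt(max(abs(rhos)), 0.05)
})

test_that("planted drugs share the stated concordance with the reference", {
  ref <- signed_signature(up = demo_genes[1:20], down = demo_genes[21:40])
  cfg <- sim_config(planted_drugs = data.frame(
    drug = c("full", "anti"), concordance = c(1, 0)), seed = 37)
  bank <- generate_signature_bank(cfg, ref)
  full <- bank[["full"]]
  expect_setequal(full$up, ref$up)
  expect_setequal(full$down, ref$down)
  anti <- bank[["anti"]]
  expect_setequal(anti$up, ref$down)
  expect_setequal(anti$down, ref$up)
  # decoy overlaps sit near the independence expectation
  decoys <- bank[grepl("^decoy", names(bank))]
  UU <- vapply(decoys, function(d) length(intersect(ref$up, d$up)),
               numeric(1))
  exp_uu <- 20 * 20 / cfg$n_genes # per decoy
  total <- sum(UU)
  expect_lt(abs(total - length(decoys) * exp_uu),
            4 * sqrt(length(decoys) * exp_uu) + 4)
})

test_that("truth records round-trip losslessly through JSON", {
  tr <- truth_record(
    planted_de = data.frame(gene = c("g0001", "g0002"),
                            effect = c(2, -1.5),
                            direction = c("up", "down"),
                            stringsAsFactors = FALSE),
    planted_sets = list(s1 = c("g0001", "g0002")),
    planted_drugs = data.frame(drug = "d", concordance = 0.9,
                               stringsAsFactors = FALSE),
    planted_tf_modules = list(g0003 = c("g0004", "g0005")),
    panel_twin = "entity07")
  f <- tempfile(fileext = ".json")
  write_truth(tr, f)
  back <- read_truth(f)
  expect_equal(back$planted_de, tr$planted_de)
  expect_equal(back$planted_sets, tr$planted_sets)
  expect_equal(back$planted_drugs, tr$planted_drugs)
  expect_equal(back$planted_tf_modules, tr$planted_tf_modules)
  expect_equal(back$panel_twin, tr$panel_twin)
  unlink(f)
})
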