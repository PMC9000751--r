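# Shared fixtures: a fully planted simulation configuration exercising every
# downstream stage, and a small toy expression matrix for hand-checked cases.

demo_genes <- sprintf("g%04d", 1:2000)

# The fully planted demonstration configuration now ships with the package.
demo_config <- function(seed = 7) demo_sim_config(seed = seed)

arm_samples <- function(exp, group) {
  names(exp$groups)[exp$groups == group]
}

toy_matrix <- function() {
  m <- matrix(c(5, 3, 1,
                5, 5, 1), ncol = 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  m
}
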