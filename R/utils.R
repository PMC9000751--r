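# Internal helpers shared across modules.

# Derive a deterministic per-stage seed from the master seed. Kept below
# 2^31 - 1 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# One-sided Fisher exact probability of concordance at least as large as
# observed: upper tail of the UU cell of the 2x2 table
#   UU UD
#   DU DD
# conditioned on its margins (hypergeometric).
concordance_tail <- function(UU, UD, DU, DD) {
  stats::phyper(UU - 1, UU + DU, UD + DD, UU + UD, lower.tail = FALSE)
}

# Lower-direction tail: probability of concordance at most as large (i.e.,
# discordance at least as extreme as observed).
discordance_tail <- function(UU, UD, DU, DD) {
  stats::phyper(UU, UU + DU, UD + DD, UU + UD, lower.tail = TRUE)
}

assert_named_numeric <- function(x, what) {
  if (!is.numeric(x) || is.null(names(x)) || anyNA(names(x))) {
    stop(what, " must be a named numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop(what, " has duplicated names", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
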