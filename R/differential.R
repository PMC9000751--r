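#' Treated-versus-control differential Z profile (probe level)
#'
#' For each probe the log2 fold change is the treated-arm mean minus the
#' control-arm mean, and the Z score is the two-group linear-fit statistic:
#' the fold change divided by its pooled-variance standard error
#' (equivalently the pooled two-sample t statistic, reported directly as Z).
#' The pooled variance is floored and |Z| capped so degenerate inputs cannot
#' produce non-finite values.
#'
#' @param matrix numeric expression matrix (probes x samples, log scale).
#' @param control,treated character vectors of column names, each of length
#'   >= 2.
#' @param var_floor lower bound on the pooled variance (default `1e-8`).
#' @param z_cap cap on |Z| (default 40).
#' @return data frame with columns `key`, `z`, `log2fc`, one row per probe,
#'   with attribute `level = "probe"`.
#' @export
differential_profile <- function(matrix, control, treated,
                                 var_floor = 1e-8, z_cap = 40) {
  for (arm in list(control, treated)) {
    if (length(arm) < 2) stop("each arm needs at least 2 samples", call. = FALSE)
    missing <- setdiff(arm, colnames(matrix))
    if (length(missing)) {
      stop("samples not in matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  if (length(intersect(control, treated))) {
    stop("control and treated arms overlap", call. = FALSE)
  }
  xc <- matrix[, control, drop = FALSE]
  xt <- matrix[, treated, drop = FALSE]
  n1 <- ncol(xc)
  n2 <- ncol(xt)
  log2fc <- rowMeans(xt) - rowMeans(xc)
  v1 <- apply(xc, 1, stats::var)
  v2 <- apply(xt, 1, stats::var)
  pooled <- pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2), var_floor)
  z <- log2fc / sqrt(pooled * (1 / n1 + 1 / n2))
  z <- pmin(pmax(z, -z_cap), z_cap)
  out <- data.frame(key = rownames(matrix), z = unname(z),
                    log2fc = unname(log2fc), stringsAsFactors = FALSE)
  attr(out, "level") <- "probe"
  out
}

#' Collapse a probe-level differential profile to genes
#'
#' Per gene, keeps the (z, log2fc) pair of the probe with the maximal |z|;
#' ties are broken toward the positive z, then by lexicographic probe ID.
#' Probes without a gene mapping are dropped.
#'
#' @param profile probe-level differential profile from
#'   [differential_profile()].
#' @param map data frame with columns `probe` and `gene`.
#' @return gene-level data frame with columns `key`, `z`, `log2fc` and
#'   attribute `level = "gene"`, sorted by gene.
#' @export
collapse_probes <- function(profile, map) {
  check_profile(profile)
  map <- validate_probe_map(map)
  idx <- match(profile$key, map$probe)
  keep <- !is.na(idx)
  genes <- map$gene[idx[keep]]
  probes <- profile$key[keep]
  z <- profile$z[keep]
  fc <- profile$log2fc[keep]
  if (length(genes) == 0) stop("no probes map to genes", call. = FALSE)
  ord <- order(genes, -abs(z), -sign(z), probes, method = "radix")
  first <- !duplicated(genes[ord])
  out <- data.frame(key = genes[ord][first], z = z[ord][first],
                    log2fc = fc[ord][first], stringsAsFactors = FALSE)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "level") <- "gene"
  out
}

#' Count fold-regulated genes
#'
#' @param profile differential profile data frame.
#' @param fold fold-change threshold as a ratio, >= 1 (default 2).
#' @return named integer vector `c(n_up, n_down)`: genes with
#'   `log2fc >= log2(fold)` and `log2fc <= -log2(fold)`.
#' @export
fold_change_counts <- function(profile, fold = 2) {
  check_profile(profile)
  if (!"log2fc" %in% names(profile)) {
    stop("profile has no log2fc column", call. = FALSE)
  }
  if (!is.numeric(fold) || length(fold) != 1 || fold < 1) {
    stop("fold must be a single ratio >= 1", call. = FALSE)
  }
  cut <- log2(fold)
  c(n_up = sum(profile$log2fc >= cut), n_down = sum(profile$log2fc <= -cut))
}

#' Threshold a differential profile into a signed gene signature
#'
#' @param profile differential profile data frame (gene level).
#' @param z_cut positive Z threshold (default 5).
#' @return a `signed_signature`: list with disjoint character vectors `up`
#'   (`z >= z_cut`) and `down` (`z <= -z_cut`).
#' @export
threshold_signature <- function(profile, z_cut = 5) {
  check_profile(profile)
  if (!is.numeric(z_cut) || length(z_cut) != 1 || z_cut <= 0) {
    stop("z_cut must be a single positive number", call. = FALSE)
  }
  signed_signature(up = profile$key[profile$z >= z_cut],
                   down = profile$key[profile$z <= -z_cut],
                   meta = list(z_cut = z_cut))
}

#' Construct a signed gene signature
#'
#' @param up,down character vectors of up- and down-regulated genes; must be
#'   disjoint.
#' @param meta optional list recording threshold provenance.
#' @return object of class `signed_signature`.
#' @export
signed_signature <- function(up, down, meta = list()) {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (length(intersect(up, down))) {
    stop("up and down gene sets must be disjoint", call. = FALSE)
  }
  structure(list(up = up, down = down, meta = meta),
            class = "signed_signature")
}

#' @export
print.signed_signature <- function(x, ...) {
  cat("signed gene signature:", length(x$up), "up /", length(x$down),
      "down genes\n")
  invisible(x)
}

#' Sign-concordance Fisher test between two differential profiles
#'
#' Restricts to keys with `|z| >= z_cut` in both profiles, tabulates sign
#' concordance (UU, UD, DU, DD where U/D is the sign in each profile) and
#' reports the one-sided Fisher exact probability of concordance at least as
#' large as observed (hypergeometric upper tail of the UU cell on the table's
#' margins).
#'
#' @param a,b differential profiles sharing a key space.
#' @param z_cut positive threshold applied to both profiles (default 3).
#' @return an `overlap_table`: list with counts `UU`, `UD`, `DU`, `DD`,
#'   probability `p` and `direction` ("concordant", "discordant" or "none").
#'   An empty overlap gives `p = 1`, direction "none".
#' @export
overlap_fisher <- function(a, b, z_cut = 3) {
  check_profile(a)
  check_profile(b)
  if (!is.numeric(z_cut) || length(z_cut) != 1 || z_cut <= 0) {
    stop("z_cut must be a single positive number", call. = FALSE)
  }
  za <- stats::setNames(a$z, a$key)
  zb <- stats::setNames(b$z, b$key)
  shared <- intersect(names(za), names(zb))
  keep <- shared[abs(za[shared]) >= z_cut & abs(zb[shared]) >= z_cut]
  sa <- za[keep] > 0
  sb <- zb[keep] > 0
  overlap_table(UU = sum(sa & sb), UD = sum(sa & !sb),
                DU = sum(!sa & sb), DD = sum(!sa & !sb))
}

#' Build an overlap table from its four counts
#'
#' @param UU,UD,DU,DD non-negative counts of sign-concordance classes.
#' @return an `overlap_table` with the one-sided concordance p value.
#' @export
overlap_table <- function(UU, UD, DU, DD) {
  counts <- c(UU = UU, UD = UD, DU = DU, DD = DD)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  conc <- UU + DD
  disc <- UD + DU
  direction <- if (conc + disc == 0) "none"
    else if (conc > disc) "concordant"
    else if (disc > conc) "discordant"
    else "none"
  p <- if (conc + disc == 0) 1 else concordance_tail(UU, UD, DU, DD)
  structure(list(UU = UU, UD = UD, DU = DU, DD = DD, p = p,
                 direction = direction),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("overlap table: UU %d, UD %d, DU %d, DD %d; p = %.4g (%s)\n",
              x$UU, x$UD, x$DU, x$DD, x$p, x$direction))
  invisible(x)
}

#' Combine two differential profiles by Stouffer's method
#'
#' Per shared key, the combined score is \eqn{(z_a + z_b)/\sqrt{2}}, the
#' equal-weight Stouffer combination under a shared standard-normal null.
#'
#' @param a,b differential profiles.
#' @return data frame with columns `key` and `z` over the shared keys,
#'   sorted by key.
#' @export
stouffer_combine <- function(a, b) {
  check_profile(a)
  check_profile(b)
  shared <- intersect(a$key, b$key)
  if (length(shared) == 0) stop("profiles share no keys", call. = FALSE)
  za <- stats::setNames(a$z, a$key)[shared]
  zb <- stats::setNames(b$z, b$key)[shared]
  out <- data.frame(key = shared, z = unname((za + zb) / sqrt(2)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_profile <- function(profile) {
  if (!is.data.frame(profile) || !all(c("key", "z") %in% names(profile))) {
    stop("profile must be a data frame with columns `key` and `z`",
         call. = FALSE)
  }
  if (anyDuplicated(profile$key)) {
    stop("profile keys must be unique", call. = FALSE)
  }
  invisible(profile)
}
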