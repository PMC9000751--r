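#' Per-probe scaled expression ranks averaged over a sample set
#'
#' Within each sample, probes are ranked by descending intensity (average
#' ranks for ties) and the ranks are scaled to lie in \eqn{[0, 1]}: 0 for the
#' highest-expressed probe, 1 for the lowest. The returned vector is the mean
#' scaled rank per probe over the requested samples. Because only ranks are
#' used, the result is invariant under any strictly monotone transform of the
#' intensities.
#'
#' @param matrix numeric expression matrix, probes in rows (unique rownames),
#'   samples in columns (unique colnames); log-scale intensities.
#' @param samples character vector of column names to average over; defaults
#'   to all columns.
#' @return named numeric vector of mean scaled ranks in \eqn{[0, 1]}, one per
#'   probe.
#' @examples
#' m <- matrix(c(5, 3, 1), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
#' scaled_ranks(m) # a=0, b=0.5, c=1
#' @export
scaled_ranks <- function(matrix, samples = colnames(matrix)) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("probe IDs (rownames) must be present and unique", call. = FALSE)
  }
  if (length(samples) == 0) stop("sample subset is empty", call. = FALSE)
  missing <- setdiff(samples, colnames(matrix))
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(matrix[, samples]) || any(!is.finite(matrix[, samples]))) {
    stop("expression values must be finite", call. = FALSE)
  }
  p <- nrow(matrix)
  if (p < 2) stop("need at least two probes to rank", call. = FALSE)
  sub <- matrix[, samples, drop = FALSE]
  scaled <- apply(sub, 2, function(x) (rank(-x, ties.method = "average") - 1) / (p - 1))
  out <- rowMeans(scaled)
  names(out) <- rownames(matrix)
  out
}

#' Relative rank of a probe against its background rank
#'
#' Transforms a probe's mean scaled rank \eqn{r} relative to its background
#' mean scaled rank \eqn{r_0} into a relative rank in \eqn{[-1, +1]}:
#' \eqn{(r_0 - r)/r_0} for \eqn{r < r_0} and \eqn{(r_0 - r)/(1 - r_0)} for
#' \eqn{r > r_0}; 0 at equality. Positive values mean the probe ranks higher
#' (more expressed) than in the background. The degenerate backgrounds
#' \eqn{r_0 = 0} and \eqn{r_0 = 1} are handled by the continuous limit of the
#' applicable branch so the result stays within \eqn{[-1, 1]}.
#'
#' @param r scaled rank(s) in \eqn{[0, 1]}.
#' @param r0 background scaled rank(s) in \eqn{[0, 1]}; recycled against `r`.
#' @return numeric vector of relative ranks in \eqn{[-1, +1]}.
#' @export
relative_rank <- function(r, r0) {
  if (anyNA(r) || anyNA(r0) || any(r < 0 | r > 1) || any(r0 < 0 | r0 > 1)) {
    stop("r and r0 must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(r), length(r0))
  r <- rep_len(r, n)
  r0 <- rep_len(r0, n)
  out <- numeric(n)
  up <- r < r0    # higher expression than background
  dn <- r > r0
  out[up] <- (r0[up] - r[up]) / r0[up]
  out[dn] <- (r0[dn] - r[dn]) / (1 - r0[dn])
  # continuous limits for degenerate backgrounds
  out[dn & r0 == 1] <- 0 # unreachable (r > 1 impossible); kept for safety
  bad <- up & r0 == 0
  out[bad] <- 0          # unreachable (r < 0 impossible)
  out
}

#' Build a gene rank profile (GRP)
#'
#' Computes per-probe relative ranks of a sample set against a background
#' compendium and collapses probes to genes. Where several probes map to one
#' gene, the probe with the largest-magnitude relative rank is kept (ties
#' broken toward the positive value, then by lexicographic probe ID); probes
#' without a gene mapping are dropped.
#'
#' @param sample_ranks named numeric vector of mean scaled ranks for the
#'   sample set (see [scaled_ranks()]).
#' @param background_ranks named numeric vector of background mean scaled
#'   ranks over the same probe universe.
#' @param map data frame with columns `probe` and `gene`; each probe maps to
#'   at most one gene.
#' @return named numeric vector: gene -> relative rank in \eqn{[-1, +1]},
#'   sorted by gene name.
#' @export
build_grp <- function(sample_ranks, background_ranks, map) {
  assert_named_numeric(sample_ranks, "sample_ranks")
  assert_named_numeric(background_ranks, "background_ranks")
  if (!setequal(names(sample_ranks), names(background_ranks))) {
    stop("probe universes of sample and background ranks differ", call. = FALSE)
  }
  map <- validate_probe_map(map)
  background_ranks <- background_ranks[names(sample_ranks)]
  rr <- relative_rank(sample_ranks, background_ranks)
  names(rr) <- names(sample_ranks)
  keep <- map$probe %in% names(rr)
  map <- map[keep, , drop = FALSE]
  if (nrow(map) == 0) stop("no mapped probes in the rank vectors", call. = FALSE)
  collapse_by_magnitude(map$gene, map$probe, rr[map$probe])
}

# Shared probe->gene collapse: keep, per gene, the value with maximal
# magnitude; ties broken toward the positive value, then lexicographic probe.
collapse_by_magnitude <- function(genes, probes, values) {
  ord <- order(genes, -abs(values), -sign(values), probes, method = "radix")
  first <- !duplicated(genes[ord])
  out <- values[ord][first]
  names(out) <- genes[ord][first]
  out[order(names(out))]
}

validate_probe_map <- function(map) {
  if (!is.data.frame(map) || !all(c("probe", "gene") %in% names(map))) {
    stop("map must be a data frame with columns `probe` and `gene`",
         call. = FALSE)
  }
  map <- map[!is.na(map$gene) & map$gene != "", c("probe", "gene")]
  map$probe <- as.character(map$probe)
  map$gene <- as.character(map$gene)
  if (anyDuplicated(map$probe)) {
    stop("each probe may map to at most one gene", call. = FALSE)
  }
  map
}

#' Compare two rank profiles by Spearman correlation
#'
#' Spearman's rho over the shared keys of two profiles, with the large-sample
#' significance score \eqn{z = \rho \sqrt{n - 1}}.
#'
#' @param a,b named numeric profiles (gene -> relative rank, or any named
#'   scores).
#' @return list with `rho`, `z` and `n` (number of shared keys).
#' @export
compare_rank_profiles <- function(a, b) {
  assert_named_numeric(a, "a")
  assert_named_numeric(b, "b")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("need at least 3 shared keys", call. = FALSE)
  rho <- stats::cor(a[shared], b[shared], method = "spearman")
  list(rho = rho, z = rho * sqrt(length(shared) - 1), n = length(shared))
}

#' Rank a panel of profiles by correlation with a query profile
#'
#' @param query named numeric rank profile.
#' @param panel named list of rank profiles.
#' @return data frame with columns `entity`, `rho`, `z`, `n`, sorted by
#'   descending rho (ties by entity name).
#' @export
rank_panel <- function(query, panel) {
  if (!is.list(panel) || length(panel) == 0 || is.null(names(panel))) {
    stop("panel must be a non-empty named list of profiles", call. = FALSE)
  }
  rows <- lapply(names(panel), function(nm) {
    cr <- compare_rank_profiles(query, panel[[nm]])
    data.frame(entity = nm, rho = cr$rho, z = cr$z, n = cr$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rho, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
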