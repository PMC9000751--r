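#' Call per-sample expression deviations within series
#'
#' Within each series of a compendium, each gene's values are standardised
#' against the series mean and SD; samples deviating by at least `z_dev`
#' SDs are called +1 (above) or -1 (below), all others 0. Genes absent from
#' a series get NA calls for its samples.
#'
#' @param compendium named list of expression matrices (genes x samples),
#'   one per series; each series must have at least 4 samples.
#' @param z_dev positive deviation threshold in SD units (default 2).
#' @param sd_floor lower bound on the series SD (default `1e-8`).
#' @return object of class `deviation_calls`: list with `calls` (integer
#'   matrix, union of genes x all samples, NA where a gene is absent from a
#'   series) and `series` (factor of series membership per sample column).
#' @export
call_deviations <- function(compendium, z_dev = 2, sd_floor = 1e-8) {
  if (!is.list(compendium) || length(compendium) == 0 ||
      is.null(names(compendium))) {
    stop("compendium must be a non-empty named list of matrices",
         call. = FALSE)
  }
  if (!is.numeric(z_dev) || z_dev <= 0) {
    stop("z_dev must be positive", call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(compendium, rownames))))
  blocks <- list()
  series_of <- character()
  for (nm in names(compendium)) {
    m <- compendium[[nm]]
    if (ncol(m) < 4) {
      stop("series `", nm, "` has fewer than 4 samples", call. = FALSE)
    }
    mu <- rowMeans(m)
    sdv <- pmax(apply(m, 1, stats::sd), sd_floor)
    z <- (m - mu) / sdv
    calls <- matrix(NA_integer_, nrow = length(genes), ncol = ncol(m),
                    dimnames = list(genes, paste(nm, colnames(m), sep = ".")))
    block <- matrix(0L, nrow = nrow(m), ncol = ncol(m))
    block[z >= z_dev] <- 1L
    block[z <= -z_dev] <- -1L
    calls[match(rownames(m), genes), ] <- block
    blocks[[nm]] <- calls
    series_of <- c(series_of, rep(nm, ncol(m)))
  }
  structure(list(calls = do.call(cbind, blocks),
                 series = factor(series_of, levels = names(compendium)),
                 z_dev = z_dev),
            class = "deviation_calls")
}

#' Fisher-exact co-expression of a gene pair
#'
#' Over the samples where both genes have a nonzero deviation call, the
#' 2x2 table of call signs is tested for concordance (same-sign deviations)
#' and discordance (opposite-sign): the direction with the smaller one-sided
#' Fisher tail is reported. Pairs with fewer than `min_joint` joint nonzero
#' samples return `p = 1`, direction "none".
#'
#' @param a,b gene names present in the calls.
#' @param calls a [call_deviations()] object.
#' @param min_joint minimum joint nonzero samples (default 3).
#' @return list with `p`, `direction` ("positive", "negative" or "none")
#'   and `n_joint`.
#' @export
coexpress_pair <- function(a, b, calls, min_joint = 3) {
  stopifnot(inherits(calls, "deviation_calls"))
  cm <- calls$calls
  if (!a %in% rownames(cm) || !b %in% rownames(cm)) {
    stop("both genes must be present in the calls", call. = FALSE)
  }
  ca <- cm[a, ]
  cb <- cm[b, ]
  joint <- !is.na(ca) & !is.na(cb) & ca != 0L & cb != 0L
  if (sum(joint) < min_joint) {
    return(list(p = 1, direction = "none", n_joint = sum(joint)))
  }
  pp <- sum(ca[joint] == 1L & cb[joint] == 1L)
  pm <- sum(ca[joint] == 1L & cb[joint] == -1L)
  mp <- sum(ca[joint] == -1L & cb[joint] == 1L)
  mm <- sum(ca[joint] == -1L & cb[joint] == -1L)
  p_conc <- concordance_tail(pp, pm, mp, mm)
  p_disc <- discordance_tail(pp, pm, mp, mm)
  if (p_conc <= p_disc) {
    list(p = p_conc, direction = "positive", n_joint = sum(joint))
  } else {
    list(p = p_disc, direction = "negative", n_joint = sum(joint))
  }
}

#' Build a bank of transcription-factor co-expression signatures (TFCEP)
#'
#' For each transcription factor, every other gene is scored by
#' [coexpress_pair()] (vectorised over genes) and the top `k` positively and
#' top `k` negatively co-expressed partners with `p <= partner_p` (ascending
#' p, ties by gene name) form the up and down sets of a signed signature.
#' Transcription factors absent from the calls are skipped with a message.
#'
#' @param calls a [call_deviations()] object.
#' @param tf_list character vector of transcription-factor gene names.
#' @param k maximum partners per direction (default 500).
#' @param min_joint minimum joint nonzero samples per pair (default 3).
#' @param partner_p p-value cutoff a partner must pass before the top-k
#'   truncation (default 0.05).
#' @return a [signature_bank()] of TF signatures over the call gene universe.
#' @export
build_tfcep_bank <- function(calls, tf_list, k = 500, min_joint = 3,
                             partner_p = 0.05) {
  stopifnot(inherits(calls, "deviation_calls"))
  cm <- calls$calls
  genes <- rownames(cm)
  absent <- setdiff(tf_list, genes)
  if (length(absent)) {
    message("TF(s) absent from the compendium skipped: ",
            paste(absent, collapse = ", "))
  }
  tfs <- intersect(tf_list, genes)
  # indicator matrices with NA treated as no call
  Cp <- cm == 1L
  Cm <- cm == -1L
  Cp[is.na(Cp)] <- FALSE
  Cm[is.na(Cm)] <- FALSE
  sigs <- list()
  for (tf in tfs) {
    tp <- Cp[tf, ]
    tm <- Cm[tf, ]
    pp <- as.vector(Cp %*% tp)
    mp <- as.vector(Cp %*% tm)
    pm <- as.vector(Cm %*% tp)
    mm <- as.vector(Cm %*% tm)
    joint <- pp + pm + mp + mm
    p_conc <- stats::phyper(pp - 1, pp + mp, pm + mm, pp + pm,
                            lower.tail = FALSE)
    p_disc <- stats::phyper(pp, pp + mp, pm + mm, pp + pm,
                            lower.tail = TRUE)
    positive <- p_conc <= p_disc
    p <- pmin(p_conc, p_disc)
    eligible <- joint >= min_joint & p <= partner_p & genes != tf
    pick <- function(dir_pos) {
      sel <- which(eligible & (positive == dir_pos))
      sel <- sel[order(p[sel], genes[sel], method = "radix")]
      genes[utils::head(sel, k)]
    }
    sigs[[tf]] <- signed_signature(up = pick(TRUE), down = pick(FALSE),
                                   meta = list(tf = tf, k = k,
                                               partner_p = partner_p))
  }
  if (length(sigs) == 0) stop("no TF present in the compendium", call. = FALSE)
  signature_bank(sigs, universe = length(genes))
}

#' Query a signed signature against a TFCEP bank
#'
#' Thin wrapper over [query_signature_bank()].
#'
#' @inheritParams query_signature_bank
#' @return see [query_signature_bank()].
#' @export
query_tfcep <- function(query, bank) {
  query_signature_bank(query, bank)
}
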