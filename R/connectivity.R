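#' Signed Fisher-exact score between two signed signatures
#'
#' Tabulates the four directional overlaps between a query and a target
#' signature (UU = query-up with target-up, UD = query-up with target-down,
#' DU, DD) and tests sign concordance on the table's own margins. Both
#' one-sided Fisher tails (toward concordance and toward discordance) are
#' evaluated and the smaller is reported, so a strongly discordant target is
#' as detectable as a strongly concordant one; the score is
#' \eqn{\mathrm{sign}(UU + DD - UD - DU) \cdot (-\log_{10} p)}. An empty
#' overlap gives p = 1 and score 0.
#'
#' @param query,target `signed_signature` objects.
#' @param universe optional gene-universe size, retained for provenance only
#'   (the test conditions on the 2x2 margins).
#' @return list with the `overlap_table` (`table`) and signed `score`.
#' @export
score_signature_pair <- function(query, target, universe = NULL) {
  stopifnot(inherits(query, "signed_signature"),
            inherits(target, "signed_signature"))
  UU <- length(intersect(query$up, target$up))
  UD <- length(intersect(query$up, target$down))
  DU <- length(intersect(query$down, target$up))
  DD <- length(intersect(query$down, target$down))
  tab <- overlap_table(UU, UD, DU, DD)
  total <- UU + UD + DU + DD
  if (total == 0) {
    return(list(table = tab, score = 0))
  }
  p_conc <- concordance_tail(UU, UD, DU, DD)
  p_disc <- discordance_tail(UU, UD, DU, DD)
  p <- min(p_conc, p_disc)
  tab$p <- p
  balance <- UU + DD - UD - DU
  list(table = tab, score = sign(balance) * (-log10(p)))
}

#' Construct a signature bank
#'
#' @param signatures named list of `signed_signature` objects.
#' @param universe gene-universe size the signatures were drawn from.
#' @return object of class `signature_bank` (a named list with a `universe`
#'   attribute).
#' @export
signature_bank <- function(signatures, universe) {
  if (!is.list(signatures) || is.null(names(signatures)) ||
      anyDuplicated(names(signatures))) {
    stop("signatures must be a uniquely named list", call. = FALSE)
  }
  ok <- vapply(signatures, inherits, logical(1), "signed_signature")
  if (!all(ok)) stop("all bank entries must be signed signatures", call. = FALSE)
  span <- max(c(0, vapply(signatures,
                          function(s) length(s$up) + length(s$down),
                          numeric(1))))
  if (universe < span) {
    stop("universe smaller than the largest signature", call. = FALSE)
  }
  structure(signatures, universe = universe, class = "signature_bank")
}

#' Query a signed signature against a signature bank
#'
#' Scores every bank member with [score_signature_pair()] and ranks by
#' descending signed score (ties broken by name).
#'
#' @param query a `signed_signature`.
#' @param bank a [signature_bank()].
#' @return data frame with columns `name`, `UU`, `UD`, `DU`, `DD`, `p`,
#'   `score`, sorted by descending score.
#' @export
query_signature_bank <- function(query, bank) {
  stopifnot(inherits(bank, "signature_bank"))
  if (length(bank) == 0) stop("bank is empty", call. = FALSE)
  universe <- attr(bank, "universe")
  rows <- lapply(names(bank), function(nm) {
    sc <- score_signature_pair(query, bank[[nm]], universe)
    data.frame(name = nm, UU = sc$table$UU, UD = sc$table$UD,
               DU = sc$table$DU, DD = sc$table$DD, p = sc$table$p,
               score = sc$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
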