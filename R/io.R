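# Readers and writers for the package's plain-text formats. All writers can
# emit '#'-prefixed provenance header lines; all readers skip them.

#' Write / read an expression matrix as TSV
#'
#' First column `probe_id`, remaining columns one per sample. Lines starting
#' with `#` are provenance comments and are skipped on read.
#'
#' @param matrix numeric matrix with unique row and column names.
#' @param path file path.
#' @param header optional character vector of provenance lines (written
#'   `#`-prefixed).
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the numeric matrix.
#' @export
write_matrix <- function(matrix, path, header = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, header)
  writeLines(paste(c("probe_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1, function(x)
    paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- read_body(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    stop("ragged rows in ", path, call. = FALSE)
  }
  hdr <- fields[[1]]
  ids <- vapply(fields[-1], `[`, character(1), 1)
  if (anyDuplicated(ids)) stop("duplicate probe IDs in ", path, call. = FALSE)
  vals <- vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric cell in ", path, call. = FALSE)
    v
  }, numeric(length(hdr) - 1))
  m <- t(matrix(vals, nrow = length(hdr) - 1))
  dimnames(m) <- list(ids, hdr[-1])
  m
}

#' Write / read a profile as TSV
#'
#' Two or three tab-separated columns: a key plus one (`relative_rank` or
#' `z`) or two (`z`, `log2fc`) numeric columns. Values round-trip at full
#' double precision.
#'
#' @param profile named numeric vector (rank profile) or data frame with
#'   `key`, `z` and optionally `log2fc`.
#' @param path file path.
#' @param header optional provenance lines.
#' @return `read_profile` returns a named vector for 2-column files and a
#'   differential-profile data frame otherwise.
#' @export
write_profile <- function(profile, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, header)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  if (is.data.frame(profile)) {
    cols <- intersect(c("key", "z", "log2fc"), names(profile))
    writeLines(paste(cols, collapse = "\t"), con)
    body <- do.call(paste, c(lapply(cols, function(cl) {
      v <- profile[[cl]]
      if (is.numeric(v)) fmt(v) else as.character(v)
    }), sep = "\t"))
    writeLines(body, con)
  } else {
    assert_named_numeric(profile, "profile")
    writeLines("key\trelative_rank", con)
    writeLines(paste(names(profile), fmt(unname(profile)), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- read_body(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(unique(lengths(fields))) != 1) {
    stop("ragged rows in ", path, call. = FALSE)
  }
  hdr <- fields[[1]]
  keys <- vapply(fields[-1], `[`, character(1), 1)
  if (anyDuplicated(keys)) stop("duplicate keys in ", path, call. = FALSE)
  nums <- lapply(seq_along(hdr)[-1], function(j) {
    v <- suppressWarnings(as.numeric(vapply(fields[-1], `[`,
                                            character(1), j)))
    if (anyNA(v)) stop("non-numeric cell in ", path, call. = FALSE)
    v
  })
  if (length(hdr) == 2) {
    return(stats::setNames(nums[[1]], keys))
  }
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  for (j in seq_along(nums)) out[[hdr[j + 1]]] <- nums[[j]]
  out
}

#' Write / read a probe-to-gene map as 2-column TSV
#'
#' @param map data frame with columns `probe` and `gene`.
#' @param path file path.
#' @param header optional provenance lines.
#' @export
write_probe_map <- function(map, path, header = NULL) {
  map <- validate_probe_map(map)
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, header)
  writeLines("probe\tgene", con)
  writeLines(paste(map$probe, map$gene, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  lines <- read_body(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) stop("map rows need 2 fields", call. = FALSE)
  validate_probe_map(data.frame(
    probe = vapply(fields[-1], `[`, character(1), 1),
    gene = vapply(fields[-1], `[`, character(1), 2),
    stringsAsFactors = FALSE))
}

#' Write / read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated
#' (the standard GSEA dialect). Duplicate set names are an error; duplicate
#' genes within a set are deduplicated with a message.
#'
#' @param collection named list; each element either a character vector of
#'   genes or a list with `description` and `genes`.
#' @param path file path.
#' @return `read_gmt` returns a named list with elements `description` and
#'   `genes` per set.
#' @export
write_gmt <- function(collection, path) {
  if (is.null(names(collection)) || anyDuplicated(names(collection))) {
    stop("collection must have unique names", call. = FALSE)
  }
  lines <- vapply(names(collection), function(nm) {
    el <- collection[[nm]]
    if (is.list(el)) {
      desc <- el$description %||% "na"
      genes <- el$genes
    } else {
      desc <- "na"
      genes <- el
    }
    if (length(genes) == 0) stop("set `", nm, "` is empty", call. = FALSE)
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- read_body(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  nms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nms)) {
    stop("duplicate set names in ", path, call. = FALSE)
  }
  out <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      message("set `", f[1], "`: ", sum(duplicated(genes)),
              " duplicate gene(s) removed")
      genes <- unique(genes)
    }
    list(description = f[2], genes = genes)
  })
  stats::setNames(out, nms)
}

#' Write / read a signed gene signature
#'
#' Two-section text format: a `>up` line followed by one gene per line,
#' then `>down` and its genes. Overlapping up/down genes are an error.
#'
#' @param signature a `signed_signature`.
#' @param path file path.
#' @param header optional provenance lines.
#' @export
write_signature <- function(signature, path, header = NULL) {
  stopifnot(inherits(signature, "signed_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, header)
  writeLines(c(">up", signature$up, ">down", signature$down), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- read_body(path)
  iu <- match(">up", lines)
  id <- match(">down", lines)
  if (is.na(iu) || is.na(id) || id < iu) {
    stop("signature file needs `>up` then `>down` sections", call. = FALSE)
  }
  up <- lines[seq(iu + 1, length.out = id - iu - 1)]
  down <- if (id == length(lines)) character() else
    lines[seq(id + 1, length.out = length(lines) - id)]
  signed_signature(up = up[nzchar(up)], down = down[nzchar(down)])
}

#' Write / read a truth record as JSON
#'
#' @param truth a [truth_record()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- lapply(x$planted_sets, as.character)
  mods <- lapply(x$planted_tf_modules, as.character)
  truth_record(planted_de = x$planted_de,
               planted_sets = sets,
               planted_drugs = x$planted_drugs,
               planted_tf_modules = mods,
               panel_twin = x$panel_twin)
}

write_header <- function(con, header) {
  if (!is.null(header) && length(header)) {
    writeLines(paste0("# ", header), con)
  }
}

read_body <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) stop("no content in ", path, call. = FALSE)
  lines
}
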