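#' Configuration for the end-to-end pipeline
#'
#' Bundles the synthetic-data configuration, stage toggles and all stage
#' parameters for [run_pipeline()].
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param outdir output directory (created if missing).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "grp", "de", "enrich", "connect", "tfcep")`. Later
#'   stages need the artifacts of earlier ones.
#' @param z_cut_overlap Z threshold for the between-line concordance test
#'   (default 3).
#' @param z_cut_signature Z threshold for signed signatures (default 5).
#' @param fold fold-change threshold for regulated-gene counts (default 2).
#' @param model a [ks_null_model()] for enrichment.
#' @param n_min minimum set size for enrichment (default 5).
#' @param z_dev deviation-call threshold for co-expression (default 2).
#' @param k partners per direction in TFCEP signatures (default 500).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, outdir,
                            stages = c("simulate", "grp", "de", "enrich",
                                       "connect", "tfcep"),
                            z_cut_overlap = 3, z_cut_signature = 5,
                            fold = 2, model = ks_null_model(), n_min = 5,
                            z_dev = 2, k = 500) {
  stopifnot(inherits(sim, "sim_config"))
  known <- c("simulate", "grp", "de", "enrich", "connect", "tfcep")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(sim = sim, outdir = outdir, stages = stages,
                 z_cut_overlap = z_cut_overlap,
                 z_cut_signature = z_cut_signature, fold = fold,
                 model = model, n_min = n_min, z_dev = z_dev, k = k),
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' `simulate` generates the experiment, background compendium and truth
#' record; `grp` builds gene rank profiles for both cell lines against the
#' background and ranks the synthetic panel; `de` computes per-line
#' differential profiles, signatures, the between-line concordance table
#' and the Stouffer-combined profile; `enrich` scores the planted gene sets
#' on the combined profile; `connect` queries the core signature against
#' the generated drug bank; `tfcep` builds the co-expression bank and
#' queries the core signature against it. Every artifact is written under
#' `config$outdir` with a provenance header, and a manifest of artifacts
#' with md5 digests is returned (and written as `manifest.tsv`).
#'
#' @param config a [pipeline_config()].
#' @return data frame manifest with columns `stage`, `artifact`, `path`,
#'   `md5`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  sim <- config$sim
  art <- list()
  state <- new.env(parent = emptyenv())
  prov <- function(stage, ...) {
    c(paste("stage:", stage),
      paste("seed:", sim$seed), ...)
  }
  emit <- function(stage, name, path) {
    art[[length(art) + 1]] <<- data.frame(
      stage = stage, artifact = name, path = path,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  need <- function(what, stage) {
    if (!exists(what, envir = state)) {
      stop("stage `", stage, "` needs the output of an earlier stage ",
           "that was not run (missing: ", what, ")", call. = FALSE)
    }
    get(what, envir = state)
  }

  if ("simulate" %in% stages) {
    exp <- generate_experiment(sim)
    bg <- generate_background_compendium(sim)
    assign("exp", exp, state)
    assign("bg", bg, state)
    p <- file.path(config$outdir, "experiment.tsv")
    write_matrix(exp$exprs, p, header = prov("simulate",
      paste("groups:", paste(names(exp$groups), exp$groups, sep = "=",
                             collapse = ","))))
    emit("simulate", "experiment", p)
    p <- file.path(config$outdir, "probe_map.tsv")
    write_probe_map(exp$map, p, header = prov("simulate"))
    emit("simulate", "probe_map", p)
    p <- file.path(config$outdir, "truth.json")
    write_truth(exp$truth, p)
    emit("simulate", "truth", p)
  }

  if ("grp" %in% stages) {
    exp <- need("exp", "grp")
    bg <- need("bg", "grp")
    r0 <- rowMeans(vapply(bg, scaled_ranks, numeric(nrow(exp$exprs))))
    grps <- list()
    for (line in c("core", "margin")) {
      samples <- names(exp$groups)[exp$groups == paste0(line, "_vehicle")]
      r <- scaled_ranks(exp$exprs, samples)
      grps[[line]] <- build_grp(r, r0, exp$map)
      p <- file.path(config$outdir, paste0("grp_", line, ".tsv"))
      write_profile(grps[[line]], p, header = prov("grp",
        paste("line:", line)))
      emit("grp", paste0("grp_", line), p)
    }
    assign("grps", grps, state)
    panel <- generate_panel(sim, grps$core, grps$margin)
    ranking <- rank_panel(grps$core, panel)
    assign("panel_twin", attr(panel, "twin"), state)
    p <- file.path(config$outdir, "panel_ranking.tsv")
    utils::write.table(ranking, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit("grp", "panel_ranking", p)
  }

  if ("de" %in% stages) {
    exp <- need("exp", "de")
    des <- list()
    sigs <- list()
    for (line in c("core", "margin")) {
      ctrl <- names(exp$groups)[exp$groups == paste0(line, "_vehicle")]
      trt <- names(exp$groups)[exp$groups == paste0(line, "_treated")]
      de <- collapse_probes(
        differential_profile(exp$exprs, ctrl, trt), exp$map)
      des[[line]] <- de
      sigs[[line]] <- threshold_signature(de, config$z_cut_signature)
      p <- file.path(config$outdir, paste0("de_", line, ".tsv"))
      cnt <- fold_change_counts(de, config$fold)
      write_profile(de, p, header = prov("de",
        paste0("fold", config$fold, "_up: ", cnt["n_up"]),
        paste0("fold", config$fold, "_down: ", cnt["n_down"])))
      emit("de", paste0("de_", line), p)
      p <- file.path(config$outdir, paste0("signature_", line, ".txt"))
      write_signature(sigs[[line]], p, header = prov("de",
        paste("z_cut:", config$z_cut_signature)))
      emit("de", paste0("signature_", line), p)
    }
    assign("des", des, state)
    assign("sigs", sigs, state)
    ov <- overlap_fisher(des$core, des$margin, config$z_cut_overlap)
    p <- file.path(config$outdir, "overlap.tsv")
    utils::write.table(
      data.frame(UU = ov$UU, UD = ov$UD, DU = ov$DU, DD = ov$DD,
                 p = ov$p, direction = ov$direction),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("de", "overlap", p)
    comb <- stouffer_combine(des$core, des$margin)
    assign("comb", comb, state)
    p <- file.path(config$outdir, "combined.tsv")
    write_profile(comb, p, header = prov("de", "method: stouffer"))
    emit("de", "combined", p)
  }

  if ("enrich" %in% stages) {
    comb <- need("comb", "enrich")
    collection <- lapply(sim$planted_sets, function(g) g)
    if (length(collection) == 0) {
      stop("stage `enrich` needs planted gene sets in the sim config",
           call. = FALSE)
    }
    p <- file.path(config$outdir, "sets.gmt")
    write_gmt(collection, p)
    emit("enrich", "sets", p)
    res <- enrich_collection(comb, collection, config$model, config$n_min)
    p <- file.path(config$outdir, "enrichment.tsv")
    utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("enrich", "enrichment", p)
  }

  if ("connect" %in% stages) {
    sigs <- need("sigs", "connect")
    bank <- generate_signature_bank(sim, sigs$core)
    res <- query_signature_bank(sigs$core, bank)
    p <- file.path(config$outdir, "connectivity.tsv")
    utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("connect", "connectivity", p)
  }

  if ("tfcep" %in% stages) {
    sigs <- need("sigs", "tfcep")
    comp <- generate_coexpression_compendium(sim)
    calls <- call_deviations(comp, config$z_dev)
    tf_list <- names(sim$planted_tf_modules)
    bank <- build_tfcep_bank(calls, tf_list, k = config$k)
    res <- query_tfcep(sigs$core, bank)
    p <- file.path(config$outdir, "tfcep.tsv")
    utils::write.table(res, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit("tfcep", "tfcep", p)
  }

  manifest <- do.call(rbind, art)
  mp <- file.path(config$outdir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
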