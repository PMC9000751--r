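#' Configuration for the synthetic data generator
#'
#' Defines the simulated study: two cell lines (a tumour-core-like and an
#' invasive-margin-like population), each with vehicle and treated arms in
#' replicate on a shared probe universe, a multi-series background
#' compendium, a rank-profile panel, a drug-signature bank, and a
#' co-expression compendium with planted transcription-factor modules. All
#' randomness downstream flows from the single `seed` through deterministic
#' per-stage substreams, so identical configurations give byte-identical
#' outputs.
#'
#' @param n_genes number of genes in the universe (default 2000). Gene IDs
#'   are `g0001`, `g0002`, ...
#' @param probes_per_gene named numeric vector of probe-count probabilities;
#'   names are probe counts (default 70\% of genes with one probe, 15\% each
#'   with two or three, exercising the probe-to-gene collapse rules).
#' @param n_background_series,samples_per_series background compendium
#'   shape (defaults 10 series of 40 samples); `samples_per_series` also
#'   sets the series length of the co-expression compendium.
#' @param replicates_per_arm replicate arrays per arm (default 4).
#' @param noise_sd residual log2-intensity SD within an arm (default 0.25).
#' @param planted_de data frame with columns `gene`, `effect` (log2 shift of
#'   the treated arm in both cell lines), or NULL.
#' @param planted_sets named list of character gene vectors used as truly
#'   enriched gene sets, or an empty list.
#' @param planted_drugs data frame with columns `drug`, `concordance`
#'   (fraction of shared genes moving with the reference signature, in
#'   [0, 1]), or NULL.
#' @param planted_tf_modules named list: TF gene -> character vector of
#'   module genes that co-vary with it in the co-expression compendium.
#' @param panel_entities number of panel rank profiles (default 17).
#' @param seed master integer seed.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution per
#'   probe (defaults 8 and 2; only ranks matter downstream, so the exact law
#'   is free).
#' @param background_noise_sd within-series sample SD in the background
#'   compendium (default 0.5).
#' @param constitutive_frac fraction of probes forced constitutively high
#'   (and the same fraction low) across every background series (default
#'   0.02).
#' @param twin_noise half-width of the uniform rank noise added to the
#'   panel twin (default 0.05).
#' @param module_loading,module_noise latent-factor loading and residual SD
#'   of planted TF modules in the co-expression compendium (defaults 3 and
#'   0.3; non-module genes get unit-SD independent noise).
#' @param coexpr_series number of series in the co-expression compendium
#'   (default 25, each of `samples_per_series` samples). The default is
#'   sized so a planted module pair accumulates roughly 35-45 joint
#'   deviation calls at the 2-SD threshold, enough for the concordance
#'   Fisher test to resolve p well below 1e-4 for any plausible split of
#'   the latent factor's excursions between up and down.
#' @param bank_size total signatures in the generated drug bank, planted
#'   plus decoys (default 100).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       probes_per_gene = c("1" = 0.7, "2" = 0.15, "3" = 0.15),
                       n_background_series = 10,
                       samples_per_series = 40,
                       replicates_per_arm = 4,
                       noise_sd = 0.25,
                       planted_de = NULL,
                       planted_sets = list(),
                       planted_drugs = NULL,
                       planted_tf_modules = list(),
                       panel_entities = 17,
                       seed = 1,
                       baseline_mean = 8,
                       baseline_sd = 2,
                       background_noise_sd = 0.5,
                       constitutive_frac = 0.02,
                       twin_noise = 0.05,
                       module_loading = 3,
                       module_noise = 0.3,
                       coexpr_series = 25,
                       bank_size = 100) {
  counts <- c(n_genes = n_genes, n_background_series = n_background_series,
              samples_per_series = samples_per_series,
              replicates_per_arm = replicates_per_arm,
              panel_entities = panel_entities, bank_size = bank_size,
              coexpr_series = coexpr_series)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (is.null(names(probes_per_gene)) ||
      any(as.integer(names(probes_per_gene)) < 1) ||
      any(probes_per_gene < 0) ||
      abs(sum(probes_per_gene) - 1) > 1e-8) {
    stop("probes_per_gene must be probabilities named by counts >= 1",
         call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (!is.null(planted_de)) {
    if (!is.data.frame(planted_de) ||
        !all(c("gene", "effect") %in% names(planted_de))) {
      stop("planted_de must have columns `gene` and `effect`", call. = FALSE)
    }
    if (!all(planted_de$gene %in% genes)) {
      stop("planted DE genes absent from the gene universe", call. = FALSE)
    }
    if (anyDuplicated(planted_de$gene)) {
      stop("planted DE genes must be unique", call. = FALSE)
    }
  }
  if (length(planted_sets)) {
    if (is.null(names(planted_sets)) ||
        !all(unlist(planted_sets) %in% genes)) {
      stop("planted sets must be named and drawn from the gene universe",
           call. = FALSE)
    }
  }
  if (!is.null(planted_drugs)) {
    if (!is.data.frame(planted_drugs) ||
        !all(c("drug", "concordance") %in% names(planted_drugs))) {
      stop("planted_drugs must have columns `drug` and `concordance`",
           call. = FALSE)
    }
    if (any(planted_drugs$concordance < 0 | planted_drugs$concordance > 1)) {
      stop("concordance fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  if (length(planted_tf_modules)) {
    members <- c(names(planted_tf_modules), unlist(planted_tf_modules))
    if (is.null(names(planted_tf_modules)) || !all(members %in% genes)) {
      stop("planted TF modules must be named by TF genes in the universe",
           call. = FALSE)
    }
    all_mod <- unlist(lapply(names(planted_tf_modules), function(tf) {
      c(tf, planted_tf_modules[[tf]])
    }))
    if (anyDuplicated(all_mod)) {
      stop("planted TF modules must be disjoint", call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, probes_per_gene = probes_per_gene,
                 n_background_series = n_background_series,
                 samples_per_series = samples_per_series,
                 replicates_per_arm = replicates_per_arm,
                 noise_sd = noise_sd, planted_de = planted_de,
                 planted_sets = planted_sets, planted_drugs = planted_drugs,
                 planted_tf_modules = planted_tf_modules,
                 panel_entities = panel_entities, seed = seed,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 background_noise_sd = background_noise_sd,
                 constitutive_frac = constitutive_frac,
                 twin_noise = twin_noise, module_loading = module_loading,
                 module_noise = module_noise, coexpr_series = coexpr_series,
                 bank_size = bank_size, genes = genes),
            class = "sim_config")
}

# Deterministic probe->gene map shared by the experiment and background
# generators: the number of probes per gene is drawn from the configured
# distribution under the "map" substream.
probe_gene_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "map"))
  counts <- as.integer(names(config$probes_per_gene))
  n_probes <- sample(counts, config$n_genes, replace = TRUE,
                     prob = config$probes_per_gene)
  probe <- unlist(lapply(seq_along(config$genes), function(i) {
    sprintf("%s_p%d", config$genes[i], seq_len(n_probes[i]))
  }))
  data.frame(probe = probe,
             gene = rep(config$genes, n_probes),
             stringsAsFactors = FALSE)
}

#' Generate the treated-versus-control microarray experiment
#'
#' Simulates two cell lines ("core" and "margin"), each with vehicle and
#' treated arms in `replicates_per_arm` replicates on a shared probe
#' universe. Per-probe baselines are drawn per cell line from a broad
#' unimodal log2 distribution; the treated arms shift every probe of a
#' planted differential gene by its stated log2 effect (in both lines);
#' residual noise is additive Gaussian with `noise_sd`.
#'
#' @param config a [sim_config()].
#' @return list with `exprs` (probe x sample matrix), `groups` (named
#'   character vector sample -> `<line>_<arm>`), `map` (probe-gene data
#'   frame) and `truth` (a [truth_record()]).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- probe_gene_map(config)
  set.seed(stage_seed(config$seed, "experiment"))
  P <- nrow(map)
  effect <- stats::setNames(rep(0, config$n_genes), config$genes)
  if (!is.null(config$planted_de)) {
    effect[config$planted_de$gene] <- config$planted_de$effect
  }
  probe_effect <- effect[map$gene]
  reps <- config$replicates_per_arm
  cols <- list()
  groups <- character()
  for (line in c("core", "margin")) {
    mu <- stats::rnorm(P, config$baseline_mean, config$baseline_sd)
    for (arm in c("vehicle", "treated")) {
      shift <- if (arm == "treated") probe_effect else 0
      for (r in seq_len(reps)) {
        nm <- paste(line, arm, r, sep = "_")
        cols[[nm]] <- mu + shift + stats::rnorm(P, 0, config$noise_sd)
        groups[nm] <- paste(line, arm, sep = "_")
      }
    }
  }
  exprs <- do.call(cbind, cols)
  rownames(exprs) <- map$probe
  truth <- truth_record(
    planted_de = if (is.null(config$planted_de)) NULL else
      data.frame(gene = config$planted_de$gene,
                 effect = config$planted_de$effect,
                 direction = ifelse(config$planted_de$effect >= 0,
                                    "up", "down"),
                 stringsAsFactors = FALSE),
    planted_sets = config$planted_sets)
  validate_truth(truth, config)
  list(exprs = exprs, groups = groups, map = map, truth = truth)
}

#' Generate a multi-series background expression compendium
#'
#' Each series has its own per-probe baseline over the shared probe
#' universe, plus within-series Gaussian sample noise. A fixed fraction of
#' probes is forced constitutively high (and another fraction low) across
#' every series, so background mean scaled ranks near 0 and 1 occur.
#'
#' @param config a [sim_config()] with `n_background_series >= 2` and
#'   `samples_per_series >= 2`.
#' @return named list of probe x sample matrices, with attribute
#'   `constitutive` (list of `high` and `low` probe IDs).
#' @export
generate_background_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_background_series < 2) {
    stop("need at least 2 background series", call. = FALSE)
  }
  if (config$samples_per_series < 2) {
    stop("need at least 2 samples per series", call. = FALSE)
  }
  map <- probe_gene_map(config)
  P <- nrow(map)
  set.seed(stage_seed(config$seed, "background"))
  n_const <- round(config$constitutive_frac * P)
  const <- sample.int(P, 2 * n_const)
  high <- map$probe[const[seq_len(n_const)]]
  low <- map$probe[const[n_const + seq_len(n_const)]]
  offset <- numeric(P)
  offset[const[seq_len(n_const)]] <- 6
  offset[const[n_const + seq_len(n_const)]] <- -6
  out <- lapply(seq_len(config$n_background_series), function(s) {
    mu <- stats::rnorm(P, config$baseline_mean, config$baseline_sd) + offset
    m <- mu + matrix(stats::rnorm(P * config$samples_per_series, 0,
                                  config$background_noise_sd),
                     nrow = P)
    dimnames(m) <- list(map$probe,
                        sprintf("s%02d_%02d", s,
                                seq_len(config$samples_per_series)))
    m
  })
  names(out) <- sprintf("series%02d", seq_len(config$n_background_series))
  attr(out, "constitutive") <- list(high = high, low = low)
  out
}

#' Generate a panel of rank profiles with one planted twin
#'
#' Exactly one panel entity is the core gene rank profile plus bounded
#' uniform rank noise (clipped back to \eqn{[-1, 1]}); all other entities
#' are independent uniform random profiles over the same genes. The twin's
#' identity is recorded in the `twin` attribute.
#'
#' @param config a [sim_config()] with `panel_entities >= 2`.
#' @param grp_core named numeric gene rank profile of the core cells.
#' @param grp_margin optional margin profile (no twin is planted for it; it
#'   is accepted so callers can pass both profiles symmetrically).
#' @return named list of rank profiles with attribute `twin` (entity name).
#' @export
generate_panel <- function(config, grp_core, grp_margin = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$panel_entities < 2) {
    stop("need at least 2 panel entities", call. = FALSE)
  }
  assert_named_numeric(grp_core, "grp_core")
  set.seed(stage_seed(config$seed, "panel"))
  n <- length(grp_core)
  entities <- sprintf("entity%02d", seq_len(config$panel_entities))
  twin_idx <- sample.int(config$panel_entities, 1)
  panel <- lapply(seq_len(config$panel_entities), function(i) {
    if (i == twin_idx) {
      prof <- grp_core + stats::runif(n, -config$twin_noise,
                                      config$twin_noise)
      prof <- pmin(pmax(prof, -1), 1)
    } else {
      prof <- stats::runif(n, -1, 1)
    }
    stats::setNames(prof, names(grp_core))
  })
  names(panel) <- entities
  attr(panel, "twin") <- entities[twin_idx]
  panel
}

#' Generate a drug-signature bank with planted concordant drugs
#'
#' Planted drugs share the reference signature's gene span: a fraction
#' `concordance` of the shared genes keeps the reference direction and the
#' rest is flipped. Decoy signatures of matched up/down sizes are drawn
#' uniformly from the gene universe to fill the bank to `bank_size`.
#'
#' @param config a [sim_config()].
#' @param reference non-empty `signed_signature` (e.g. the treated-cell
#'   differential signature).
#' @return a [signature_bank()] with attribute `planted` (data frame of
#'   planted drug names and concordance fractions).
#' @export
generate_signature_bank <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "signed_signature"))
  ref_genes <- c(reference$up, reference$down)
  if (length(ref_genes) == 0) {
    stop("reference signature is empty", call. = FALSE)
  }
  set.seed(stage_seed(config$seed, "bank"))
  sigs <- list()
  planted <- config$planted_drugs
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      n_conc <- round(planted$concordance[i] * length(ref_genes))
      conc <- ref_genes[sample.int(length(ref_genes), n_conc)]
      up <- c(intersect(reference$up, conc),
              setdiff(reference$down, conc))
      down <- c(intersect(reference$down, conc),
                setdiff(reference$up, conc))
      sigs[[planted$drug[i]]] <- signed_signature(up, down,
        meta = list(planted = TRUE, concordance = planted$concordance[i]))
    }
  }
  n_decoys <- config$bank_size - length(sigs)
  for (i in seq_len(max(0, n_decoys))) {
    pick <- sample(config$genes, length(ref_genes))
    sigs[[sprintf("decoy%03d", i)]] <-
      signed_signature(up = pick[seq_along(reference$up)],
                       down = pick[length(reference$up) +
                                     seq_along(reference$down)])
  }
  bank <- signature_bank(sigs, universe = config$n_genes)
  attr(bank, "planted") <- planted
  bank
}

#' Generate a co-expression compendium with planted TF modules
#'
#' Gene-level series in which each planted transcription factor and its
#' module genes load on a shared per-series latent factor (loading
#' `module_loading`, residual SD `module_noise`), while all other genes
#' carry independent unit-SD noise. The first half of each module loads
#' with the transcription factor's sign and the second half against it, so
#' a TF acquires both positively and negatively co-expressed partners (as
#' real regulons do). Deviation calls on this compendium recover the
#' modules as strongly co-expressed partners.
#'
#' @param config a [sim_config()] with non-empty `planted_tf_modules`.
#' @return named list of gene x sample matrices, with attribute
#'   `module_signs`: per TF, a named +1/-1 vector over its module genes.
#' @export
generate_coexpression_compendium <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$planted_tf_modules) == 0) {
    stop("config has no planted TF modules", call. = FALSE)
  }
  set.seed(stage_seed(config$seed, "coexpr"))
  genes <- config$genes
  nG <- length(genes)
  nS <- config$samples_per_series
  module_signs <- lapply(config$planted_tf_modules, function(members) {
    k <- length(members)
    stats::setNames(rep(c(1, -1), c(ceiling(k / 2), floor(k / 2))), members)
  })
  out <- lapply(seq_len(config$coexpr_series), function(s) {
    mu <- stats::rnorm(nG, config$baseline_mean, config$baseline_sd)
    m <- mu + matrix(stats::rnorm(nG * nS), nrow = nG)
    dimnames(m) <- list(genes, sprintf("s%02d_%02d", s, seq_len(nS)))
    for (tf in names(config$planted_tf_modules)) {
      f <- stats::rnorm(nS)
      mod <- c(tf, names(module_signs[[tf]]))
      signs <- c(1, unname(module_signs[[tf]]))
      idx <- match(mod, genes)
      m[idx, ] <- mu[idx] +
        config$module_loading * signs * rep(f, each = length(idx)) +
        matrix(stats::rnorm(length(idx) * nS, 0, config$module_noise),
               nrow = length(idx))
    }
    m
  })
  names(out) <- sprintf("series%02d", seq_len(config$coexpr_series))
  attr(out, "module_signs") <- module_signs
  out
}

#' Assemble a record of planted truths
#'
#' @param planted_de data frame (gene, effect, direction) or NULL.
#' @param planted_sets named list of gene vectors.
#' @param planted_drugs data frame (drug, concordance) or NULL.
#' @param planted_tf_modules named list TF -> module genes.
#' @param panel_twin entity name of the planted panel twin, or NULL.
#' @return list of class `truth_record`.
#' @export
truth_record <- function(planted_de = NULL, planted_sets = list(),
                         planted_drugs = NULL, planted_tf_modules = list(),
                         panel_twin = NULL) {
  structure(list(planted_de = planted_de, planted_sets = planted_sets,
                 planted_drugs = planted_drugs,
                 planted_tf_modules = planted_tf_modules,
                 panel_twin = panel_twin),
            class = "truth_record")
}

# Post-generation consistency check: every planted entity must exist in the
# generated universe.
validate_truth <- function(truth, config) {
  genes <- config$genes
  named <- c(if (!is.null(truth$planted_de)) truth$planted_de$gene,
             unlist(truth$planted_sets),
             names(truth$planted_tf_modules),
             unlist(truth$planted_tf_modules))
  if (!all(named %in% genes)) {
    stop("truth record names genes absent from the generated data",
         call. = FALSE)
  }
  invisible(truth)
}

#' A fully planted demonstration configuration
#'
#' Builds a [sim_config()] whose synthetic data exercise every analysis
#' stage: 60 differential genes with alternating +2/-2 effects, two gene
#' sets split by direction, a near-concordant and a near-discordant drug,
#' and 20 transcription-factor modules of 18 genes each.
#'
#' @param seed integer seed driving every generator stage.
#' @return a [sim_config()] object.
#' @examples
#' cfg <- demo_sim_config(seed = 1)
#' exp <- generate_experiment(cfg)
#' dim(exp$exprs)
#' @export
demo_sim_config <- function(seed = 1) {
  genes <- sprintf("g%04d", 1:2000)
  de_genes <- genes[seq(101, 396, 5)]
  mods <- stats::setNames(
    lapply(0:19, function(i) genes[500 + i * 20 + 1:18]),
    genes[1:20])
  sim_config(
    planted_de = data.frame(gene = de_genes,
                            effect = rep(c(2, -2), 30),
                            stringsAsFactors = FALSE),
    planted_sets = list(up_block = de_genes[seq(1, 60, 2)],
                        down_block = de_genes[seq(2, 60, 2)]),
    planted_drugs = data.frame(drug = c("drugA", "drugB"),
                               concordance = c(0.9, 0.1),
                               stringsAsFactors = FALSE),
    planted_tf_modules = mods,
    seed = seed)
}
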