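# End-to-end orchestration: enumerate -> superpose -> generate -> report,
# driven by a list or YAML run configuration with one global seed.

#' Save / load a trained model
#'
#' Checkpoints include parameters, vocabulary and hyperparameters.
#'
#' @param model A `seq2seq_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model stage: checkpoint not found: ", path)
  m <- readRDS(path)
  if (!inherits(m, "seq2seq_model")) stop("model stage: not a model file")
  m
}

#' Split structure pairs and build model input
#'
#' Pairs are split into train/validation *before* augmentation; each split
#' is then either augmented and aligned (random rooted traversals, gaps
#' removed for the model) or reduced to canonical string pairs.
#'
#' @param pairs List of [structure_pair()] objects.
#' @param val_frac Validation fraction.
#' @param k_augment Augmentation multiplicity (ignored for canonical).
#' @param aligned Use augmented-and-aligned strings (`TRUE`) or canonical
#'   strings (`FALSE`).
#' @param seed Integer seed.
#' @return List with `train` and `val` data frames (`source`, `target`).
#' @export
prepare_training_data <- function(pairs, val_frac = 0.1, k_augment = 5L,
                                  aligned = TRUE, seed = 1L) {
  n <- length(pairs)
  idx <- with_local_seed(seed, sample(n))
  nval <- floor(n * val_frac)
  val_ix <- idx[seq_len(nval)]
  train_ix <- setdiff(idx, val_ix)
  build <- function(px, sd) {
    if (aligned) {
      pairs_to_df(augment_corpus(pairs[px], k_augment, seed = sd))
    } else {
      pairs_to_df(pairs[px])
    }
  }
  list(train = build(train_ix, seed + 1L), val = build(val_ix, seed + 2L))
}

#' Default run configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed propagated to every stochastic stage.
#' @param profile Model profile (`"paper"` or `"test"`).
#' @return Nested configuration list.
#' @export
default_run_config <- function(out_dir = "design_out", seed = 1L,
                               profile = "test") {
  list(
    version = 1L,
    seed = as.integer(seed),
    out_dir = out_dir,
    peptide = list(pdb = NULL, chain = NULL, residues = NULL),
    skeletons = list(source = "toy", smi = NULL, n_conformers = 1L),
    corpus = list(n_pairs = 300L, p_het = 0.2, p_unsat = 0.15),
    pairing = list(k_augment = 5L, val_frac = 0.1),
    model = list(profile = profile, checkpoint = NULL, overrides = NULL),
    sampling = list(n_unique = 100L, temperature = 1.0)
  )
}

.read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config()
  modifyList(base, config)
}

#' Run the two-stage design pipeline
#'
#' Stage 1: a skeleton library (packaged toy pool or a SMILES file) is
#' ranked against the peptide query by attachment-vector superposition.
#' Stage 2: the top-ranked skeleton (or `skeleton_override`) is fed to the
#' trained transformer (loaded from a checkpoint, or trained on a
#' synthetic corpus when none is given), sampling unique decorated
#' scaffolds which are then scored for validity, retention, novelty and
#' synthetic accessibility. All artefacts (ranking table, generated
#' SMILES, report, resolved configuration) are written to the output
#' directory.
#'
#' @param config Configuration list or YAML path (see
#'   [default_run_config()]).
#' @param query Optional [peptide_query()] overriding the `peptide` config
#'   block.
#' @param skeleton_override Optional skeleton name to decorate instead of
#'   the top-ranked one.
#' @param pool Optional named list of [skeleton()] objects overriding the
#'   `skeletons` config block.
#' @return List with `ranking`, `skeleton`, `model`, `samples`, `report`,
#'   `paths`.
#' @export
run_design <- function(config = default_run_config(), query = NULL,
                       skeleton_override = NULL, pool = NULL) {
  cfg <- .read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "resolved_config.yaml"))

  # skeleton library
  pool <- if (!is.null(pool)) {
    pool
  } else if (identical(cfg$skeletons$source, "toy") ||
               is.null(cfg$skeletons$smi)) {
    toy_skeleton_pool()
  } else {
    smi <- utils::read.table(cfg$skeletons$smi, header = FALSE,
                             stringsAsFactors = FALSE)[, 1]
    gs <- parse_smiles_batch(smi)
    ok <- !vapply(gs, is_parse_failure, logical(1))
    stats::setNames(lapply(gs[ok], function(g) {
      skeleton(g, attachment = attachment_pairs(skeleton(g, 0L))[, "core"])
    }), paste0("sk", which(ok)))
  }
  if (length(pool) == 0) stop("skeleton stage: empty library")

  # peptide query
  if (is.null(query)) {
    pep <- cfg$peptide
    if (is.null(pep$pdb)) stop("peptide stage: no query or PDB given")
    query <- load_peptide(pep$pdb, pep$chain, pep$residues)
  }

  ranking <- rank_library(query, pool,
                          n_conformers = cfg$skeletons$n_conformers,
                          seed = cfg$seed)
  if (is.null(ranking)) stop("superposition stage: no skeleton embedded")
  utils::write.table(ranking, file.path(cfg$out_dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top_name <- if (is.null(skeleton_override)) {
    ranking$skeleton[1]
  } else {
    skeleton_override
  }
  top <- pool[[top_name]]
  if (is.null(top)) stop("superposition stage: unknown skeleton ", top_name)

  # model
  training_targets <- character(0)
  if (!is.null(cfg$model$checkpoint)) {
    model <- load_model(cfg$model$checkpoint)
  } else {
    pairs <- synthetic_corpus(cfg$corpus$n_pairs, seed = cfg$seed,
                              skeleton_pool = pool,
                              p_het = cfg$corpus$p_het,
                              p_unsat = cfg$corpus$p_unsat)
    splits <- prepare_training_data(pairs, cfg$pairing$val_frac,
                                    cfg$pairing$k_augment, aligned = TRUE,
                                    seed = cfg$seed)
    hp <- do.call(hyperparams, c(list(cfg$model$profile),
                                 cfg$model$overrides))
    model <- seq2seq_train(splits$train, hp, seed = cfg$seed,
                           val_df = splits$val)
    training_targets <- unique(splits$train$target)
    save_model(model, file.path(cfg$out_dir, "model.rds"))
  }

  src <- canonical_smiles(top$graph)
  samples <- seq2seq_sample(model, src,
                            n_unique = cfg$sampling$n_unique,
                            temperature = cfg$sampling$temperature,
                            seed = cfg$seed)
  writeLines(samples$unique, file.path(cfg$out_dir, "generated.smi"))
  report <- evaluate_generation(samples$raw, samples$graphs, top,
                                training_targets)
  jsonlite::write_json(
    list(skeleton = top_name, source_smiles = src,
         ssd_A2 = ranking$ssd_A2[match(top_name, ranking$skeleton)],
         n_sampled = report$n_sampled, n_unique = report$n_unique,
         validity = report$validity, retention = report$retention,
         novelty = report$novelty, sa_mean = report$sa_mean),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  list(ranking = ranking, skeleton = top, model = model, samples = samples,
       report = report,
       paths = file.path(cfg$out_dir,
                         c("resolved_config.yaml", "ranking.tsv",
                           "generated.smi", "report.json")))
}
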