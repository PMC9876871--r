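# Training-pair construction: target structures are ring frameworks plus
# first-shell substituent atoms extracted from library compounds; source
# structures are their carbonized skeletons. A seeded synthetic-corpus
# generator stands in for external compound libraries.

#' Structure pair
#'
#' @param target `molgraph` scaffold with primary substituents.
#' @param source Carbonized counterpart.
#' @param origin Library identifier or `"synthetic"`.
#' @export
structure_pair <- function(target, source = carbonize(target),
                           origin = "unknown") {
  structure(list(target = target, source = source, origin = origin),
            class = "structure_pair")
}

#' Rejection value for corpus extraction
#' @param reason Reason code.
#' @export
extract_reject <- function(reason) {
  structure(list(reason = reason), class = "extract_reject")
}

#' @rdname extract_reject
#' @param x Object to test.
#' @export
is_extract_reject <- function(x) inherits(x, "extract_reject")

#' Extract a target structure from a library compound
#'
#' Keeps the ring framework (rings plus inter-ring linker atoms, obtained
#' by iteratively pruning terminal atoms) together with the first shell of
#' atoms directly bonded to it, each retaining its original bond order into
#' the framework; everything beyond the first shell is replaced by implicit
#' hydrogens. The largest covalent fragment is used and formal charges are
#' cleared. Compounds that are acyclic, contain rings of more than eight
#' atoms, elements outside C/N/O/S/F/Cl/Br/I, or atoms with more than four
#' heavy-atom neighbours are rejected.
#'
#' @param compound A `molgraph`.
#' @return A `molgraph` target, or an [extract_reject()] value.
#' @export
extract_target <- function(compound) {
  comps <- mol_components(compound)
  g <- if (length(comps) > 1) subgraph_mol(compound, comps[[1]]) else compound
  # neutralize; reject if the neutral form violates valence
  g$charges <- integer(n_atoms(g))
  if (!is.null(validate_molgraph(g))) return(extract_reject("valence"))
  if (!all(g$elements %in% .ELEMENT_WHITELIST)) {
    return(extract_reject("element"))
  }
  n <- n_atoms(g)
  # framework: iteratively prune degree-1 atoms
  keep <- rep(TRUE, n)
  repeat {
    deg <- vapply(seq_len(n), function(i) {
      if (!keep[i]) return(0L)
      b <- g$bonds
      sum(keep[c(b$to[b$from == i], b$from[b$to == i])])
    }, integer(1))
    drop <- keep & deg <= 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  if (!any(keep)) return(extract_reject("acyclic"))
  framework <- which(keep)
  b <- g$bonds
  shell <- setdiff(unique(c(b$to[b$from %in% framework],
                            b$from[b$to %in% framework])), framework)
  atoms <- sort(c(framework, shell))
  inset <- logical(n); inset[atoms] <- TRUE
  infw <- logical(n); infw[framework] <- TRUE
  # bonds: all framework-framework bonds + framework-shell attachment bonds
  bkeep <- (infw[b$from] & infw[b$to]) |
    (infw[b$from] & inset[b$to]) | (inset[b$from] & infw[b$to])
  map <- match(seq_len(n), atoms)
  tgt <- molgraph(g$elements[atoms],
                  data.frame(from = map[b$from[bkeep]], to = map[b$to[bkeep]],
                             order = b$order[bkeep]),
                  validate = FALSE)
  if (!is.null(validate_molgraph(tgt))) return(extract_reject("valence"))
  ri <- ring_info(tgt)
  if (any(ri$sizes > 8)) return(extract_reject("ring_size"))
  if (any(heavy_degree(tgt) > 4)) return(extract_reject("degree"))
  tgt
}

#' Build a structure pair from a target
#'
#' @param target A `molgraph` that passed [extract_target()] filtering.
#' @param origin Origin label.
#' @return A [structure_pair()] whose source is the carbonized target.
#' @export
make_pair <- function(target, origin = "unknown") {
  structure_pair(target, carbonize(target), origin)
}

#' Deduplicate a pair corpus
#'
#' Pairs are keyed jointly on canonical target and canonical source SMILES;
#' output is ordered by canonical target string for determinism.
#'
#' @param pairs List of [structure_pair()] objects.
#' @return Deduplicated list.
#' @export
dedup_corpus <- function(pairs) {
  if (length(pairs) == 0) return(pairs)
  tkeys <- vapply(pairs, function(p) canonical_smiles(p$target), "")
  skeys <- vapply(pairs, function(p) canonical_smiles(p$source), "")
  key <- paste(tkeys, skeys, sep = ">")
  pairs <- pairs[!duplicated(key)]
  pairs[order(tkeys[!duplicated(key)])]
}

#' Synthetic training corpus
#'
#' Emulates library-derived training pairs by decorating all-carbon
#' skeletons: ring and substituent carbons are swapped for N/O/S where
#' valence permits (probability `p_het` per eligible atom) and single bonds
#' promoted to double bonds where both atoms have spare valence
#' (probability `p_unsat` per eligible bond); the source is the carbonized
#' decorated structure, which by construction is isomorphic to the starting
#' skeleton.
#'
#' @param n Number of pairs.
#' @param seed Integer seed; the corpus is reproducible.
#' @param skeleton_pool List of [skeleton()] objects (or bare `molgraph`s)
#'   to decorate; defaults to [toy_skeleton_pool()].
#' @param p_het Per-atom heteroatom substitution probability.
#' @param p_unsat Per-bond unsaturation probability.
#' @return List of [structure_pair()] objects (origin `"synthetic"`).
#' @export
synthetic_corpus <- function(n, seed = 1L, skeleton_pool = toy_skeleton_pool(),
                             p_het = 0.2, p_unsat = 0.15) {
  if (n < 1) stop("n must be >= 1")
  pool <- lapply(skeleton_pool, function(s) {
    if (inherits(s, "skeleton")) s$graph else s
  })
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      g <- pool[[sample.int(length(pool), 1)]]
      tgt <- decorate_skeleton(g, p_het, p_unsat)
      structure_pair(tgt, carbonize(tgt), origin = "synthetic")
    })
  })
}

# one random decoration of an all-carbon single-bond graph; uses the
# current RNG stream
decorate_skeleton <- function(g, p_het = 0.2, p_unsat = 0.15) {
  n <- n_atoms(g)
  deg <- heavy_degree(g)
  elements <- g$elements
  for (i in seq_len(n)) {
    if (stats::runif(1) < p_het) {
      opts <- c("N", "O", "S")[c(deg[i] <= 3, deg[i] <= 2, deg[i] <= 2)]
      if (length(opts) > 0) elements[i] <- opts[sample.int(length(opts), 1)]
    }
  }
  out <- molgraph(elements, g$bonds, validate = FALSE)
  # promote single bonds to double where both ends have spare valence
  bidx <- sample(seq_len(nrow(out$bonds)))
  for (bi in bidx) {
    if (stats::runif(1) >= p_unsat) next
    cand <- out$bonds
    cand$order[bi] <- 2L
    g2 <- out; g2$bonds <- cand
    if (all(implicit_hydrogens(g2) >= 0)) out <- g2
  }
  out
}

#' Packaged toy skeleton pool
#'
#' A small built-in set of bridged tri-/tetracyclic skeletons with three
#' methyl attachment points, used as default input for the synthetic-corpus
#' generator and in examples. Built by running the enumerator on the
#' norbornane and bicyclo\[2.2.2\]octane seeds at reduced scale.
#'
#' @param n_cores Number of distinct ring-system cores to decorate.
#' @param per_core Skeletons kept per core.
#' @return Named list of [skeleton()] objects.
#' @export
toy_skeleton_pool <- function(n_cores = 12L, per_core = 3L) {
  cache_key <- paste0("pool_", n_cores, "_", per_core)
  if (!is.null(.scaffmime_cache[[cache_key]])) {
    return(.scaffmime_cache[[cache_key]])
  }
  cfg <- enum_config(seed_smiles = .DEFAULT_SEEDS[c(
    "bicyclo[2.2.1]heptane", "bicyclo[2.2.2]octane")],
    carbon_min = 10L, carbon_max = 11L)
  recs <- enumerate_ring_systems(cfg)
  recs <- recs[seq_len(min(n_cores, length(recs)))]
  out <- list()
  for (r in recs) {
    sks <- place_substituents(r$graph, cfg)
    sks <- sks[seq_len(min(per_core, length(sks)))]
    for (k in seq_along(sks)) {
      sks[[k]]$provenance <- list(seed = r$seed, m = r$m, n = r$n)
    }
    out <- c(out, sks)
  }
  names(out) <- paste0("sk", seq_along(out))
  .scaffmime_cache[[cache_key]] <- out
  out
}

.scaffmime_cache <- new.env(parent = emptyenv())

#' Write / read a pair corpus as TSV
#'
#' Columns: `source_smiles`, `target_smiles`, `origin`.
#'
#' @param pairs List of [structure_pair()] objects.
#' @param path Output path.
#' @export
write_corpus_tsv <- function(pairs, path) {
  df <- data.frame(
    source_smiles = vapply(pairs, function(p) canonical_smiles(p$source), ""),
    target_smiles = vapply(pairs, function(p) canonical_smiles(p$target), ""),
    origin = vapply(pairs, function(p) p$origin, "")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    structure_pair(parse_smiles(df$target_smiles[i]),
                   parse_smiles(df$source_smiles[i]), df$origin[i])
  })
}
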