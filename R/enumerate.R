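# Stage 1 database construction: exhaustive generation of bridged tri- and
# tetracyclic all-carbon ring systems from bicyclic seeds, strain filtering,
# and methyl attachment-point decoration.

# Default bicyclic seeds: the fused and bridged bicyclics assembled from 5-
# and/or 6-membered rings. Seed 1 is the eight-carbon fused 5-5 system.
.DEFAULT_SEEDS <- c(
  "bicyclo[3.3.0]octane" = "C1CCC2CCCC12",
  "bicyclo[4.3.0]nonane" = "C1CCC2CCCCC12",
  "bicyclo[4.4.0]decane" = "C1CCC2CCCCC2C1",
  "bicyclo[2.2.1]heptane" = "C1CC2CCC1C2",
  "bicyclo[2.2.2]octane" = "C1CC2CCC1CC2",
  "bicyclo[3.2.1]octane" = "C1CCC2CCC1C2"
)

#' Enumeration configuration
#'
#' Parameters of the ring-system enumerator and skeleton builder.
#'
#' @param seed_smiles Named character vector of bicyclic seed SMILES.
#' @param carbon_min,carbon_max Allowed carbon count of final systems.
#' @param ring_size_whitelist Allowed SSSR ring sizes of final systems, or
#'   `NULL` to disable the filter.
#' @param require_bridged Keep only systems containing a bridged (not purely
#'   edge-fused) ring arrangement.
#' @param allow_spiro Fragment closures onto a single ring atom (forming a
#'   spiro ring): `"none"`, `"tetracyclic"` (second extension stage only,
#'   the default) or `"both"`.
#' @param allow_zero_atom_bridge Allow fragments of zero atoms (a direct
#'   bond between two ring atoms).
#' @param energy_threshold Strain-energy cutoff in kcal/mol for
#'   [strain_filter()].
#' @param n_conformers Conformers attempted per system during embedding.
#' @param substituent_count Number of methyl attachment points.
#' @param max_quaternary Maximum quaternary carbons per skeleton.
#' @param seed RNG seed propagated to stochastic steps.
#' @return A list of class `enum_config`.
#' @export
enum_config <- function(seed_smiles = .DEFAULT_SEEDS,
                        carbon_min = 10L, carbon_max = 14L,
                        ring_size_whitelist = c(5L, 6L),
                        require_bridged = TRUE,
                        allow_spiro = c("tetracyclic", "none", "both"),
                        allow_zero_atom_bridge = FALSE,
                        energy_threshold = 100,
                        n_conformers = 1L,
                        substituent_count = 3L,
                        max_quaternary = 1L,
                        seed = 20221203L) {
  stopifnot(carbon_min <= carbon_max, energy_threshold > 0)
  allow_spiro <- match.arg(allow_spiro)
  structure(list(seed_smiles = seed_smiles, carbon_min = as.integer(carbon_min),
                 carbon_max = as.integer(carbon_max),
                 ring_size_whitelist = ring_size_whitelist,
                 require_bridged = isTRUE(require_bridged),
                 allow_spiro = allow_spiro,
                 allow_zero_atom_bridge = isTRUE(allow_zero_atom_bridge),
                 energy_threshold = energy_threshold,
                 n_conformers = as.integer(n_conformers),
                 substituent_count = as.integer(substituent_count),
                 max_quaternary = as.integer(max_quaternary),
                 seed = as.integer(seed)),
            class = "enum_config")
}

#' Bicyclic seed systems
#'
#' @param config An [enum_config()].
#' @return Named list of all-carbon `molgraph` seeds.
#' @export
bicyclic_seeds <- function(config = enum_config()) {
  out <- parse_smiles_batch(unname(config$seed_smiles))
  names(out) <- names(config$seed_smiles)
  for (i in seq_along(out)) {
    if (is_parse_failure(out[[i]])) stop("seed ", i, " failed to parse")
  }
  out
}

#' Fragment-size combinations
#'
#' All `(m, n)` fragment carbon-count pairs taking a seed of
#' `base_carbons` atoms to a final system inside the configured carbon
#' range. `n = 0` means the product stays tricyclic (no fourth ring).
#'
#' @param base_carbons Carbon count of the seed.
#' @param config An [enum_config()].
#' @return Data frame with columns `m` and `n`.
#' @export
mn_combinations <- function(base_carbons, config = enum_config()) {
  stopifnot(base_carbons >= 5)
  m_lo <- if (config$allow_zero_atom_bridge) 0L else 1L
  res <- expand.grid(m = m_lo:max(m_lo, config$carbon_max - base_carbons),
                     n = 0L:max(0L, config$carbon_max - base_carbons))
  tot <- base_carbons + res$m + res$n
  res <- res[tot >= config$carbon_min & tot <= config$carbon_max, ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# fast canonical key for connected all-carbon single-bond graphs
.plain_key <- function(n, edges) {
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, t(edges))
  lab <- igraph::canonical_permutation(ig)$labeling
  e2 <- cbind(lab[edges[, 1]], lab[edges[, 2]])
  e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
  paste0(n, ":", paste(e2[, 1], e2[, 2], sep = "-", collapse = ","))
}

mol_edges <- function(g) cbind(g$bonds$from, g$bonds$to)

#' Bridge extension
#'
#' Attaches a path of `k` new carbon atoms between every valence-compatible
#' unordered pair of distinct ring atoms of an all-carbon ring system,
#' creating one additional ring per product. With `spiro = TRUE` both
#' fragment ends may also close onto the same ring atom, forming a spiro
#' ring of `k + 1` atoms. Products are deduplicated by canonical graph key.
#'
#' @param g All-carbon single-bond `molgraph`.
#' @param k Number of fragment carbons (`k = 0` adds a direct bond and is
#'   only allowed when `allow_zero` is `TRUE`).
#' @param allow_zero Permit zero-atom bridges.
#' @param spiro Also attach fragments to single atoms (spiro closure).
#' @return Named list of product `molgraph`s keyed by canonical key.
#' @export
bridge_extend <- function(g, k, allow_zero = FALSE, spiro = FALSE) {
  if (k < 0) stop("fragment size k must be >= 0")
  if (k == 0 && !allow_zero) return(list())
  n <- n_atoms(g)
  edges <- mol_edges(g)
  deg <- tabulate(edges, n)
  adjset <- matrix(FALSE, n, n)
  adjset[edges] <- TRUE
  adjset[edges[, 2:1, drop = FALSE]] <- TRUE
  out <- list()
  add <- function(e2, n2) {
    key <- .plain_key(n2, e2)
    if (is.null(out[[key]])) {
      out[[key]] <<- molgraph(rep("C", n2),
                              data.frame(from = e2[, 1], to = e2[, 2],
                                         order = 1L),
                              validate = FALSE)
    }
  }
  for (u in seq_len(n - 1)) {
    if (deg[u] >= 4) next
    for (v in (u + 1):n) {
      if (deg[v] >= 4) next
      if (k == 0 && adjset[u, v]) next
      if (k == 0) {
        add(rbind(edges, c(u, v)), n)
      } else {
        newv <- n + seq_len(k)
        add(rbind(edges, cbind(c(u, newv), c(newv, v))), n + k)
      }
    }
  }
  if (spiro && k >= 2) {
    for (u in seq_len(n)) {
      if (deg[u] > 2) next  # spiro closure uses two valences of one atom
      newv <- n + seq_len(k)
      add(rbind(edges, cbind(c(u, newv), c(newv, u))), n + k)
    }
  }
  out
}

#' Bridged ring-arrangement test
#'
#' A polycyclic system counts as bridged when some atom pair is joined by at
#' least three internally vertex-disjoint paths each passing through at
#' least one intermediate atom; purely edge-fused (and spiro) systems fail
#' this.
#'
#' @param g A `molgraph`.
#' @return Logical.
#' @export
is_bridged <- function(g) {
  n <- n_atoms(g)
  ig <- mol_igraph(g)
  deg <- igraph::degree(ig)
  hubs <- which(deg >= 3)
  if (length(hubs) < 2) return(FALSE)
  for (a in seq_along(hubs)[-length(hubs)]) {
    for (b in (a + 1):length(hubs)) {
      u <- hubs[a]; v <- hubs[b]
      g2 <- ig
      eid <- igraph::get_edge_ids(ig, c(u, v))
      if (eid > 0) g2 <- igraph::delete_edges(ig, eid)
      k <- tryCatch(igraph::vertex_connectivity(g2, source = u, target = v),
                    error = function(e) 0L)
      if (k >= 3) return(TRUE)
    }
  }
  FALSE
}

#' Enumerate bridged tri-/tetracyclic carbon ring systems
#'
#' From every bicyclic seed, tricyclic systems are generated by attaching
#' fragments of `m` carbons between all ring-atom pairs; tetracyclic
#' systems by a second fragment of `n` carbons applied to the tricyclic
#' intermediates (including atoms introduced by the first fragment, which
#' are by then ring atoms). Products are globally deduplicated by canonical
#' graph key across seeds and annotated with SSSR ring sizes and the
#' bridged-arrangement flag; the configured ring-size and bridged filters
#' are then applied unless `keep_all` is set.
#'
#' @param config An [enum_config()].
#' @param keep_all Return all candidates with annotation columns instead of
#'   applying the ring-size/bridged filters.
#' @param progress Print progress.
#' @return A list of records, each with elements `graph`, `key`, `seed`,
#'   `m`, `n`, `carbons`, `ring_sizes`, `ring_ok`, `bridged`,
#'   `cyclomatic`.
#' @export
enumerate_ring_systems <- function(config = enum_config(), keep_all = FALSE,
                                   progress = FALSE) {
  seeds <- bicyclic_seeds(config)
  az <- config$allow_zero_atom_bridge
  spiro_tri <- config$allow_spiro == "both"
  spiro_tet <- config$allow_spiro %in% c("both", "tetracyclic")
  m_lo <- if (az) 0L else 1L
  tri <- new.env(parent = emptyenv())   # key -> record
  for (si in seq_along(seeds)) {
    s <- seeds[[si]]
    b <- n_atoms(s)
    m_hi <- config$carbon_max - b
    if (m_hi < m_lo) next
    for (m in m_lo:m_hi) {
      prods <- bridge_extend(s, m, allow_zero = az, spiro = spiro_tri)
      for (key in names(prods)) {
        if (is.null(tri[[key]])) {
          tri[[key]] <- list(graph = prods[[key]], key = key,
                             seed = names(seeds)[si], m = m, n = 0L,
                             carbons = b + m)
        }
      }
    }
    if (progress) message("seed ", names(seeds)[si], ": ",
                          length(ls(tri)), " unique tricyclic systems")
  }
  tet <- new.env(parent = emptyenv())
  for (key in ls(tri)) {
    t <- tri[[key]]
    s <- t$carbons
    n_lo <- max(if (az) 0L else 1L, config$carbon_min - s)
    n_hi <- config$carbon_max - s
    if (n_hi < n_lo) next
    for (nn in n_lo:n_hi) {
      prods <- bridge_extend(t$graph, nn, allow_zero = az,
                             spiro = spiro_tet)
      for (k2 in names(prods)) {
        if (is.null(tet[[k2]])) {
          tet[[k2]] <- list(graph = prods[[k2]], key = k2, seed = t$seed,
                            m = t$m, n = nn, carbons = s + nn)
        }
      }
    }
  }
  if (progress) message(length(ls(tet)), " unique tetracyclic systems")
  tri <- as.list(tri)
  tet <- as.list(tet)
  tri_final <- Filter(function(t) t$carbons >= config$carbon_min &&
                        t$carbons <= config$carbon_max, tri)
  recs <- c(tri_final, tet[setdiff(names(tet), names(tri_final))])
  recs <- lapply(recs, function(r) {
    ri <- ring_info(r$graph)
    r$ring_sizes <- ri$sizes
    r$ring_ok <- is.null(config$ring_size_whitelist) ||
      all(ri$sizes %in% config$ring_size_whitelist)
    r$bridged <- is_bridged(r$graph)
    r$cyclomatic <- nrow(r$graph$bonds) - n_atoms(r$graph) + 1L
    r
  })
  if (!keep_all) {
    recs <- Filter(function(r) r$ring_ok &&
                     (!config$require_bridged || r$bridged), recs)
  }
  recs
}

#' Enumeration counts under alternative conventions
#'
#' The qualifying scaffold definition leaves several conventions open:
#' whether fragment closures onto a single atom (spiro rings) are
#' permitted and at which stage, whether zero-atom bridges are allowed,
#' whether the 5-/6-ring whitelist applies to final products, and whether
#' purely fused products are discarded. This reports the unique-system
#' count under every combination so the convention matching a reference
#' count is identifiable. Each spiro/zero-bridge setting requires a full
#' re-enumeration; expect several minutes per row group on one CPU.
#'
#' @param config Base [enum_config()]; the convention flags are swept.
#' @param include_zero_bridge Also sweep `allow_zero_atom_bridge = TRUE`
#'   (doubles the enumeration work).
#' @return Data frame with the flag combination and resulting count.
#' @export
convention_sweep <- function(config = enum_config(),
                             include_zero_bridge = FALSE) {
  res <- NULL
  az_values <- if (include_zero_bridge) c(FALSE, TRUE) else FALSE
  for (spiro in c("none", "tetracyclic", "both")) {
    for (az in az_values) {
      cfg <- config
      cfg$allow_spiro <- spiro
      cfg$allow_zero_atom_bridge <- az
      recs <- enumerate_ring_systems(cfg, keep_all = TRUE)
      ring_ok <- vapply(recs, function(r)
        is.null(config$ring_size_whitelist) ||
          all(r$ring_sizes %in% config$ring_size_whitelist), logical(1))
      bridged <- vapply(recs, `[[`, logical(1), "bridged")
      for (rw in c(TRUE, FALSE)) {
        for (br in c(TRUE, FALSE)) {
          keep <- (!rw | ring_ok) & (!br | bridged)
          res <- rbind(res, data.frame(allow_spiro = spiro,
                                       allow_zero_atom_bridge = az,
                                       ring_size_whitelist = rw,
                                       require_bridged = br,
                                       count = sum(keep)))
        }
      }
    }
  }
  res
}

#' Add methyl attachment points to a carbon core
#'
#' Enumerates all multisets of `substituent_count` methyl placements on the
#' atoms of an all-carbon ring system (geminal placements allowed), keeping
#' results with at most `max_quaternary` quaternary carbons and valid
#' carbon valence, deduplicated by canonical key so symmetry-equivalent
#' placements collapse.
#'
#' @param core All-carbon single-bond `molgraph`.
#' @param config An [enum_config()].
#' @return Named list of [skeleton] objects keyed by canonical key.
#' @export
place_substituents <- function(core, config = enum_config()) {
  n <- n_atoms(core)
  edges <- mol_edges(core)
  deg <- tabulate(edges, n)
  ns <- config$substituent_count
  combos <- utils::combn(n + ns - 1, ns)  # multisets via stars-and-bars
  out <- list()
  for (j in seq_len(ncol(combos))) {
    pos <- combos[, j] - seq_len(ns) + 1L   # sorted multiset of atom indices
    mult <- tabulate(pos, n)
    newdeg <- deg + mult
    if (any(newdeg > 4)) next
    if (sum(newdeg == 4) > config$max_quaternary) next
    methyls <- n + seq_len(ns)
    e2 <- rbind(edges, cbind(pos, methyls))
    g2 <- molgraph(rep("C", n + ns),
                   data.frame(from = e2[, 1], to = e2[, 2], order = 1L),
                   validate = FALSE)
    key <- .plain_key(n + ns, e2)
    if (is.null(out[[key]])) {
      out[[key]] <- skeleton(g2, attachment = unique(pos))
    }
  }
  out
}

#' Skeleton object
#'
#' An all-carbon, all-single-bond ring system decorated with terminal
#' methyls marking attachment positions.
#'
#' @param graph All-carbon `molgraph` including the methyl carbons.
#' @param attachment Core atom indices bearing the methyls.
#' @param provenance Optional list (seed id, m, n).
#' @export
skeleton <- function(graph, attachment, provenance = NULL) {
  structure(list(graph = graph, attachment = as.integer(attachment),
                 provenance = provenance),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton: %d C, attachments at %s>\n", n_atoms(x$graph),
              paste(x$attachment, collapse = ",")))
  invisible(x)
}

#' Methyl attachment pairs of a skeleton
#'
#' @param sk A [skeleton()].
#' @return Two-column matrix (core atom, methyl atom), one row per
#'   attachment point.
#' @export
attachment_pairs <- function(sk) {
  g <- sk$graph
  deg <- heavy_degree(g)
  methyls <- which(deg == 1)
  core <- vapply(methyls, function(mm) {
    b <- g$bonds
    nb <- c(b$to[b$from == mm], b$from[b$to == mm])
    nb[1]
  }, integer(1))
  cbind(core = core, methyl = methyls)
}
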