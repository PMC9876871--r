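# Shared fixtures and independent oracles used across the suite.

# pairwise-isomorphism deduplication oracle (quadratic VF2, independent of
# the canonical-key route used by the implementation)
dedup_by_vf2 <- function(graphs) {
  keep <- list()
  for (g in graphs) {
    dup <- FALSE
    for (h in keep) {
      if (mol_isomorphic(g, h)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep[[length(keep) + 1]] <- g
  }
  keep
}

# brute-force bridge products: all atom pairs, no dedup shortcut
brute_bridge_products <- function(g, k) {
  n <- n_atoms(g)
  deg <- heavy_degree(g)
  out <- list()
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (deg[u] >= 4 || deg[v] >= 4) next
      newv <- n + seq_len(k)
      e <- rbind(cbind(g$bonds$from, g$bonds$to),
                 cbind(c(u, newv), c(newv, v)))
      out[[length(out) + 1]] <- molgraph(rep("C", n + k),
                                         data.frame(from = e[, 1],
                                                    to = e[, 2], order = 1L),
                                         validate = FALSE)
    }
  }
  out
}

# brute-force methyl placement: all multisets, valence+quaternary filter,
# VF2 dedup
brute_substituted <- function(core, ns = 3L, max_quaternary = 1L) {
  n <- n_atoms(core)
  deg <- heavy_degree(core)
  out <- list()
  grid <- expand.grid(rep(list(seq_len(n)), ns))
  grid <- grid[apply(grid, 1, function(r) all(diff(sort(r)) >= 0)) |
                 TRUE, , drop = FALSE]  # keep all; dedup handles symmetry
  seen <- character(0)
  for (i in seq_len(nrow(grid))) {
    pos <- sort(as.integer(grid[i, ]))
    key <- paste(pos, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    mult <- tabulate(pos, n)
    nd <- deg + mult
    if (any(nd > 4) || sum(nd == 4) > max_quaternary) next
    methyls <- n + seq_len(ns)
    e <- rbind(cbind(core$bonds$from, core$bonds$to), cbind(pos, methyls))
    out[[length(out) + 1]] <- molgraph(rep("C", n + ns),
                                       data.frame(from = e[, 1], to = e[, 2],
                                                  order = 1L),
                                       validate = FALSE)
  }
  dedup_by_vf2(out)
}

# hierarchical rotation-grid SSD oracle: global scan refined to the stated
# angular resolution around the best cell
grid_ssd_oracle <- function(P, Q, final_step_deg = 0.1) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cc <- cos(c); sc <- sin(c)
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
    Rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  ssd_at <- function(a, b, c) sum((P0 %*% t(rot(a, b, c)) - Q0)^2)
  best <- c(0, 0, 0); best_val <- Inf
  step <- 15 * pi / 180
  for (a in seq(0, 2 * pi - step, by = step)) {
    for (b in seq(0, pi, by = step)) {
      for (c in seq(0, 2 * pi - step, by = step)) {
        v <- ssd_at(a, b, c)
        if (v < best_val) {
          best_val <- v
          best <- c(a, b, c)
        }
      }
    }
  }
  while (step > final_step_deg * pi / 180 / 2) {
    step <- step / 3
    rng <- seq(-3 * step, 3 * step, by = step)
    for (da in rng) for (db in rng) for (dc in rng) {
      v <- ssd_at(best[1] + da, best[2] + db, best[3] + dc)
      if (v < best_val) {
        best_val <- v
        best <- best + c(da, db, dc)
      }
    }
  }
  best_val
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# small fixed skeleton pool shared across tests (built once per session)
test_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- toy_skeleton_pool()
    pool
  }
})

# full default-convention enumeration, annotated, computed once per session
# (shared by the database-size check and the generative-model corpus)
enum_candidates_cached <- local({
  recs <- NULL
  function() {
    if (is.null(recs)) {
      recs <<- enumerate_ring_systems(enum_config(), keep_all = TRUE)
    }
    recs
  }
})

# skeleton pools for the generative experiment: corpus skeletons from the
# first cores of the enumerated database, held-out skeletons from later,
# disjoint cores
acceptance_pools <- function() {
  recs <- enum_candidates_cached()
  keep <- Filter(function(r) r$ring_ok && r$bridged, recs)
  cfg <- enum_config()
  mk <- function(core_idx, per_core) {
    out <- list()
    for (i in core_idx) {
      sks <- place_substituents(keep[[i]]$graph, cfg)
      out <- c(out, sks[seq_len(min(per_core, length(sks)))])
    }
    stats::setNames(out, paste0("sk", seq_along(out)))
  }
  pool <- mk(1:100, 21L)
  held <- mk(101:115, 2L)
  stopifnot(length(held) >= 20L)
  list(pool = pool, held = held[1:20])
}

# a synthetic three-residue PDB written in code
write_test_pdb <- function(path, ca, cb, resid = c("ALA", "LEU", "SER")) {
  lines <- character(0)
  serial <- 1L
  for (i in 1:3) {
    for (at in c("CA", "CB")) {
      xyz <- if (at == "CA") ca[i, ] else cb[i, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, at, resid[i], i, xyz[1], xyz[2], xyz[3]))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
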