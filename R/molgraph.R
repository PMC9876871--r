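#' @useDynLib scaffmime, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ChemmineR atomblock bondblock
#' @importFrom methods as
NULL

# Standard valences used for implicit-hydrogen assignment and validity checks.
# Multiple entries = allowed valence states (smallest consistent one is used).
.VALENCES <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6),
  Se = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1
)

# Elements admitted into training targets.
.ELEMENT_WHITELIST <- c("C", "N", "O", "S", "F", "Cl", "Br", "I")

#' Construct a molecular graph
#'
#' A `molgraph` is an element-labelled undirected graph with integer bond
#' orders (1, 2, 3; aromatic systems are kekulized on input so no aromatic
#' bond order is stored). Hydrogens are implicit and derived from standard
#' valences.
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Data frame (or 3-column matrix) with columns `from`, `to`,
#'   `order`; atom indices are 1-based.
#' @param charges Integer vector of formal charges (default all zero).
#' @param validate Check valences and connectivity-consistency on
#'   construction.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(elements, bonds = NULL, charges = NULL, validate = TRUE) {
  n <- length(elements)
  if (n == 0L) stop("molgraph needs at least one atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("from", "to", "order")
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    bonds$order <- as.integer(bonds$order)
  }
  if (is.null(charges)) charges <- integer(n)
  g <- structure(
    list(elements = as.character(elements),
         charges = as.integer(charges),
         bonds = bonds),
    class = "molgraph"
  )
  if (validate) {
    bad <- validate_molgraph(g)
    if (!is.null(bad)) stop("invalid molgraph: ", bad)
  }
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms (%s), %d bonds>\n",
              n_atoms(x), paste(unique(x$elements), collapse = ","),
              nrow(x$bonds)))
  invisible(x)
}

#' Number of heavy atoms
#' @param g A `molgraph`.
#' @export
n_atoms <- function(g) length(g$elements)

# returns NULL if fine, else a reason string
validate_molgraph <- function(g) {
  n <- n_atoms(g)
  b <- g$bonds
  if (nrow(b) > 0) {
    if (any(b$from < 1 | b$from > n | b$to < 1 | b$to > n)) {
      return("bond index out of range")
    }
    if (any(b$from == b$to)) return("self-bond")
    key <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
    if (anyDuplicated(key)) return("duplicate bond")
    if (!all(b$order %in% 1:3)) return("bond order outside 1..3")
  }
  if (any(is.na(match(g$elements, names(.VALENCES))))) {
    return(paste("unsupported element:",
                 paste(setdiff(g$elements, names(.VALENCES)), collapse = ",")))
  }
  if (any(implicit_hydrogens(g) < 0)) return("valence exceeded")
  NULL
}

# Sum of bond orders incident to each atom.
bond_order_sum <- function(g) {
  n <- n_atoms(g)
  b <- g$bonds
  if (nrow(b) == 0) return(numeric(n))
  as.numeric(vapply(seq_len(n), function(i) {
    sum(b$order[b$from == i]) + sum(b$order[b$to == i])
  }, numeric(1)))
}

# Heavy-atom degree (number of neighbours).
heavy_degree <- function(g) {
  n <- n_atoms(g)
  tabulate(c(g$bonds$from, g$bonds$to), n)
}

#' Implicit hydrogen counts
#'
#' Chooses the smallest standard valence state consistent with the bond
#' order sum; formal charge shifts the effective valence by its sign for
#' N/O/S-type centres (e.g. `[N+]` has valence 4, `[O-]` has valence 1).
#'
#' @param g A `molgraph`.
#' @return Integer vector; negative entries flag valence violations.
#' @export
implicit_hydrogens <- function(g) {
  bos <- bond_order_sum(g)
  vapply(seq_len(n_atoms(g)), function(i) {
    v <- .VALENCES[[g$elements[i]]] + g$charges[i]
    v <- v[v >= bos[i]]
    if (length(v) == 0L) return(-1L)
    as.integer(min(v) - bos[i])
  }, integer(1))
}

# adjacency list: for each atom a data.frame(nbr, order)
adjacency <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$from[i]]] <- rbind(adj[[b$from[i]]], c(b$to[i], b$order[i]))
    adj[[b$to[i]]] <- rbind(adj[[b$to[i]]], c(b$from[i], b$order[i]))
  }
  adj
}

mol_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n_atoms(g), directed = FALSE)
  if (nrow(g$bonds) > 0) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$from, g$bonds$to))
  }
  ig
}

is_connected_mol <- function(g) {
  igraph::is_connected(mol_igraph(g))
}

# connected components as list of atom index vectors, largest first
mol_components <- function(g) {
  cmp <- igraph::components(mol_igraph(g))
  idx <- split(seq_len(n_atoms(g)), cmp$membership)
  idx[order(-vapply(idx, length, integer(1)))]
}

# induced subgraph on a set of atoms (preserves relative order)
subgraph_mol <- function(g, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  map <- match(seq_len(n_atoms(g)), atoms)
  b <- g$bonds
  keep <- !is.na(map[b$from]) & !is.na(map[b$to])
  molgraph(g$elements[atoms],
           data.frame(from = map[b$from[keep]], to = map[b$to[keep]],
                      order = b$order[keep]),
           charges = g$charges[atoms], validate = FALSE)
}

#' Carbonize a molecular graph
#'
#' Reduces a structure to its cyclic-skeleton form: every heteroatom is
#' replaced by carbon, every bond order is set to 1, and formal charges are
#' cleared. Atom count and connectivity are unchanged; implicit hydrogens
#' follow from carbon valence.
#'
#' @param g A `molgraph`.
#' @return The carbonized `molgraph`.
#' @export
carbonize <- function(g) {
  b <- g$bonds
  b$order <- rep(1L, nrow(b))
  out <- molgraph(rep("C", n_atoms(g)), b, validate = FALSE)
  bad <- validate_molgraph(out)
  if (!is.null(bad)) stop("carbonization produced an invalid graph: ", bad)
  out
}

#' Smallest set of smallest rings
#'
#' Computes a minimum cycle basis (SSSR) by collecting, for every bond, the
#' shortest cycle through it and greedily selecting a GF(2)-independent set
#' in increasing length order.
#'
#' @param g A `molgraph`.
#' @return A list with `sizes` (sorted integer ring sizes), `ring_atoms`
#'   (logical per atom) and `rings` (list of atom index vectors).
#' @export
ring_info <- function(g) {
  n <- n_atoms(g)
  ig <- mol_igraph(g)
  m <- igraph::ecount(ig)
  ncomp <- igraph::components(ig)$no
  nc <- m - n + ncomp
  ring_atoms <- rep(FALSE, n)
  if (nc <= 0) return(list(sizes = integer(0), ring_atoms = ring_atoms,
                           rings = list()))
  cand <- list()
  for (i in seq_len(m)) {
    ee <- igraph::ends(ig, i)
    g2 <- igraph::delete_edges(ig, i)
    sp <- suppressWarnings(igraph::shortest_paths(g2, ee[1], ee[2]))$vpath[[1]]
    if (length(sp) > 0) {
      vs <- as.integer(sp)
      es <- sort(c(i, igraph::get_edge_ids(ig, rbind(vs[-length(vs)], vs[-1]))))
      cand[[length(cand) + 1]] <- list(edges = es, atoms = vs)
    }
  }
  if (length(cand) == 0) return(list(sizes = integer(0),
                                     ring_atoms = ring_atoms, rings = list()))
  keys <- vapply(cand, function(x) paste(x$edges, collapse = ","), "")
  cand <- cand[!duplicated(keys)]
  lens <- vapply(cand, function(x) length(x$edges), integer(1))
  ord <- order(lens)
  basis <- matrix(0L, 0, m)
  rings <- list()
  for (ci in ord) {
    v <- integer(m); v[cand[[ci]]$edges] <- 1L
    r <- v
    if (nrow(basis) > 0) {
      for (j in seq_len(nrow(basis))) {
        piv <- which(basis[j, ] == 1L)[1]
        if (r[piv] == 1L) r <- (r + basis[j, ]) %% 2L
      }
    }
    if (any(r == 1L)) {
      basis <- rbind(basis, r)
      rings[[length(rings) + 1]] <- cand[[ci]]$atoms
    }
    if (length(rings) == nc) break
  }
  for (rg in rings) ring_atoms[rg] <- TRUE
  list(sizes = sort(vapply(rings, length, integer(1))),
       ring_atoms = ring_atoms, rings = rings)
}

# ---- canonical keys and isomorphism ----------------------------------------

# Fixed global colour codes so canonical forms are comparable across graphs.
.atom_color <- function(elements, charges) {
  ei <- match(elements, names(.VALENCES))
  as.integer(ei * 10L + (charges + 4L))
}
.bond_color <- function(order) as.integer(1000L + order)

# Augmented coloured graph: every bond is subdivided by a dummy vertex
# carrying the bond order as its colour, so that BLISS (vertex colours only)
# canonicalizes the edge-labelled graph.
.aug_igraph <- function(g) {
  n <- n_atoms(g)
  nb <- nrow(g$bonds)
  colors <- .atom_color(g$elements, g$charges)
  if (nb == 0) {
    return(list(ig = igraph::make_empty_graph(n, directed = FALSE),
                colors = colors, n = n))
  }
  dummy <- n + seq_len(nb)
  edges <- rbind(cbind(g$bonds$from, dummy), cbind(dummy, g$bonds$to))
  ig <- igraph::make_empty_graph(n + nb, directed = FALSE)
  ig <- igraph::add_edges(ig, t(edges))
  list(ig = ig, colors = c(colors, .bond_color(g$bonds$order)), n = n)
}

#' Canonical atom ranks
#'
#' Isomorphism-invariant atom ordering via BLISS canonical labelling on a
#' bond-subdivided, colour-augmented graph.
#'
#' @param g A `molgraph`.
#' @return Integer vector: rank of each atom in the canonical order.
#' @export
canonical_ranks <- function(g) {
  a <- .aug_igraph(g)
  lab <- igraph::canonical_permutation(a$ig, colors = a$colors)$labeling
  rank(lab[seq_len(a$n)])
}

#' Canonical graph key
#'
#' Deterministic string key identical for graph-isomorphic molecules
#' (element, charge and bond-order aware). Used for deduplication.
#'
#' @param g A `molgraph`.
#' @return A character scalar.
#' @export
graph_key <- function(g) {
  r <- canonical_ranks(g)
  ord <- order(r)
  el <- paste(g$elements[ord], g$charges[ord], sep = "", collapse = ".")
  b <- g$bonds
  if (nrow(b) == 0) return(paste0(el, "|"))
  e2 <- cbind(pmin(r[b$from], r[b$to]), pmax(r[b$from], r[b$to]), b$order)
  e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
  paste0(el, "|", paste(e2[, 1], e2[, 2], e2[, 3], sep = "-", collapse = ","))
}

#' Graph isomorphism test
#'
#' VF2 isomorphism respecting element, charge and bond order. Used as the
#' pairwise oracle against which canonical-key deduplication is checked.
#'
#' @param g1,g2 `molgraph` objects.
#' @return Logical.
#' @export
mol_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2) || nrow(g1$bonds) != nrow(g2$bonds)) {
    return(FALSE)
  }
  a1 <- .aug_igraph(g1); a2 <- .aug_igraph(g2)
  igraph::isomorphic(a1$ig, a2$ig, method = "vf2",
                     vertex.color1 = a1$colors, vertex.color2 = a2$colors)
}
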