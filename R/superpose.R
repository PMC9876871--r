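# Stage-1 ranking: rigid-body superposition of skeleton attachment vectors
# (core carbon -> methyl carbon) onto the Calpha -> Cbeta side-chain
# vectors of a three-residue peptide query, scored by the sum of squared
# deviations over the six paired atoms.

#' Load a peptide query from a PDB file
#'
#' Extracts Calpha and Cbeta coordinates for exactly three residues. The
#' first alternate location is used; glycine (which has no Cbeta) and
#' missing atoms raise errors naming the residue.
#'
#' @param pdb_file Path to a PDB file.
#' @param chain Chain identifier (default: first chain present).
#' @param residues Integer vector of exactly three residue numbers.
#' @return A `peptide_query`: list with `residues` (data frame) and `ca`,
#'   `cb` (3 x 3 coordinate matrices, one row per residue).
#' @export
load_peptide <- function(pdb_file, chain = NULL, residues) {
  if (length(residues) != 3) stop("exactly 3 residues are required")
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  ca <- matrix(NA_real_, 3, 3)
  cb <- matrix(NA_real_, 3, 3)
  resid <- character(3)
  for (i in seq_along(residues)) {
    sel <- at[at$chain == chain & at$resno == residues[i], , drop = FALSE]
    if (nrow(sel) == 0) stop("residue ", residues[i], " not found")
    resid[i] <- sel$resid[1]
    if (toupper(resid[i]) == "GLY") {
      stop("residue ", residues[i], " is glycine (no Cbeta)")
    }
    for (atom in c("CA", "CB")) {
      rows <- sel[sel$elety == atom, , drop = FALSE]
      if (nrow(rows) == 0) {
        stop("residue ", residues[i], " lacks atom ", atom)
      }
      xyz <- as.numeric(rows[1, c("x", "y", "z")])
      if (atom == "CA") ca[i, ] <- xyz else cb[i, ] <- xyz
    }
  }
  peptide_query(ca, cb, data.frame(resno = residues, resid = resid))
}

#' Construct a peptide query from coordinates
#'
#' @param ca,cb 3 x 3 matrices of Calpha / Cbeta coordinates (angstrom),
#'   one row per residue.
#' @param residues Optional residue annotation data frame.
#' @return A `peptide_query`.
#' @export
peptide_query <- function(ca, cb, residues = NULL) {
  ca <- as.matrix(ca); cb <- as.matrix(cb)
  stopifnot(all(dim(ca) == c(3, 3)), all(dim(cb) == c(3, 3)),
            all(is.finite(ca)), all(is.finite(cb)))
  if (is.null(residues)) {
    residues <- data.frame(resno = 1:3, resid = paste0("X", 1:3))
  }
  structure(list(ca = ca, cb = cb, residues = residues),
            class = "peptide_query")
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping point set `P`
#' onto `Q` via singular value decomposition; reflections are excluded
#' since molecules are chiral objects in three dimensions.
#'
#' @param P,Q n x 3 coordinate matrices with paired rows.
#' @return List with `rotation` (3 x 3, det = +1), `translation` (length
#'   3), `ssd` (angstrom squared) and `degenerate` (near-singular flag).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  ssd <- sum((P0 %*% t(R) - Q0)^2)
  list(rotation = R, translation = as.numeric(cq - R %*% cp), ssd = ssd,
       degenerate = s$d[3] < 1e-8 * max(s$d[1], 1e-12))
}

# 3! assignments of residues to attachment points
.PERMS3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))

#' Superpose skeleton attachment vectors onto a peptide query
#'
#' Over all six residue-to-attachment assignments, the six paired atoms
#' (attachment core vs Calpha, methyl vs Cbeta) are rigidly superposed by
#' [kabsch()] and the assignment with the smallest SSD is returned; ties
#' break by lexicographic assignment order.
#'
#' @param vectors List of 3 attachment vector pairs, each a list/matrix
#'   with `core` and `methyl` coordinates (length-3 numerics).
#' @param query A [peptide_query()].
#' @return A `superposition_result`: list with `assignment` (residue index
#'   for each attachment), `rotation`, `translation`, `ssd`, `degenerate`.
#' @export
superpose <- function(vectors, query) {
  stopifnot(length(vectors) == 3)
  P <- do.call(rbind, lapply(vectors, function(v) {
    rbind(as.numeric(v$core), as.numeric(v$methyl))
  }))
  best <- NULL
  for (pi in seq_len(nrow(.PERMS3))) {
    perm <- .PERMS3[pi, ]
    Q <- do.call(rbind, lapply(perm, function(ri) {
      rbind(query$ca[ri, ], query$cb[ri, ])
    }))
    k <- kabsch(P, Q)
    if (is.null(best) || k$ssd < best$ssd - 1e-12) {
      best <- k
      best$assignment <- perm
    }
  }
  structure(best, class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition: ssd = %.4f A^2, assignment %s%s>\n", x$ssd,
              paste(x$assignment, collapse = "-"),
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Embed a skeleton and extract attachment vectors
#'
#' @param sk A [skeleton()].
#' @param n_conformers Conformers to generate.
#' @param seed Accepted for interface stability; the Open Babel embedding
#'   used here is deterministic.
#' @return List of conformers, each with `vectors` (3 core/methyl pairs),
#'   `coords` and `energy`; `NULL` when embedding fails.
#' @export
embed_skeleton <- function(sk, n_conformers = 1L, seed = NULL) {
  confs <- embed_molgraph(sk$graph, n_conformers)
  if (is.null(confs)) return(NULL)
  ap <- attachment_pairs(sk)
  lapply(confs, function(cf) {
    vectors <- lapply(seq_len(nrow(ap)), function(i) {
      list(core = cf$coords[ap[i, "core"], ],
           methyl = cf$coords[ap[i, "methyl"], ])
    })
    list(vectors = vectors, coords = cf$coords, energy = cf$energy)
  })
}

#' Rank a skeleton library against a peptide query
#'
#' Per skeleton, the best SSD over conformers and residue assignments is
#' computed; results are sorted by ascending SSD.
#'
#' @param query A [peptide_query()].
#' @param skeletons Named list of [skeleton()] objects.
#' @param n_conformers Conformers per skeleton.
#' @param seed Seed passed to [embed_skeleton()].
#' @param top_k Number of entries returned (default: all).
#' @return Data frame with `skeleton`, `conformer`, `assignment`, `ssd_A2`,
#'   ordered by SSD; attribute `results` holds the full
#'   `superposition_result` objects.
#' @export
rank_library <- function(query, skeletons, n_conformers = 1L, seed = NULL,
                         top_k = Inf) {
  stopifnot(length(skeletons) > 0)
  if (is.null(names(skeletons))) {
    names(skeletons) <- paste0("sk", seq_along(skeletons))
  }
  rows <- NULL
  results <- list()
  for (nm in names(skeletons)) {
    confs <- embed_skeleton(skeletons[[nm]], n_conformers, seed)
    if (is.null(confs)) next
    best <- NULL; best_ci <- NA_integer_
    for (ci in seq_along(confs)) {
      if (length(confs[[ci]]$vectors) != 3) next
      sp <- superpose(confs[[ci]]$vectors, query)
      if (is.null(best) || sp$ssd < best$ssd) {
        best <- sp; best_ci <- ci
      }
    }
    if (is.null(best)) next
    rows <- rbind(rows, data.frame(
      skeleton = nm, conformer = best_ci,
      assignment = paste(best$assignment, collapse = "-"),
      ssd_A2 = best$ssd))
    results[[nm]] <- best
  }
  if (is.null(rows)) return(NULL)
  ord <- order(rows$ssd_A2)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  if (is.finite(top_k)) rows <- utils::head(rows, top_k)
  attr(rows, "results") <- results[rows$skeleton]
  rows
}
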