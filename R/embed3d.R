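# 3D embedding and strain energies via the Open Babel command line tools
# (obabel --gen3d for coordinates, obenergy for MMFF94 energies). These
# stand behind the strain filter and the skeleton superposition geometry.

ob_available <- function() {
  nzchar(Sys.which("obabel")) && nzchar(Sys.which("obenergy"))
}

.require_ob <- function() {
  if (!ob_available()) {
    stop("Open Babel tools (obabel/obenergy) not found on PATH")
  }
}

# parse one SDF text block into heavy-atom coordinates + elements + bonds
.sdf_block_geometry <- function(lines) {
  natoms <- as.integer(substr(lines[4], 1, 3))
  nbonds <- as.integer(substr(lines[4], 4, 6))
  arows <- lines[4 + seq_len(natoms)]
  coords <- cbind(as.numeric(substr(arows, 1, 10)),
                  as.numeric(substr(arows, 11, 20)),
                  as.numeric(substr(arows, 21, 30)))
  elements <- trimws(substr(arows, 32, 34))
  brows <- lines[4 + natoms + seq_len(nbonds)]
  bonds <- cbind(as.integer(substr(brows, 1, 3)),
                 as.integer(substr(brows, 4, 6)))
  list(coords = coords, elements = elements, bonds = bonds)
}

#' Embed a molecular graph in 3D
#'
#' Generates force-field-relaxed 3D coordinates with `obabel --gen3d`
#' (single deterministic conformer) or the Open Babel conformer search for
#' `n_conformers > 1`. Heavy-atom order is verified against the input graph
#' by comparing bond sets.
#'
#' @param g A connected `molgraph`.
#' @param n_conformers Number of conformers requested.
#' @return List of conformers, each with `coords` (heavy-atom matrix, rows
#'   in `g`'s atom order) and `energy` (MMFF94, kcal/mol), or `NULL` when
#'   embedding fails.
#' @export
embed_molgraph <- function(g, n_conformers = 1L) {
  .require_ob()
  smi <- write_smiles(g)
  order <- attr(smi, "atom_order")
  args <- c(paste0("-:", as.character(smi)), "-osdf", "--gen3d")
  if (n_conformers > 1) {
    args <- c(args, "--conformer", "--nconf", n_conformers,
              "--writeconformers")
  }
  out <- suppressWarnings(system2("obabel", shQuote(args), stdout = TRUE,
                                  stderr = FALSE))
  if (length(out) == 0) return(NULL)
  ends <- which(out == "$$$$")
  if (length(ends) == 0) return(NULL)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  n <- n_atoms(g)
  inv <- order(order)  # SMILES emission position of each molgraph atom
  confs <- list()
  for (k in seq_along(ends)) {
    block <- out[starts[k]:ends[k]]
    geo <- tryCatch(.sdf_block_geometry(block), error = function(e) NULL)
    if (is.null(geo)) next
    heavy <- which(geo$elements != "H")
    if (length(heavy) != n) next
    # sanity: embedded heavy-atom bonds must reproduce the input graph
    hb <- geo$bonds[geo$bonds[, 1] %in% heavy & geo$bonds[, 2] %in% heavy, ,
                    drop = FALSE]
    hmap <- match(seq_len(max(heavy)), heavy)
    want <- sort(paste(pmin(inv[g$bonds$from], inv[g$bonds$to]),
                       pmax(inv[g$bonds$from], inv[g$bonds$to])))
    got <- sort(paste(pmin(hmap[hb[, 1]], hmap[hb[, 2]]),
                      pmax(hmap[hb[, 1]], hmap[hb[, 2]])))
    if (!identical(want, got)) next
    coords <- geo$coords[heavy, , drop = FALSE][inv, , drop = FALSE]
    en <- .ob_energy(block)
    confs[[length(confs) + 1]] <- list(coords = coords, energy = en)
  }
  if (length(confs) == 0) NULL else confs
}

.ob_energy <- function(sdf_lines) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_lines, tf)
  out <- suppressWarnings(system2("obenergy", c("-ff", "MMFF94",
                                                shQuote(tf)),
                                  stdout = TRUE, stderr = FALSE))
  ln <- grep("TOTAL ENERGY", out, value = TRUE)
  if (length(ln) == 0) return(NA_real_)
  suppressWarnings(as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1",
                                  ln[length(ln)])))
}

#' Strain filter for enumerated ring systems
#'
#' Embeds each system in 3D and keeps those whose minimum conformer energy
#' is at most `config$energy_threshold` (kcal/mol, MMFF94). Embedding
#' failures count as rejections and are reported via attribute
#' `n_embed_failures`.
#'
#' @param records List of enumeration records (see
#'   [enumerate_ring_systems()]) or bare `molgraph`s.
#' @param config An [enum_config()].
#' @return The retained records, each annotated with `energy`; attribute
#'   `n_embed_failures` counts embedding failures.
#' @export
strain_filter <- function(records, config = enum_config()) {
  kept <- list()
  fails <- 0L
  for (r in records) {
    g <- if (inherits(r, "molgraph")) r else r$graph
    confs <- embed_molgraph(g, config$n_conformers)
    if (is.null(confs)) {
      fails <- fails + 1L
      next
    }
    en <- suppressWarnings(min(vapply(confs, `[[`, numeric(1), "energy"),
                               na.rm = TRUE))
    if (!is.finite(en)) {
      fails <- fails + 1L
      next
    }
    if (en <= config$energy_threshold) {
      rec <- if (inherits(r, "molgraph")) list(graph = r) else r
      rec$energy <- en
      kept[[length(kept) + 1]] <- rec
    }
  }
  attr(kept, "n_embed_failures") <- fails
  kept
}
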