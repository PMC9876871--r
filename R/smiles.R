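# SMILES input goes through Open Babel (ChemmineOB) and is kekulized there;
# SMILES output is produced by the package's own rooted writer so that
# traversal roots and atom visit order stay under caller control (needed for
# the string-pairing strategy and for canonical keys).

#' Parse-failure value
#'
#' Malformed SMILES yield a typed failure value instead of an error so that
#' validity statistics can be computed over noisy generator output.
#'
#' @param reason Short reason code (`"empty"`, `"syntax"`, `"valence"`,
#'   `"kekulization"`).
#' @param smiles The offending string.
#' @export
parse_failure <- function(reason, smiles = NA_character_) {
  structure(list(reason = reason, smiles = smiles),
            class = "smiles_parse_failure")
}

#' @rdname parse_failure
#' @param x Object to test.
#' @export
is_parse_failure <- function(x) inherits(x, "smiles_parse_failure")

# cheap grammar screen before handing strings to Open Babel
.smiles_precheck <- function(s) {
  if (is.na(s) || !nzchar(s)) return("empty")
  if (grepl("[^A-Za-z0-9@\\[\\]()=#%/\\\\.+-]", s)) return("syntax")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (cumsum(chars == "(")[length(chars)] != sum(chars == ")") ||
      any(cumsum(chars == "(") - cumsum(chars == ")") < 0)) return("syntax")
  if (sum(chars == "[") != sum(chars == "]")) return("syntax")
  NULL
}

.ob_options <- function() data.frame(names = c("e", "errorlevel"),
                                     args = c("", "0"))

# one SDF block (character vector of lines) -> molgraph or failure
.molgraph_from_sdfblock <- function(lines, smiles) {
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  if (!is.na(nbonds) && nbonds == 0L) {
    # ChemmineR cannot represent bond-less records; read the fixed-width
    # atom lines directly
    if (is.na(natoms) || natoms < 1) return(parse_failure("syntax", smiles))
    elements <- trimws(substr(lines[4 + seq_len(natoms)], 32, 34))
    charges <- integer(natoms)
    for (cl in grep("^M  CHG", lines, value = TRUE)) {
      vals <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
      for (j in seq_len(vals[1])) charges[vals[2 * j]] <- vals[2 * j + 1]
    }
    keep <- which(elements != "H")
    if (length(keep) == 0) return(parse_failure("syntax", smiles))
    g <- tryCatch(molgraph(elements[keep], NULL, charges[keep],
                           validate = FALSE), error = function(e) NULL)
    if (is.null(g)) return(parse_failure("syntax", smiles))
    bad <- validate_molgraph(g)
    if (!is.null(bad)) return(parse_failure("valence", smiles))
    return(g)
  }
  sdfset <- tryCatch(
    suppressWarnings(methods::as(methods::as(list(lines), "SDFstr"), "SDFset")),
    error = function(e) NULL
  )
  if (is.null(sdfset) || length(sdfset) == 0 || is.na(nbonds)) {
    return(parse_failure("syntax", smiles))
  }
  sdf <- sdfset[[1]]
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  bb <- if (nbonds > 0) {
    tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  } else {
    matrix(integer(0), 0, 3)
  }
  if (is.null(ab) || is.null(bb)) return(parse_failure("syntax", smiles))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  bb <- matrix(as.integer(bb[, 1:3]), ncol = 3)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charges <- integer(n)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    vals <- as.integer(strsplit(trimws(sub("^M  CHG", "", cl)), "\\s+")[[1]])
    k <- vals[1]
    for (j in seq_len(k)) {
      charges[vals[2 * j]] <- vals[2 * j + 1]
    }
  }
  if (NROW(bb) > 0) {
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- NULL
  }
  if (!is.null(bonds) && any(bonds$order > 3)) {
    return(parse_failure("kekulization", smiles))
  }
  # drop explicit hydrogens; they are represented implicitly
  hs <- which(elements == "H")
  if (length(hs) > 0) {
    keep <- setdiff(seq_len(n), hs)
    if (length(keep) == 0) return(parse_failure("syntax", smiles))
    map <- match(seq_len(n), keep)
    if (!is.null(bonds)) {
      ok <- !is.na(map[bonds$from]) & !is.na(map[bonds$to])
      bonds <- data.frame(from = map[bonds$from[ok]], to = map[bonds$to[ok]],
                          order = bonds$order[ok])
    }
    elements <- elements[keep]
    charges <- charges[keep]
  }
  g <- tryCatch(molgraph(elements, bonds, charges, validate = FALSE),
                error = function(e) NULL)
  if (is.null(g)) return(parse_failure("syntax", smiles))
  bad <- validate_molgraph(g)
  if (!is.null(bad)) {
    reason <- if (grepl("valence", bad)) "valence" else "syntax"
    return(parse_failure(reason, smiles))
  }
  g
}

#' Parse SMILES strings
#'
#' Strings are screened by a light grammar check, converted by Open Babel
#' (aromatic systems kekulized), and validated against standard valences.
#' Failures are returned as [parse_failure()] values, never raised, so
#' batches of generated strings can be scored for validity.
#'
#' @param smiles Character vector of SMILES strings.
#' @return `parse_smiles_batch`: a list of `molgraph`/failure values, one per
#'   input. `parse_smiles`: a single `molgraph` or failure value.
#' @export
parse_smiles_batch <- function(smiles) {
  out <- vector("list", length(smiles))
  pre <- vapply(smiles, function(s) {
    r <- .smiles_precheck(s)
    if (is.null(r)) "" else r
  }, "", USE.NAMES = FALSE)
  for (i in which(nzchar(pre))) out[[i]] <- parse_failure(pre[i], smiles[i])
  todo <- which(!nzchar(pre))
  if (length(todo) == 0) return(out)
  input <- paste0(smiles[todo], " q", seq_along(todo), collapse = "\n")
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(input, "\n"),
                              options = .ob_options()),
    error = function(e) ""
  )
  for (i in todo) out[[i]] <- parse_failure("syntax", smiles[i])
  if (!nzchar(sdf)) return(out)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:ends[k]]
    id <- suppressWarnings(as.integer(sub("^q", "", trimws(block[1]))))
    if (is.na(id) || id < 1 || id > length(todo)) next
    i <- todo[id]
    out[[i]] <- .molgraph_from_sdfblock(block, smiles[i])
  }
  out
}

#' @rdname parse_smiles_batch
#' @param s A single SMILES string.
#' @export
parse_smiles <- function(s) {
  stopifnot(length(s) == 1L)
  parse_smiles_batch(s)[[1]]
}

# ---- SMILES writer ---------------------------------------------------------

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.atom_token <- function(element, charge) {
  if (charge == 0 && element %in% .ORGANIC_SUBSET) return(element)
  chg <- if (charge == 0) "" else if (charge == 1) "+" else if (charge == -1)
    "-" else sprintf("%+d", charge)
  # hydrogen count must be explicit inside brackets; computed by caller
  paste0("[", element, "{H}", chg, "]")
}

.bond_token <- function(order) c("", "=", "#")[order]

.ring_digit <- function(d) if (d < 10) as.character(d) else sprintf("%%%d", d)

#' Write a SMILES string
#'
#' Depth-first writer over a `molgraph`. The traversal starts at `root` and
#' visits neighbours in increasing `ranks` order, so the same rank vector
#' applied to a structure and to its carbonized form yields positionally
#' matched strings. Aromatic rings are emitted in kekulized form.
#'
#' @param g A `molgraph` (connected).
#' @param root 1-based index of the first atom.
#' @param ranks Numeric vector of distinct visit priorities (lower first);
#'   defaults to input order.
#' @return SMILES string with attribute `atom_order` (the emission order of
#'   atom indices).
#' @export
write_smiles <- function(g, root = 1L, ranks = seq_len(n_atoms(g))) {
  n <- n_atoms(g)
  stopifnot(root >= 1, root <= n)
  if (!is_connected_mol(g)) stop("write_smiles requires a connected graph")
  adj <- adjacency(g)
  hyd <- implicit_hydrogens(g)

  visited <- rep(FALSE, n)
  children <- vector("list", n)
  child_order <- vector("list", n)
  ring_at <- vector("list", n)
  edge_used <- new.env(parent = emptyenv())
  visit_seq <- integer(0)
  ekey <- function(u, v) paste(min(u, v), max(u, v))

  dfs <- function(u) {
    visited[u] <<- TRUE
    visit_seq[length(visit_seq) + 1L] <<- u
    nb <- adj[[u]]
    if (is.null(nb)) return(invisible())
    ordnb <- nb[order(ranks[nb[, 1]]), , drop = FALSE]
    for (j in seq_len(nrow(ordnb))) {
      v <- ordnb[j, 1]; bo <- ordnb[j, 2]
      k <- ekey(u, v)
      if (!is.null(edge_used[[k]])) next
      edge_used[[k]] <- TRUE
      if (visited[v]) {
        rc <- list(key = k, order = bo)
        ring_at[[v]] <<- c(ring_at[[v]], list(rc))
        ring_at[[u]] <<- c(ring_at[[u]], list(rc))
      } else {
        children[[u]] <<- c(children[[u]], v)
        child_order[[u]] <<- c(child_order[[u]], bo)
        dfs(v)
      }
    }
    invisible()
  }
  dfs(as.integer(root))

  # assign ring-closure digits in emission order with reuse
  digit_of <- new.env(parent = emptyenv())
  free <- seq_len(99)
  closure_token <- vector("list", n)
  for (u in visit_seq) {
    toks <- character(0)
    for (rc in ring_at[[u]]) {
      d <- digit_of[[rc$key]]
      if (is.null(d)) {
        d <- free[1]; free <- free[-1]
        digit_of[[rc$key]] <- d
        toks <- c(toks, paste0(.bond_token(rc$order), .ring_digit(d)))
      } else {
        free <- sort(c(free, d))
        toks <- c(toks, paste0(.bond_token(rc$order), .ring_digit(d)))
      }
    }
    closure_token[[u]] <- toks
  }

  emit <- function(u) {
    tok <- .atom_token(g$elements[u], g$charges[u])
    if (grepl("{H}", tok, fixed = TRUE)) {
      h <- hyd[u]
      hstr <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
      tok <- sub("{H}", hstr, tok, fixed = TRUE)
    }
    out <- paste0(tok, paste(closure_token[[u]], collapse = ""))
    ch <- children[[u]]
    if (length(ch) > 0) {
      for (j in seq_along(ch)) {
        sub <- paste0(.bond_token(child_order[[u]][j]), emit(ch[j]))
        if (j < length(ch)) {
          out <- paste0(out, "(", sub, ")")
        } else {
          out <- paste0(out, sub)
        }
      }
    }
    out
  }
  s <- emit(as.integer(root))
  attr(s, "atom_order") <- visit_seq
  s
}

#' Canonical SMILES
#'
#' Deterministic SMILES based on BLISS canonical atom ranks: isomorphic
#' graphs yield identical strings (element, charge and bond-order aware).
#'
#' @param g A `molgraph` (connected).
#' @return A SMILES string.
#' @export
canonical_smiles <- function(g) {
  r <- canonical_ranks(g)
  as.character(write_smiles(g, root = which(r == 1L), ranks = r))
}

#' Randomized SMILES
#'
#' SMILES rooted at a chosen atom with randomly permuted neighbour visit
#' order; parses back to a graph isomorphic to the input. Used for training
#' data augmentation.
#'
#' @param g A `molgraph` (connected).
#' @param root_atom 1-based root atom index.
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return SMILES string with attribute `atom_order`.
#' @export
randomized_smiles <- function(g, root_atom, seed = NULL) {
  n <- n_atoms(g)
  if (root_atom < 1 || root_atom > n) stop("invalid root atom index")
  ranks <- with_local_seed(seed, sample(n))
  write_smiles(g, root = root_atom, ranks = ranks)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the previous RNG state on
#' exit; with `seed = NULL` the expression is evaluated unchanged. Used to
#' make individual stochastic steps reproducible without disturbing the
#' caller's random stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
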