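# Generation quality metrics: string validity, input-scaffold retention,
# novelty against the training targets, and synthetic accessibility.

#' Scaffold retention check
#'
#' A generated structure retains its input skeleton when its carbonized
#' form is graph-isomorphic to the skeleton graph; because isomorphisms
#' preserve degree, terminal substituent atoms necessarily map onto the
#' methyl attachment caps, so ring systems and substituent positions must
#' both match exactly.
#'
#' @param generated A `molgraph` (or a parse failure, which returns
#'   `FALSE`).
#' @param input_skeleton A [skeleton()] (or bare `molgraph`).
#' @return Logical.
#' @export
retention_check <- function(generated, input_skeleton) {
  if (is_parse_failure(generated)) return(FALSE)
  ref <- if (inherits(input_skeleton, "skeleton")) {
    input_skeleton$graph
  } else {
    input_skeleton
  }
  mol_isomorphic(carbonize(generated), ref)
}

#' Evaluate generated structures
#'
#' @param raw Character vector of all sampled strings.
#' @param unique_graphs List of `molgraph`s for the unique valid
#'   structures.
#' @param skeleton The input [skeleton()].
#' @param training_targets Character vector of canonical training target
#'   SMILES (for novelty).
#' @param sa Also compute synthetic accessibility scores.
#' @return A `generation_report`: list with `n_sampled`, `n_unique`,
#'   `validity`, `retention`, `novelty`, `sa_scores`, `sa_mean`. With zero
#'   valid structures, retention and novelty are reported as 0.
#' @export
evaluate_generation <- function(raw, unique_graphs, skeleton,
                                training_targets = character(0),
                                sa = TRUE) {
  n_raw <- length(raw)
  parsed <- parse_smiles_batch(raw)
  valid <- vapply(parsed, function(g) !is_parse_failure(g), logical(1))
  validity <- if (n_raw == 0) 0 else mean(valid)
  nu <- length(unique_graphs)
  if (nu == 0) {
    return(structure(list(n_sampled = n_raw, n_unique = 0L,
                          validity = validity, retention = 0, novelty = 0,
                          sa_scores = numeric(0), sa_mean = NA_real_),
                     class = "generation_report"))
  }
  ret <- vapply(unique_graphs, retention_check, logical(1),
                input_skeleton = skeleton)
  canon <- vapply(unique_graphs, canonical_smiles, "")
  nov <- !(canon %in% training_targets)
  sas <- if (sa) vapply(unique_graphs, sa_score, numeric(1)) else numeric(0)
  structure(list(n_sampled = n_raw, n_unique = nu, validity = validity,
                 retention = mean(ret), novelty = mean(nov),
                 sa_scores = sas,
                 sa_mean = if (sa) mean(sas) else NA_real_),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf(
    "<generation report: %d sampled, %d unique | validity %.3f retention %.3f novelty %.3f%s>\n",
    x$n_sampled, x$n_unique, x$validity, x$retention, x$novelty,
    if (!is.na(x$sa_mean)) sprintf(" | mean SA %.2f", x$sa_mean) else ""))
  invisible(x)
}
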