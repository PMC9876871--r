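# Minimum-edit-distance pairing of source/target SMILES. Edit distance and
# alignment operate on characters; the model vocabulary (tokenize.R) uses
# multi-character atom tokens — two deliberate granularities.

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions.
#'
#' @param a,b Character scalars (or equal-length vectors, compared
#'   elementwise).
#' @return Integer distance(s).
#' @export
edit_distance <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(a) == 1 && length(b) == 1) return(as.integer(d[1, 1]))
  as.integer(diag(d))
}

#' Global alignment maximising matched characters
#'
#' Needleman-Wunsch style global alignment with match score 1 and zero gap
#' and mismatch penalties, i.e. identical characters score 1, all other
#' pairings 0. Traceback is deterministic and prefers placing gaps as late
#' as possible in the source string.
#'
#' @param source_str,target_str Non-empty strings.
#' @return An `aligned_pair`: list with `source_str`, `target_str`,
#'   `aligned_source`, `aligned_target`, `match_score`, `edit_distance`.
#' @export
global_align <- function(source_str, target_str) {
  stopifnot(nzchar(source_str), nzchar(target_str))
  al <- .align_chars(source_str, target_str)
  structure(list(source_str = source_str, target_str = target_str,
                 aligned_source = al$aligned_source,
                 aligned_target = al$aligned_target,
                 match_score = al$match_score,
                 edit_distance = edit_distance(source_str, target_str)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(x$aligned_source, "\n", x$aligned_target, "\n",
      sprintf("matches=%d edit=%d", x$match_score, x$edit_distance),
      "\n", sep = "")
  invisible(x)
}

# source/target SMILES written with a shared traversal, so strings are
# positionally comparable; returns c(source, target)
.paired_strings <- function(pair, root, ranks) {
  tgt <- write_smiles(pair$target, root = root, ranks = ranks)
  src <- write_smiles(pair$source, root = root, ranks = ranks)
  c(as.character(src), as.character(tgt))
}

#' Minimum-edit-distance string pair
#'
#' Generates target SMILES rooted at every atom (randomized neighbour
#' order, plus the canonical string), regenerates the matching source
#' SMILES by writing the carbonized molecule with the same traversal, and
#' returns the aligned pair with the smallest character edit distance. Ties
#' are broken by shorter target string, then lexicographically.
#'
#' @param pair A [structure_pair()].
#' @param n_augment Randomized traversals per root atom.
#' @param seed Integer seed.
#' @return An `aligned_pair` (see [global_align()]).
#' @export
best_pairing <- function(pair, n_augment = 1L, seed = NULL) {
  stopifnot(n_augment >= 1)
  n <- n_atoms(pair$target)
  cand <- with_local_seed(seed, {
    out <- list()
    for (root in seq_len(n)) {
      for (j in seq_len(n_augment)) {
        out[[length(out) + 1]] <- .paired_strings(pair, root, sample(n))
      }
    }
    out
  })
  # canonical candidate: canonical ranks of the target applied to both
  r <- canonical_ranks(pair$target)
  cand[[length(cand) + 1]] <- .paired_strings(pair, which(r == 1L), r)
  src <- vapply(cand, `[`, "", 1)
  tgt <- vapply(cand, `[`, "", 2)
  d <- as.integer(utils::adist(src, tgt)[cbind(seq_along(src),
                                               seq_along(tgt))])
  ord <- order(d, nchar(tgt), tgt, src)
  best <- ord[1]
  global_align(src[best], tgt[best])
}

#' Augment and align a pair corpus
#'
#' Produces about `k_augment` aligned string variants per structure pair
#' (random roots and traversals; matched source/target strings), then
#' deduplicates on the string pair. Reproducible under `seed`.
#'
#' @param pairs List of [structure_pair()] objects.
#' @param k_augment Variants per pair.
#' @param seed Integer seed.
#' @return List of `aligned_pair` objects.
#' @export
augment_corpus <- function(pairs, k_augment = 5L, seed = 1L) {
  stopifnot(k_augment >= 1)
  with_local_seed(seed, {
    out <- list()
    seen <- new.env(parent = emptyenv())
    for (p in pairs) {
      n <- n_atoms(p$target)
      for (j in seq_len(k_augment)) {
        st <- .paired_strings(p, sample.int(n, 1), sample(n))
        key <- paste(st[1], st[2], sep = ">")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1]] <- global_align(st[1], st[2])
        }
      }
    }
    out
  })
}

#' Canonical (unaugmented) aligned corpus
#'
#' One aligned pair per structure pair using canonical SMILES of source and
#' target independently — the baseline representation against which
#' augmented-and-aligned training is compared.
#'
#' @param pairs List of [structure_pair()] objects.
#' @return List of `aligned_pair` objects.
#' @export
canonical_corpus <- function(pairs) {
  lapply(pairs, function(p) {
    global_align(canonical_smiles(p$source), canonical_smiles(p$target))
  })
}

#' Write aligned pairs as TSV
#'
#' Columns: `source_str`, `target_str`, `aligned_source`, `aligned_target`,
#' `edit_distance`.
#'
#' @param aligned List of `aligned_pair` objects.
#' @param path Output path.
#' @export
write_aligned_tsv <- function(aligned, path) {
  df <- data.frame(
    source_str = vapply(aligned, `[[`, "", "source_str"),
    target_str = vapply(aligned, `[[`, "", "target_str"),
    aligned_source = vapply(aligned, `[[`, "", "aligned_source"),
    aligned_target = vapply(aligned, `[[`, "", "aligned_target"),
    edit_distance = vapply(aligned, `[[`, 1L, "edit_distance")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
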