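# Atom-level SMILES tokenization for the sequence model. Multi-character
# units (two-letter halogens, bracket atoms, %NN ring closures) are single
# tokens; alignment gap characters never reach the model (gap-free strings
# are tokenized).

.TOKEN_REGEX <- paste0(
  "(\\[[^\\]]*\\]",      # bracket atoms
  "|Cl|Br",              # two-letter elements in the organic subset
  "|%[0-9]{2}",          # two-digit ring closures
  "|.)"                  # any single remaining character
)

#' Tokenize a SMILES string
#'
#' @param s SMILES string (gap-free).
#' @return Character vector of tokens; collapsing them recovers `s`.
#' @export
smiles_tokenize <- function(s) {
  m <- gregexpr(.TOKEN_REGEX, s, perl = TRUE)[[1]]
  regmatches(s, list(m))[[1]]
}

#' Build a token vocabulary
#'
#' Special tokens `<pad>`, `<bos>`, `<eos>`, `<unk>` occupy ids 1-4;
#' remaining tokens are sorted for deterministic ids.
#'
#' @param strings Character vector of SMILES strings (typically all source
#'   and target strings of the training split).
#' @return A `vocab` object (named integer vector of token ids).
#' @export
build_vocab <- function(strings) {
  stopifnot(length(strings) > 0)
  toks <- sort(unique(unlist(lapply(strings, smiles_tokenize))))
  ids <- seq_len(4L + length(toks))
  names(ids) <- c("<pad>", "<bos>", "<eos>", "<unk>", toks)
  structure(ids, class = "vocab")
}

.PAD <- 1L; .BOS <- 2L; .EOS <- 3L; .UNK <- 4L

#' Encode / decode token id sequences
#'
#' @param s SMILES string.
#' @param vocab A [build_vocab()] vocabulary.
#' @return `encode_smiles`: integer id vector (no BOS/EOS); `decode_ids`:
#'   the SMILES string, dropping special tokens.
#' @export
encode_smiles <- function(s, vocab) {
  ids <- vocab[smiles_tokenize(s)]
  ids[is.na(ids)] <- .UNK
  unname(ids)
}

#' @rdname encode_smiles
#' @param ids Integer token ids.
#' @export
decode_ids <- function(ids, vocab) {
  toks <- names(vocab)[ids]
  paste(toks[ids > 4L], collapse = "")
}
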