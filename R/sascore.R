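# Fragment-contribution synthetic accessibility score: circular
# atom-environment frequencies from a reference set of common organic
# structures, combined with size and ring-complexity penalties, mapped to
# the conventional 1 (easy) .. 10 (very difficult) scale. The reference
# frequency table is built from a packaged list of ubiquitous organic
# molecules; scores are therefore internally consistent rather than tied
# to any external fragment database.

# Widespread organic structures used to calibrate fragment frequencies.
.SA_REFERENCE_SMILES <- c(
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "COc1ccccc1", "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1",
  "OC(=O)c1ccccc1", "O=Cc1ccccc1", "CC(=O)c1ccccc1", "NC(=O)c1ccccc1",
  "C=Cc1ccccc1", "CC(=O)Nc1ccccc1", "CNc1ccccc1", "CN(C)c1ccccc1",
  "c1ccc(cc1)-c1ccccc1", "O=C(c1ccccc1)c1ccccc1", "C(c1ccccc1)c1ccccc1",
  "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1ccc2ncccc2c1",
  "c1ccc2occc2c1", "c1ccc2sccc2c1", "C1Cc2ccccc2C1", "C1CCc2ccccc2C1",
  "c1ccncc1", "Cc1ccncc1", "c1cncnc1", "c1cnccn1", "c1ccnnc1",
  "c1c[nH]cn1", "c1cc[nH]n1", "c1ocnc1", "c1scnc1", "c1ccoc1", "c1ccsc1",
  "c1cc[nH]c1", "Nc1ncnc2[nH]cnc12", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  "C1CCNCC1", "C1CNCCN1", "C1COCCN1", "C1CCNC1", "C1CCOC1", "C1CCOCC1",
  "C1COCCO1", "CN1CCCC1", "CN1CCNCC1", "CC(=O)N1CCCC1", "O=C1CCCCN1",
  "O=C1CCCN1", "O=C1CCCCC1", "OC1CCCCC1", "NC1CCCCC1", "C1=CCCCC1",
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1", "CC1CCCCC1",
  "CC1(C)CCCCC1", "C1CCC2CCCCC2C1", "C1CC2CCC1C2", "C1CC2CCC1CC2",
  "C1C2CC3CC1CC(C2)C3",
  "CCO", "CCN", "CCOCC", "CC(C)O", "CC(C)(C)O", "CC(O)=O", "CC(C)=O",
  "CCOC(C)=O", "CC(N)=O", "NC(N)=O", "CN(C)C=O", "CS(C)=O", "CC#N",
  "CCCCCC", "CCCCCCCC", "CC(C)C", "CC(C)CC", "C=CC", "C#CC", "OCCO",
  "NCCO", "NCCN", "OCC(O)CO", "NCC(O)=O", "CC(N)C(O)=O", "CSCC",
  "CCS", "CCCl", "CCBr", "CCF", "FC(F)F", "ClC(Cl)Cl",
  "CC(=O)Oc1ccccc1C(O)=O", "CC(=O)Nc1ccc(O)cc1",
  "CC(C)Cc1ccc(cc1)C(C)C(O)=O", "Nc1ccc(cc1)S(N)(=O)=O",
  "Cc1ccc(cc1)S(N)(=O)=O", "CS(=O)(=O)c1ccccc1", "CCOC(=O)c1ccccc1",
  "COC(=O)c1ccccc1", "O=C(Nc1ccccc1)c1ccccc1", "CN1CCCC1c1cccnc1",
  "OCC1OC(O)C(O)C(O)C1O", "CC1CCC(C)CC1", "Cc1ccc(C)cc1", "Cc1cccc(C)c1",
  "Oc1ccc(O)cc1", "Clc1ccc(Cl)cc1", "Nc1ccc(N)cc1", "COc1ccc(OC)cc1",
  "O=c1ccc2ccccc2o1", "c1ccc2c(c1)CCCC2", "C1CCC2(CC1)CCCCC2"
)

# circular atom-environment keys (Weisfeiler-Lehman style labels); all
# radii up to `radius` are returned — with a compact reference set the
# coarse environments carry most of the frequency signal
.atom_env_keys <- function(g, radius = 2L) {
  n <- n_atoms(g)
  adj <- adjacency(g)
  ri <- ring_info(g)
  h <- implicit_hydrogens(g)
  lab <- paste0(g$elements, "|", heavy_degree(g), "|", h, "|",
                g$charges, "|", as.integer(ri$ring_atoms))
  out <- lab
  for (r in seq_len(radius)) {
    lab <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(paste0(r, "(", lab[i], ")"))
      parts <- sort(paste0(nb[, 2], ":", lab[nb[, 1]]))
      paste0(r, "(", lab[i], "[", paste(parts, collapse = ","), "])")
    }, "")
    out <- c(out, lab)
  }
  out
}

.sa_table <- function() {
  if (!is.null(.scaffmime_cache$sa_table)) return(.scaffmime_cache$sa_table)
  mols <- parse_smiles_batch(.SA_REFERENCE_SMILES)
  keys <- unlist(lapply(mols, function(g) {
    if (is_parse_failure(g)) return(character(0))
    .atom_env_keys(g)
  }))
  tab <- table(keys)
  .scaffmime_cache$sa_table <- tab
  tab
}

#' Synthetic accessibility score
#'
#' Fragment-contribution estimate in the spirit of frequency-based SA
#' scoring: atom-centred circular environments (radius 2) are scored by
#' their log-frequency in a reference set of common organic structures;
#' penalties are added for molecular size, bridged and spiro ring
#' complexity, and macrocycles, with a bonus for internal symmetry. The
#' result is scaled to \[1, 10\] with 1 = easy and 10 = very difficult to
#' synthesise.
#'
#' @param g A `molgraph`.
#' @return Numeric score in \[1, 10\].
#' @export
sa_score <- function(g) {
  tab <- .sa_table()
  keys <- .atom_env_keys(g)
  # frequencies are compared within each environment radius so that the
  # intrinsically rarer wide environments do not dominate the mean
  radius_of <- function(k) ifelse(startsWith(k, "2("), 2L,
                                  ifelse(startsWith(k, "1("), 1L, 0L))
  ref_rad <- radius_of(names(tab))
  mx <- vapply(0:2, function(r) {
    if (any(ref_rad == r)) max(tab[ref_rad == r]) else 1
  }, numeric(1))
  krad <- radius_of(keys)
  fs <- vapply(seq_along(keys), function(i) {
    ct <- tab[keys[i]]
    if (is.na(ct)) return(-4)
    max(-4, log10(as.numeric(ct) / mx[krad[i] + 1L]))
  }, numeric(1))
  score1 <- mean(fs)
  n <- n_atoms(g)
  ri <- ring_info(g)
  size_pen <- n^1.005 - n
  nb <- .count_bridgeheads(g)
  nsp <- .count_spiro(g, ri)
  ring_pen <- log10(nb + 1) + log10(nsp + 1)
  macro_pen <- if (length(ri$sizes) > 0 && max(ri$sizes) > 8) log10(2) else 0
  nuniq <- length(unique(keys))
  sym_bonus <- if (n > nuniq) 0.5 * log(n / nuniq) else 0
  raw <- score1 - size_pen - ring_pen - macro_pen + sym_bonus
  # scale: raw 0.5 (very common, small) .. -5 (rare fragments, complex)
  sa <- 11 - (raw - (-5)) / (0.5 - (-5)) * 9
  if (sa > 8) sa <- 8 + log(sa - 7)
  min(10, max(1, sa))
}

# atoms that bridge two rings through three or more internally disjoint
# paths (bridgehead pairs of bridged polycyclics)
.count_bridgeheads <- function(g) {
  ig <- mol_igraph(g)
  deg <- igraph::degree(ig)
  hubs <- which(deg >= 3)
  if (length(hubs) < 2) return(0L)
  bh <- logical(n_atoms(g))
  for (a in seq_along(hubs)[-length(hubs)]) {
    for (b in (a + 1):length(hubs)) {
      u <- hubs[a]; v <- hubs[b]
      g2 <- ig
      eid <- igraph::get_edge_ids(ig, c(u, v))
      if (eid > 0) g2 <- igraph::delete_edges(ig, eid)
      k <- tryCatch(igraph::vertex_connectivity(g2, source = u, target = v),
                    error = function(e) 0L)
      if (k >= 3) bh[c(u, v)] <- TRUE
    }
  }
  sum(bh)
}

.count_spiro <- function(g, ri = ring_info(g)) {
  rings <- ri$rings
  if (length(rings) < 2) return(0L)
  sp <- logical(n_atoms(g))
  for (a in seq_along(rings)[-length(rings)]) {
    for (b in (a + 1):length(rings)) {
      shared <- intersect(rings[[a]], rings[[b]])
      if (length(shared) == 1) sp[shared] <- TRUE
    }
  }
  sum(sp)
}
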