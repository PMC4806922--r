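# Duplex detection and (CUG)n fragment extraction.

.VALID_PAIRS <- c("AU", "UA", "CG", "GC", "UU")

# Detect an antiparallel duplex between two chains: equal length >= min_len
# and every position i of the first chain pairing with position L+1-i of the
# second under Watson-Crick complementarity with U.U accepted.
.chains_paired <- function(seq_a, seq_b, min_len = 6) {
  la <- strsplit(seq_a, "")[[1]]; lb <- strsplit(seq_b, "")[[1]]
  if (length(la) != length(lb) || length(la) < min_len) return(FALSE)
  all(paste0(la, rev(lb)) %in% .VALID_PAIRS)
}

#' Identify the paired chains of a duplex
#'
#' @param structure an `rna_structure`.
#' @param min_len minimum complementary length, nucleotides.
#' @return Character vector of the two chain ids (reference strand first), or
#'   an error if no antiparallel complementary chain pair exists.
#' @export
duplex_chains <- function(structure, min_len = 6) {
  seqs <- chain_sequences(structure)
  ids <- names(seqs)
  if (length(ids) < 2) stop("structure has fewer than 2 chains; not a duplex")
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i != j && .chains_paired(seqs[[i]], seqs[[j]], min_len))
      return(c(ids[i], ids[j]))
  }
  stop("no antiparallel complementary chain pair of >= ", min_len,
       " nt found (U.U counted as a valid pair position)")
}

#' Extract double-stranded (CUG)n windows from a duplex
#'
#' Enumerates windows of `n_repeats` CUG triplets along the repeat tract of
#' the reference strand, advanced by `stride` triplets, and cuts the paired
#' window from the complementary strand. Each fragment is returned 5' to 3'
#' with chains relabeled "A"/"B" and residues renumbered from 1, so fragments
#' from different source structures share node labels.
#'
#' @param structure an `rna_structure` containing a duplex.
#' @param n_repeats CUG triplets per fragment strand.
#' @param stride window advance in triplets (1 = overlapping windows).
#' @return List of `rna_structure` fragments (empty if no tract is long
#'   enough).
#' @export
extract_cug_fragments <- function(structure, n_repeats = 3, stride = 1) {
  stopifnot(n_repeats >= 1, stride >= 1)
  ch <- duplex_chains(structure, min_len = 3 * n_repeats)
  seqs <- chain_sequences(structure)
  sa <- seqs[[ch[1]]]
  L <- nchar(sa)
  w <- 3 * n_repeats
  target <- strrep("CUG", n_repeats)
  starts <- which(vapply(seq_len(L - w + 1),
                         function(i) substr(sa, i, i + w - 1) == target,
                         logical(1)))
  if (length(starts) == 0) return(list())
  # group in-phase runs (consecutive starts 3 apart) and apply the stride
  keep <- integer(0)
  run_start <- starts[1]
  for (s in starts) {
    if (!any(starts == s - 3)) run_start <- s
    if (((s - run_start) / 3) %% stride == 0) keep <- c(keep, s)
  }
  res_a <- residue_table(structure); res_a <- res_a[res_a$chain == ch[1], ]
  res_b <- residue_table(structure); res_b <- res_b[res_b$chain == ch[2], ]
  lapply(keep, function(s) {
    ia <- res_a$resno[s:(s + w - 1)]
    ib <- res_b$resno[(L + 1 - (s + w - 1)):(L + 1 - s)] # 5'->3' on strand B
    at <- structure$atoms
    fa <- at[at$chain == ch[1] & at$resno %in% ia, , drop = FALSE]
    fb <- at[at$chain == ch[2] & at$resno %in% ib, , drop = FALSE]
    fa$resno <- match(fa$resno, ia); fa$chain <- "A"
    fb$resno <- match(fb$resno, ib); fb$chain <- "B"
    rna_structure(rbind(fa, fb), model = structure$model)
  })
}

#' Build an aligned coarse-grained ensemble from structures
#'
#' Selects nodes under one scheme from each structure, restricts to the labels
#' common to all (so interior fragments with a 5' P and terminal fragments
#' without one stay comparable), and iteratively aligns the conformers.
#'
#' @param structures list of `rna_structure` objects with matching residue
#'   labeling (e.g. the output of [extract_cug_fragments()]).
#' @param scheme coarse-graining scheme.
#' @param source provenance tag.
#' @return An aligned `rna_ensemble`.
#' @export
ensemble_from_structures <- function(structures, scheme = cg_scheme("CG2"),
                                     source = "") {
  if (length(structures) < 2) stop("need at least 2 structures")
  ns <- lapply(structures, select_nodes, scheme = scheme)
  ns <- common_nodes(ns)
  align_ensemble(ns, source = source)
}
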