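# Shared fixture builders and independent oracles for the test suite.

# identity alignment: sequence position i <-> chain ordinal i
identity_alignment <- function(n, gene = "GENE1",
                               structure_id = "SYN1", chain_id = "A",
                               identity = 1.0) {
  list(gene = gene, structure_id = structure_id, chain_id = chain_id,
       identity = identity,
       pairs = data.frame(seq_pos = seq_len(n), chain_ordinal = seq_len(n)))
}

# construct a structure_chain directly from per-residue atom coordinate
# blocks (list of k x 3 matrices), for randomized multi-atom fixtures
chain_from_atoms <- function(atom_blocks, structure_id = "RAND",
                             chain_id = "A") {
  n <- length(atom_blocks)
  res <- data.frame(res_index = seq_len(n), resno = seq_len(n), insert = "",
                    resid = rep(c("ALA", "GLY", "SER"), length.out = n),
                    stringsAsFactors = FALSE)
  atom <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- atom_blocks[[i]]
    data.frame(res_index = i, elety = paste0("C", seq_len(nrow(b))),
               x = b[, 1], y = b[, 2], z = b[, 3],
               stringsAsFactors = FALSE)
  }))
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 res = res, atom = atom),
            class = "structure_chain")
}

# brute-force contact oracle: exhaustive all-atom-pair comparison
brute_contact_edges <- function(chain, cutoff = 5.0) {
  n <- nrow(chain$res)
  out <- NULL
  for (i in seq_len(n - 1)) {
    ai <- as.matrix(chain$atom[chain$atom$res_index == i, c("x", "y", "z")])
    for (j in (i + 1):n) {
      aj <- as.matrix(chain$atom[chain$atom$res_index == j,
                                 c("x", "y", "z")])
      mind <- Inf
      for (a in seq_len(nrow(ai))) {
        for (b in seq_len(nrow(aj))) {
          mind <- min(mind, sqrt(sum((ai[a, ] - aj[b, ])^2)))
        }
      }
      if (mind <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# independent p-value oracle: enumerate ALL n! labeled permutations of the
# (capped) count vector and count those whose maximum cluster score reaches
# the observed score. Distinct from the package's distinct-multiset
# enumeration in exact_pvalue().
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_permutations(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

labeled_perm_pvalue <- function(assessed, counts, all_clusters) {
  obs <- sum(counts[assessed$members])
  cap <- max(counts[assessed$members])
  capped <- pmin(counts, cap)
  P <- all_permutations(capped)
  hits <- 0L
  for (r in seq_len(nrow(P))) {
    mx <- max(vapply(all_clusters,
                     function(cl) sum(P[r, cl$members]), numeric(1)))
    if (mx >= obs) hits <- hits + 1L
  }
  hits / nrow(P)
}

# quick residue_counts builder from a named vector of seq position -> count
counts_object <- function(counts, aligned, gene = "GENE1") {
  structure(list(gene = gene,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 aligned_positions = sort(as.integer(aligned))),
            class = "residue_counts")
}

# minimal PDB text builder (fixed-width ATOM records)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          altloc = " ", icode = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), altloc, resname, chain, resno, icode,
          x, y, z, 1.0, 0.0, element)
}
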