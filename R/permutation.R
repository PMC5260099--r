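# The statistical core: capped decoy generation, the max-over-clusters
# permutation p-value, and an exact enumeration oracle for small problems.
#
# The null hypothesis is that per-residue mutated-sample counts are
# exchangeable across the aligned region of the structure. A decoy pattern
# is a uniformly random bijection of the observed (capped) count multiset
# onto the aligned positions. The exceedance event compares the observed
# score of the assessed cluster to the maximum decoy score over ALL
# candidate clusters, which makes the p-value family-wise with respect to
# clusters within one structure chain.

#' Cap per-residue counts
#'
#' Truncates every count above `cap` down to `cap`. Used before decoy
#' generation with `cap` set to the largest count inside the assessed
#' cluster, so that a dominant single-residue hotspot elsewhere in the gene
#' cannot dominate the decoy maxima and mask modest clusters.
#'
#' @param counts Numeric vector of per-position counts.
#' @param cap Positive integer cap.
#' @return `counts` with every entry bounded by `cap`.
#' @export
apply_cap <- function(counts, cap) {
  if (!is.numeric(cap) || length(cap) != 1L || cap < 1) {
    stop("cap must be a single integer >= 1 (an assessed cluster always ",
         "contains at least one mutation)")
  }
  pmin(counts, cap)
}

#' Draw one decoy mutational pattern
#'
#' Permutes the (capped) count vector uniformly at random over its
#' positions: a uniformly random bijection of the count multiset, zeros
#' included, onto the aligned region.
#'
#' @param capped_counts Numeric vector of capped counts over the aligned
#'   positions.
#' @param seed Optional integer seed for a reproducible draw.
#' @return Numeric vector, a permutation of `capped_counts`.
#' @export
sample_decoy <- function(capped_counts, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  capped_counts[sample.int(length(capped_counts))]
}

# zero-row frame with the test_structure() column layout
.empty_result_frame <- function() {
  out <- data.frame(
    gene = character(0), structure_id = character(0),
    chain_id = character(0), center = integer(0), center_seq = integer(0),
    n_members = integer(0), observed = numeric(0), cap = numeric(0),
    n_decoys = integer(0), n_exceed = integer(0), p_value = numeric(0),
    zero_exceed = logical(0), seed = integer(0),
    stringsAsFactors = FALSE
  )
  out$members <- list()
  out$seq_members <- list()
  out
}

# Deterministic per-(gene, cap) decoy-stream seed so results do not depend
# on the order in which genes/structures/clusters are processed.
.derive_seed <- function(seed, gene, cap) {
  g <- sum(utf8ToInt(paste(gene, collapse = "")))
  as.integer((as.double(seed) %% 2147483629 * 48271 +
                g * 1299709 + as.double(cap) * 104729) %% 2147483629)
}

# Maximum decoy cluster score for each of n_decoys decoys.
# members: list of integer vectors in aligned-space indices 1..n;
# capped: capped count vector over the n aligned positions.
.max_decoy_scores <- function(members, capped, n_decoys, batch = 20000L) {
  n <- length(capped)
  v <- capped[capped > 0]
  k <- length(v)
  if (k == 0L) return(numeric(n_decoys))
  M <- Matrix::sparseMatrix(
    i = rep.int(seq_along(members), lengths(members)),
    j = unlist(members), x = 1, dims = c(length(members), n)
  )
  out <- numeric(n_decoys)
  done <- 0L
  while (done < n_decoys) {
    B <- min(batch, n_decoys - done)
    idx <- vapply(seq_len(B), function(b) sample.int(n, k), integer(k))
    C <- Matrix::sparseMatrix(
      i = as.integer(idx), j = rep(seq_len(B), each = k),
      x = rep.int(v, B), dims = c(n, B)
    )
    S <- as.matrix(M %*% C)
    out[done + seq_len(B)] <- Reduce(pmax, asplit(S, 1))
    done <- done + B
  }
  out
}

#' Permutation p-value for one 3D cluster
#'
#' Monte Carlo estimate of the probability, under uniform shuffling of the
#' capped count multiset over the aligned positions, that any candidate
#' cluster scores at least as high as the assessed cluster's observed score
#' (inclusive comparison). The observed score is computed on uncapped
#' counts; since the cap equals the largest count within the assessed
#' cluster, capping never alters the assessed cluster's own members.
#'
#' @param cluster A `cluster3d`, the assessed cluster.
#' @param counts Integer vector of per-ordinal mutated-sample counts
#'   (uncapped), covering all cluster members.
#' @param all_clusters List of all candidate `cluster3d` on the chain (one
#'   per aligned residue); the decoy maximum is taken over these.
#' @param aligned Integer vector of aligned ordinals, the shuffle domain.
#'   Defaults to all positions of `counts`.
#' @param n_decoys Number of decoys (default 1e5).
#' @param seed Optional integer seed.
#' @param cap Cap applied to decoy counts. Defaults to the method's rule,
#'   the largest count among the assessed cluster's members; pass `Inf` to
#'   disable capping (diagnostic use, e.g. to quantify how much a dominant
#'   distant hotspot would mask the cluster).
#' @return A `cluster_test_result` list: `cluster`, `observed`, `cap`,
#'   `n_decoys`, `n_exceed`, `p_value`, and `zero_exceed` (TRUE when no
#'   decoy reached the observed score, in which case `p_value` is 0 and the
#'   result should be read as p below `1/n_decoys`; no smoothing applied).
#' @export
permutation_pvalue <- function(cluster, counts, all_clusters,
                               aligned = seq_along(counts),
                               n_decoys = 1e5, seed = NULL, cap = NULL) {
  stopifnot(inherits(cluster, "cluster3d"))
  if (n_decoys < 1) stop("n_decoys must be >= 1")
  obs <- cluster_score(cluster, counts)
  if (obs < 1) stop("assessed cluster has no mutations (observed score 0)")
  aligned <- sort(unique(as.integer(aligned)))
  mem_aligned <- lapply(all_clusters, function(cl) {
    m <- match(cl$members, aligned)
    if (anyNA(m)) stop("cluster members outside the aligned region")
    m
  })
  if (is.null(cap)) cap <- max(counts[cluster$members])
  capped <- apply_cap(counts[aligned], cap)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  mx <- .max_decoy_scores(mem_aligned, capped, n_decoys)
  n_exceed <- sum(mx >= obs)
  structure(
    list(cluster = cluster, observed = obs, cap = cap,
         n_decoys = as.integer(n_decoys), n_exceed = n_exceed,
         p_value = n_exceed / n_decoys, zero_exceed = n_exceed == 0L),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  p <- if (x$zero_exceed) paste0("< ", format(1 / x$n_decoys)) else
    format(x$p_value)
  cat("<cluster_test_result> center ", x$cluster$center, " observed ",
      x$observed, " cap ", x$cap, " p ", p, " (", x$n_exceed, "/",
      x$n_decoys, " decoys)\n", sep = "")
  invisible(x)
}

# All distinct permutations of a multiset, as a matrix (rows = placements).
# Counted first so callers can refuse oversized enumerations.
.count_multiset_perms <- function(v) {
  tab <- table(v)
  round(exp(lfactorial(length(v)) - sum(lfactorial(tab))))
}

.multiset_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  u <- unique(v)
  blocks <- lapply(u, function(val) {
    sub <- .multiset_perms(v[-match(val, v)])
    cbind(val, sub, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

#' Exact permutation p-value by enumeration
#'
#' Enumerates every distinct placement of the capped count multiset onto
#' the aligned positions and computes the exact probability that some
#' candidate cluster scores at least the assessed cluster's observed score.
#' This is the independent oracle for [permutation_pvalue()]; it refuses
#' when the number of distinct placements exceeds `max_placements`.
#'
#' @inheritParams permutation_pvalue
#' @param max_placements Combinatorial bound above which enumeration is
#'   refused (caller falls back to Monte Carlo).
#' @return Exact p-value as a fraction in `[0, 1]`.
#' @export
exact_pvalue <- function(cluster, counts, all_clusters,
                         aligned = seq_along(counts),
                         max_placements = 1e6) {
  stopifnot(inherits(cluster, "cluster3d"))
  obs <- cluster_score(cluster, counts)
  if (obs < 1) stop("assessed cluster has no mutations (observed score 0)")
  aligned <- sort(unique(as.integer(aligned)))
  mem_aligned <- lapply(all_clusters, function(cl) {
    m <- match(cl$members, aligned)
    if (anyNA(m)) stop("cluster members outside the aligned region")
    m
  })
  cap <- max(counts[cluster$members])
  capped <- apply_cap(counts[aligned], cap)
  np <- .count_multiset_perms(capped)
  if (np > max_placements) {
    stop("exact enumeration refused: ", format(np), " distinct placements ",
         "exceed max_placements = ", format(max_placements))
  }
  P <- .multiset_perms(capped)
  M <- matrix(0, length(mem_aligned), length(capped))
  for (j in seq_along(mem_aligned)) M[j, mem_aligned[[j]]] <- 1
  n_exceed <- 0L
  step <- 10000L
  for (s in seq(1L, nrow(P), by = step)) {
    e <- min(s + step - 1L, nrow(P))
    S <- M %*% t(P[s:e, , drop = FALSE])
    n_exceed <- n_exceed + sum(Reduce(pmax, asplit(S, 1)) >= obs)
  }
  n_exceed / nrow(P)
}

#' Test every mutated cluster on a structure chain
#'
#' Runs the full per-chain analysis: contact map, one candidate cluster per
#' aligned residue, observed scores from the mutated-sample counts, and a
#' capped max-over-clusters permutation p-value for every cluster with at
#' least one mutated sample. Decoys are regenerated per distinct cap value
#' (the cap depends on the assessed cluster); clusters sharing a cap share a
#' decoy stream, which is statistically identical and much faster. Decoy
#' streams are seeded by (gene, cap, seed), so results are independent of
#' processing order.
#'
#' @param chain A `structure_chain`.
#' @param alignment Alignment object for this chain (identity-filtered).
#' @param counts A `residue_counts` object for the gene.
#' @param cutoff Contact distance in Angstrom (default 5.0).
#' @param n_decoys Number of decoys per cap value (default 1e5).
#' @param seed Integer seed recorded in the results.
#' @return Data frame with one row per tested cluster: `gene`,
#'   `structure_id`, `chain_id`, `center` (ordinal), `center_seq`,
#'   `n_members`, `observed`, `cap`, `n_decoys`, `n_exceed`, `p_value`,
#'   `zero_exceed`, `seed`, plus list-columns `members` and `seq_members`.
#'   Empty (zero rows) when no aligned residue is mutated.
#' @export
test_structure <- function(chain, alignment, counts, cutoff = 5.0,
                           n_decoys = 1e5, seed = 1L) {
  stopifnot(inherits(chain, "structure_chain"),
            inherits(counts, "residue_counts"))
  if (n_decoys < 1) stop("n_decoys must be >= 1")
  validate_alignment(alignment)
  nres <- n_residues(chain)
  x <- ordinal_counts(counts, alignment, nres)
  aligned <- sort(unique(alignment$pairs$chain_ordinal))
  cmap <- compute_contact_map(chain, cutoff)
  clusters <- build_clusters(cmap, aligned, alignment)

  obs <- vapply(clusters, function(cl) sum(x[cl$members]), numeric(1))
  tested <- which(obs >= 1)
  if (length(tested) == 0L) return(.empty_result_frame())

  mem_aligned <- lapply(clusters, function(cl) match(cl$members, aligned))
  x_aligned <- x[aligned]
  caps <- vapply(tested, function(j) max(x[clusters[[j]]$members]),
                 numeric(1))
  n_exceed <- integer(length(tested))
  for (cap in sort(unique(caps))) {
    capped <- apply_cap(x_aligned, cap)
    set.seed(.derive_seed(seed, counts$gene, cap))
    mx <- .max_decoy_scores(mem_aligned, capped, n_decoys)
    grp <- which(caps == cap)
    for (g in grp) n_exceed[g] <- sum(mx >= obs[tested[g]])
  }
  ord2seq <- stats::setNames(alignment$pairs$seq_pos,
                             alignment$pairs$chain_ordinal)
  res <- data.frame(
    gene = counts$gene,
    structure_id = chain$structure_id,
    chain_id = chain$chain_id,
    center = vapply(clusters[tested], `[[`, integer(1), "center"),
    center_seq = as.integer(ord2seq[as.character(
      vapply(clusters[tested], `[[`, integer(1), "center"))]),
    n_members = vapply(clusters[tested],
                       function(cl) length(cl$members), integer(1)),
    observed = obs[tested],
    cap = caps,
    n_decoys = as.integer(n_decoys),
    n_exceed = n_exceed,
    p_value = n_exceed / n_decoys,
    zero_exceed = n_exceed == 0L,
    seed = as.integer(seed),
    stringsAsFactors = FALSE
  )
  res$members <- lapply(clusters[tested], `[[`, "members")
  res$seq_members <- lapply(clusters[tested], `[[`, "seq_members")
  rownames(res) <- NULL
  res
}
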