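# Cluster construction: one candidate cluster per residue (the residue plus
# its contact neighbors), scoring by mutated-sample counts, and
# deduplication of clusters that share a residue set in sequence space.

#' Build one candidate cluster per aligned residue
#'
#' Every aligned residue is used in turn as a cluster center; its cluster is
#' the center plus its contact neighbors, restricted to the aligned region
#' (only aligned residues are shuffled by the null, so unshuffleable
#' neighbors are excluded from scoring). Clusters are never merged: a
#' residue can belong to many clusters.
#'
#' @param cmap A `contact_map`.
#' @param aligned Integer vector of aligned residue ordinals (1-based).
#' @param alignment Optional alignment object; when given, each cluster also
#'   carries `seq_members`, the corresponding 1-based sequence positions.
#' @return List of `cluster3d` objects with elements `structure_id`,
#'   `chain_id`, `center`, `members` (sorted ordinals, always containing the
#'   center) and optionally `seq_members`.
#' @export
#' @examples
#' ch <- make_structure(6, geometry = "linear", spacing = 3.8)
#' cl <- build_clusters(compute_contact_map(ch), aligned = 1:6)
#' cl[[3]]$members   # residue 3 with neighbors 2 and 4
build_clusters <- function(cmap, aligned, alignment = NULL) {
  stopifnot(inherits(cmap, "contact_map"))
  aligned <- sort(unique(as.integer(aligned)))
  if (length(aligned) == 0L) stop("aligned set must be non-empty")
  if (any(aligned < 1L | aligned > cmap$n_res)) {
    stop("aligned ordinals outside [1, ", cmap$n_res, "]")
  }
  adj <- .adjacency_list(cmap)
  ord2seq <- NULL
  if (!is.null(alignment)) {
    validate_alignment(alignment)
    ord2seq <- stats::setNames(alignment$pairs$seq_pos,
                               alignment$pairs$chain_ordinal)
  }
  in_aligned <- logical(cmap$n_res)
  in_aligned[aligned] <- TRUE
  lapply(aligned, function(center) {
    nb <- adj[[center]]
    members <- sort(c(center, nb[in_aligned[nb]]))
    cl <- list(structure_id = cmap$structure_id, chain_id = cmap$chain_id,
               center = center, members = members)
    if (!is.null(ord2seq)) {
      cl$seq_members <- sort(unname(ord2seq[as.character(members)]))
    }
    structure(cl, class = "cluster3d")
  })
}

#' @export
print.cluster3d <- function(x, ...) {
  cat("<cluster3d> ", x$structure_id, ":", x$chain_id, " center ", x$center,
      " members {", paste(x$members, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Score a cluster by mutated samples
#'
#' The score of a cluster is the sum, over its member residues, of the
#' number of distinct mutated samples at each residue.
#'
#' @param cluster A `cluster3d`.
#' @param counts Integer vector of per-ordinal mutated-sample counts (as
#'   from [ordinal_counts()]), of length at least `max(cluster$members)`.
#' @return Integer score.
#' @export
cluster_score <- function(cluster, counts) {
  stopifnot(inherits(cluster, "cluster3d"))
  if (max(cluster$members) > length(counts)) {
    stop("counts vector shorter than cluster members")
  }
  sum(counts[cluster$members])
}

#' Deduplicate clusters by sequence residue set
#'
#' Clusters from different structures with the same gene and the same set of
#' sequence positions are counted as one unique cluster. Input is a result
#' table (as from [test_structure()] or a row-bound set of them); the
#' representative of each unique key is the row with the minimum p-value,
#' and the provenance of all contributing structure chains is retained.
#'
#' @param results Data frame of cluster test results with columns `gene`,
#'   `structure_id`, `chain_id`, `p_value` and list-column `seq_members`.
#' @return Data frame with one row per unique (gene, residue-set) key,
#'   ordered by gene then p-value, with a list-column `structures` of
#'   contributing `"structure:chain"` labels.
#' @export
dedupe_unique_clusters <- function(results) {
  if (nrow(results) == 0L) {
    results$structures <- list()
    return(results)
  }
  key <- paste(results$gene,
               vapply(results$seq_members,
                      function(v) paste(sort(v), collapse = ","), ""),
               sep = "\r")
  # provenance: prior `structures` lists (when re-deduping) or the rows' own
  # structure:chain labels; unioned per key so dedupe is idempotent
  prov <- if ("structures" %in% names(results)) {
    results$structures
  } else {
    as.list(paste0(results$structure_id, ":", results$chain_id))
  }
  lab <- paste0(results$structure_id, ":", results$chain_id)
  # stable representative: minimum p-value within key, ties broken by
  # provenance label, so the result is independent of input order
  ord <- order(key, results$p_value, lab)
  r <- results[ord, , drop = FALSE]
  k <- key[ord]
  p <- prov[ord]
  first <- !duplicated(k)
  out <- r[first, , drop = FALSE]
  prov_by_key <- lapply(split(p, k), function(v) sort(unique(unlist(v))))
  out$structures <- prov_by_key[k[first]]
  out <- out[order(out$gene, out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
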