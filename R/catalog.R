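# Catalog assembly: significance filtering, unique-cluster deduplication,
# residue categorization relative to an external single-residue hotspot
# list, gene/sample summaries, and TSV/JSON exports.

#' Assemble the catalog of significant unique clusters
#'
#' Filters cluster test results at the significance threshold and collapses
#' clusters with the same gene and the same sequence residue set into one
#' unique catalog entry, keeping the minimum p-value across contributing
#' structures as the representative statistic.
#'
#' The threshold defaults to 0.05 but is an explicit analysis choice and is
#' recorded on the returned object.
#'
#' @param results Cluster test results ([test_structure()] rows, possibly
#'   row-bound across genes and structures).
#' @param alpha Significance threshold on the permutation p-value
#'   (inclusive).
#' @param mutations Optional mutation data frame; when given, each entry is
#'   annotated with per-residue mutated-sample counts, reference amino
#'   acids, and the cancer-type breakdown of its samples.
#' @return A `cluster_catalog`: data frame with one row per unique cluster
#'   (`gene`, `p_value`, list-columns `seq_members` and `structures`, and
#'   when `mutations` is given `residue_counts`, `residue_ref` and
#'   `cancer_types` list-columns), with attribute `alpha`.
#' @export
significant_clusters <- function(results, alpha = 0.05, mutations = NULL) {
  keep <- results[results$p_value <= alpha, , drop = FALSE]
  cat_df <- dedupe_unique_clusters(keep)
  if (!is.null(mutations) && nrow(cat_df) > 0L) {
    mis <- mutations[mutations$variant_class == "missense", , drop = FALSE]
    cat_df$residue_counts <- vector("list", nrow(cat_df))
    cat_df$residue_ref <- vector("list", nrow(cat_df))
    cat_df$cancer_types <- vector("list", nrow(cat_df))
    for (r in seq_len(nrow(cat_df))) {
      g <- cat_df$gene[r]
      pos <- sort(cat_df$seq_members[[r]])
      m <- mis[mis$gene == g & mis$protein_position %in% pos, , drop = FALSE]
      sp <- unique(m[, c("sample_id", "protein_position")])
      tab <- table(factor(sp$protein_position, levels = pos))
      cat_df$residue_counts[[r]] <- stats::setNames(as.integer(tab), pos)
      refs <- vapply(pos, function(p) {
        rr <- m$ref_aa[m$protein_position == p]
        if (length(rr)) names(sort(table(rr), decreasing = TRUE))[1L] else "X"
      }, character(1))
      cat_df$residue_ref[[r]] <- stats::setNames(refs, pos)
      ct <- table(unique(m[, c("sample_id", "cancer_type")])$cancer_type)
      cat_df$cancer_types[[r]] <-
        stats::setNames(as.integer(ct), names(ct))
    }
  }
  attr(cat_df, "alpha") <- alpha
  class(cat_df) <- c("cluster_catalog", class(cat_df))
  cat_df
}

#' @export
print.cluster_catalog <- function(x, ...) {
  cat("<cluster_catalog> ", nrow(x), " unique significant clusters in ",
      length(unique(x$gene)), " gene(s), alpha = ",
      attr(x, "alpha"), "\n", sep = "")
  if (nrow(x)) {
    show <- data.frame(
      gene = x$gene,
      members = vapply(x$seq_members,
                       function(v) paste(sort(v), collapse = ","), ""),
      p_value = x$p_value
    )
    print(utils::head(show, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Classify catalog residues against a single-residue hotspot list
#'
#' Assigns each residue appearing in the catalog to one of three
#' categories: 1 — the residue is itself a single-residue hotspot (the
#' hotspot list is an external input, produced by a frequency-based
#' method); 2 — a rarely mutated residue that shares at least one
#' significant cluster with a hotspot residue; 3 — a rarely mutated residue
#' clustering only with other rarely mutated residues. A residue in
#' category 2 in one cluster and category 3 in another is classified as
#' category 2.
#'
#' @param catalog A `cluster_catalog`.
#' @param hotspot_list Data frame with columns `gene` and `position`, or a
#'   character vector of `"GENE:position"` labels.
#' @return The catalog with an added list-column `categories` (integer
#'   vector parallel to `seq_members`) and attribute `residue_categories`,
#'   a data frame (`gene`, `position`, `category`) with one row per
#'   distinct catalog residue.
#' @export
classify_residues <- function(catalog, hotspot_list) {
  if (is.character(hotspot_list)) {
    sp <- strsplit(hotspot_list, ":", fixed = TRUE)
    hotspot_list <- data.frame(
      gene = vapply(sp, `[[`, "", 1L),
      position = as.integer(vapply(sp, `[[`, "", 2L))
    )
  }
  hk <- paste(hotspot_list$gene, hotspot_list$position)
  n <- nrow(catalog)
  catalog$categories <- vector("list", n)
  best <- new.env(parent = emptyenv())  # residue key -> lowest category
  for (r in seq_len(n)) {
    pos <- catalog$seq_members[[r]]
    keys <- paste(catalog$gene[r], pos)
    is_hot <- keys %in% hk
    cat_r <- ifelse(is_hot, 1L, if (any(is_hot)) 2L else 3L)
    catalog$categories[[r]] <- stats::setNames(as.integer(cat_r), pos)
    for (i in seq_along(keys)) {
      prev <- best[[keys[i]]]
      if (is.null(prev) || cat_r[i] < prev) best[[keys[i]]] <- cat_r[i]
    }
  }
  # cross-cluster tie-break: the residue-level category is the lowest over
  # all clusters containing it; rewrite per-cluster vectors accordingly
  for (r in seq_len(n)) {
    keys <- paste(catalog$gene[r], catalog$seq_members[[r]])
    catalog$categories[[r]][] <-
      vapply(keys, function(k) best[[k]], integer(1))
  }
  res_keys <- ls(best)
  sp <- strsplit(res_keys, " ", fixed = TRUE)
  residues <- data.frame(
    gene = vapply(sp, `[[`, "", 1L),
    position = as.integer(vapply(sp, `[[`, "", 2L)),
    category = vapply(res_keys, function(k) best[[k]], integer(1))
  )
  residues <- residues[order(residues$gene, residues$position), ]
  rownames(residues) <- NULL
  attr(catalog, "residue_categories") <- residues
  catalog
}

#' Residue-level category table of a classified catalog
#' @param catalog A catalog returned by [classify_residues()].
#' @return Data frame with `gene`, `position`, `category`.
#' @export
residue_categories <- function(catalog) {
  rc <- attr(catalog, "residue_categories")
  if (is.null(rc)) stop("catalog has not been classified; ",
                        "run classify_residues() first")
  rc
}

#' Gene and sample summaries of a catalog
#'
#' Per gene: the number of distinct residues in significant clusters and
#' the fraction of cohort samples carrying at least one missense mutation
#' at those residues. Per sample: the lowest (most significant) residue
#' category among its cluster mutations — a sample with both a category-1
#' and a category-3 mutation is a category-1 sample.
#'
#' @param catalog A classified `cluster_catalog`.
#' @param mutations Mutation data frame for the cohort.
#' @param n_samples Cohort size for prevalence denominators; defaults to
#'   the number of distinct samples in `mutations`.
#' @return List with `genes` (data frame: `gene`, `n_residues`,
#'   `n_samples`, `prevalence`), `samples` (data frame: `sample_id`,
#'   `category`), and `overall_prevalence` (fraction of cohort samples with
#'   any cluster mutation).
#' @export
summarize_catalog <- function(catalog, mutations, n_samples = NULL) {
  rc <- residue_categories(catalog)
  if (is.null(n_samples)) n_samples <- length(unique(mutations$sample_id))
  mis <- mutations[mutations$variant_class == "missense", , drop = FALSE]
  key <- paste(mis$gene, mis$protein_position)
  rkey <- paste(rc$gene, rc$position)
  hit <- mis[key %in% rkey, , drop = FALSE]
  genes <- unique(rc$gene)
  gene_df <- data.frame(
    gene = genes,
    n_residues = vapply(genes, function(g) sum(rc$gene == g), integer(1)),
    n_samples = vapply(genes, function(g) {
      length(unique(hit$sample_id[hit$gene == g]))
    }, integer(1))
  )
  gene_df$prevalence <- if (n_samples > 0) gene_df$n_samples / n_samples
    else numeric(nrow(gene_df))
  gene_df <- gene_df[order(-gene_df$n_residues, gene_df$gene), ]
  rownames(gene_df) <- NULL
  samp <- character(0)
  scat <- integer(0)
  if (nrow(hit) > 0L) {
    hcat <- rc$category[match(paste(hit$gene, hit$protein_position), rkey)]
    agg <- tapply(hcat, hit$sample_id, min)
    samp <- names(agg)
    scat <- as.integer(agg)
  }
  list(
    genes = gene_df,
    samples = data.frame(sample_id = samp, category = scat),
    overall_prevalence = if (n_samples > 0) length(samp) / n_samples else 0
  )
}

# "R248(9)" style member label: ref amino acid + position + sample count
.member_label <- function(ref, pos, count) sprintf("%s%d(%d)", ref, pos, count)

#' Export a catalog to TSV or JSON
#'
#' TSV export writes two files: `<prefix>_clusters.tsv`, one row per unique
#' cluster with members formatted as `"R248(9) S249(18) P250(1)"` (reference
#' amino acid, position, mutated-sample count), and `<prefix>_residues.tsv`,
#' one row per catalog residue with its category. JSON export writes the
#' same content to a single machine-readable file; [import_catalog_json()]
#' restores it.
#'
#' @param catalog A classified, annotated `cluster_catalog` (see
#'   [significant_clusters()] with `mutations`, then [classify_residues()]).
#' @param path For `format = "json"` the output file; for `format = "tsv"`
#'   the path prefix.
#' @param format `"tsv"` or `"json"`.
#' @return Character vector of the files written, invisibly.
#' @export
export_catalog <- function(catalog, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rc <- residue_categories(catalog)
  n <- nrow(catalog)
  member_str <- vapply(seq_len(n), function(r) {
    pos <- sort(catalog$seq_members[[r]])
    cnt <- catalog$residue_counts[[r]]
    ref <- catalog$residue_ref[[r]]
    if (is.null(cnt)) cnt <- stats::setNames(rep(NA_integer_, length(pos)), pos)
    if (is.null(ref)) ref <- stats::setNames(rep("X", length(pos)), pos)
    paste(.member_label(ref[as.character(pos)], pos,
                        cnt[as.character(pos)]), collapse = " ")
  }, character(1))
  clusters <- data.frame(
    gene = catalog$gene,
    members = member_str,
    p_value = catalog$p_value,
    structures = vapply(catalog$structures, paste, "", collapse = ";"),
    categories = vapply(seq_len(n), function(r) {
      paste(catalog$categories[[r]], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if (format == "tsv") {
    fc <- paste0(path, "_clusters.tsv")
    fr <- paste0(path, "_residues.tsv")
    utils::write.table(clusters, fc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(rc, fr, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(c(fc, fr)))
  }
  obj <- list(
    alpha = attr(catalog, "alpha"),
    clusters = lapply(seq_len(n), function(r) {
      list(
        gene = catalog$gene[r],
        seq_members = sort(catalog$seq_members[[r]]),
        p_value = catalog$p_value[r],
        structures = catalog$structures[[r]],
        categories = unname(catalog$categories[[r]][
          as.character(sort(catalog$seq_members[[r]]))]),
        residue_counts = if (!is.null(catalog$residue_counts[[r]]))
          unname(catalog$residue_counts[[r]][
            as.character(sort(catalog$seq_members[[r]]))]),
        residue_ref = if (!is.null(catalog$residue_ref[[r]]))
          unname(catalog$residue_ref[[r]][
            as.character(sort(catalog$seq_members[[r]]))])
      )
    }),
    residues = rc
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Re-import a JSON catalog export
#'
#' Restores a `cluster_catalog` (with classification attributes) from a
#' file written by [export_catalog()] with `format = "json"`.
#'
#' @param path JSON file path.
#' @return A classified `cluster_catalog`.
#' @export
import_catalog_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cl <- obj$clusters
  n <- length(cl)
  out <- data.frame(
    gene = vapply(cl, function(x) x$gene, ""),
    p_value = vapply(cl, function(x) as.numeric(x$p_value), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$seq_members <- lapply(cl, function(x)
    as.integer(unlist(x$seq_members)))
  out$structures <- lapply(cl, function(x) unlist(x$structures))
  out$categories <- lapply(cl, function(x) {
    stats::setNames(as.integer(unlist(x$categories)),
                    as.integer(unlist(x$seq_members)))
  })
  out$residue_counts <- lapply(cl, function(x) {
    if (is.null(x$residue_counts)) NULL else
      stats::setNames(as.integer(unlist(x$residue_counts)),
                      as.integer(unlist(x$seq_members)))
  })
  out$residue_ref <- lapply(cl, function(x) {
    if (is.null(x$residue_ref)) NULL else
      stats::setNames(as.character(unlist(x$residue_ref)),
                      as.integer(unlist(x$seq_members)))
  })
  attr(out, "alpha") <- as.numeric(obj$alpha)
  rs <- obj$residues
  attr(out, "residue_categories") <- data.frame(
    gene = vapply(rs, function(x) x$gene, ""),
    position = vapply(rs, function(x) as.integer(x$position), integer(1)),
    category = vapply(rs, function(x) as.integer(x$category), integer(1))
  )
  class(out) <- c("cluster_catalog", class(out))
  out
}
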