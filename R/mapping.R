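# Mutation and alignment input handling: MAF-like tables, sequence-to-
# structure alignments, the germline and expression filters, and the
# per-residue mutated-sample counts that feed cluster scoring.

.VARIANT_CLASSES <- c("missense", "nonsense", "silent", "splice",
                      "frameshift", "inframe_indel", "other")

.MUTATION_COLS <- c("sample_id", "gene", "protein_position",
                    "ref_aa", "alt_aa", "variant_class", "cancer_type")

#' Load a MAF-like mutation table
#'
#' Reads a tab-separated table of protein-level somatic mutations. Required
#' columns: `sample_id`, `gene`, `protein_position` (1-based on the
#' canonical isoform), `ref_aa`, `alt_aa`, `variant_class`, `cancer_type`.
#' Rows with non-integer positions (e.g. indel ranges like `"12_13"`) or
#' variant classes outside the supported vocabulary are rejected with
#' row-numbered errors.
#'
#' @param path Path to the TSV file.
#' @return Data frame of mutation records, one per row of the input.
#' @export
load_mutations <- function(path) {
  if (!file.exists(path)) stop("mutation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(.MUTATION_COLS, names(df))
  if (length(missing)) {
    stop("mutation table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df <- df[, .MUTATION_COLS]
  if (nrow(df) == 0L) {
    df$protein_position <- integer(0)
    return(df)
  }
  pos <- suppressWarnings(as.integer(df$protein_position))
  bad <- which(is.na(pos) | pos < 1 |
                 as.character(pos) != trimws(df$protein_position))
  if (length(bad)) {
    stop("mutation table row error (protein_position must be a single ",
         "1-based integer; indel ranges are unsupported) at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  badv <- which(!(df$variant_class %in% .VARIANT_CLASSES))
  if (length(badv)) {
    stop("mutation table row error (unknown variant_class) at row(s): ",
         paste(utils::head(badv, 10L), collapse = ", "))
  }
  df$protein_position <- pos
  df
}

#' Load sequence-to-structure alignments
#'
#' Reads the long-format alignment TSV (columns `gene`, `structure_id`,
#' `chain_id`, `identity`, `seq_pos`, `chain_ordinal`) and groups it into
#' one alignment object per (gene, structure, chain). Position pairs must be
#' one-to-one in both coordinates within an alignment.
#'
#' @param path Path to the TSV file.
#' @return List of alignment objects, each a list with `gene`,
#'   `structure_id`, `chain_id`, `identity` and `pairs` (data frame with
#'   `seq_pos`, `chain_ordinal`).
#' @export
load_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "structure_id", "chain_id", "identity",
            "seq_pos", "chain_ordinal")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("alignment table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$gene, df$structure_id, df$chain_id, sep = "\r")
  lapply(split(df, key), function(g) {
    aln <- list(
      gene = g$gene[1L], structure_id = g$structure_id[1L],
      chain_id = g$chain_id[1L], identity = g$identity[1L],
      pairs = data.frame(seq_pos = as.integer(g$seq_pos),
                         chain_ordinal = as.integer(g$chain_ordinal))
    )
    validate_alignment(aln)
  })
}

#' Validate an alignment object
#' @param aln Alignment list as produced by [load_alignments()].
#' @return `aln`, invisibly checked.
#' @export
validate_alignment <- function(aln) {
  stopifnot(is.list(aln),
            all(c("gene", "identity", "pairs") %in% names(aln)))
  if (aln$identity < 0 || aln$identity > 1) {
    stop("alignment identity must lie in [0, 1]: ", aln$identity)
  }
  p <- aln$pairs
  if (anyDuplicated(p$seq_pos) || anyDuplicated(p$chain_ordinal)) {
    stop("alignment pairs must be one-to-one in both coordinates (",
         aln$gene, " ", aln$structure_id, ":", aln$chain_id, ")")
  }
  aln
}

#' Filter alignments by sequence identity
#'
#' Retains alignments whose sequence identity is at or above the threshold.
#' The default of 0.90 restricts analysis to near-identical
#' sequence-to-structure mappings, so mutations can be transferred onto the
#' structure without homology-model uncertainty.
#'
#' @param alignments List of alignment objects.
#' @param min_identity Minimum identity fraction to retain (default 0.90).
#' @return Filtered list.
#' @export
filter_alignments <- function(alignments, min_identity = 0.90) {
  Filter(function(a) a$identity >= min_identity, alignments)
}

.variant_key <- function(gene, position, ref, alt) {
  paste(gene, position, ref, alt, sep = "\r")
}

#' Remove likely germline variants misreported as somatic
#'
#' Drops mutations that appear in both the 1000 Genomes and ESP population
#' variant lists, and mutations seen in two or more 1000 Genomes samples
#' regardless of ESP. Matching is on (gene, protein position, ref, alt);
#' the inputs here are protein-level, so population variants must be given
#' in the same protein coordinates.
#'
#' @param mutations Mutation data frame ([load_mutations()] layout).
#' @param thousand_genomes Data frame with columns `gene`, `position`,
#'   `ref`, `alt`, `n_samples` (observation count in 1000 Genomes).
#' @param esp Data frame with columns `gene`, `position`, `ref`, `alt`.
#' @return Filtered mutation data frame.
#' @export
filter_germline <- function(mutations, thousand_genomes, esp) {
  if (nrow(mutations) == 0L) return(mutations)
  mk <- .variant_key(mutations$gene, mutations$protein_position,
                     mutations$ref_aa, mutations$alt_aa)
  kg <- .variant_key(thousand_genomes$gene, thousand_genomes$position,
                     thousand_genomes$ref, thousand_genomes$alt)
  ke <- .variant_key(esp$gene, esp$position, esp$ref, esp$alt)
  in_both <- mk %in% kg & mk %in% ke
  recurrent_kg <- kg[thousand_genomes$n_samples >= 2]
  drop <- in_both | mk %in% recurrent_kg
  out <- mutations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove mutations in unexpressed genes
#'
#' For a mutation whose cancer type has expression data, the mutation is
#' dropped when the gene has TPM below 0.1 in at least 90 percent of the
#' tumors of that type. For cancer types without expression data, the
#' fallback drops the mutation when more than 95 percent of all expression
#' tumors have TPM below 0.1 for that gene. Genes absent from the expression
#' matrix are kept (no evidence either way).
#'
#' @param mutations Mutation data frame.
#' @param expression Numeric gene x sample TPM matrix (rownames = genes,
#'   colnames = expression sample ids).
#' @param expression_types Character vector of cancer-type labels for the
#'   expression samples, parallel to `colnames(expression)` (or named by
#'   them).
#' @param covered_types Cancer types considered to have expression data;
#'   defaults to the types present in `expression_types`.
#' @param tpm_threshold,type_fraction,global_fraction The filter constants:
#'   TPM cutoff 0.1, within-type fraction 0.90 (inclusive), all-tumor
#'   fallback fraction 0.95 (exclusive).
#' @return Filtered mutation data frame.
#' @export
filter_expression <- function(mutations, expression, expression_types,
                              covered_types = unique(expression_types),
                              tpm_threshold = 0.1,
                              type_fraction = 0.90,
                              global_fraction = 0.95) {
  if (nrow(mutations) == 0L) return(mutations)
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  if (any(expression < 0)) stop("expression TPM values must be non-negative")
  if (!is.null(names(expression_types))) {
    expression_types <- expression_types[colnames(expression)]
  }
  stopifnot(length(expression_types) == ncol(expression))

  low <- expression < tpm_threshold
  genes <- rownames(expression)
  # per-type and overall fractions of tumors with TPM below threshold
  frac_by_type <- vapply(unique(expression_types), function(tt) {
    rowMeans(low[, expression_types == tt, drop = FALSE])
  }, numeric(nrow(expression)))
  if (is.null(dim(frac_by_type))) {
    frac_by_type <- matrix(frac_by_type, ncol = 1,
                           dimnames = list(genes, unique(expression_types)))
  }
  frac_all <- rowMeans(low)

  gi <- match(mutations$gene, genes)
  drop <- logical(nrow(mutations))
  covered <- mutations$cancer_type %in% covered_types &
    mutations$cancer_type %in% colnames(frac_by_type)
  has_gene <- !is.na(gi)
  idx <- which(has_gene & covered)
  if (length(idx)) {
    drop[idx] <- frac_by_type[cbind(gi[idx],
                                    match(mutations$cancer_type[idx],
                                          colnames(frac_by_type)))] >=
      type_fraction
  }
  idx <- which(has_gene & !covered)
  if (length(idx)) {
    drop[idx] <- frac_all[gi[idx]] > global_fraction
  }
  out <- mutations[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue mutated-sample counts for one gene
#'
#' Counts, at each protein position of the gene, the number of distinct
#' tumor samples with at least one missense mutation there. Multiple
#' missense alleles in one sample at one position count once (counts are
#' mutated samples, not mutation events). Non-missense records are ignored.
#'
#' @param mutations Mutation data frame.
#' @param gene Gene symbol.
#' @param alignment Alignment object for this gene (identity-filtered); its
#'   `seq_pos` set defines `aligned_positions`.
#' @return A `residue_counts` object: list with `gene`, `counts` (named
#'   integer vector, names = 1-based sequence positions, all entries >= 1)
#'   and `aligned_positions` (sorted integer vector). Positions outside the
#'   alignment stay in `counts` but not in `aligned_positions`.
#' @export
residue_counts <- function(mutations, gene, alignment) {
  validate_alignment(alignment)
  m <- mutations[mutations$gene == gene &
                   mutations$variant_class == "missense", , drop = FALSE]
  aligned <- sort(unique(alignment$pairs$seq_pos))
  if (nrow(m) == 0L) {
    return(structure(list(gene = gene,
                          counts = stats::setNames(integer(0), character(0)),
                          aligned_positions = aligned),
                     class = "residue_counts"))
  }
  pairs <- unique(m[, c("sample_id", "protein_position")])
  tab <- table(pairs$protein_position)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[order(as.integer(names(counts)))]
  structure(list(gene = gene, counts = counts, aligned_positions = aligned),
            class = "residue_counts")
}

#' @export
print.residue_counts <- function(x, ...) {
  cat("<residue_counts> ", x$gene, " — ", length(x$counts),
      " mutated positions (", sum(x$counts), " mutated samples), ",
      length(x$aligned_positions), " aligned positions\n", sep = "")
  invisible(x)
}

#' Project residue counts onto structure ordinals
#'
#' Maps sequence-position counts through an alignment's one-to-one pairs
#' onto 1-based chain ordinals, yielding the count vector over the aligned
#' region that the permutation null shuffles. Counted positions outside the
#' alignment are excluded.
#'
#' @param counts A `residue_counts` object.
#' @param alignment Alignment object.
#' @param n_res Number of residues in the structure chain.
#' @return Integer vector of length `n_res`; zero outside the aligned region
#'   and at unmutated aligned positions.
#' @export
ordinal_counts <- function(counts, alignment, n_res) {
  stopifnot(inherits(counts, "residue_counts"))
  validate_alignment(alignment)
  x <- integer(n_res)
  if (length(counts$counts) == 0L) return(x)
  p <- alignment$pairs
  if (any(p$chain_ordinal < 1L | p$chain_ordinal > n_res)) {
    stop("alignment chain_ordinal outside [1, n_res]")
  }
  hit <- match(as.integer(names(counts$counts)), p$seq_pos)
  ok <- !is.na(hit)
  x[p$chain_ordinal[hit[ok]]] <- counts$counts[ok]
  x
}
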