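# End-to-end pipeline: configuration, input wiring, per-gene/chain testing,
# catalog assembly and export, with a stage-count run report.

#' Build a run configuration
#'
#' Collects the analysis constants and input paths for [run_end_to_end()].
#' Defaults are the method's standard operating point: 5 Angstrom contact
#' cutoff, 90 percent minimum alignment identity, 1e5 decoys, significance
#' threshold 0.05.
#'
#' @param mutations Path to the MAF-like mutation TSV (required).
#' @param alignments Path to the alignment TSV (required).
#' @param structures Directory containing PDB files named
#'   `<structure_id>.pdb`, or a named character vector of PDB paths.
#' @param thousand_genomes,esp Optional germline blacklist TSVs (columns
#'   `gene`, `position`, `ref`, `alt`[, `n_samples`]).
#' @param expression Optional expression TSV (genes x samples, TPM; first
#'   column gene).
#' @param expression_types Optional TSV mapping expression samples to
#'   cancer types (columns `sample_id`, `cancer_type`).
#' @param hotspots Optional single-residue hotspot TSV (columns `gene`,
#'   `position`).
#' @param out_dir Output directory.
#' @param cutoff,min_identity,n_decoys,alpha,seed Analysis constants.
#' @return A `run_config` list.
#' @export
run_config <- function(mutations, alignments, structures,
                       thousand_genomes = NULL, esp = NULL,
                       expression = NULL, expression_types = NULL,
                       hotspots = NULL, out_dir = "mutclust3d_out",
                       cutoff = 5.0, min_identity = 0.90,
                       n_decoys = 1e5, alpha = 0.05, seed = 1L) {
  stopifnot(cutoff > 0, min_identity >= 0, min_identity <= 1,
            n_decoys >= 1, alpha > 0, alpha <= 1)
  structure(
    list(mutations = mutations, alignments = alignments,
         structures = structures, thousand_genomes = thousand_genomes,
         esp = esp, expression = expression,
         expression_types = expression_types, hotspots = hotspots,
         out_dir = out_dir, cutoff = cutoff, min_identity = min_identity,
         n_decoys = n_decoys, alpha = alpha, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

.read_optional_tsv <- function(path) {
  if (is.null(path)) return(NULL)
  if (!file.exists(path)) stop("configured input not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full 3D-cluster detection pipeline
#'
#' Loads mutations and alignments, applies the identity, germline and
#' expression filters, computes contact maps and clusters for every
#' (gene, structure chain) alignment, runs the capped max-over-clusters
#' permutation test, assembles the significant-cluster catalog (classified
#' when a hotspot list is configured), and writes the catalog TSVs, a JSON
#' export and a JSON run report with counts at every stage.
#'
#' Structure chains that fail to parse are logged and skipped; the run
#' continues.
#'
#' @param config A `run_config`.
#' @param quiet Suppress progress messages.
#' @return List with `catalog`, `results` (all tested clusters), `report`
#'   (stage counts) and `files` (paths written), invisibly.
#' @export
run_end_to_end <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  report <- list(seed = config$seed, alpha = config$alpha,
                 cutoff = config$cutoff, min_identity = config$min_identity,
                 n_decoys = config$n_decoys)

  mut <- load_mutations(config$mutations)
  report$mutations_loaded <- nrow(mut)

  if (!is.null(config$thousand_genomes) || !is.null(config$esp)) {
    kg <- .read_optional_tsv(config$thousand_genomes)
    esp <- .read_optional_tsv(config$esp)
    if (is.null(kg)) kg <- data.frame(gene = character(0),
                                      position = integer(0),
                                      ref = character(0),
                                      alt = character(0),
                                      n_samples = integer(0))
    if (is.null(esp)) esp <- data.frame(gene = character(0),
                                        position = integer(0),
                                        ref = character(0),
                                        alt = character(0))
    n0 <- nrow(mut)
    mut <- filter_germline(mut, kg, esp)
    report$mutations_removed_germline <- n0 - nrow(mut)
  } else {
    report$mutations_removed_germline <- 0L
  }

  if (!is.null(config$expression)) {
    ex <- .read_optional_tsv(config$expression)
    em <- as.matrix(ex[, -1, drop = FALSE])
    rownames(em) <- ex[[1]]
    tm <- .read_optional_tsv(config$expression_types)
    if (is.null(tm)) stop("expression configured without expression_types")
    types <- stats::setNames(tm$cancer_type, tm$sample_id)
    n0 <- nrow(mut)
    mut <- filter_expression(mut, em, types[colnames(em)])
    report$mutations_removed_expression <- n0 - nrow(mut)
  } else {
    report$mutations_removed_expression <- 0L
  }
  report$mutations_analyzed <- nrow(mut)

  alns <- load_alignments(config$alignments)
  report$alignments_loaded <- length(alns)
  alns <- filter_alignments(alns, config$min_identity)
  report$alignments_passing_identity <- length(alns)

  structure_path <- function(sid) {
    if (is.character(config$structures) && !is.null(names(config$structures))
        && sid %in% names(config$structures)) {
      return(config$structures[[sid]])
    }
    file.path(config$structures, paste0(sid, ".pdb"))
  }

  results <- list()
  tested_chains <- 0L
  failed_chains <- 0L
  for (aln in alns) {
    path <- structure_path(aln$structure_id)
    chains <- tryCatch(read_pdb(path, structure_id = aln$structure_id),
                       error = function(e) {
                         warning("skipping ", aln$structure_id, ": ",
                                 conditionMessage(e))
                         NULL
                       })
    if (is.null(chains) || !(aln$chain_id %in% names(chains))) {
      failed_chains <- failed_chains + 1L
      next
    }
    chain <- chains[[aln$chain_id]]
    cnt <- residue_counts(mut, aln$gene, aln)
    res <- test_structure(chain, aln, cnt, cutoff = config$cutoff,
                          n_decoys = config$n_decoys, seed = config$seed)
    tested_chains <- tested_chains + 1L
    if (nrow(res)) results[[length(results) + 1L]] <- res
    say("tested ", aln$gene, " on ", aln$structure_id, ":", aln$chain_id,
        " — ", nrow(res), " mutated clusters")
  }
  report$chains_tested <- tested_chains
  report$chains_failed <- failed_chains

  all_res <- if (length(results)) do.call(rbind, results) else
    .empty_result_frame()
  report$clusters_tested <- nrow(all_res)

  catalog <- significant_clusters(all_res, alpha = config$alpha,
                                  mutations = mut)
  report$clusters_significant_unique <- nrow(catalog)

  hs <- .read_optional_tsv(config$hotspots)
  if (!is.null(hs)) {
    catalog <- classify_residues(catalog, hs)
  } else {
    catalog <- classify_residues(catalog,
                                 data.frame(gene = character(0),
                                            position = integer(0)))
  }
  report$catalog_residues <- nrow(residue_categories(catalog))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    export_catalog(catalog, file.path(config$out_dir, "catalog"),
                   format = "tsv"),
    export_catalog(catalog, file.path(config$out_dir, "catalog.json"),
                   format = "json")
  )
  report_path <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, report_path)
  say("catalog: ", report$clusters_significant_unique,
      " unique significant clusters, ", report$catalog_residues, " residues")
  invisible(list(catalog = catalog, results = all_res, report = report,
                 files = files))
}
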