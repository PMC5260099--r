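# Synthetic fixtures: CA-trace structures, mutation tables and identity
# alignments with known ground truth, so every pipeline stage can be tested
# without downloading real data. CA-only geometry is sufficient because the
# contact rule is any-atom; no side-chain realism is implied.

# Ideal alpha-helix constants for CA traces (fixed for deterministic fixtures)
.HELIX_RISE   <- 1.5   # A per residue along the axis
.HELIX_TWIST  <- 100   # degrees per residue
.HELIX_RADIUS <- 2.3   # A, CA distance from the helix axis

#' Generate a synthetic CA-only structure chain
#'
#' Builds a deterministic CA trace: either a straight chain with fixed
#' spacing or an ideal alpha helix (rise 1.5 A/residue, 100 degrees/residue,
#' radius 2.3 A), or arbitrary user-supplied coordinates. Residue names
#' cycle through the 20 standard amino acids so fixture positions carry
#' well-defined reference residues.
#'
#' @param n_residues Number of residues.
#' @param geometry `"linear"`, `"helix"`, or `"custom"`.
#' @param spacing CA-CA spacing in Angstrom for linear geometry (default 3.8,
#'   the canonical virtual bond length).
#' @param coords For `geometry = "custom"`, an `n_residues` x 3 matrix of CA
#'   coordinates.
#' @param structure_id,chain_id Identifiers stamped on the chain.
#' @param path Optional path; when given, the chain is also written as a PDB
#'   file via [write_fixture_pdb()].
#' @return A `structure_chain` (same class as [read_pdb()] output).
#' @export
#' @examples
#' ch <- make_structure(30, geometry = "helix")
#' compute_contact_map(ch)
make_structure <- function(n_residues,
                           geometry = c("linear", "helix", "custom"),
                           spacing = 3.8, coords = NULL,
                           structure_id = "SYN1", chain_id = "A",
                           path = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 1)
  i <- seq_len(n_residues)
  if (geometry == "linear") {
    xyz <- cbind(x = (i - 1) * spacing, y = 0, z = 0)
  } else if (geometry == "helix") {
    th <- (i - 1) * .HELIX_TWIST * pi / 180
    xyz <- cbind(x = .HELIX_RADIUS * cos(th),
                 y = .HELIX_RADIUS * sin(th),
                 z = (i - 1) * .HELIX_RISE)
  } else {
    if (is.null(coords) || nrow(coords) != n_residues || ncol(coords) != 3) {
      stop("custom geometry needs an n_residues x 3 coords matrix")
    }
    xyz <- coords
  }
  res <- data.frame(
    res_index = i,
    resno     = i,
    insert    = "",
    resid     = .AA3[(i - 1L) %% 20L + 1L],
    stringsAsFactors = FALSE
  )
  atom <- data.frame(
    res_index = i, elety = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  chain <- structure(
    list(structure_id = structure_id, chain_id = chain_id,
         res = res, atom = atom),
    class = "structure_chain"
  )
  if (!is.null(path)) write_fixture_pdb(chain, path)
  chain
}

#' Write a structure chain as a PDB file
#'
#' Emits standard ATOM records readable by [read_pdb()] (and any other PDB
#' consumer); used to round-trip synthetic fixtures through the parser.
#'
#' @param chain A `structure_chain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "structure_chain"))
  at <- chain$atom
  res <- chain$res
  bio3d::write.pdb(
    file  = path,
    xyz   = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = res$resno[at$res_index],
    resid = res$resid[at$res_index],
    eleno = seq_len(nrow(at)),
    elety = at$elety,
    chain = chain$chain_id
  )
  invisible(path)
}

# one-letter amino acid at a fixture position (cycled, matches make_structure)
.fixture_aa <- function(pos) .AA1[(pos - 1L) %% 20L + 1L]

#' Generate a synthetic mutation table with known ground truth
#'
#' Injected positions receive missense mutations in distinct tumor samples
#' (so the per-residue mutated-sample count equals the requested count);
#' background mutations are placed uniformly at random over the remaining
#' positions, each in its own sample. A trivial identity alignment
#' (sequence position i to chain ordinal i, identity 1.0) is produced
#' alongside.
#'
#' @param n_positions Length of the protein / fixture chain.
#' @param n_samples Size of the tumor cohort; sample ids are `S0001`...
#' @param injected Named-list spec of ground-truth clusters: a list of
#'   `list(positions = <int vector>, count = <samples per position>)`.
#' @param background Total number of background missense events, placed
#'   uniformly over positions not in any injected cluster.
#' @param gene,cancer_type,structure_id,chain_id Labels for the emitted rows.
#' @param seed Optional integer seed for reproducible placement.
#' @param dir Optional directory: when given, writes `mutations.tsv` and
#'   `alignment.tsv` there.
#' @return List with `mutations` (data frame in the MAF-like layout read by
#'   [load_mutations()]) and `alignment` (data frame in the layout read by
#'   [load_alignments()]); when `dir` is given also `mutations_path` /
#'   `alignment_path`.
#' @export
#' @examples
#' fx <- make_mutations(50, n_samples = 100,
#'                      injected = list(list(positions = 10:12, count = 2)),
#'                      background = 5, seed = 1)
#' table(fx$mutations$protein_position)
make_mutations <- function(n_positions, n_samples,
                           injected = list(), background = 0,
                           gene = "GENE1", cancer_type = "FIXTURE",
                           structure_id = "SYN1", chain_id = "A",
                           seed = NULL, dir = NULL) {
  stopifnot(n_positions >= 1, n_samples >= 1, background >= 0)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  inj_pos <- integer(0)
  rows <- list()
  samples <- sprintf("S%04d", seq_len(n_samples))
  for (cl in injected) {
    stopifnot(all(cl$positions >= 1), all(cl$positions <= n_positions))
    if (cl$count > n_samples) {
      stop("injected count ", cl$count, " exceeds n_samples ", n_samples)
    }
    inj_pos <- c(inj_pos, cl$positions)
    for (p in cl$positions) {
      who <- samples[seq_len(cl$count)]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = who, gene = gene, protein_position = p,
        ref_aa = .fixture_aa(p),
        alt_aa = .AA1[(match(.fixture_aa(p), .AA1)) %% 20L + 1L],
        variant_class = "missense", cancer_type = cancer_type,
        stringsAsFactors = FALSE
      )
    }
  }
  if (background > 0) {
    pool <- setdiff(seq_len(n_positions), unique(inj_pos))
    if (length(pool) == 0L) stop("no positions left for background mutations")
    if (background > n_samples) {
      stop("background ", background, " exceeds n_samples ", n_samples,
           "; one distinct sample per background event is required")
    }
    bp <- pool[sample.int(length(pool), background, replace = TRUE)]
    # each background event in its own sample so counts are conserved
    who <- rev(samples)[seq_len(background)]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = who, gene = gene, protein_position = bp,
      ref_aa = .fixture_aa(bp),
      alt_aa = .AA1[(match(.fixture_aa(bp), .AA1)) %% 20L + 1L],
      variant_class = "missense", cancer_type = cancer_type,
      stringsAsFactors = FALSE
    )
  }
  mut <- if (length(rows)) do.call(rbind, rows) else data.frame(
    sample_id = character(0), gene = character(0),
    protein_position = integer(0), ref_aa = character(0),
    alt_aa = character(0), variant_class = character(0),
    cancer_type = character(0), stringsAsFactors = FALSE
  )
  rownames(mut) <- NULL
  aln <- data.frame(
    gene = gene, structure_id = structure_id, chain_id = chain_id,
    identity = 1.0,
    seq_pos = seq_len(n_positions), chain_ordinal = seq_len(n_positions),
    stringsAsFactors = FALSE
  )
  out <- list(mutations = mut, alignment = aln)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mp <- file.path(dir, "mutations.tsv")
    ap <- file.path(dir, "alignment.tsv")
    utils::write.table(mut, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(aln, ap, sep = "\t", quote = FALSE, row.names = FALSE)
    out$mutations_path <- mp
    out$alignment_path <- ap
  }
  out
}

#' Generate replicate null mutation tables
#'
#' Produces independent uniform placements of `background` mutations with no
#' injected clusters; used for family-wise calibration simulations.
#'
#' @inheritParams make_mutations
#' @param n_replicates Number of independent tables.
#' @param seed Integer seed; replicate r uses a sub-seed derived from it.
#' @return List of `n_replicates` mutation data frames.
#' @export
null_batch <- function(n_positions, n_samples, background, n_replicates,
                       gene = "GENE1", seed = NULL) {
  stopifnot(n_replicates >= 1)
  base <- if (is.null(seed)) sample.int(2^30, 1L) else as.integer(seed)
  lapply(seq_len(n_replicates), function(r) {
    make_mutations(n_positions, n_samples, injected = list(),
                   background = background, gene = gene,
                   seed = (base + 7919L * r) %% 2147483647L)$mutations
  })
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
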