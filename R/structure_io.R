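# Three-letter codes of the 20 standard amino acids; everything else in a
# PDB file (waters, ligands, modified residues) is dropped at parse time.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read polypeptide chains from a PDB file
#'
#' Parses a PDB-format structure and returns one `structure_chain` object per
#' polypeptide chain. Waters and non-amino-acid heteroatoms are dropped, only
#' the first MODEL of multi-model files is used, and when an atom has
#' alternate locations only the first-listed altloc is kept, so parsing is
#' deterministic.
#'
#' @param source Path to a PDB file, or a character string containing
#'   PDB-format text (detected by embedded newlines).
#' @param structure_id Identifier recorded on the returned chains. Defaults
#'   to the file name without extension.
#'
#' @return A named list of `structure_chain` objects (one per chain that
#'   contains at least one amino-acid residue). Each has elements
#'   `structure_id`, `chain_id`, `res` (data frame with 1-based ordinal
#'   `res_index`, author `resno`, `insert` code and 3-letter `resid`) and
#'   `atom` (data frame of atom records with coordinates, carrying
#'   `res_index` back-references). Chains without amino-acid residues are
#'   omitted with a warning.
#' @export
#' @examples
#' ch <- make_structure(6, geometry = "linear", spacing = 3.8)
#' pdb <- tempfile(fileext = ".pdb")
#' write_fixture_pdb(ch, pdb)
#' chains <- read_pdb(pdb)
#' length(chains[[1]]$res$res_index)
read_pdb <- function(source, structure_id = NULL) {
  path <- source
  if (length(source) == 1L && grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(source, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
    if (is.null(structure_id)) structure_id <- "inline"
  } else if (!file.exists(path)) {
    stop("PDB source not found: ", path)
  }
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }

  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM records in '", path, "'")

  # bio3d with multi = FALSE already restricts to the first MODEL.
  at <- at[at$resid %in% .AA3, , drop = FALSE]
  if (nrow(at) == 0L) stop("no amino-acid residues in '", path, "'")
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""

  chains <- list()
  for (cid in unique(at$chain)) {
    ca <- at[at$chain == cid, , drop = FALSE]
    # first-listed altloc per (residue, atom name): file order is authoritative
    key <- paste(ca$resno, ca$insert, ca$elety, sep = "|")
    ca <- ca[!duplicated(key), , drop = FALSE]
    rkey <- paste(ca$resno, ca$insert, sep = "|")
    ures <- unique(rkey)
    if (length(ures) == 0L) {
      warning("chain ", cid, " of ", structure_id,
              " has no amino-acid residues; omitted")
      next
    }
    res_index <- match(rkey, ures)
    first <- match(ures, rkey)
    res <- data.frame(
      res_index = seq_along(ures),
      resno     = ca$resno[first],
      insert    = ca$insert[first],
      resid     = ca$resid[first],
      stringsAsFactors = FALSE
    )
    atom <- data.frame(
      res_index = res_index,
      elety     = ca$elety,
      x = ca$x, y = ca$y, z = ca$z,
      stringsAsFactors = FALSE
    )
    if (any(!is.finite(c(atom$x, atom$y, atom$z)))) {
      stop("non-finite atom coordinates in chain ", cid, " of ", structure_id)
    }
    chains[[cid]] <- structure(
      list(structure_id = structure_id, chain_id = cid,
           res = res, atom = atom),
      class = "structure_chain"
    )
  }
  if (length(chains) == 0L) stop("no usable chains in '", path, "'")
  chains
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("<structure_chain> ", x$structure_id, ":", x$chain_id,
      " — ", nrow(x$res), " residues, ", nrow(x$atom), " atoms\n", sep = "")
  invisible(x)
}

#' Number of residues in a chain
#' @param chain A `structure_chain`.
#' @return Integer residue count.
#' @export
n_residues <- function(chain) {
  stopifnot(inherits(chain, "structure_chain"))
  nrow(chain$res)
}

#' Compute the residue contact map of a chain
#'
#' Two residues are in contact when any pair of their atoms lies within the
#' distance cutoff (inclusive: a pair at exactly the cutoff is an edge). All
#' atoms present in the file participate, hydrogens included when deposited.
#'
#' @param chain A `structure_chain` from [read_pdb()] or [make_structure()].
#' @param cutoff Contact distance in Angstrom; default 5.0.
#'
#' @return A `contact_map` object with elements `structure_id`, `chain_id`,
#'   `cutoff`, `n_res` and `edges`, a two-column integer matrix of unordered
#'   residue-index pairs (i < j, 1-based ordinals along the parsed chain).
#' @export
#' @examples
#' ch <- make_structure(6, geometry = "linear", spacing = 3.8)
#' cm <- compute_contact_map(ch)
#' cm$edges   # consecutive residues only at 3.8 A spacing
compute_contact_map <- function(chain, cutoff = 5.0) {
  stopifnot(inherits(chain, "structure_chain"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  n <- nrow(chain$res)
  if (n == 0L) stop("chain has no residues")
  xyz <- as.matrix(chain$atom[, c("x", "y", "z")])
  ridx <- chain$atom$res_index
  na <- nrow(xyz)

  # residue adjacency via atom adjacency, in row blocks to bound memory
  adj <- matrix(FALSE, n, n)
  block <- 2000L
  cut2 <- cutoff^2
  sq <- rowSums(xyz^2)
  for (s in seq(1L, na, by = block)) {
    e <- min(s + block - 1L, na)
    # squared distances between atoms [s:e] and all atoms
    cross <- xyz[s:e, , drop = FALSE] %*% t(xyz)
    d2 <- outer(sq[s:e], sq, "+") - 2 * cross
    hit <- which(d2 <= cut2 + 1e-9, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      ri <- ridx[s:e][hit[, 1L]]
      rj <- ridx[hit[, 2L]]
      keep <- ri != rj
      if (any(keep)) adj[cbind(ri[keep], rj[keep])] <- TRUE
    }
  }
  adj <- adj | t(adj)
  up <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- matrix(as.integer(up), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(
    list(structure_id = chain$structure_id, chain_id = chain$chain_id,
         cutoff = cutoff, n_res = n, edges = edges),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$structure_id, ":", x$chain_id, " — ", x$n_res,
      " residues, ", nrow(x$edges), " contacts at ", x$cutoff, " A\n",
      sep = "")
  invisible(x)
}

#' Contact neighbors of a residue
#'
#' @param cmap A `contact_map`.
#' @param residue_index 1-based residue ordinal along the chain.
#' @return Sorted integer vector of neighboring residue ordinals; never
#'   includes `residue_index` itself.
#' @export
neighbors <- function(cmap, residue_index) {
  stopifnot(inherits(cmap, "contact_map"))
  if (length(residue_index) != 1L || !is.numeric(residue_index) ||
      residue_index != as.integer(residue_index) ||
      residue_index < 1L || residue_index > cmap$n_res) {
    stop("residue_index out of range [1, ", cmap$n_res, "]")
  }
  e <- cmap$edges
  sort(unique(c(e[e[, 1L] == residue_index, 2L],
                e[e[, 2L] == residue_index, 1L])))
}

# adjacency list for all residues; internal fast path used by build_clusters
.adjacency_list <- function(cmap) {
  adj <- vector("list", cmap$n_res)
  for (k in seq_len(nrow(cmap$edges))) {
    i <- cmap$edges[k, 1L]
    j <- cmap$edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}
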