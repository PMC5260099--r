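mut_row <- function(sample, gene, pos, ref = "A", alt = "V",
                    class = "missense", type = "LUAD") {
  data.frame(sample_id = sample, gene = gene, protein_position = pos,
             ref_aa = ref, alt_aa = alt, variant_class = class,
             cancer_type = type, stringsAsFactors = FALSE)
}

write_mut_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_mutations enforces schema and per-row validity", {
  df <- rbind(mut_row("s1", "KRAS", 12), mut_row("s2", "KRAS", 13),
              mut_row("s3", "TP53", 273))
  got <- load_mutations(write_mut_tsv(df))
  expect_equal(nrow(got), 3L)
  expect_type(got$protein_position, "integer")

  # empty table with header is fine
  empty <- load_mutations(write_mut_tsv(df[0, ]))
  expect_equal(nrow(empty), 0L)

  # indel-style position range is a row error
  bad <- df
  bad$protein_position <- as.character(bad$protein_position)
  bad$protein_position[2] <- "12_13"
  expect_error(load_mutations(write_mut_tsv(bad)), "row(s): 2", fixed = TRUE)

  # missing column is a schema error
  expect_error(load_mutations(write_mut_tsv(df[, -3])), "schema")

  badc <- df
  badc$variant_class[3] <- "weird"
  expect_error(load_mutations(write_mut_tsv(badc)), "variant_class")
})

test_that("alignment identity filter keeps 0.90 and drops 0.89", {
  alns <- list(
    identity_alignment(10, gene = "G1", identity = 0.90),
    identity_alignment(10, gene = "G2", identity = 0.89),
    identity_alignment(10, gene = "G3", identity = 1.0)
  )
  kept <- filter_alignments(alns)
  expect_equal(vapply(kept, `[[`, "", "gene"), c("G1", "G3"))
  expect_length(filter_alignments(list()), 0L)
})

test_that("alignment loader groups rows and rejects many-to-one pairs", {
  df <- rbind(
    data.frame(gene = "G1", structure_id = "1ABC", chain_id = "A",
               identity = 0.95, seq_pos = 1:5, chain_ordinal = 1:5),
    data.frame(gene = "G2", structure_id = "2XYZ", chain_id = "B",
               identity = 0.80, seq_pos = 10:12, chain_ordinal = 1:3)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  alns <- load_alignments(path)
  expect_length(alns, 2L)
  ids <- sort(unname(vapply(alns, `[[`, "", "gene")))
  expect_equal(ids, c("G1", "G2"))

  dup <- df
  dup$chain_ordinal[2] <- 1L
  write.table(dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_alignments(path), "one-to-one")
})

test_that("germline filter removes 1000G/ESP and recurrent 1000G variants", {
  mut <- rbind(
    mut_row("s1", "KRAS", 12, ref = "G", alt = "D"),  # in both lists
    mut_row("s2", "KRAS", 13, ref = "G", alt = "C"),  # 1000G x2, not ESP
    mut_row("s3", "KRAS", 61, ref = "Q", alt = "H"),  # 1000G x1, not ESP
    mut_row("s4", "TP53", 273, ref = "R", alt = "H")  # in neither
  )
  kg <- data.frame(gene = c("KRAS", "KRAS"), position = c(12, 13),
                   ref = c("G", "G"), alt = c("D", "C"),
                   n_samples = c(1, 2))
  kg <- rbind(kg, data.frame(gene = "KRAS", position = 61, ref = "Q",
                             alt = "H", n_samples = 1))
  esp <- data.frame(gene = "KRAS", position = 12, ref = "G", alt = "D")
  out <- filter_germline(mut, kg, esp)
  expect_equal(out$sample_id, c("s3", "s4"))
})

test_that("expression filter applies the per-type and all-tumor rules", {
  # 25 expression tumors of type T1, 20 of type T2
  em <- matrix(1, nrow = 3, ncol = 45,
               dimnames = list(c("GLOW", "GOK", "GALLLOW"),
                               paste0("e", 1:45)))
  types <- c(rep("T1", 25), rep("T2", 20))
  # GLOW: TPM < 0.1 in 23/25 = 92% of T1 tumors -> dropped for T1 samples
  em["GLOW", 1:23] <- 0.01
  # GOK: below threshold in only 85% of T1 (21/25) -> kept
  em["GOK", 1:21] <- 0.01
  # GALLLOW: below threshold in 44/45 (~98%) of all tumors -> dropped for
  # samples of types with no expression data (the >95% fallback)
  em["GALLLOW", 1:44] <- 0.01

  mut <- rbind(
    mut_row("s1", "GLOW", 10, type = "T1"),
    mut_row("s2", "GOK", 10, type = "T1"),
    mut_row("s3", "GLOW", 10, type = "T2"),   # only 92% of T1, not T2
    mut_row("s4", "GALLLOW", 10, type = "T9"),  # uncovered type, fallback
    mut_row("s5", "GNOEXPR", 10, type = "T1")   # gene absent: kept
  )
  out <- filter_expression(mut, em, types)
  expect_setequal(out$sample_id, c("s2", "s3", "s5"))

  # exactly 90% within type is dropped (inclusive); exactly 95% overall kept
  em2 <- matrix(1, nrow = 2, ncol = 20,
                dimnames = list(c("GA", "GB"), paste0("e", 1:20)))
  em2["GA", 1:18] <- 0.01  # 90% of the 20 T1 tumors
  em2["GB", 1:19] <- 0.01  # 95% of all tumors: not "more than 95%"
  mut2 <- rbind(mut_row("s1", "GA", 5, type = "T1"),
                mut_row("s2", "GB", 5, type = "T9"))
  out2 <- filter_expression(mut2, em2, rep("T1", 20))
  expect_equal(out2$sample_id, "s2")
})

test_that("residue_counts counts distinct mutated samples, missense only", {
  aln <- identity_alignment(50, gene = "KRAS")
  mut <- rbind(
    mut_row("s1", "KRAS", 12),
    mut_row("s2", "KRAS", 12),
    mut_row("s2", "KRAS", 12, alt = "C"),    # second allele, same sample
    mut_row("s3", "KRAS", 30, class = "nonsense"),
    mut_row("s4", "KRAS", 99),               # outside the 1..50 alignment
    mut_row("s5", "TP53", 12)                # other gene
  )
  rc <- residue_counts(mut, "KRAS", aln)
  expect_equal(rc$counts, c("12" = 2L, "99" = 1L))
  expect_equal(rc$aligned_positions, 1:50)

  # empty gene gives empty counts, not an error
  rc0 <- residue_counts(mut, "BRAF", aln)
  expect_length(rc0$counts, 0L)

  # projection: position 99 is outside the alignment, excluded from the
  # ordinal vector; position 12 maps to exactly one ordinal
  x <- ordinal_counts(rc, aln, 50)
  expect_equal(sum(x), 2L)
  expect_equal(x[12], 2L)
})

test_that("germline and expression filters commute on random tables", {
  set.seed(33)
  genes <- c("G1", "G2", "G3")
  for (rep in 1:5) {
    mut <- do.call(rbind, lapply(1:40, function(i) {
      mut_row(paste0("s", sample(20, 1)), sample(genes, 1),
              sample(100, 1), ref = sample(LETTERS[1:4], 1),
              type = sample(c("T1", "T2", "T9"), 1))
    }))
    kg <- data.frame(gene = sample(genes, 5, TRUE),
                     position = sample(100, 5),
                     ref = sample(LETTERS[1:4], 5, TRUE), alt = "V",
                     n_samples = sample(1:3, 5, TRUE))
    esp <- kg[sample(5, 2), c("gene", "position", "ref", "alt")]
    em <- matrix(runif(3 * 30, 0, 0.3), 3, 30,
                 dimnames = list(genes, paste0("e", 1:30)))
    tys <- rep(c("T1", "T2"), each = 15)
    a <- filter_expression(filter_germline(mut, kg, esp), em, tys)
    b <- filter_germline(filter_expression(mut, em, tys), kg, esp)
    expect_equal(a, b)
  }
})
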