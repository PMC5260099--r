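# fixture: 6-residue 3.8 A chain, contacts {(i,i+1)}, counts {2,2,0,0,0,0};
# assessed cluster {1,2,3} has observed 4 and exact p = 9/15 = 0.6 (both
# mutated residues must land within one 3-residue window)
chain_fixture <- function() {
  lin <- make_structure(6, geometry = "linear", spacing = 3.8)
  cl <- build_clusters(compute_contact_map(lin), aligned = 1:6)
  list(clusters = cl, assessed = cl[[2]], counts = c(2, 2, 0, 0, 0, 0))
}

test_that("apply_cap truncates above the cap and rejects caps below 1", {
  counts <- c(30, 0, 0, 0, 2, 2, 2)
  expect_equal(apply_cap(counts, 2), c(2, 0, 0, 0, 2, 2, 2))
  expect_equal(apply_cap(c(1, 2, 2), 2), c(1, 2, 2))
  expect_equal(apply_cap(counts, 30), counts)
  expect_error(apply_cap(counts, 0), "cap")
})

test_that("decoys are seeded, conserve the multiset, and are uniform", {
  capped <- c(2, 0, 0, 0)
  expect_equal(sample_decoy(capped, seed = 11),
               sample_decoy(capped, seed = 11))
  set.seed(5)
  for (i in 1:20) {
    v <- sample(0:3, sample(3:10, 1), replace = TRUE)
    d <- sample_decoy(v)
    expect_equal(sort(d), sort(v))
    expect_equal(sum(d), sum(v))
  }
  # the single nonzero count lands on each of 4 positions with prob 1/4
  set.seed(99)
  hits <- integer(4)
  for (i in 1:10000) {
    d <- sample_decoy(capped)
    hits[d == 2] <- hits[d == 2] + 1L
  }
  expect_gt(stats::chisq.test(hits)$p.value, 1e-4)
})

test_that("Monte Carlo p-value matches the exact enumeration on the chain fixture", {
  fx <- chain_fixture()
  p_exact <- exact_pvalue(fx$assessed, fx$counts, fx$clusters)
  expect_equal(p_exact, 9 / 15)
  r <- permutation_pvalue(fx$assessed, fx$counts, fx$clusters,
                          n_decoys = 1e5, seed = 7)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(r$p_value - p_exact), tol)
  expect_equal(r$observed, 4)
  expect_equal(r$cap, 2)
  expect_equal(r$p_value, r$n_exceed / r$n_decoys)
})

test_that("exact enumeration agrees with a labeled full-permutation oracle", {
  set.seed(606)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    ch <- chain_from_atoms(lapply(seq_len(n),
                                  function(i) matrix(runif(3, 0, 9), 1)))
    cl <- build_clusters(compute_contact_map(ch), aligned = seq_len(n))
    counts <- sample(0:3, n, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    assessed <- cl[[which(counts > 0)[1]]]
    expect_equal(exact_pvalue(assessed, counts, cl),
                 labeled_perm_pvalue(assessed, counts, cl),
                 label = paste("rep", rep))
  }
})

test_that("degenerate nulls force p = 1", {
  fx <- chain_fixture()
  # single mutated residue: its count lands in some cluster in every decoy
  counts1 <- c(0, 0, 0, 3, 0, 0)
  expect_equal(exact_pvalue(fx$clusters[[4]], counts1, fx$clusters), 1.0)
  r <- permutation_pvalue(fx$clusters[[4]], counts1, fx$clusters,
                          n_decoys = 500, seed = 2)
  expect_equal(r$p_value, 1.0)
  # all positions mutated equally: every placement is identical
  expect_equal(exact_pvalue(fx$clusters[[1]], rep(2, 6), fx$clusters), 1.0)
  # fully connected chain: every cluster holds every residue, totals conserved
  fc <- chain_from_atoms(list(matrix(c(0, 0, 0), 1), matrix(c(3, 0, 0), 1),
                              matrix(c(0, 3, 0), 1), matrix(c(0, 0, 3), 1)))
  clf <- build_clusters(compute_contact_map(fc), aligned = 1:4)
  rf <- permutation_pvalue(clf[[2]], c(1, 0, 2, 0), clf,
                           n_decoys = 500, seed = 3)
  expect_equal(rf$p_value, 1.0)
})

test_that("exact enumeration refuses oversized placements", {
  n <- 12
  ch <- make_structure(n, geometry = "linear", spacing = 3.8)
  cl <- build_clusters(compute_contact_map(ch), aligned = 1:n)
  counts <- c(rep(1, 6), rep(0, 6))
  expect_error(
    exact_pvalue(cl[[1]], counts, cl, max_placements = 100),
    "refused"
  )
})

test_that("inclusive comparison: raising the observed score never raises exceedance", {
  fx <- chain_fixture()
  capped <- apply_cap(fx$counts, 2)
  set.seed(12)
  mx <- replicate(2000, {
    d <- sample_decoy(capped)
    max(vapply(fx$clusters, function(cl) sum(d[cl$members]), numeric(1)))
  })
  expect_gte(sum(mx >= 4), sum(mx >= 5))
  expect_equal(sum(mx >= 1), 2000)   # score 1 is always reached somewhere
})

test_that("the cap rule restores sensitivity beside a dominant distant hotspot", {
  n <- 60
  lin <- make_structure(n, geometry = "linear", spacing = 3.8)
  cl <- build_clusters(compute_contact_map(lin), aligned = 1:n)
  counts <- numeric(n)
  counts[5] <- 30                  # dominant single-residue hotspot
  counts[40:42] <- 2               # modest 3-residue cluster
  assessed <- cl[[41]]             # members {40,41,42}, observed 6
  with_cap <- permutation_pvalue(assessed, counts, cl,
                                 n_decoys = 2e4, seed = 21)
  expect_equal(with_cap$cap, 2)
  without_cap <- permutation_pvalue(assessed, counts, cl,
                                    n_decoys = 2e4, seed = 21, cap = Inf)
  expect_lte(with_cap$p_value, without_cap$p_value)
  # uncapped, the shuffled count 30 lands in some cluster in every decoy
  expect_equal(without_cap$p_value, 1.0)
  expect_lt(with_cap$p_value, 0.05)
})

test_that("test_structure is deterministic, total and order-independent", {
  ch <- make_structure(40, geometry = "helix")
  aln <- identity_alignment(40)
  fx <- make_mutations(40, n_samples = 100, background = 12, seed = 9)
  cnt <- residue_counts(fx$mutations, "GENE1", aln)
  r1 <- test_structure(ch, aln, cnt, n_decoys = 2000, seed = 4)
  r2 <- test_structure(ch, aln, cnt, n_decoys = 2000, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(is.finite(r1$p_value)))
  expect_true(all(r1$p_value >= 0 & r1$p_value <= 1))
  expect_true(all(r1$observed >= 1))
  # every mutated aligned residue is the center of some tested cluster
  x <- ordinal_counts(cnt, aln, 40)
  expect_true(all(which(x > 0) %in% r1$center))
  # no mutations: empty result, not an error
  cnt0 <- residue_counts(fx$mutations[0, ], "GENE1", aln)
  expect_equal(nrow(test_structure(ch, aln, cnt0, n_decoys = 10)), 0L)
})

test_that("an injected adjacent cluster scores below background clusters", {
  ch <- make_structure(30, geometry = "linear", spacing = 3.8)
  aln <- identity_alignment(30)
  fx <- make_mutations(30, n_samples = 60,
                       injected = list(list(positions = 14:16, count = 2)),
                       background = 4, seed = 31)
  cnt <- residue_counts(fx$mutations, "GENE1", aln)
  res <- test_structure(ch, aln, cnt, n_decoys = 5000, seed = 8)
  inj <- res[vapply(res$seq_members, function(v) all(14:16 %in% v), TRUE), ]
  expect_gte(nrow(inj), 1L)
  expect_equal(min(res$p_value), min(inj$p_value))
})
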