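# Fixture builders and independent oracles used across the suite.

# single maternal line shaped as a chain: ids[1] <- ids[2] <- ... (dam links)
chain_pedigree <- function(ids, haplotype = NULL) {
  pedigree(id = ids,
           dam = c(NA, ids[-length(ids)]),
           gender = "F",
           yob = 2000 + seq_along(ids),
           haplotype = haplotype)
}

# star: founder F with n_leaves daughters
star_pedigree <- function(n_leaves, hub = "F", haplotype = NULL) {
  ids <- c(hub, sprintf("l%02d", seq_len(n_leaves)))
  pedigree(id = ids, dam = c(NA, rep(hub, n_leaves)), gender = "F",
           yob = c(2000, rep(2001, n_leaves)), haplotype = haplotype)
}

# random recursive single-line tree on m nodes (node i's dam is a uniform
# earlier node); reproducible under the caller's RNG state
random_line_tree <- function(m) {
  ids <- sprintf("t%02d", seq_len(m))
  dam <- c(NA, ids[vapply(2:m, function(i) sample.int(i - 1L, 1L), integer(1))])
  pedigree(id = ids, dam = dam, gender = "F", yob = 2000 + seq_len(m))
}

# brute-force pairwise conflict counts from an enumerated pair list
brute_conflict_counts <- function(pairs) {
  if (!nrow(pairs)) return(integer(0))
  table(c(pairs$i, pairs$j))
}

# sum of pairwise tree distances within a subset
subset_score <- function(D, subset) {
  if (length(subset) < 2L) return(0)
  sum(D[subset, subset]) / 2
}

# exhaustive optimum over all subsets of size k that contain `anchor`
# (the dispersion problem the greedy heuristic addresses: the first pick
# is fixed at the central individual / seed group)
best_anchored_score <- function(D, ids, k, anchor) {
  others <- setdiff(ids, anchor)
  if (k - 1L > length(others)) stop("k too large")
  if (k == 1L) return(0)
  combos <- utils::combn(others, k - 1L)
  max(apply(combos, 2L, function(s) subset_score(D, c(anchor, s))))
}

expect_no_conflicts <- function(report) {
  expect_identical(length(report$conflicting_individuals), 0L)
  expect_identical(report$n_conflicting_pairs, 0L)
  expect_equal(report$hc_index, 0)
}
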