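# shared fixture: one line {x:A, y:A, z:B} below founder F (unhaplotyped)
abz_pedigree <- function() {
  pedigree(id = c("F", "x", "y", "z"),
           dam = c(NA, "F", "F", "F"), gender = "F",
           haplotype = c(NA, "A", "A", "B"))
}

test_that("conflicting pairs enumerate cross-haplotype same-line pairs", {
  p <- abz_pedigree()
  f <- build_forest(p)
  pairs <- find_conflicting_pairs(f, p)
  got <- sort(paste(pairs$i, pairs$j))
  expect_identical(got, sort(c("x z", "y z")))

  # concordant line -> no pairs
  p2 <- pedigree(id = c("F", "x", "y"), dam = c(NA, "F", "F"), gender = "F",
                 haplotype = c("A", "A", "A"))
  expect_identical(nrow(find_conflicting_pairs(build_forest(p2), p2)), 0L)

  # different lines, different haplotypes -> no pairs
  p3 <- pedigree(id = c("A1", "B1"), dam = c(NA, NA), gender = "F",
                 haplotype = c("A", "B"))
  expect_identical(nrow(find_conflicting_pairs(build_forest(p3), p3)), 0L)
})

test_that("flagging follows the pairwise-conflict majority rule", {
  p <- abz_pedigree()
  f <- build_forest(p)
  pairs <- find_conflicting_pairs(f, p)
  # counts: x=1, y=1, z=2 -> only z under either tie rule
  expect_identical(flag_conflicting_individuals(pairs, "strict"), "z")
  expect_identical(flag_conflicting_individuals(pairs, "both"), "z")

  # 1-vs-1 tie: strict flags nobody, default flags both
  p2 <- pedigree(id = c("F", "x", "z"), dam = c(NA, "F", "F"), gender = "F",
                 haplotype = c(NA, "A", "B"))
  pairs2 <- find_conflicting_pairs(build_forest(p2), p2)
  expect_identical(flag_conflicting_individuals(pairs2, "strict"), character())
  expect_identical(flag_conflicting_individuals(pairs2, "both"), c("x", "z"))

  expect_identical(flag_conflicting_individuals(pairs2[0, ]), character())
})

test_that("count-based flagging agrees with the pair-based rule", {
  for (seed in 1:8) {
    s <- synth_pedigree(n_founder_dams = 6, generations = 4,
                        n_conflicts = 2, seed = seed)
    f <- build_forest(s$pedigree)
    pairs <- find_conflicting_pairs(f, s$pedigree)
    for (rule in c("strict", "both")) {
      oracle <- flag_conflicting_individuals(pairs, rule)
      rep <- verify_pedigree(s$pedigree, forest = f, tie_rule = rule)
      expect_identical(rep$conflicting_individuals, oracle)
    }
    # conflict counts match brute-force pair counts
    rep <- verify_pedigree(s$pedigree, forest = f)
    brute <- brute_conflict_counts(pairs)
    for (id in names(rep$conflict_count)) {
      expect_identical(as.integer(rep$conflict_count[[id]]),
                       as.integer(brute[[id]]))
    }
  }
})

test_that("informative individuals are exactly the between-pair path nodes", {
  # haplotyped grandmother g and granddaughter c, silent mother m between
  p <- pedigree(id = c("g", "m", "c", "out"),
                dam = c(NA, "g", "m", NA), gender = "F",
                haplotype = c("H", NA, "H", NA))
  f <- build_forest(p)
  expect_setequal(find_informative_individuals(f, p), c("g", "m", "c"))

  # a single haplotyped individual contributes nothing
  p2 <- pedigree(id = c("F", "a"), dam = c(NA, "F"), gender = "F",
                 haplotype = c(NA, "H"))
  expect_identical(find_informative_individuals(build_forest(p2), p2),
                   character())

  # star: the path between two haplotyped daughters passes the silent hub
  p3 <- pedigree(id = c("F", "d1", "d2", "d3"),
                 dam = c(NA, "F", "F", "F"), gender = "F",
                 haplotype = c(NA, "H", "H", NA))
  expect_setequal(find_informative_individuals(build_forest(p3), p3),
                  c("d1", "F", "d2"))
})

# a 4-conflict misplaced branch: chain t <- c1 <- c2 <- c3 carries B inside
# an A line with five concordant members
branch_pedigree <- function() {
  pedigree(
    id = c("F", "a1", "a2", "a3", "a4", "t", "c1", "c2", "c3"),
    dam = c(NA, "F", "F", "F", "F", "a1", "t", "c1", "c2"),
    gender = "F",
    haplotype = c("A", "A", "A", "A", "A", "B", "B", "B", "B"))
}

test_that("misplaced individuals repeat their nearest haplotyped ancestor", {
  p <- branch_pedigree()
  f <- build_forest(p)
  rep <- verify_pedigree(p, forest = f, tie_rule = "strict")
  expect_setequal(rep$conflicting_individuals, c("t", "c1", "c2", "c3"))
  # t's nearest haplotyped ancestor is a1 (A != B): conflicting, not misplaced
  expect_setequal(rep$misplaced_individuals, c("c1", "c2", "c3"))
  expect_identical(rep$misplaced_branches$root, "t")
  expect_identical(rep$misplaced_branches$n_conflicts, 4L)
  # the whole branch counts as one error
  expect_identical(rep$pruned_conflicts, 1L)
  expect_equal(rep$misplaced_index, 100 * 3 / 4)

  # a flagged individual with no haplotyped ancestor is not misplaced
  p2 <- pedigree(id = c("z", "x1", "x2"), dam = c(NA, "z", "z"),
                 gender = "F", haplotype = c("B", "A", "A"))
  rep2 <- verify_pedigree(p2, tie_rule = "strict")
  expect_identical(rep2$conflicting_individuals, "z")
  expect_identical(rep2$misplaced_individuals, character())
})

test_that("indices follow their definitions including undefined cases", {
  p <- abz_pedigree()
  rep <- verify_pedigree(p, tie_rule = "strict")
  expect_equal(rep$hc_index, 100 * 1 / 3)
  # informative: x, y, z and hub F; z is the only conflicting one
  expect_equal(rep$ic_index, 100 * 1 / 4)
  expect_equal(rep$misplaced_index, 0)
  expect_identical(rep$pruned_conflicts, 1L)

  clean <- pedigree(id = c("F", "a"), dam = c(NA, "F"), gender = "F",
                    haplotype = c("H", "H"))
  repc <- verify_pedigree(clean)
  expect_equal(repc$hc_index, 0)
  expect_equal(repc$ic_index, 0)
  expect_true(is.na(repc$misplaced_index))
  expect_match(repc$undefined[["misplaced_index"]], "no conflicting")

  nohap <- pedigree(id = "F", haplotype = NULL)
  repn <- verify_pedigree(nohap)
  expect_true(is.na(repn$hc_index))
})

test_that("conflict-free random pedigrees verify clean", {
  for (seed in 1:10) {
    s <- synth_pedigree(n_founder_dams = 8, generations = 4, seed = seed)
    expect_no_conflicts(verify_pedigree(s$pedigree))
  }
})

test_that("a single injected wrong haplotype is flagged exactly", {
  for (seed in 1:10) {
    s <- synth_pedigree(n_founder_dams = 8, generations = 4,
                        n_conflicts = 1, seed = seed)
    victim <- s$truth$injections[[1]]$ids
    rep <- verify_pedigree(s$pedigree, tie_rule = "strict")
    expect_identical(rep$conflicting_individuals, victim)
  }
})

test_that("record order does not change the verification result", {
  s <- synth_pedigree(n_founder_dams = 6, generations = 4, n_conflicts = 2,
                      n_misplaced_branches = 1, seed = 7)
  p <- s$pedigree
  set.seed(1)
  perm <- sample(nrow(p))
  p2 <- pedigree(id = p$id[perm], sire = p$sire[perm], dam = p$dam[perm],
                 yob = p$yob[perm], gender = p$gender[perm],
                 haplotype = p$haplotype[perm])
  r1 <- verify_pedigree(p)
  r2 <- verify_pedigree(p2)
  expect_identical(r1$conflicting_individuals, r2$conflicting_individuals)
  expect_identical(r1$misplaced_individuals, r2$misplaced_individuals)
  expect_equal(r1$hc_index, r2$hc_index)
  expect_equal(r1$ic_index, r2$ic_index)
  expect_identical(r1$pruned_conflicts, r2$pruned_conflicts)
})
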