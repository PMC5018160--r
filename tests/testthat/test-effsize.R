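test_that("probability of identity is the sum of squared frequencies", {
  expect_equal(prob_identity(rep(0.25, 4)), 0.25)
  expect_equal(prob_identity(1), 1)
  expect_equal(prob_identity(c(0.75, 0.25)), 0.625)
  expect_error(prob_identity(numeric()), "empty")
  expect_error(prob_identity(c(0.5, 0.2)), "sum to 1")
})

test_that("increase in identity and effective size follow the formulas", {
  expect_equal(delta_pi(0.5, 0.625), 0.25)
  expect_equal(delta_pi(0.3, 0.3), 0)
  expect_equal(delta_pi(0.25, 1), 1)
  expect_error(delta_pi(1, 1), "undefined")
  expect_equal(effective_size(0.25), 4)
  expect_identical(effective_size(0), Inf)
  expect_equal(effective_size(1), 1)
  expect_error(effective_size(-0.1), "negative")
})

# 4 founder dams with reference daughters 3,1,0,0; one extra ref male
freq_fixture <- function() {
  pedigree(
    id = c("D1", "D2", "D3", "D4",
           "x1", "x2", "x3", "y1", "m1"),
    dam = c(NA, NA, NA, NA, "D1", "D1", "D1", "D2", "D1"),
    gender = c("F", "F", "F", "F", "F", "F", "F", "F", "M"),
    yob = c(rep(1990, 4), rep(2005, 5)),
    haplotype = c("HT1", "HT1", "HT2", NA, rep(NA, 5)))
}

test_that("maternal frequencies weight founder dams by reference females", {
  p <- freq_fixture()
  f <- build_forest(p)
  refpop <- reference_population(p, c(2005, 2005))
  mf <- maternal_frequencies(f, p, refpop)
  expect_equal(unname(mf$founder), rep(0.25, 4))
  expect_equal(sort(unname(mf$reference)), c(0.25, 0.75))
  # males in the reference population do not enter the maternal map
  expect_false("m1" %in% names(mf$reference))
  expect_equal(prob_identity(mf$reference), 0.625)
})

test_that("haplotype frequencies use imputed lines and pseudo-haplotypes", {
  p <- freq_fixture()
  f <- build_forest(p)
  refpop <- reference_population(p, c(2005, 2005))
  hf <- haplotype_frequencies(f, p, refpop)
  # founder dams: two HT1, one HT2, one unknown -> unique pseudo label
  expect_equal(unname(hf$founder[c("HT1", "HT2")]), c(0.5, 0.25))
  expect_equal(unname(hf$founder[["PSEUDO_D4"]]), 0.25)
  # reference: x1,x2,x3,m1 in line D1 (HT1), y1 in line D2 (HT1)
  expect_equal(unname(hf$reference[["HT1"]]), 1)
  expect_equal(prob_identity(hf$reference), 1)
})

test_that("closed-form limits: uniform survival and single-line collapse", {
  # k lines surviving uniformly: delta = 0, Ne infinite
  p <- pedigree(id = c("A", "B", "a1", "b1"),
                dam = c(NA, NA, "A", "B"), gender = "F",
                yob = c(1990, 1990, 2005, 2005),
                haplotype = c("H1", "H2", NA, NA))
  e <- effective_sizes(p, window = c(2005, 2005), modes = "maternal")
  expect_equal(e$results$maternal$pi_founder, 0.5)
  expect_equal(e$results$maternal$delta_pi, 0)
  expect_identical(e$results$maternal$ne, Inf)

  # all reference females in one of k lines: delta = 1, Ne = 1
  p2 <- pedigree(id = c("A", "B", "a1", "a2"),
                 dam = c(NA, NA, "A", "A"), gender = "F",
                 yob = c(1990, 1990, 2005, 2005))
  e2 <- effective_sizes(p2, window = c(2005, 2005), modes = "maternal")
  expect_equal(e2$results$maternal$delta_pi, 1)
  expect_equal(e2$results$maternal$ne, 1)
})

test_that("reference PI equals brute-force sum of squares on synthetic data", {
  for (seed in 1:6) {
    s <- synth_pedigree(n_founder_dams = 6, generations = 4, seed = seed)
    p <- s$pedigree
    f <- build_forest(p)
    w <- c(2006, 2015)
    refpop <- reference_population(p, w)
    mf <- maternal_frequencies(f, p, refpop)
    # oracle: raw count table of founder dams over reference females
    ref_f <- p$id[p$id %in% refpop & p$gender == "F"]
    counts <- table(line_of(f)[ref_f])
    expect_equal(prob_identity(mf$reference),
                 sum((as.numeric(counts) / sum(counts))^2))
    hf <- haplotype_frequencies(f, p, refpop)
    imp <- impute_haplotypes(f, p)
    lab <- imp[refpop]
    lab[is.na(lab)] <- paste0("PSEUDO_", line_of(f)[refpop][is.na(lab)])
    counts_h <- table(lab)
    expect_equal(prob_identity(hf$reference),
                 sum((as.numeric(counts_h) / sum(counts_h))^2))
  }
})

test_that("adding males to the reference changes haplotype but not maternal Ne", {
  s <- synth_pedigree(n_founder_dams = 6, generations = 4, seed = 12)
  p <- s$pedigree
  f <- build_forest(p)
  w <- c(2000, 2015)
  refpop <- reference_population(p, w)
  ref_females <- refpop[refpop %in% p$id[p$gender == "F"]]
  mf_all <- maternal_frequencies(f, p, refpop)
  mf_f <- maternal_frequencies(f, p, ref_females)
  expect_equal(mf_all$reference, mf_f$reference)
  hf_all <- haplotype_frequencies(f, p, refpop)
  hf_f <- haplotype_frequencies(f, p, ref_females)
  expect_false(isTRUE(all.equal(hf_all$reference, hf_f$reference)))
})

test_that("paternal effective size mirrors the maternal computation", {
  pm <- pedigree(id = c("A", "B", "a1", "a2", "a3", "b1"),
                 dam = c(NA, NA, "A", "A", "A", "B"),
                 gender = "F", yob = c(1990, 1990, rep(2005, 4)))
  swap <- pedigree(id = c("A", "B", "a1", "a2", "a3", "b1"),
                   sire = c(NA, NA, "A", "A", "A", "B"),
                   gender = "M", yob = c(1990, 1990, rep(2005, 4)))
  em <- effective_sizes(pm, window = c(2005, 2005), modes = "maternal")
  ep <- effective_sizes(swap, window = c(2005, 2005), modes = "paternal")
  expect_equal(em$results$maternal$pi_founder, ep$results$paternal$pi_founder)
  expect_equal(em$results$maternal$pi_reference,
               ep$results$paternal$pi_reference)
  expect_equal(em$results$maternal$ne, ep$results$paternal$ne)

  # founder sires exist but no reference males -> paternal Ne undefined
  mixed <- pedigree(id = c("A", "B", "f1", "f2"),
                    sire = c(NA, NA, "A", "B"),
                    gender = c("M", "M", "F", "F"),
                    yob = c(1990, 1990, 2005, 2005))
  expect_error(effective_sizes(mixed, window = c(2005, 2005),
                               modes = "paternal"),
               "males")
})

test_that("haplotype effective size demands a conflict-free pedigree", {
  p <- pedigree(id = c("F", "x", "z"), dam = c(NA, "F", "F"), gender = "F",
                yob = c(1990, 2005, 2005), haplotype = c(NA, "A", "B"))
  expect_error(effective_sizes(p, window = c(1990, 2005),
                               modes = "haplotype"),
               "verif")
})
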