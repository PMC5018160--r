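test_that("header keywords map columns regardless of order; extras ignored", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,father,mother,YOB,gender,haplotype",
               "101,734,10,1998,F,HT2"), f1)
  p <- read_pedigree(f1)
  expect_identical(p$id, "101")
  expect_identical(p$sire, "734")
  expect_identical(p$dam, "10")
  expect_identical(p$yob, 1998L)
  expect_identical(p$gender, "F")
  expect_identical(p$haplotype, "HT2")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("breed,haplotype,gender,YOB,mother,father,ID",
               "x,HT2,F,1998,10,734,101"), f2)
  p2 <- read_pedigree(f2)
  expect_identical(as.data.frame(p), as.data.frame(p2))
})

test_that("missing mandatory keyword is a fatal parse error naming it", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,father,mother,YOB", "1,,,2000"), f)
  expect_error(read_pedigree(f), "gender")
})

test_that("rows shorter than the mapped columns fail with a line number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,father,mother,YOB,gender",
               "1,,,2000,F",
               "2,,"), f)
  expect_error(read_pedigree(f), "line.*3")
})

test_that("unknown-parent tokens and gender tokens normalize", {
  p <- pedigree(id = c("a", "b", "c", "d"),
                dam = c("0", "", "a", NA),
                sire = c("", "0", NA, "b"),
                gender = c("F", "2", "1", "weird"))
  expect_true(all(is.na(p$dam[1:2])))
  expect_true(all(is.na(p$sire[1:2])))
  expect_identical(p$gender, c("F", "F", "M", NA))
})

test_that("availability accepts exactly the token 1", {
  p <- pedigree(id = c("a", "b", "c"), available = c("1", "yes", ""))
  expect_identical(p$available, c(TRUE, FALSE, FALSE))
  p2 <- pedigree(id = "a")
  expect_false(attr(p2, "has_available"))
})

test_that("duplicate or empty ids are rejected", {
  expect_error(pedigree(id = c("a", "a")), "duplicated")
  expect_error(pedigree(id = c("a", "")), "non-empty")
})

test_that("write -> read round-trips a pedigree field for field", {
  s <- synth_pedigree(n_founder_dams = 4, generations = 3,
                      availability_fraction = 0.5, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(s$pedigree, f)
  back <- read_pedigree(f)
  expect_identical(as.data.frame(s$pedigree), as.data.frame(back))
  expect_true(attr(back, "has_haplotype"))
  expect_true(attr(back, "has_available"))
})

test_that("reference window parses, defaults to the YOB span, validates", {
  f <- withr::local_tempfile()
  writeLines(c("1990", "2005"), f)
  expect_identical(unname(read_reference_window(f)), c(1990L, 2005L))

  ped <- pedigree(id = c("a", "b", "c"), yob = c(1980, NA, 2010))
  expect_identical(unname(read_reference_window(NULL, ped)), c(1980L, 2010L))

  bad <- withr::local_tempfile()
  writeLines(c("2005", "1990"), bad)
  expect_error(read_reference_window(bad), "after")
  writeLines(c("abc", "1990"), bad)
  expect_error(read_reference_window(bad), "non-integer")
  writeLines("1990", bad)
  expect_error(read_reference_window(bad), "two lines")
})

test_that("budget file needs one non-negative integer", {
  f <- withr::local_tempfile()
  writeLines("25", f)
  expect_identical(read_budget(f), 25L)
  writeLines("-3", f)
  expect_error(read_budget(f), "non-negative")
})

test_that("fatal errors: ancestry cycles including self-parent", {
  p <- pedigree(id = c("a", "b"), dam = c("a", NA), gender = "F")
  e <- check_fatal_errors(p)
  expect_identical(e$type, "cycle")
  expect_identical(e$id, "a")

  # two-step cycle through dam links
  p2 <- pedigree(id = c("a", "b", "c"), dam = c("b", "a", "a"), gender = "F")
  e2 <- check_fatal_errors(p2)
  expect_setequal(e2$id[e2$type == "cycle"], c("a", "b"))
  # c hangs below the cycle but is not on it
  expect_false("c" %in% e2$id)
})

test_that("fatal errors: gender inconsistencies in parental roles", {
  # recorded female used as father
  p <- pedigree(id = c("x", "k"), sire = c(NA, "x"), gender = c("F", "M"))
  e <- check_fatal_errors(p)
  expect_identical(e$type, "gender_inconsistency")
  expect_identical(e$id, "x")

  # same id in both parent columns (even without its own record)
  p2 <- pedigree(id = c("a", "b"), sire = c("z", NA), dam = c(NA, "z"))
  e2 <- check_fatal_errors(p2)
  expect_identical(e2$id, "z")

  # clean pedigree
  p3 <- pedigree(id = c("m", "f", "kid"), sire = c(NA, NA, "m"),
                 dam = c(NA, NA, "f"), gender = c("M", "F", "F"))
  expect_identical(nrow(check_fatal_errors(p3)), 0L)
})

test_that("auto-correction removes single mentions, creates multi mentions", {
  p <- pedigree(id = c("c1", "c2", "c3"),
                sire = c("P9", NA, NA),
                dam = c("D7", "D7", NA),
                gender = "F")
  res <- autocorrect_missing_parents(p)
  expect_identical(res$log$deleted$parent, "P9")
  expect_true(is.na(res$pedigree$sire[1]))
  expect_identical(res$log$created$id, "D7")
  expect_identical(res$log$created$gender, "F")
  expect_true("D7" %in% res$pedigree$id)
  d7 <- res$pedigree[res$pedigree$id == "D7", ]
  expect_identical(d7$gender, "F")
  expect_true(is.na(d7$yob))

  # idempotence: the second pass has nothing to do
  res2 <- autocorrect_missing_parents(res$pedigree)
  expect_identical(nrow(res2$log$deleted), 0L)
  expect_identical(nrow(res2$log$created), 0L)
  expect_identical(as.data.frame(res2$pedigree), as.data.frame(res$pedigree))
})

test_that("column order permutation leaves verification unchanged", {
  s <- synth_pedigree(n_founder_dams = 5, generations = 3, n_conflicts = 1,
                      seed = 21)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(s$pedigree, f)
  lines <- readLines(f)
  hdr <- strsplit(lines[1], ",")[[1]]
  perm <- rev(seq_along(hdr))
  shuffled <- vapply(lines, function(l) {
    paste(strsplit(l, ",")[[1]][perm], collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(shuffled, f2)
  r1 <- verify_pedigree(read_pedigree(f))
  r2 <- verify_pedigree(read_pedigree(f2))
  expect_identical(r1$conflicting_individuals, r2$conflicting_individuals)
  expect_equal(r1$hc_index, r2$hc_index)
})
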