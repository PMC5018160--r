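#' Generate a synthetic pedigree with known ground truth
#'
#' Forward-time simulator for testing and power exploration. Founder dams
#' (unknown parents) head the maternal lines; in each generation every
#' female produces Poisson-distributed numbers of daughters and sons, with
#' sires drawn among the males already present. Each founder carries a true
#' mtDNA haplotype drawn from a label pool (shared labels across lines occur
#' by design, so maternal and haplotype effective sizes can differ); a
#' sequencing mask exposes haplotypes for a fraction of individuals. Birth
#' years advance one generation step per generation across `year_span`.
#'
#' Optionally injects recording errors with known ground truth: isolated
#' wrong-haplotype individuals and misplaced branches (see
#' [inject_conflict()]).
#'
#' @param n_founder_dams,n_founder_sires numbers of founders.
#' @param generations number of offspring generations.
#' @param mean_daughters,mean_sons Poisson means per female per generation.
#' @param year_span integer `c(first, last)` birth years.
#' @param n_haplotypes size of the founder haplotype label pool.
#' @param distinct_haplotypes force all founder lines to carry distinct
#'   haplotypes (requires `n_haplotypes >= n_founder_dams + n_founder_sires`).
#' @param sequencing_fraction probability that an individual is sequenced.
#' @param availability_fraction probability that an individual is available
#'   for sampling; `NA` (default) omits the availability column.
#' @param n_conflicts,n_misplaced_branches numbers of injected
#'   single-individual conflicts and misplaced branches.
#' @param seed integer seed; the generated pedigree is fully reproducible
#'   from it.
#' @return An object of class `synth_pedigree`: a list with `pedigree` (a
#'   [pedigree]) and `truth` (line membership, true line haplotypes,
#'   sequenced ids, injection records).
#' @examples
#' s <- synth_pedigree(n_founder_dams = 4, generations = 3, seed = 1)
#' summary(s$pedigree)
#' @export
synth_pedigree <- function(n_founder_dams = 10, n_founder_sires = 5,
                           generations = 5, mean_daughters = 1.6,
                           mean_sons = 1.6, year_span = c(2000, 2015),
                           n_haplotypes = 6, distinct_haplotypes = FALSE,
                           sequencing_fraction = 0.3,
                           availability_fraction = NA,
                           n_conflicts = 0, n_misplaced_branches = 0,
                           seed = NULL) {
  stopifnot(n_founder_dams >= 1, n_founder_sires >= 1, generations >= 0,
            mean_daughters >= 0, mean_sons >= 0,
            sequencing_fraction >= 0, sequencing_fraction <= 1,
            n_conflicts >= 0, n_misplaced_branches >= 0)
  if (!is.null(seed)) set.seed(seed)

  dams0 <- sprintf("D%03d", seq_len(n_founder_dams))
  sires0 <- sprintf("S%03d", seq_len(n_founder_sires))
  years <- round(seq(year_span[1], year_span[2], length.out = generations + 1))

  id <- c(dams0, sires0)
  sire <- rep(NA_character_, length(id))
  dam <- rep(NA_character_, length(id))
  gender <- c(rep("F", n_founder_dams), rep("M", n_founder_sires))
  yob <- rep(years[1], length(id))
  gen <- rep(0L, length(id))
  line <- id                       # founders root their own lines

  counter <- 0L
  for (g in seq_len(generations)) {
    mothers <- id[gender == "F" & gen == g - 1L]
    if (!length(mothers)) break
    males_pool <- id[gender == "M"]
    nd <- stats::rpois(length(mothers), mean_daughters)
    ns <- stats::rpois(length(mothers), mean_sons)
    n_off <- sum(nd) + sum(ns)
    if (n_off == 0L) next
    moms <- c(rep(mothers, nd), rep(mothers, ns))
    sex <- c(rep("F", sum(nd)), rep("M", sum(ns)))
    kids <- sprintf("I%06d", counter + seq_len(n_off))
    counter <- counter + n_off
    dads <- sample(males_pool, n_off, replace = TRUE)
    id <- c(id, kids)
    sire <- c(sire, dads)
    dam <- c(dam, moms)
    gender <- c(gender, sex)
    yob <- c(yob, rep(years[g + 1L], n_off))
    gen <- c(gen, rep(g, n_off))
    line <- c(line, line[match(moms, id)])
  }

  roots <- c(dams0, sires0)
  if (distinct_haplotypes) {
    if (n_haplotypes < length(roots)) {
      stop("distinct haplotypes require n_haplotypes >= number of founders")
    }
    line_hap <- sample(sprintf("HT%02d", seq_len(n_haplotypes)), length(roots))
  } else {
    line_hap <- sample(sprintf("HT%02d", seq_len(n_haplotypes)),
                       length(roots), replace = TRUE)
  }
  names(line_hap) <- roots

  sequenced <- stats::runif(length(id)) < sequencing_fraction
  haplotype <- ifelse(sequenced, line_hap[line], NA_character_)

  available <- NULL
  if (!is.na(availability_fraction)) {
    available <- stats::runif(length(id)) < availability_fraction
  }

  ped <- pedigree(id = id, sire = sire, dam = dam, yob = yob,
                  gender = gender, haplotype = haplotype,
                  available = available)
  truth <- list(line_of = stats::setNames(line, id),
                line_haplotype = line_hap,
                sequenced = id[sequenced],
                config = list(n_founder_dams = n_founder_dams,
                              n_founder_sires = n_founder_sires,
                              generations = generations,
                              sequencing_fraction = sequencing_fraction,
                              seed = seed),
                injections = list())
  out <- structure(list(pedigree = ped, truth = truth),
                   class = "synth_pedigree")
  for (i in seq_len(n_conflicts)) {
    out <- inject_conflict(out, "single_individual")
  }
  for (i in seq_len(n_misplaced_branches)) {
    out <- inject_conflict(out, "misplaced_branch")
  }
  out
}

#' @export
print.synth_pedigree <- function(x, ...) {
  cat("Synthetic pedigree:", nrow(x$pedigree), "individuals,",
      length(unique(x$truth$line_of)), "lines,",
      length(x$truth$sequenced), "sequenced,",
      length(x$truth$injections), "injected error(s)\n")
  invisible(x)
}

#' Inject a known pedigree-recording error
#'
#' * `single_individual`: one sequenced individual in a line with at least
#'   three sequenced members gets another line's haplotype — the classic
#'   isolated conflict; verification should flag exactly this individual.
#' * `misplaced_branch`: a grandmother-mother-daughter chain inside one line
#'   is overwritten with a foreign haplotype (and enough concordant members
#'   are force-sequenced for the chain to be the minority), reproducing the
#'   signature of a whole branch recorded in the wrong line: the chain top
#'   is conflicting, its descendants are misplaced, and verification should
#'   report a single branch of three conflicts.
#'
#' The injection record in `truth$injections` stores everything needed to
#' revert the mutation.
#'
#' @param x a `synth_pedigree` from [synth_pedigree()].
#' @param mode `"single_individual"` or `"misplaced_branch"`.
#' @return The mutated `synth_pedigree` with an updated ground truth.
#' @export
inject_conflict <- function(x, mode = c("single_individual",
                                        "misplaced_branch")) {
  stopifnot(inherits(x, "synth_pedigree"))
  mode <- match.arg(mode)
  ped <- x$pedigree
  truth <- x$truth
  line <- truth$line_of[ped$id]
  hseq <- !is.na(ped$haplotype)
  touched <- unlist(lapply(truth$injections, function(j) j$ids),
                    use.names = FALSE)

  foreign_hap <- function(h) {
    pool <- setdiff(unique(truth$line_haplotype), h)
    if (!length(pool)) "HT_INJ" else sort(pool)[1L]
  }

  if (mode == "single_individual") {
    tab <- table(line[hseq])
    elig_lines <- names(tab)[tab >= 3L]
    elig_lines <- setdiff(elig_lines, unique(line[match(touched, ped$id)]))
    if (!length(elig_lines)) stop("no line with >= 3 sequenced members to inject into")
    ln <- if (length(elig_lines) == 1L) elig_lines else sample(elig_lines, 1L)
    members <- ped$id[hseq & line == ln]
    victim <- if (length(members) == 1L) members else sample(members, 1L)
    old <- ped$haplotype[ped$id == victim]
    new <- foreign_hap(old)
    ped$haplotype[ped$id == victim] <- new
    truth$injections <- c(truth$injections, list(list(
      mode = mode, ids = victim, line = ln,
      old_haplotype = old, new_haplotype = new)))
  } else {
    f <- build_forest(ped, "dam")
    # candidates: individuals with a grandmother in their line, in lines
    # large enough to force four concordant sequenced members
    line_size <- table(line)
    deep <- ped$id[f$depth >= 2L]
    deep <- deep[line_size[line[match(deep, ped$id)]] >= 7L]
    deep <- deep[!(line[match(deep, ped$id)] %in%
                     c(unique(line[match(touched, ped$id)])))]
    if (!length(deep)) stop("no line offers a reassignable 3-generation chain")
    tip <- if (length(deep) == 1L) deep else sample(deep, 1L)
    v <- match(tip, f$ids)
    m <- f$parent[v]
    gm <- f$parent[m]
    chain <- ped$id[c(gm, m, v)]
    ln <- line[[tip]]
    h_line <- truth$line_haplotype[[ln]]
    new <- foreign_hap(h_line)
    old_hap <- stats::setNames(ped$haplotype[match(chain, ped$id)], chain)
    ped$haplotype[match(chain, ped$id)] <- new
    # force at least 4 concordant sequenced members outside the chain
    others <- setdiff(ped$id[line == ln], chain)
    have <- others[!is.na(ped$haplotype[match(others, ped$id)])]
    need <- 4L - length(have)
    forced <- character()
    if (need > 0L) {
      cand <- setdiff(others, have)
      if (length(cand) < need) stop("line too small to anchor the branch injection")
      forced <- sort(cand)[seq_len(need)]
      ped$haplotype[match(forced, ped$id)] <- h_line
    }
    truth$injections <- c(truth$injections, list(list(
      mode = mode, ids = chain, line = ln,
      branch_root = chain[1L], branch_size = 3L,
      old_haplotype = old_hap, new_haplotype = new,
      forced_sequenced = forced)))
  }
  attr(ped, "has_haplotype") <- TRUE
  x$pedigree <- ped
  x$truth <- truth
  x
}
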