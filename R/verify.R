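#' Enumerate conflicting pairs of haplotyped individuals
#'
#' A conflicting pair is two sequenced individuals in the same maternal line
#' that carry different haplotypes — impossible under error-free maternal
#' transmission, hence a pedigree-recording (or sample) error signal.
#'
#' @param f a [maternal_forest][build_forest].
#' @param ped the [pedigree] the forest was built from.
#' @return A data frame with columns `i`, `j` (unordered pairs, `i < j`
#'   lexicographically) and `line` (the shared line root).
#' @export
find_conflicting_pairs <- function(f, ped) {
  hseq <- which(!is.na(ped$haplotype))
  out <- list()
  for (members in split(hseq, f$root[hseq])) {
    if (length(members) < 2L) next
    haps <- ped$haplotype[members]
    if (length(unique(haps)) < 2L) next
    idx <- t(utils::combn(seq_along(members), 2L))
    diff <- haps[idx[, 1L]] != haps[idx[, 2L]]
    if (!any(diff)) next
    a <- ped$id[members[idx[diff, 1L]]]
    b <- ped$id[members[idx[diff, 2L]]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out[[length(out) + 1L]] <- data.frame(
      i = a, j = b, line = f$root[members[1L]], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(i = character(), j = character(), line = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Flag conflicting individuals from a pair list
#'
#' An individual is conflicting when it has more pairwise conflicts than
#' every individual it is in conflict with. Under the default `"both"` tie
#' rule, equal conflict counts flag both members of the tie (a 1-vs-1
#' conflict is otherwise unattributable); `"strict"` applies the
#' more-conflicts-than rule literally.
#'
#' @param pairs a data frame of conflicting pairs as returned by
#'   [find_conflicting_pairs()].
#' @param tie_rule `"both"` (default) or `"strict"`.
#' @return Character vector of flagged individual ids.
#' @export
flag_conflicting_individuals <- function(pairs, tie_rule = c("both", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (!nrow(pairs)) return(character())
  cnt <- table(c(pairs$i, pairs$j))
  ids <- names(cnt)
  flagged <- vapply(ids, function(v) {
    opp <- c(pairs$j[pairs$i == v], pairs$i[pairs$j == v])
    m <- max(cnt[opp])
    if (tie_rule == "strict") cnt[[v]] > m else cnt[[v]] >= m
  }, logical(1))
  sort(ids[flagged])
}

#' Find informative individuals
#'
#' An informative individual lies on the tree path between two haplotyped
#' individuals of the same line (endpoints included). Only this part of the
#' pedigree enters the conflict analysis.
#'
#' @inheritParams find_conflicting_pairs
#' @return Character vector of informative individual ids.
#' @export
find_informative_individuals <- function(f, ped) {
  n <- length(f$ids)
  is_hap <- !is.na(ped$haplotype)
  h_sub <- .subtree_count(f, is_hap)
  # haplotyped individuals per line
  H_line <- stats::setNames(rep(0L, length(f$founders)), f$founders)
  tab <- table(f$root[is_hap])
  H_line[names(tab)] <- as.integer(tab)
  H_here <- H_line[f$root]
  # number of child subtrees of each node holding >= 1 haplotyped individual
  has_par <- which(!is.na(f$parent) & h_sub > 0L)
  n_hap_kids <- integer(n)
  if (length(has_par)) {
    tb <- table(f$parent[has_par])
    n_hap_kids[as.integer(names(tb))] <- as.integer(tb)
  }
  below <- h_sub - as.integer(is_hap)      # haplotyped strict descendants
  outside <- H_here - h_sub                # haplotyped outside own subtree
  informative <- (is_hap & H_here >= 2L) |
    (n_hap_kids >= 2L) |
    (below > 0L & outside > 0L)
  sort(f$ids[informative])
}

#' Find misplaced individuals and misplaced branches
#'
#' A conflicting individual is *misplaced* when its nearest haplotyped
#' maternal ancestor carries the same haplotype: the signature of a whole
#' branch recorded in the wrong line, so that all its conflicts stem from a
#' single error. A misplaced branch is reported at its anchor — the topmost
#' conflicting individual whose subtree the misplaced individuals repeat the
#' haplotype of — with the number of conflicting individuals in that
#' subtree; nested anchors merge into the outermost.
#'
#' @inheritParams find_conflicting_pairs
#' @param conflicting character vector of conflicting individual ids (see
#'   [flag_conflicting_individuals()]).
#' @return A list with `misplaced` (character vector) and `branches` (data
#'   frame with columns `root` and `n_conflicts`).
#' @export
find_misplaced <- function(f, ped, conflicting) {
  n <- length(f$ids)
  empty <- list(misplaced = character(),
                branches = data.frame(root = character(),
                                      n_conflicts = integer(),
                                      stringsAsFactors = FALSE))
  if (!length(conflicting)) return(empty)
  conf <- f$ids %in% conflicting
  nha <- .nha_all(f, ped$haplotype)
  has_anc <- !is.na(nha)
  same_hap <- rep(FALSE, n)
  same_hap[has_anc] <- ped$haplotype[nha[has_anc]] == ped$haplotype[has_anc] &
    !is.na(ped$haplotype[has_anc])
  misplaced <- which(conf & has_anc & same_hap)
  if (!length(misplaced)) return(empty)

  # branch anchors: misplaced individuals plus the haplotyped ancestors they
  # repeat (always conflicting, same haplotype); keep the maximal elements
  in_set <- rep(FALSE, n)
  in_set[misplaced] <- TRUE
  in_set[nha[misplaced]] <- TRUE
  # has_set_anc[v]: some strict ancestor of v is in the set
  has_set_anc <- rep(FALSE, n)
  for (d in sort(unique(f$depth[f$depth > 0L]))) {
    vs <- which(f$depth == d)
    ps <- f$parent[vs]
    has_set_anc[vs] <- in_set[ps] | has_set_anc[ps]
  }
  roots <- which(in_set & !has_set_anc)
  c_sub <- .subtree_count(f, conf)
  branches <- data.frame(root = f$ids[roots],
                         n_conflicts = c_sub[roots],
                         stringsAsFactors = FALSE)
  branches <- branches[order(branches$root), , drop = FALSE]
  rownames(branches) <- NULL
  list(misplaced = sort(f$ids[misplaced]), branches = branches)
}

#' Verify haplotype segregation along maternal lines
#'
#' Runs the full concordance analysis: conflicting pairs and individuals,
#' informative individuals, misplaced individuals and branches, and the
#' three pedigree-reliability indices —
#' `HC` (percent conflicting among all haplotyped individuals),
#' `IC` (percent conflicting among informative individuals) and
#' `MISPLACED` (percent misplaced among conflicting individuals) — plus the
#' pruned conflict count in which each misplaced branch contributes a single
#' error.
#'
#' Conflict counts are computed from per-line haplotype tallies (an
#' individual's conflict count is the number of same-line haplotyped
#' individuals with a different haplotype), which is equivalent to pair
#' enumeration but linear in pedigree size.
#'
#' @param ped a [pedigree] with a haplotype column, free of fatal errors.
#' @param forest optional precomputed [maternal_forest][build_forest].
#' @param tie_rule tie handling for flagging, `"both"` (default) or
#'   `"strict"`; see [flag_conflicting_individuals()].
#' @param include_pairs if `TRUE` (default) the enumerated pair list is
#'   stored in the report (automatically skipped when more than
#'   `max_pairs` pairs exist).
#' @param max_pairs cap on stored pairs.
#' @return An object of class `conflict_report`.
#' @examples
#' p <- pedigree(id = c("F", "x", "y", "z"),
#'               dam = c(NA, "F", "F", "F"), gender = "F",
#'               haplotype = c(NA, "A", "A", "B"))
#' verify_pedigree(p)
#' @export
verify_pedigree <- function(ped, forest = NULL,
                            tie_rule = c("both", "strict"),
                            include_pairs = TRUE, max_pairs = 10000L) {
  stopifnot(inherits(ped, "pedigree"))
  tie_rule <- match.arg(tie_rule)
  f <- forest %||% build_forest(ped, "dam")

  hap <- ped$haplotype
  hseq <- !is.na(hap)
  n_hap <- sum(hseq)

  # per line x haplotype counts
  key <- paste0(f$root, "\r", hap)
  key[!hseq] <- NA
  n_lh <- table(key[hseq])
  H_tab <- table(f$root[hseq])

  n_same <- as.integer(n_lh[key[hseq]])
  H_here <- as.integer(H_tab[f$root[hseq]])
  conflict_count <- H_here - n_same
  # total pairs per line: (H^2 - sum over haplotypes n_h^2) / 2
  pl <- split(seq_len(n_hap), f$root[hseq])
  n_pairs_total <- sum(vapply(pl, function(ix) {
    H <- length(ix)
    nh <- table(hap[hseq][ix])
    (H * H - sum(as.numeric(nh)^2)) / 2
  }, numeric(1)))

  # flag rule via per-line minima of haplotype counts (two-minima trick)
  flagged <- logical(n_hap)
  if (any(conflict_count > 0L)) {
    line_of_h <- f$root[hseq]
    hap_h <- hap[hseq]
    for (ln in names(H_tab)[as.integer(H_tab) >= 2L]) {
      ix <- which(line_of_h == ln)
      nh <- table(hap_h[ix])
      if (length(nh) < 2L) next
      cnts <- as.integer(nh)
      o <- order(cnts)
      min1 <- cnts[o[1L]]
      n_at_min <- sum(cnts == min1)
      min2 <- if (length(cnts) > 1L) cnts[o[2L]] else Inf
      my <- as.integer(nh[hap_h[ix]])
      min_other <- ifelse(my == min1 & n_at_min == 1L, min2, min1)
      flagged[ix] <- if (tie_rule == "strict") my < min_other else my <= min_other
    }
  }
  conflicting <- sort(ped$id[hseq][flagged])
  cc_map <- stats::setNames(conflict_count[flagged], ped$id[hseq][flagged])
  cc_map <- cc_map[order(names(cc_map))]

  informative <- find_informative_individuals(f, ped)
  mp <- find_misplaced(f, ped, conflicting)

  pairs <- NULL
  if (include_pairs && n_pairs_total <= max_pairs) {
    pairs <- find_conflicting_pairs(f, ped)
  }

  idx <- compute_indices(n_haplotyped = n_hap,
                         conflicting = conflicting,
                         informative = informative,
                         misplaced = mp$misplaced,
                         branches = mp$branches)

  structure(c(list(conflicting_pairs = pairs,
                   n_conflicting_pairs = as.integer(n_pairs_total),
                   conflict_count = cc_map,
                   conflicting_individuals = conflicting,
                   informative_individuals = informative,
                   misplaced_individuals = mp$misplaced,
                   misplaced_branches = mp$branches,
                   n_haplotyped = n_hap,
                   tie_rule = tie_rule),
              idx),
            class = "conflict_report")
}

#' Reliability indices from verification components
#'
#' `HC = 100 |conflicting| / |haplotyped|`,
#' `IC = 100 |conflicting ∩ informative| / |informative|`,
#' `MISPLACED = 100 |misplaced| / |conflicting|`, and the pruned conflict
#' count `|conflicting| - sum(branch conflicts - 1)`. Indices with an empty
#' denominator are `NA` with the reason recorded.
#'
#' @param n_haplotyped number of haplotyped individuals.
#' @param conflicting,informative,misplaced character vectors of ids.
#' @param branches misplaced-branch data frame (`root`, `n_conflicts`).
#' @return A list with `hc_index`, `ic_index`, `misplaced_index`,
#'   `pruned_conflicts` and `undefined` (named reasons for NA indices).
#' @export
compute_indices <- function(n_haplotyped, conflicting, informative,
                            misplaced, branches) {
  undefined <- character()
  hc <- if (n_haplotyped > 0L) 100 * length(conflicting) / n_haplotyped else {
    undefined["hc_index"] <- "no haplotyped individuals"
    NA_real_
  }
  ic <- if (length(informative) > 0L) {
    100 * length(intersect(conflicting, informative)) / length(informative)
  } else {
    undefined["ic_index"] <- "no informative individuals"
    NA_real_
  }
  mis <- if (length(conflicting) > 0L) {
    100 * length(misplaced) / length(conflicting)
  } else {
    undefined["misplaced_index"] <- "no conflicting individuals"
    NA_real_
  }
  pruned <- length(conflicting) -
    sum(pmax(branches$n_conflicts - 1L, 0L))
  list(hc_index = hc, ic_index = ic, misplaced_index = mis,
       pruned_conflicts = as.integer(pruned), undefined = undefined)
}

#' @export
print.conflict_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("Maternal-line haplotype concordance report\n")
  cat("  haplotyped individuals:   ", x$n_haplotyped, "\n")
  cat("  conflicting pairs:        ", x$n_conflicting_pairs, "\n")
  cat("  conflicting individuals:  ", length(x$conflicting_individuals),
      sprintf(" (tie rule: %s)", x$tie_rule), "\n")
  cat("  informative individuals:  ", length(x$informative_individuals), "\n")
  cat("  misplaced individuals:    ", length(x$misplaced_individuals), "\n")
  cat("  misplaced branches:       ", nrow(x$misplaced_branches), "\n")
  cat("  HC index:                 ", fmt(x$hc_index), "\n")
  cat("  IC index:                 ", fmt(x$ic_index), "\n")
  cat("  MISPLACED index:          ", fmt(x$misplaced_index), "\n")
  cat("  pruned conflict count:    ", x$pruned_conflicts, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
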