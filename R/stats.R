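#' Reference population for a year window
#'
#' All individuals with a recorded year of birth inside the window
#' (inclusive bounds). Individuals with a missing birth year are never
#' members of the reference population.
#'
#' @param ped a [pedigree].
#' @param window integer `c(first, last)` as from [read_reference_window()].
#' @return Character vector of member ids (warns when empty).
#' @export
reference_population <- function(ped, window) {
  stopifnot(inherits(ped, "pedigree"), length(window) == 2L)
  if (window[1] > window[2]) stop("reference window: first year after last year")
  keep <- !is.na(ped$yob) & ped$yob >= window[1] & ped$yob <= window[2]
  ids <- ped$id[keep]
  if (!length(ids)) {
    warning("reference population is empty for window ",
            window[1], "-", window[2],
            "; effective sizes are undefined")
  }
  ids
}

#' Impute mtDNA haplotypes along maternal lines
#'
#' Under error-free maternal transmission every member of a line shares the
#' haplotype of its sequenced members, so one sequenced individual types the
#' whole line. Lines without any sequenced member remain unassigned (`NA`);
#' the effective-size calculation later gives each such line a unique
#' pseudo-haplotype.
#'
#' The imputation requires a conflict-free pedigree: if any line carries two
#' different haplotypes the function refuses and directs the user to the
#' verification step.
#'
#' @param f a [maternal_forest][build_forest].
#' @param ped the [pedigree] the forest was built from.
#' @return Named character vector mapping every individual id to its line
#'   haplotype (`NA` when the line has no sequenced member).
#' @export
impute_haplotypes <- function(f, ped) {
  hseq <- !is.na(ped$haplotype)
  line_hap <- tapply(ped$haplotype[hseq], f$root[hseq],
                     function(h) unique(h))
  bad <- names(line_hap)[lengths(line_hap) > 1L]
  if (length(bad)) {
    stop("haplotype conflicts present in line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; run the verification step (verif) and resolve them before imputation",
         call. = FALSE)
  }
  lh <- stats::setNames(vapply(line_hap, `[`, character(1), 1L),
                        names(line_hap))
  out <- rep(NA_character_, nrow(ped))
  m <- match(f$root, names(lh))
  out[!is.na(m)] <- lh[m[!is.na(m)]]
  stats::setNames(out, ped$id)
}

#' Maternal-line membership and reference-population distributions
#'
#' For every founder dam line: total descendants, members of the reference
#' population (all and females only), and the imputed line haplotype. Lines
#' represented in the reference population are split into those with at
#' least one female member (these drive the maternal effective size) and
#' those represented only by males (these still contribute to the haplotype
#' effective size).
#'
#' @param f a [maternal_forest][build_forest] built on dam links.
#' @param ped the [pedigree].
#' @param refpop character vector of reference-population ids (see
#'   [reference_population()]).
#' @param imputed optional precomputed result of [impute_haplotypes()]; when
#'   `NULL` and the pedigree is conflict-free it is computed, otherwise line
#'   haplotypes are reported as `NA`.
#' @return An object of class `line_distribution`: a list with `table` (one
#'   row per line root: `founder`, `total`, `ref_all`, `ref_female`,
#'   `haplotype`), `lines_with_ref_females`, `lines_males_only_in_ref`, and
#'   the population totals.
#' @export
line_distributions <- function(f, ped, refpop, imputed = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(imputed)) {
    imputed <- tryCatch(impute_haplotypes(f, ped),
                        error = function(e) stats::setNames(
                          rep(NA_character_, nrow(ped)), ped$id))
  }
  in_ref <- ped$id %in% refpop
  is_f <- !is.na(ped$gender) & ped$gender == "F"
  lev <- f$founders
  cnt <- function(keep) {
    tb <- table(factor(f$root[keep], levels = lev))
    as.integer(tb)
  }
  tab <- data.frame(founder = lev,
                    total = cnt(rep(TRUE, nrow(ped))),
                    ref_all = cnt(in_ref),
                    ref_female = cnt(in_ref & is_f),
                    haplotype = unname(imputed[match(lev, ped$id)]),
                    stringsAsFactors = FALSE)
  structure(list(
    table = tab,
    members = split(ped$id, factor(f$root, levels = lev)),
    flat_membership = stats::setNames(f$root, ped$id),
    lines_with_ref_females = tab$founder[tab$ref_female >= 1L],
    lines_males_only_in_ref = tab$founder[tab$ref_all >= 1L & tab$ref_female == 0L],
    n_individuals = nrow(ped),
    n_reference = sum(in_ref),
    n_reference_females = sum(in_ref & is_f),
    window_members = refpop),
    class = "line_distribution")
}

#' @export
print.line_distribution <- function(x, ...) {
  cat("Maternal-line distribution over", nrow(x$table), "lines\n")
  cat("  pedigree size:", x$n_individuals,
      "| reference population:", x$n_reference,
      "(", x$n_reference_females, "females )\n")
  cat("  lines with females in the reference population:",
      length(x$lines_with_ref_females), "\n")
  cat("  lines with only males in the reference population:",
      length(x$lines_males_only_in_ref), "\n")
  print.data.frame(utils::head(x$table, 15L))
  if (nrow(x$table) > 15L) cat("  ... and", nrow(x$table) - 15L, "more lines\n")
  invisible(x)
}
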