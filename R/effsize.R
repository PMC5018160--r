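#' Probability of identity
#'
#' The probability that two line labels drawn at random (with replacement)
#' coincide: the sum of squared label frequencies. For `k` equally frequent
#' labels it equals `1/k`.
#'
#' @param freq named numeric vector of label frequencies summing to one.
#' @return A probability in `(0, 1]`.
#' @examples
#' prob_identity(c(a = 0.75, b = 0.25))  # 0.625
#' @export
prob_identity <- function(freq) {
  if (!length(freq)) stop("empty frequency map")
  if (any(freq < 0)) stop("negative frequency")
  if (abs(sum(freq) - 1) > 1e-8) stop("frequencies must sum to 1")
  sum(freq^2)
}

#' Relative increase in identity from founder to reference population
#'
#' `delta_pi = (pi_r - pi_f) / (1 - pi_f)`: the share of the founder
#' population's remaining diversity that has been lost by the reference
#' population. Zero when line representation is unchanged, one at fixation.
#'
#' @param pi_f,pi_r probabilities of identity in the founder and reference
#'   populations.
#' @return A real number (`NA` with an error when `pi_f == 1`, i.e. a single
#'   founder line).
#' @export
delta_pi <- function(pi_f, pi_r) {
  if (pi_f >= 1) {
    stop("probability of identity in the founder population is 1 ",
         "(single founder line); the increase in identity is undefined")
  }
  (pi_r - pi_f) / (1 - pi_f)
}

#' Effective size of a uniparental line system
#'
#' `Ne = 1 / delta_pi`; infinite when identity has not increased.
#'
#' @param delta the increase in identity from [delta_pi()]; must be
#'   non-negative (a negative value signals inconsistent founder/reference
#'   inputs and is a hard error, not clamped).
#' @return A positive real, or `Inf` when `delta == 0`.
#' @export
effective_size <- function(delta) {
  if (is.na(delta)) return(NA_real_)
  if (delta < 0) {
    stop("negative increase in identity (", format(delta),
         "): founder and reference populations are inconsistent")
  }
  if (delta == 0) Inf else 1 / delta
}

# founder dams of a dam-link forest = line roots that are not recorded males
# (symmetrically, founder sires of a sire-link forest are non-female roots)
.founder_parents <- function(f, ped) {
  g <- ped$gender[match(f$founders, ped$id)]
  bad <- if (f$link == "dam") "M" else "F"
  f$founders[is.na(g) | g != bad]
}

#' Founder and reference frequencies of maternal (or paternal) lines
#'
#' In the founder population every founder dam has frequency `1/k`. In the
#' reference population a dam's frequency is the number of her female line
#' members in the reference population divided by all reference females
#' (males do not transmit mtDNA to offspring); dams without reference
#' females drop from the reference map. With a sire-link forest the roles of
#' the sexes are mirrored.
#'
#' @param f a [maternal_forest][build_forest].
#' @param ped the [pedigree].
#' @param refpop character vector of reference-population ids.
#' @return List with named numeric vectors `founder` and `reference`.
#' @export
maternal_frequencies <- function(f, ped, refpop) {
  founders <- .founder_parents(f, ped)
  k <- length(founders)
  if (k == 0L) stop("no founder ", if (f$link == "dam") "dams" else "sires",
                    " in the pedigree")
  sex <- if (f$link == "dam") "F" else "M"
  in_ref <- ped$id %in% refpop
  keep <- in_ref & !is.na(ped$gender) & ped$gender == sex
  if (!any(keep)) {
    stop("no reference-population ", if (sex == "F") "females" else "males",
         "; this effective size is undefined")
  }
  tb <- table(factor(f$root[keep], levels = founders))
  tb <- tb[tb > 0L]
  list(founder = stats::setNames(rep(1 / k, k), founders),
       reference = stats::setNames(as.numeric(tb) / sum(tb), names(tb)))
}

#' Founder and reference frequencies of mtDNA haplotype lines
#'
#' Line haplotypes come from [impute_haplotypes()]; every line without a
#' sequenced member (its founder dam's haplotype is unknown) is assigned the
#' unique pseudo-haplotype `PSEUDO_<founder id>` so that it counts as its
#' own haplotype line. The founder map is the haplotype frequency among
#' founder dams; the reference map counts all reference individuals of both
#' sexes, since every individual carries its line's mtDNA.
#'
#' @inheritParams maternal_frequencies
#' @param imputed optional precomputed [impute_haplotypes()] result.
#' @return List with named numeric vectors `founder` and `reference`.
#' @export
haplotype_frequencies <- function(f, ped, refpop, imputed = NULL) {
  if (is.null(imputed)) imputed <- impute_haplotypes(f, ped)
  founders <- .founder_parents(f, ped)
  if (!length(founders)) stop("no founder dams in the pedigree")
  label <- imputed[f$ids]
  pseudo <- is.na(label)
  label[pseudo] <- paste0("PSEUDO_", f$root[pseudo])
  label <- stats::setNames(label, f$ids)

  fl <- label[founders]
  founder_map <- table(fl) / length(founders)

  in_ref <- f$ids %in% refpop
  if (!any(in_ref)) stop("reference population is empty; haplotype effective size is undefined")
  rl <- table(label[in_ref])
  list(founder = stats::setNames(as.numeric(founder_map), names(founder_map)),
       reference = stats::setNames(as.numeric(rl) / sum(rl), names(rl)))
}

.effsize_from_freq <- function(freqs, mode) {
  pi_f <- prob_identity(freqs$founder)
  pi_r <- prob_identity(freqs$reference)
  if (pi_f >= 1) {
    d <- NA_real_
    ne <- NA_real_
    reason <- "single founder line: increase in identity undefined"
  } else {
    d <- delta_pi(pi_f, pi_r)
    ne <- effective_size(d)
    reason <- NULL
  }
  structure(list(mode = mode, pi_founder = pi_f, pi_reference = pi_r,
                 delta_pi = d, ne = ne,
                 frequencies_founder = freqs$founder,
                 frequencies_reference = freqs$reference,
                 undefined_reason = reason),
            class = "effsize_result")
}

#' Effective population sizes of maternal, haplotype and paternal lines
#'
#' Computes, for each requested mode, the probability of identity in the
#' founder and reference populations, the relative increase in identity and
#' the effective size `Ne = 1/delta_pi`:
#' * `maternal` — founder-dam lines weighted by reference females (pedigree
#'   information only);
#' * `haplotype` — mtDNA haplotype lines over all reference individuals,
#'   after line-wide imputation (molecular information; requires a
#'   conflict-free pedigree);
#' * `paternal` — the mirrored sire-line calculation over reference males.
#'
#' @param ped a [pedigree] free of fatal errors.
#' @param window reference year window `c(first, last)`; defaults to the
#'   full span of recorded birth years.
#' @param modes subset of `c("maternal", "haplotype", "paternal")`.
#' @param forest optional precomputed dam-link forest.
#' @return An object of class `effsize_set`: a named list of
#'   `effsize_result` objects plus the window and population sizes.
#' @examples
#' p <- pedigree(id = c("A", "B", "a1", "a2", "a3", "b1"),
#'               dam = c(NA, NA, "A", "A", "A", "B"),
#'               gender = "F", yob = c(2000, 2000, 2010, 2010, 2010, 2010),
#'               haplotype = c("H1", "H2", NA, NA, NA, NA))
#' effective_sizes(p, window = c(2010, 2010), modes = "maternal")
#' @export
effective_sizes <- function(ped, window = NULL,
                            modes = c("maternal", "haplotype", "paternal"),
                            forest = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(window)) window <- read_reference_window(NULL, ped)
  refpop <- reference_population(ped, window)
  f <- forest %||% build_forest(ped, "dam")
  out <- list()
  if ("maternal" %in% modes) {
    out$maternal <- .effsize_from_freq(maternal_frequencies(f, ped, refpop),
                                       "maternal")
  }
  if ("haplotype" %in% modes) {
    out$haplotype <- .effsize_from_freq(haplotype_frequencies(f, ped, refpop),
                                        "haplotype")
  }
  if ("paternal" %in% modes) {
    fp <- build_forest(ped, "sire")
    out$paternal <- .effsize_from_freq(maternal_frequencies(fp, ped, refpop),
                                       "paternal")
  }
  structure(list(results = out, window = window,
                 n_reference = length(refpop),
                 n_individuals = nrow(ped)),
            class = "effsize_set")
}

#' @export
print.effsize_result <- function(x, ...) {
  cat(sprintf("%s lines: PI_f = %.6f, PI_r = %.6f, delta_PI = %s, Ne = %s\n",
              x$mode, x$pi_founder, x$pi_reference,
              if (is.na(x$delta_pi)) "undefined" else sprintf("%.6f", x$delta_pi),
              if (is.na(x$ne)) "undefined" else if (is.infinite(x$ne)) "infinite"
              else sprintf("%.2f", x$ne)))
  if (!is.null(x$undefined_reason)) cat("  (", x$undefined_reason, ")\n")
  invisible(x)
}

#' @export
print.effsize_set <- function(x, ...) {
  cat("Effective population sizes (reference window ",
      x$window[1], "-", x$window[2], ", ", x$n_reference,
      " of ", x$n_individuals, " individuals)\n", sep = "")
  for (r in x$results) print(r)
  invisible(x)
}
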