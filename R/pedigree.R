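#' Construct a pedigree object
#'
#' A pedigree is a data frame with one row per individual and the normalized
#' columns `id`, `sire`, `dam`, `yob`, `gender`, `haplotype`, `available`.
#' Unknown parents are stored as `NA`; gender is `"F"`, `"M"` or `NA`;
#' `haplotype` is `NA` for unsequenced individuals; `available` is a logical
#' flag used by the sampling planner.
#'
#' @param id character vector of individual identifiers; must be non-empty and
#'   unique.
#' @param sire,dam parent identifiers; tokens listed in `unknown_tokens` (and
#'   `NA`) mean "unknown parent".
#' @param yob integer year of birth; anything non-numeric becomes `NA`.
#' @param gender gender tokens, mapped through `male_tokens`/`female_tokens`;
#'   unrecognized tokens become unknown (`NA`).
#' @param haplotype optional mtDNA haplotype labels (`NULL` if the pedigree
#'   carries no haplotype information; empty strings become `NA`).
#' @param available optional availability flags for sampling. Exactly the
#'   token `"1"` (or logical `TRUE`) counts as available; anything else is a
#'   valid negation.
#' @param male_tokens,female_tokens accepted gender spellings.
#' @param unknown_tokens tokens that denote an unknown parent.
#' @return An object of class `pedigree` (a data frame). Attributes
#'   `has_haplotype` and `has_available` record whether the optional columns
#'   were supplied.
#' @examples
#' p <- pedigree(id = c("F1", "a", "b"),
#'               dam = c(NA, "F1", "a"),
#'               gender = c("F", "F", "F"),
#'               yob = c(2000, 2005, 2010),
#'               haplotype = c("HT1", NA, "HT1"))
#' summary(p)
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_,
                     yob = NA_integer_, gender = NA_character_,
                     haplotype = NULL, available = NULL,
                     male_tokens = c("M", "m", "1"),
                     female_tokens = c("F", "f", "2"),
                     unknown_tokens = c("", "0")) {
  id <- trimws(as.character(id))
  n <- length(id)
  if (n == 0L) stop("pedigree must contain at least one individual")
  if (anyNA(id) || any(id == "")) stop("individual ids must be non-empty")
  if (anyDuplicated(id)) {
    dups <- unique(id[duplicated(id)])
    stop("duplicated individual id(s): ", paste(dups, collapse = ", "))
  }

  norm_parent <- function(x) {
    x <- trimws(as.character(rep_len(x, n)))
    x[is.na(x) | x %in% unknown_tokens] <- NA_character_
    x
  }
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)

  gender <- trimws(as.character(rep_len(gender, n)))
  g <- rep(NA_character_, n)
  g[gender %in% male_tokens] <- "M"
  g[gender %in% female_tokens] <- "F"

  yob <- suppressWarnings(as.integer(rep_len(yob, n)))

  has_hap <- !is.null(haplotype)
  if (has_hap) {
    haplotype <- trimws(as.character(rep_len(haplotype, n)))
    haplotype[haplotype == ""] <- NA_character_
  } else {
    haplotype <- rep(NA_character_, n)
  }

  has_avail <- !is.null(available)
  if (has_avail) {
    if (is.logical(available)) {
      avail <- rep_len(available, n)
      avail[is.na(avail)] <- FALSE
    } else {
      avail <- trimws(as.character(rep_len(available, n))) == "1"
      avail[is.na(avail)] <- FALSE
    }
  } else {
    avail <- rep(FALSE, n)
  }

  out <- data.frame(id = id, sire = sire, dam = dam, yob = yob, gender = g,
                    haplotype = haplotype, available = avail,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("pedigree", "data.frame"),
            has_haplotype = has_hap,
            has_available = has_avail)
}

#' Coerce a data frame to a pedigree
#'
#' Columns are located by the header keywords `ID`, `father`, `mother`, `YOB`,
#' `gender` and the optional `haplotype` and `available` (case-insensitive);
#' extra columns are ignored.
#'
#' @param x a data frame.
#' @param ... passed on to [pedigree()] (token sets).
#' @return A [pedigree] object.
#' @export
as_pedigree <- function(x, ...) {
  if (inherits(x, "pedigree")) return(x)
  x <- as.data.frame(x)
  nm <- tolower(trimws(names(x)))
  pick <- function(key) {
    i <- match(key, nm)
    if (is.na(i)) NULL else x[[i]]
  }
  mandatory <- c("id", "father", "mother", "yob", "gender")
  missing_kw <- mandatory[!(mandatory %in% nm)]
  if (length(missing_kw)) {
    stop("missing mandatory header keyword(s): ",
         paste(missing_kw, collapse = ", "))
  }
  pedigree(id = pick("id"), sire = pick("father"), dam = pick("mother"),
           yob = pick("yob"), gender = pick("gender"),
           haplotype = pick("haplotype"), available = pick("available"), ...)
}

#' Read a pedigree CSV file
#'
#' The file must be comma-separated with a header line containing the five
#' mandatory keywords `ID`, `father`, `mother`, `YOB`, `gender` and optionally
#' `haplotype` and `available`, in any column order (keyword position in the
#' header determines the column). Extra columns are ignored. Fields are plain
#' tokens; quoting is not supported.
#'
#' @param path path to the CSV file.
#' @inheritParams pedigree
#' @return A [pedigree] object.
#' @seealso [write_pedigree()], [check_fatal_errors()],
#'   [autocorrect_missing_parents()]
#' @export
read_pedigree <- function(path, unknown_tokens = c("", "0"),
                          male_tokens = c("M", "m", "1"),
                          female_tokens = c("F", "f", "2")) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- tolower(trimws(header))
  mandatory <- c("id", "father", "mother", "yob", "gender")
  missing_kw <- mandatory[!(mandatory %in% header)]
  if (length(missing_kw)) {
    stop("missing mandatory header keyword(s): ",
         paste(missing_kw, collapse = ", "))
  }
  used <- c(mandatory, intersect(c("haplotype", "available"), header))
  need <- max(match(used, header))
  nf <- utils::count.fields(path, sep = ",", quote = "")
  short <- which(nf < need)
  short <- short[short > 1L]
  if (length(short)) {
    stop("row(s) shorter than the mapped header columns at line(s): ",
         paste(utils::head(short, 10L), collapse = ", "))
  }
  df <- utils::read.csv(path, header = FALSE, skip = 1L,
                        colClasses = "character", quote = "",
                        strip.white = TRUE, blank.lines.skip = TRUE)
  col <- function(key) {
    i <- match(key, header)
    if (is.na(i)) NULL else df[[i]]
  }
  pedigree(id = col("id"), sire = col("father"), dam = col("mother"),
           yob = col("yob"), gender = col("gender"),
           haplotype = col("haplotype"), available = col("available"),
           male_tokens = male_tokens, female_tokens = female_tokens,
           unknown_tokens = unknown_tokens)
}

#' Write a pedigree back to CSV
#'
#' Emits the canonical header `ID,father,mother,YOB,gender[,haplotype][,available]`.
#' Unknown parents and missing values become empty fields; availability is
#' written as `"1"`/empty. Reading the result back with [read_pedigree()]
#' reproduces the pedigree field-for-field.
#'
#' @param ped a [pedigree].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(ID = ped$id,
                    father = ifelse(is.na(ped$sire), "", ped$sire),
                    mother = ifelse(is.na(ped$dam), "", ped$dam),
                    YOB = ifelse(is.na(ped$yob), "", as.character(ped$yob)),
                    gender = ifelse(is.na(ped$gender), "", ped$gender),
                    stringsAsFactors = FALSE)
  if (isTRUE(attr(ped, "has_haplotype"))) {
    out$haplotype <- ifelse(is.na(ped$haplotype), "", ped$haplotype)
  }
  if (isTRUE(attr(ped, "has_available"))) {
    out$available <- ifelse(ped$available, "1", "")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "individuals\n")
  cat("  haplotype column:", if (isTRUE(attr(x, "has_haplotype"))) "yes" else "no",
      "| available column:", if (isTRUE(attr(x, "has_available"))) "yes" else "no", "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  n <- nrow(object)
  cat("Pedigree:", n, "individuals;",
      sum(object$gender == "F", na.rm = TRUE), "females,",
      sum(object$gender == "M", na.rm = TRUE), "males,",
      sum(is.na(object$gender)), "unknown gender\n")
  cat("  birth years:",
      if (all(is.na(object$yob))) "none recorded" else
        paste(range(object$yob, na.rm = TRUE), collapse = "-"),
      "(", sum(is.na(object$yob)), "missing )\n")
  cat("  haplotyped:", sum(!is.na(object$haplotype)), "individuals,",
      length(unique(stats::na.omit(object$haplotype))), "distinct haplotypes\n")
  if (isTRUE(attr(object, "has_available"))) {
    cat("  available for sampling:", sum(object$available), "\n")
  }
  invisible(object)
}

#' Read (or derive) the reference-population year window
#'
#' The optional side file holds two integer lines: the first and last year of
#' birth of the reference population. When the file is absent the window
#' defaults to the full span of recorded birth years in the pedigree.
#'
#' @param path path to the two-line years file (may be missing).
#' @param ped a [pedigree]; used for the default window when `path` does not
#'   exist.
#' @return Integer vector `c(first, last)`.
#' @export
read_reference_window <- function(path = NULL, ped = NULL) {
  if (!is.null(path) && file.exists(path)) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[lines != ""]
    if (length(lines) < 2L) {
      stop("reference-years file must contain two lines (first and last year)")
    }
    yrs <- suppressWarnings(as.integer(lines[1:2]))
    if (anyNA(yrs)) stop("reference-years file contains non-integer lines")
    if (yrs[1] > yrs[2]) {
      stop("reference-years file: first year (", yrs[1],
           ") is after last year (", yrs[2], ")")
    }
    return(stats::setNames(yrs, c("first", "last")))
  }
  if (is.null(ped)) stop("no reference-years file and no pedigree to derive a default window from")
  yob <- ped$yob[!is.na(ped$yob)]
  if (!length(yob)) stop("pedigree has no recorded birth years; cannot derive a reference window")
  stats::setNames(as.integer(range(yob)), c("first", "last"))
}

#' Read the planned number of sequencings
#'
#' @param path path to a one-line file holding the intended sampling budget.
#' @return A single non-negative integer.
#' @export
read_budget <- function(path) {
  if (!file.exists(path)) stop("planned-sequencings file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  n <- suppressWarnings(as.integer(lines[1]))
  if (!length(lines) || is.na(n) || n < 0L) {
    stop("planned-sequencings file must contain one non-negative integer")
  }
  n
}
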