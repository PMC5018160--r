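#' Write the named report files for an analysis result
#'
#' Each analysis stage emits plain-text reports with fixed, self-explanatory
#' file names of the form `Output<Module>_<Content>.txt`; the maternal-line
#' statistics additionally get machine-readable CSV twins. Dispatches on the
#' result class:
#' * `conflict_report` → `OutputVerif_Summary.txt`,
#'   `OutputVerif_ConflictingUnits.txt`, `OutputVerif_MisplacedBranches.txt`
#' * `line_distribution` → the six `OutputStat_*` files (+ `.csv` twins)
#' * `effsize_set` → `OutputCalc_InputAndResults.txt`
#' * `sampling_plan` → `OutputSampl_IndividualsForSampling.txt`,
#'   `OutputSampl_DetailedInfo.txt` and, only when availability data was
#'   used, `OutputSampl_AvailabilityRestrictions.txt`
#' * `autocorrect_log` → `autocorrection_log.txt`
#'
#' @param x an analysis result object.
#' @param out_dir output directory (created if needed).
#' @param ... unused.
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(x, out_dir = ".", ...) {
  UseMethod("write_reports")
}

.ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

.emit <- function(lines, path) {
  writeLines(lines, path)
  path
}

#' @rdname write_reports
#' @export
write_reports.conflict_report <- function(x, out_dir = ".", ...) {
  .ensure_dir(out_dir)
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  paths <- character()

  summary_lines <- c(
    "Maternal-line haplotype concordance summary",
    sprintf("haplotyped individuals: %d", x$n_haplotyped),
    sprintf("conflicting pairs: %d", x$n_conflicting_pairs),
    sprintf("conflicting individuals: %d", length(x$conflicting_individuals)),
    sprintf("informative individuals: %d", length(x$informative_individuals)),
    sprintf("misplaced individuals: %d", length(x$misplaced_individuals)),
    sprintf("misplaced branches: %d", nrow(x$misplaced_branches)),
    sprintf("HC index (%% conflicting of haplotyped): %s", fmt(x$hc_index)),
    sprintf("IC index (%% conflicting of informative): %s", fmt(x$ic_index)),
    sprintf("MISPLACED index (%% misplaced of conflicting): %s",
            fmt(x$misplaced_index)),
    sprintf("pruned conflict count: %d", x$pruned_conflicts))
  paths <- c(paths, .emit(summary_lines,
                          file.path(out_dir, "OutputVerif_Summary.txt")))

  unit_lines <- "individual,n_conflicts"
  if (length(x$conflict_count)) {
    unit_lines <- c(unit_lines,
                    sprintf("%s,%d", names(x$conflict_count),
                            as.integer(x$conflict_count)))
  }
  paths <- c(paths, .emit(unit_lines,
                          file.path(out_dir, "OutputVerif_ConflictingUnits.txt")))

  br_lines <- "branch_root,n_conflicts"
  if (nrow(x$misplaced_branches)) {
    br_lines <- c(br_lines,
                  sprintf("%s,%d", x$misplaced_branches$root,
                          x$misplaced_branches$n_conflicts))
  }
  paths <- c(paths, .emit(br_lines,
                          file.path(out_dir, "OutputVerif_MisplacedBranches.txt")))
  invisible(paths)
}

#' @rdname write_reports
#' @export
write_reports.line_distribution <- function(x, out_dir = ".", ...) {
  .ensure_dir(out_dir)
  paths <- character()
  tab <- x$table
  twin <- function(df, base) {
    txt <- file.path(out_dir, paste0(base, ".txt"))
    csv <- file.path(out_dir, paste0(base, ".csv"))
    lines <- c(paste(names(df), collapse = ","),
               do.call(sprintf, c(list(paste(rep("%s", ncol(df)),
                                             collapse = ",")),
                                  lapply(df, as.character))))
    if (!nrow(df)) lines <- lines[1]
    .emit(lines, txt)
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
    c(txt, csv)
  }

  # _1: per-dam grouped membership with counts and haplotype
  lines1 <- character()
  for (i in seq_len(nrow(tab))) {
    lines1 <- c(lines1,
                sprintf("founder dam %s: %d descendants, haplotype %s",
                        tab$founder[i], tab$total[i],
                        ifelse(is.na(tab$haplotype[i]), "UNASSIGNED",
                               tab$haplotype[i])),
                paste(" ", paste(x$members[[tab$founder[i]]],
                                 collapse = " ")))
  }
  paths <- c(paths, .emit(lines1,
                          file.path(out_dir, "OutputStat_DamLineMembership_1.txt")))

  # _2: flat individual -> founder table
  flat <- data.frame(individual = names(x$flat_membership),
                     founder_dam = unname(x$flat_membership),
                     stringsAsFactors = FALSE)
  paths <- c(paths, twin(flat, "OutputStat_DamLineMembership_2"))

  paths <- c(paths, twin(tab[tab$ref_all > 0L,
                             c("founder", "ref_all", "haplotype")],
                         "OutputStat_DamLineMembershipAllInRefPop"))
  paths <- c(paths, twin(tab[tab$ref_female > 0L,
                             c("founder", "ref_female", "haplotype")],
                         "OutputStat_DamLineMembershipFemaleOnlyInRefPop"))
  paths <- c(paths, twin(tab[tab$founder %in% x$lines_with_ref_females,
                             , drop = FALSE],
                         "OutputStat_DamLinesWithFemalesInRefPop"))
  paths <- c(paths, twin(tab[tab$founder %in% x$lines_males_only_in_ref,
                             , drop = FALSE],
                         "OutputStat_DamLinesWithOnlyMalesInRefPop"))
  invisible(paths)
}

#' @rdname write_reports
#' @export
write_reports.effsize_set <- function(x, out_dir = ".", ...) {
  .ensure_dir(out_dir)
  fmt_ne <- function(v) {
    if (is.na(v)) "undefined" else if (is.infinite(v)) "infinite"
    else sprintf("%.4f", v)
  }
  lines <- c("Effective population sizes from probability of identity",
             sprintf("reference window: %d-%d", x$window[1], x$window[2]),
             sprintf("pedigree size: %d", x$n_individuals),
             sprintf("reference population size: %d", x$n_reference))
  for (r in x$results) {
    lines <- c(lines, "",
               sprintf("[%s lines]", r$mode),
               sprintf("founder lines: %d", length(r$frequencies_founder)),
               sprintf("PI founder: %.6f", r$pi_founder),
               sprintf("PI reference: %.6f", r$pi_reference),
               sprintf("delta PI: %s",
                       if (is.na(r$delta_pi)) "undefined"
                       else sprintf("%.6f", r$delta_pi)),
               sprintf("Ne: %s", fmt_ne(r$ne)),
               "founder frequencies:",
               sprintf("  %s %.6f", names(r$frequencies_founder),
                       r$frequencies_founder),
               "reference frequencies:",
               sprintf("  %s %.6f", names(r$frequencies_reference),
                       r$frequencies_reference))
    if (!is.null(r$undefined_reason)) {
      lines <- c(lines, paste("note:", r$undefined_reason))
    }
  }
  invisible(.emit(lines, file.path(out_dir, "OutputCalc_InputAndResults.txt")))
}

#' @rdname write_reports
#' @export
write_reports.sampling_plan <- function(x, out_dir = ".", ...) {
  .ensure_dir(out_dir)
  paths <- character()
  sel_lines <- "individual,line"
  df <- x$lines
  for (i in seq_len(nrow(df))) {
    s <- df$selected[[i]]
    if (length(s)) {
      sel_lines <- c(sel_lines, sprintf("%s,%s", s, df$line[i]))
    }
  }
  paths <- c(paths, .emit(sel_lines,
                          file.path(out_dir, "OutputSampl_IndividualsForSampling.txt")))

  det <- c(sprintf("budget: %d", x$budget),
           sprintf("reference window: %d-%d", x$window[1], x$window[2]),
           sprintf("availability restriction: %s",
                   if (x$availability_used) "active" else "not used"),
           "line,R_l,P_l,target,new,pool,shortfall,selected",
           vapply(seq_len(nrow(df)), function(i) {
             sprintf("%s,%d,%d,%d,%d,%d,%d,%s", df$line[i], df$r[i], df$p[i],
                     df$target[i], df$new[i], df$pool[i], df$shortfall[i],
                     paste(df$selected[[i]], collapse = " "))
           }, character(1)))
  paths <- c(paths, .emit(det,
                          file.path(out_dir, "OutputSampl_DetailedInfo.txt")))

  if (x$availability_used) {
    ov <- x$availability_overflow
    ov_lines <- "line,R_l,P_l,target,new,pool_available,shortfall"
    if (nrow(ov)) {
      ov_lines <- c(ov_lines,
                    sprintf("%s,%d,%d,%d,%d,%d,%d", ov$line, ov$r, ov$p,
                            ov$target, ov$new, ov$pool, ov$shortfall))
    }
    paths <- c(paths, .emit(ov_lines,
                            file.path(out_dir,
                                      "OutputSampl_AvailabilityRestrictions.txt")))
  }
  invisible(paths)
}

#' @rdname write_reports
#' @export
write_reports.autocorrect_log <- function(x, out_dir = ".", ...) {
  .ensure_dir(out_dir)
  lines <- c("Pedigree auto-correction log",
             sprintf("deleted parent references (mentioned once): %d",
                     nrow(x$deleted)))
  if (nrow(x$deleted)) {
    lines <- c(lines, sprintf("  child %s: %s %s set to unknown",
                              x$deleted$child, x$deleted$role,
                              x$deleted$parent))
  }
  lines <- c(lines, sprintf("created parent records (mentioned >= 2 times): %d",
                            nrow(x$created)))
  if (nrow(x$created)) {
    lines <- c(lines, sprintf("  %s (gender %s)", x$created$id,
                              x$created$gender))
  }
  invisible(.emit(lines, file.path(out_dir, "autocorrection_log.txt")))
}

# fatal-error alert file, one line per finding
.write_error_alert <- function(errors, out_dir = ".") {
  .ensure_dir(out_dir)
  lines <- if (nrow(errors)) {
    sprintf("%s: %s (%s)", errors$type, errors$id, errors$detail)
  } else {
    "no fatal errors"
  }
  invisible(.emit(lines, file.path(out_dir, "ERROR_ALERT.TXT")))
}
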