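#' Run an analysis stage end to end
#'
#' High-level driver mirroring the command-line interface: reads the
#' pedigree, checks for fatal errors (writing `ERROR_ALERT.TXT` and
#' stopping when any exist), applies the silent auto-correction (logged to
#' `autocorrection_log.txt`), then executes the requested stage and writes
#' its report files to `outdir`. The statistics, effective-size and
#' sampling stages refuse to run on a pedigree with haplotype conflicts and
#' direct the user to the `verif` stage.
#'
#' @param command one of `"verif"`, `"stat"`, `"calc"`, `"sampl"`,
#'   `"synth"`.
#' @param input path to the pedigree CSV (default `"pdg_in.csv"`). For
#'   `stat`/`calc`/`sampl`, optional `reference_years.txt` and (for
#'   `sampl`) `planned_number_of_sequencings.txt` files next to the input
#'   are honored.
#' @param outdir output directory for report files.
#' @param ref_years optional `c(first, last)` override of the reference
#'   window.
#' @param budget optional sequencing budget override for `sampl`.
#' @param tie_rule conflict-flagging tie rule, `"both"` or `"strict"`.
#' @param unknown_tokens parent tokens meaning "unknown".
#' @param use_availability honor the `available` column in `sampl`.
#' @param seed seed for `synth`.
#' @param synth_args list of arguments passed to [synth_pedigree()] for the
#'   `synth` command.
#' @return The stage's result object, invisibly.
#' @export
run_module <- function(command = c("verif", "stat", "calc", "sampl", "synth"),
                       input = "pdg_in.csv", outdir = ".",
                       ref_years = NULL, budget = NULL,
                       tie_rule = c("both", "strict"),
                       unknown_tokens = c("", "0"),
                       use_availability = TRUE, seed = NULL,
                       synth_args = list()) {
  command <- match.arg(command)
  tie_rule <- match.arg(tie_rule)
  .ensure_dir(outdir)

  if (command == "synth") {
    args <- synth_args
    if (!is.null(seed)) args$seed <- seed
    s <- do.call(synth_pedigree, args)
    write_pedigree(s$pedigree, file.path(outdir, "pdg_in.csv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(line_of = as.list(s$truth$line_of),
             line_haplotype = as.list(s$truth$line_haplotype),
             sequenced = s$truth$sequenced,
             injections = s$truth$injections),
        file.path(outdir, "ground_truth.json"), auto_unbox = TRUE)
    }
    return(invisible(s))
  }

  ped <- read_pedigree(input, unknown_tokens = unknown_tokens)
  fatal <- check_fatal_errors(ped)
  if (nrow(fatal)) {
    .write_error_alert(fatal, outdir)
    stop("fatal pedigree error(s) found (", nrow(fatal),
         "); see ERROR_ALERT.TXT and correct the pedigree",
         call. = FALSE)
  }
  ac <- autocorrect_missing_parents(ped)
  ped <- ac$pedigree
  write_reports(ac$log, outdir)

  forest <- build_forest(ped, "dam")
  report <- verify_pedigree(ped, forest = forest, tie_rule = tie_rule)

  if (command == "verif") {
    write_reports(report, outdir)
    return(invisible(report))
  }

  if (length(report$conflicting_individuals)) {
    stop("haplotype conflicts present (",
         length(report$conflicting_individuals),
         " conflicting individuals); run the verif stage and resolve them first",
         call. = FALSE)
  }

  window <- if (!is.null(ref_years)) {
    as.integer(ref_years)
  } else {
    read_reference_window(file.path(dirname(input), "reference_years.txt"),
                          ped)
  }

  if (command == "stat") {
    refpop <- reference_population(ped, window)
    dist <- line_distributions(forest, ped, refpop)
    write_reports(dist, outdir)
    return(invisible(dist))
  }
  if (command == "calc") {
    res <- effective_sizes(ped, window = window, forest = forest)
    write_reports(res, outdir)
    return(invisible(res))
  }
  # sampl
  if (is.null(budget)) {
    bfile <- file.path(dirname(input), "planned_number_of_sequencings.txt")
    if (!file.exists(bfile)) {
      stop("no sampling budget: pass `budget` or provide ",
           "planned_number_of_sequencings.txt next to the pedigree",
           call. = FALSE)
    }
    budget <- read_budget(bfile)
  }
  plan <- build_plan(ped, n = budget, window = window,
                     use_availability = use_availability, forest = forest)
  write_reports(plan, outdir)
  invisible(plan)
}
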