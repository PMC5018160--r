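#' Check a pedigree for fatal structural errors
#'
#' Two classes of error make downstream lineage analysis impossible and must
#' be corrected by hand: ancestry cycles (an individual that is its own
#' ancestor through any chain of parent links, including the self-parent
#' case) and gender inconsistencies (an id recorded as female but used in the
#' father column, recorded as male but used in the mother column, or used in
#' both parent columns).
#'
#' All occurrences are collected in one pass rather than stopping at the
#' first.
#'
#' @param ped a [pedigree].
#' @return A data frame with columns `type` (`"cycle"` or
#'   `"gender_inconsistency"`), `id` and `detail`; zero rows when the
#'   pedigree is clean.
#' @examples
#' bad <- pedigree(id = c("a", "b"), dam = c("a", NA), gender = c("F", "F"))
#' check_fatal_errors(bad)
#' @export
check_fatal_errors <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  err <- list()

  ## --- ancestry cycles -----------------------------------------------------
  sire_i <- match(ped$sire, ped$id)
  dam_i <- match(ped$dam, ped$id)
  # Kahn-style resolution: an individual is resolvable once both recorded
  # parents are resolved; whatever never resolves sits on or below a cycle.
  resolved <- c(rep(FALSE, n), TRUE)          # sentinel slot for "no parent"
  si <- ifelse(is.na(sire_i), n + 1L, sire_i)
  di <- ifelse(is.na(dam_i), n + 1L, dam_i)
  repeat {
    ok <- !resolved[seq_len(n)] & resolved[si] & resolved[di]
    if (!any(ok)) break
    resolved[seq_len(n)][ok] <- TRUE
  }
  stuck <- which(!resolved[seq_len(n)])
  if (length(stuck)) {
    # individuals actually on a cycle: strongly connected components (or
    # self-loops) of the child -> parent graph restricted to the stuck set
    sub <- data.frame(from = rep(stuck, 2L), to = c(sire_i[stuck], dam_i[stuck]))
    sub <- sub[!is.na(sub$to) & sub$to %in% stuck, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub$from), to = as.character(sub$to)),
      vertices = data.frame(name = as.character(stuck)))
    comp <- igraph::components(g, mode = "strong")
    in_cycle_v <- as.integer(names(comp$membership)[
      comp$membership %in% which(comp$csize > 1L)])
    self_loop <- which((!is.na(sire_i) & sire_i == seq_len(n)) |
                         (!is.na(dam_i) & dam_i == seq_len(n)))
    cyc <- sort(unique(c(in_cycle_v, self_loop)))
    for (v in cyc) {
      err[[length(err) + 1L]] <- data.frame(
        type = "cycle", id = ped$id[v],
        detail = "individual is its own ancestor through a parent chain",
        stringsAsFactors = FALSE)
    }
  }

  ## --- gender inconsistencies ---------------------------------------------
  fathers <- unique(ped$sire[!is.na(ped$sire)])
  mothers <- unique(ped$dam[!is.na(ped$dam)])
  both <- intersect(fathers, mothers)
  for (v in sort(both)) {
    err[[length(err) + 1L]] <- data.frame(
      type = "gender_inconsistency", id = v,
      detail = "appears in both the father and the mother column",
      stringsAsFactors = FALSE)
  }
  g <- ped$gender
  f_as_father <- ped$id[!is.na(g) & g == "F" & ped$id %in% fathers]
  for (v in sort(setdiff(f_as_father, both))) {
    err[[length(err) + 1L]] <- data.frame(
      type = "gender_inconsistency", id = v,
      detail = "recorded as female but used in the father column",
      stringsAsFactors = FALSE)
  }
  m_as_mother <- ped$id[!is.na(g) & g == "M" & ped$id %in% mothers]
  for (v in sort(setdiff(m_as_mother, both))) {
    err[[length(err) + 1L]] <- data.frame(
      type = "gender_inconsistency", id = v,
      detail = "recorded as male but used in the mother column",
      stringsAsFactors = FALSE)
  }

  if (!length(err)) {
    return(data.frame(type = character(), id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, err)
}

#' Auto-correct parents that have no record of their own
#'
#' A parent id without its own pedigree row is handled by how much relational
#' information it carries: referenced exactly once, it is uninformative and
#' the reference is replaced by unknown; referenced twice or more, a new
#' record is created for it (gender inferred from the parental column, birth
#' year and parents unknown). The operation is idempotent.
#'
#' @param ped a [pedigree] free of fatal errors (see [check_fatal_errors()]).
#' @return A list with elements `pedigree` (the corrected [pedigree]) and
#'   `log`, an object of class `autocorrect_log` with data frames `deleted`
#'   (child id, parent id, role) and `created` (id, gender).
#' @export
autocorrect_missing_parents <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  refs <- c(ped$sire, ped$dam)
  role <- rep(c("sire", "dam"), each = nrow(ped))
  keep <- !is.na(refs) & !(refs %in% ped$id)
  refs <- refs[keep]
  role <- role[keep]

  deleted <- data.frame(child = character(), parent = character(),
                        role = character(), stringsAsFactors = FALSE)
  created <- data.frame(id = character(), gender = character(),
                        stringsAsFactors = FALSE)
  if (length(refs)) {
    counts <- table(refs)
    once <- names(counts)[counts == 1L]
    multi <- names(counts)[counts >= 2L]

    if (length(once)) {
      del_s <- which(ped$sire %in% once)
      del_d <- which(ped$dam %in% once)
      deleted <- rbind(
        data.frame(child = ped$id[del_s], parent = ped$sire[del_s],
                   role = rep("sire", length(del_s)),
                   stringsAsFactors = FALSE),
        data.frame(child = ped$id[del_d], parent = ped$dam[del_d],
                   role = rep("dam", length(del_d)),
                   stringsAsFactors = FALSE))
      ped$sire[del_s] <- NA_character_
      ped$dam[del_d] <- NA_character_
    }
    if (length(multi)) {
      # a missing parent used in both roles is a fatal gender inconsistency
      # and never reaches this point; the role determines the gender
      as_sire <- multi %in% ped$sire
      created <- data.frame(id = multi,
                            gender = ifelse(as_sire, "M", "F"),
                            stringsAsFactors = FALSE)
      new_rows <- data.frame(id = multi, sire = NA_character_,
                             dam = NA_character_, yob = NA_integer_,
                             gender = created$gender,
                             haplotype = NA_character_, available = FALSE,
                             stringsAsFactors = FALSE)
      atts <- attributes(ped)
      ped <- rbind(as.data.frame(ped), new_rows)
      attr(ped, "has_haplotype") <- atts$has_haplotype
      attr(ped, "has_available") <- atts$has_available
      class(ped) <- c("pedigree", "data.frame")
      rownames(ped) <- NULL
    }
  }
  log <- structure(list(deleted = deleted, created = created),
                   class = "autocorrect_log")
  list(pedigree = ped, log = log)
}

#' @export
print.autocorrect_log <- function(x, ...) {
  cat("Pedigree auto-correction log\n")
  cat("  parent references removed (mentioned once, no own record):",
      nrow(x$deleted), "\n")
  if (nrow(x$deleted)) print.data.frame(x$deleted)
  cat("  parent records created (mentioned >= 2 times):", nrow(x$created), "\n")
  if (nrow(x$created)) print.data.frame(x$created)
  invisible(x)
}
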