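# Largest-remainder (Hamilton) apportionment of `total` integer slots
# proportional to `weights`; remainder ties go to the larger `tie_size`,
# then to the lexicographically smaller id.
.largest_remainder <- function(total, weights, tie_size = weights,
                               ids = as.character(seq_along(weights))) {
  m <- length(weights)
  if (total <= 0L || sum(weights) <= 0) return(integer(m))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0L) {
    ord <- order(-(quota - base), -tie_size, ids)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Allocate a sequencing budget across maternal lines
#'
#' Stage one of the sampling planner. With no previously sequenced
#' individuals, every line is first guaranteed one slot and the remaining
#' `N - L` slots are spread proportionally to `R_l - 1` (largest-remainder
#' division); when the budget is smaller than the number of lines, the `N`
#' largest lines by `R_l` get one slot each. With prior sequencings, the
#' `k` lines without priors are each guaranteed one new slot, the pool
#' `N - k + sum(P_l)` is divided over all lines proportionally to `R_l` to
#' give total targets `N_l`, and the remaining `N - k` new slots cover the
#' gaps `N_l - P_l` (largest-remainder scaled when the gaps exceed the
#' remaining budget, so the budget is never overspent). Targets never
#' exceed `R_l`; unusable surplus is reported, not redistributed.
#'
#' @param n non-negative integer budget (planned number of sequencings).
#' @param r integer vector: reference-population line sizes `R_l` (>= 1).
#' @param p integer vector of previously sequenced counts `P_l` (default all
#'   zero).
#' @param ids optional line identifiers (used for deterministic
#'   tie-breaking and row names).
#' @return A data frame with columns `line`, `r`, `p`, `target` (`N_l`) and
#'   `new` (sequencings still to perform).
#' @examples
#' allocate_slots(10, r = c(5, 3, 2))          # targets 5, 3, 2
#' allocate_slots(2, r = c(5, 3, 2))           # only the two largest lines
#' allocate_slots(6, r = c(6, 4), p = c(4, 0)) # prior-aware division
#' @export
allocate_slots <- function(n, r, p = rep(0L, length(r)),
                           ids = as.character(seq_along(r))) {
  stopifnot(n >= 0, length(r) == length(p), length(ids) == length(r))
  if (any(r < 1L)) stop("every line in the reference population has R_l >= 1")
  L <- length(r)
  n <- as.integer(n); r <- as.integer(r); p <- as.integer(p)
  if (n == 0L || L == 0L) {
    target <- integer(L)
    new <- integer(L)
  } else if (all(p == 0L)) {
    if (n >= L) {
      extra <- .largest_remainder(n - L, pmax(r - 1L, 0L), tie_size = r,
                                  ids = ids)
      target <- pmin(1L + extra, r)
    } else {
      target <- integer(L)
      ord <- order(-r, ids)
      target[ord[seq_len(n)]] <- 1L
    }
    new <- target
  } else {
    k <- sum(p == 0L)
    new <- integer(L)
    if (n <= k) {
      # budget cannot even seed every unsequenced line: one slot each to
      # the n largest of them, mirroring the L > N rule
      zi <- which(p == 0L)
      ord <- zi[order(-r[zi], ids[zi])]
      new[ord[seq_len(n)]] <- 1L
      target <- pmin(p + new, pmax(r, p))
    } else {
      new[p == 0L] <- 1L
      pool <- n - k + sum(p)
      target <- .largest_remainder(pool, r, tie_size = r, ids = ids)
      target <- pmin(target, pmax(r, p))
      gap <- pmax(target - p - new, 0L)
      left <- n - k
      if (sum(gap) <= left) {
        extra <- gap
      } else {
        extra <- .largest_remainder(left, gap, tie_size = r, ids = ids)
        extra <- pmin(extra, gap)
      }
      new <- new + extra
      target <- pmax(target, p + new)
    }
  }
  data.frame(line = ids, r = r, p = p, target = target, new = new,
             stringsAsFactors = FALSE)
}

#' Central individual of a line pool
#'
#' The pool member with the minimum sum of tree distances to all other pool
#' members (ties broken by lexicographically smallest id) — the best single
#' representative of the line.
#'
#' @param f a [maternal_forest][build_forest].
#' @param pool character vector of same-line individual ids.
#' @param D optional precomputed distance matrix over `pool`.
#' @return A single individual id.
#' @export
central_individual <- function(f, pool, D = NULL) {
  if (!length(pool)) stop("empty pool")
  if (length(pool) == 1L) return(pool)
  if (is.null(D)) D <- line_distance_matrix(f, pool)
  sd_i <- rowSums(D)
  cand <- pool[sd_i == min(sd_i)]
  sort(cand)[1L]
}

#' Greedy maximum-dispersion selection within a line
#'
#' Selects individuals whose mutual tree distances are as large as possible.
#' Without seeds the first pick is the central individual of the pool; each
#' further pick greedily maximizes the sum of distances to the
#' already-selected set. Previously sequenced individuals act as a seed
#' group: all picks are then greedy additions against the seeds. Distance
#' ties are broken by lexicographically smallest id, so selections are
#' reproducible.
#'
#' @param f a [maternal_forest][build_forest].
#' @param pool candidate ids (same line; seeds excluded automatically).
#' @param n_new number of new individuals to select.
#' @param seeds ids of already-sequenced line members (need not be in
#'   `pool`).
#' @return A list with `selected` (ordered ids) and `shortfall` (how many of
#'   the requested picks could not be made).
#' @export
greedy_select <- function(f, pool, n_new, seeds = character()) {
  stopifnot(n_new >= 0)
  n_new <- as.integer(n_new)
  cand <- setdiff(pool, seeds)
  if (n_new == 0L || !length(cand)) {
    return(list(selected = character(),
                shortfall = if (length(cand)) 0L else n_new))
  }
  all_ids <- unique(c(cand, seeds))
  D <- line_distance_matrix(f, all_ids)
  selected <- character()
  chosen <- seeds
  if (!length(seeds)) {
    first <- central_individual(f, cand, D = D[cand, cand, drop = FALSE])
    selected <- first
    chosen <- first
    cand <- setdiff(cand, first)
  }
  while (length(selected) < n_new && length(cand)) {
    sd_p <- colSums(D[chosen, cand, drop = FALSE])
    best <- max(sd_p)
    pick <- sort(cand[sd_p == best])[1L]
    selected <- c(selected, pick)
    chosen <- c(chosen, pick)
    cand <- setdiff(cand, pick)
  }
  list(selected = selected, shortfall = max(n_new - length(selected), 0L))
}

#' Build a molecular-sampling plan
#'
#' Runs both planner stages over every maternal line represented in the
#' reference population: budget allocation ([allocate_slots()]) and
#' within-line maximum-dispersion selection ([greedy_select()]), honoring
#' previously sequenced individuals (never re-selected; used as dispersion
#' seeds) and, when availability information exists, restricting the choice
#' to available individuals. Slot overflows over the available pool are
#' reported per line, never redistributed.
#'
#' @param ped a [pedigree] free of fatal errors and haplotype conflicts.
#' @param n integer sequencing budget.
#' @param window reference year window (default: full span of birth years).
#' @param use_availability honor the `available` column when present
#'   (default `TRUE`); when the column is absent the available population
#'   equals the reference population.
#' @param seed_outside_refpop count sequenced line members outside the
#'   reference population in `P_l` and as dispersion seeds (default `TRUE`).
#' @param forest optional precomputed dam-link forest.
#' @return An object of class `sampling_plan`: the per-line allocation table
#'   (with pool sizes, selections and shortfalls), the ordered overall
#'   selection, and availability-overflow diagnostics.
#' @export
build_plan <- function(ped, n, window = NULL, use_availability = TRUE,
                       seed_outside_refpop = TRUE, forest = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(window)) window <- read_reference_window(NULL, ped)
  refpop <- reference_population(ped, window)
  if (!length(refpop)) stop("empty reference population; nothing to sample")
  f <- forest %||% build_forest(ped, "dam")

  avail_active <- use_availability && isTRUE(attr(ped, "has_available"))
  available <- if (avail_active) ped$id[ped$available] else refpop

  in_ref <- ped$id %in% refpop
  lev <- f$founders
  r_l <- as.integer(table(factor(f$root[in_ref], levels = lev)))
  keep <- r_l >= 1L
  lines <- lev[keep]
  r_l <- r_l[keep]

  hseq <- !is.na(ped$haplotype)
  seq_scope <- if (seed_outside_refpop) hseq else hseq & in_ref
  p_l <- as.integer(table(factor(f$root[seq_scope], levels = lines)))

  alloc <- allocate_slots(n, r = r_l, p = p_l, ids = lines)

  members_ref <- split(ped$id[in_ref], factor(f$root[in_ref], levels = lines))
  seeds_all <- split(ped$id[seq_scope], factor(f$root[seq_scope], levels = lines))

  sel_list <- vector("list", length(lines))
  pool_size <- integer(length(lines))
  shortfall <- integer(length(lines))
  for (i in seq_along(lines)) {
    pool <- members_ref[[i]]
    if (avail_active) pool <- intersect(pool, available)
    seeds <- seeds_all[[i]]
    pool <- setdiff(pool, seeds)          # never re-select sequenced ones
    pool_size[i] <- length(pool)
    want <- alloc$new[i]
    if (want == 0L) {
      sel_list[[i]] <- character()
      next
    }
    gs <- greedy_select(f, pool, want, seeds = seeds)
    sel_list[[i]] <- gs$selected
    shortfall[i] <- want - length(gs$selected)
  }
  alloc$pool <- pool_size
  alloc$shortfall <- shortfall
  alloc$selected <- I(sel_list)

  overflow <- alloc[alloc$shortfall > 0L,
                    c("line", "r", "p", "target", "new", "pool", "shortfall")]
  rownames(overflow) <- NULL
  structure(list(budget = n, window = window,
                 availability_used = avail_active,
                 lines = alloc,
                 selected = unlist(sel_list, use.names = FALSE),
                 availability_overflow = overflow),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat("Molecular-sampling plan: budget", x$budget, "over",
      nrow(x$lines), "maternal lines (window ",
      x$window[1], "-", x$window[2], ")\n")
  cat("  availability restriction:",
      if (x$availability_used) "active" else "not used", "\n")
  cat("  individuals selected:", length(x$selected), "\n")
  if (nrow(x$availability_overflow)) {
    cat("  lines with unfilled slots:",
        nrow(x$availability_overflow), "(surplus reported, not redistributed)\n")
  }
  df <- x$lines
  df$selected <- vapply(df$selected, function(s) paste(s, collapse = " "),
                        character(1))
  print.data.frame(utils::head(df, 15L))
  if (nrow(df) > 15L) cat("  ... and", nrow(df) - 15L, "more lines\n")
  invisible(x)
}
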