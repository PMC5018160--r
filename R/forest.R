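#' Build the matrilineal (or patrilineal) forest of a pedigree
#'
#' Following mother links upward partitions a pedigree into maternal lines:
#' every individual (of either sex) belongs to the line of the founder
#' reached by iterating dam links until an unknown parent. Individuals whose
#' dam is unknown are their own line roots. With `link = "sire"` the same
#' construction yields paternal lines.
#'
#' @param ped a [pedigree], free of fatal errors and auto-corrected (every
#'   referenced parent has a record).
#' @param link which parent link defines the forest: `"dam"` (default,
#'   maternal lines) or `"sire"` (paternal lines).
#' @return An object of class `maternal_forest`: a list with `ids`, `parent`
#'   (row index of the link parent, `NA` at roots), `depth` (generations
#'   below the line root), `root` (line root id per individual), `founders`
#'   (line root ids) and `link`.
#' @examples
#' p <- pedigree(id = c("F1", "d1", "d2", "m1"),
#'               dam = c(NA, "F1", "d1", "d1"),
#'               gender = c("F", "F", "F", "M"))
#' f <- build_forest(p)
#' line_of(f)
#' @export
build_forest <- function(ped, link = c("dam", "sire")) {
  stopifnot(inherits(ped, "pedigree"))
  link <- match.arg(link)
  n <- nrow(ped)
  ids <- ped$id
  parent <- match(ped[[link]], ids)
  root <- seq_len(n)
  depth <- integer(n)
  guard <- 0L
  repeat {
    p <- parent[root]
    mv <- !is.na(p)
    if (!any(mv)) break
    root[mv] <- p[mv]
    depth[mv] <- depth[mv] + 1L
    guard <- guard + 1L
    if (guard > n) {
      stop("parent links contain a cycle; run check_fatal_errors() first")
    }
  }
  structure(list(ids = ids, parent = parent, depth = depth,
                 root = ids[root], founders = unique(ids[root][order(root)]),
                 link = link),
            class = "maternal_forest")
}

#' @export
print.maternal_forest <- function(x, ...) {
  cat(if (x$link == "dam") "Maternal" else "Paternal",
      "forest:", length(x$ids), "individuals in",
      length(x$founders), "lines (max depth", max(x$depth), ")\n")
  invisible(x)
}

#' Line membership of every individual
#'
#' @param f a [maternal_forest][build_forest].
#' @return Named character vector mapping each individual id to its line
#'   root (founder) id.
#' @export
line_of <- function(f) {
  stopifnot(inherits(f, "maternal_forest"))
  stats::setNames(f$root, f$ids)
}

#' Members of each line
#'
#' @param f a [maternal_forest][build_forest].
#' @return Named list: for each founder, the character vector of line member
#'   ids (the founder included).
#' @export
line_members <- function(f) {
  split(f$ids, factor(f$root, levels = f$founders))
}

# row indices of the ancestor chain of v (v itself first, root last)
.chain <- function(f, v) {
  ch <- v
  while (!is.na(f$parent[v])) {
    v <- f$parent[v]
    ch <- c(ch, v)
  }
  ch
}

#' Tree distance between two individuals of the same line
#'
#' The number of mother-link (or father-link) edges on the unique path
#' between `i` and `j` in their line's tree:
#' `depth(i) + depth(j) - 2 * depth(MRCA)`.
#'
#' @param f a [maternal_forest][build_forest].
#' @param i,j individual ids belonging to the same line.
#' @return A non-negative integer; zero iff `i == j`.
#' @export
tree_distance <- function(f, i, j) {
  vi <- match(i, f$ids)
  vj <- match(j, f$ids)
  if (is.na(vi) || is.na(vj)) stop("unknown individual id")
  if (f$root[vi] != f$root[vj]) {
    stop("individuals ", i, " and ", j, " are in different lines")
  }
  if (vi == vj) return(0L)
  ci <- .chain(f, vi)
  cj <- .chain(f, vj)
  m <- match(ci, cj)
  k <- which(!is.na(m))[1]
  (k - 1L) + (m[k] - 1L)
}

#' Pairwise tree-distance matrix for a set of same-line individuals
#'
#' @param f a [maternal_forest][build_forest].
#' @param ids individual ids, all in the same line.
#' @return Symmetric integer matrix of path lengths with `ids` as dimnames.
#' @export
line_distance_matrix <- function(f, ids) {
  v <- match(ids, f$ids)
  if (anyNA(v)) stop("unknown individual id(s)")
  if (length(unique(f$root[v])) > 1L) stop("individuals span several lines")
  m <- length(v)
  chains <- lapply(v, .chain, f = f)
  D <- matrix(0L, m, m, dimnames = list(ids, ids))
  if (m >= 2L) {
    for (a in seq_len(m - 1L)) {
      for (b in (a + 1L):m) {
        mt <- match(chains[[a]], chains[[b]])
        k <- which(!is.na(mt))[1]
        D[a, b] <- D[b, a] <- (k - 1L) + (mt[k] - 1L)
      }
    }
  }
  D
}

# Vectorized nearest-haplotyped-ancestor: for each row index, the row index
# of the closest strict ancestor (along f's link) with a non-NA haplotype.
.nha_all <- function(f, hap) {
  n <- length(f$ids)
  nha <- rep(NA_integer_, n)
  hap_known <- !is.na(hap)
  if (n == 0L) return(nha)
  for (d in sort(unique(f$depth[f$depth > 0L]))) {
    vs <- which(f$depth == d)
    ps <- f$parent[vs]
    take_parent <- hap_known[ps]
    nha[vs] <- ifelse(take_parent, ps, nha[ps])
  }
  nha
}

#' Nearest haplotyped maternal ancestor
#'
#' The closest strict ancestor of `i` (following the forest's parent link)
#' that carries a haplotype record.
#'
#' @param f a [maternal_forest][build_forest].
#' @param ped the [pedigree] the forest was built from.
#' @param i an individual id.
#' @return The ancestor's id, or `NA` when no haplotyped ancestor exists.
#' @export
nearest_haplotyped_ancestor <- function(f, ped, i) {
  v <- match(i, f$ids)
  if (is.na(v)) stop("unknown individual id: ", i)
  hap_known <- !is.na(ped$haplotype)
  while (!is.na(f$parent[v])) {
    v <- f$parent[v]
    if (hap_known[v]) return(f$ids[v])
  }
  NA_character_
}

# children row-index list keyed by parent row index (only parents with kids)
.children_index <- function(f) {
  has_par <- !is.na(f$parent)
  split(which(has_par), f$parent[has_par])
}

# all row indices in the subtree rooted at row index v (v included)
.subtree <- function(f, v, kids = .children_index(f)) {
  out <- integer(0)
  queue <- v
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(kids[as.character(queue)], use.names = FALSE)
  }
  out
}

# per-node count of flagged individuals in the node's subtree (vectorized by
# depth level); `flag` is a logical over rows
.subtree_count <- function(f, flag) {
  cnt <- as.integer(flag)
  depths <- sort(unique(f$depth[f$depth > 0L]), decreasing = TRUE)
  for (d in depths) {
    vs <- which(f$depth == d & cnt > 0L)
    if (!length(vs)) next
    add <- rowsum(cnt[vs], f$parent[vs])
    tgt <- as.integer(rownames(add))
    cnt[tgt] <- cnt[tgt] + as.integer(add[, 1L])
  }
  cnt
}
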