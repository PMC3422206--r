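# F84 distances and distance trees (UPGMA, neighbor-joining) with bootstrap
# support, over gapped window/monomer character data.

#' F84 nucleotide distance
#'
#' The Felsenstein (1984) distance with empirical base frequencies pooled
#' over both sequences.  Sites with a gap or N in either sequence are
#' dropped (pairwise deletion).  With `piR = piA + piG`, `piY = piC + piT`,
#' `A = piA piG / piR + piC piT / piY`, `B = piA piG + piC piT`,
#' `C = piR piY`, transition proportion `P` and transversion proportion `Q`:
#' `d = -2A log(1 - P/(2A) - (A - B) Q / (2AC)) + 2(A - B - C) log(1 - Q/(2C))`.
#' Saturated pairs (non-positive log arguments) return `Inf`.
#' Under uniform base composition the formula reduces to Kimura's
#' two-parameter distance `-log(1 - 2P - Q)/2 - log(1 - 2Q)/4`.
#'
#' @param a,b equal-length character vectors or single sequence strings.
#' @return Distance in substitutions per site.
#' @export
#' @examples
#' f84_distance("ACGTACGT", "ACGTACGT")
f84_distance <- function(a, b) {
  if (length(a) == 1 && is.character(a)) a <- strsplit(a, "")[[1]]
  if (length(b) == 1 && is.character(b)) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) abort("sequences must have equal length")
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) return(NA_real_)
  pi <- (tabulate(match(a, bases), 4) + tabulate(match(b, bases), 4)) / (2 * n)
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  if (piR == 0 || piY == 0) return(NA_real_)
  diffs <- a != b
  if (!any(diffs)) return(0)
  ts <- diffs & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                   (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(ts) / n
  Q <- sum(diffs & !ts) / n
  A <- piA * piG / piR + piC * piT / piY
  B <- piA * piG + piC * piT
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (!is.finite(arg1) || !is.finite(arg2) || arg1 <= 0 || arg2 <= 0) {
    return(Inf)  # saturated or degenerate composition
  }
  -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
}

#' F84 distance matrix over a character matrix
#'
#' @param mat character matrix (rows = sequences) over `{A, C, G, T, -}`;
#'   row names label the leaves.
#' @return Symmetric numeric matrix with a zero diagonal.
#' @export
f84_dist_matrix <- function(mat) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- f84_distance(mat[i, ], mat[j, ])
    }
  }
  D
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration weighted by cluster sizes; on an
#' ultrametric matrix the generating topology and node heights are
#' reproduced exactly.
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return An `ape::phylo` tree with branch lengths.
#' @export
upgma_tree <- function(D) {
  d <- stats::as.dist(D)
  if (attr(d, "Size") < 2) abort("need at least 2 leaves")
  phangorn::upgma(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining; negative branch lengths are clamped to 0
#' (logged).
#'
#' @param D symmetric distance matrix (or `dist`).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  tr <- ape::nj(stats::as.dist(D))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    censat_log(sprintf("nj: clamped %d negative branch length(s) to 0",
                       sum(neg)))
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Bootstrap support for distance trees
#'
#' Resamples alignment columns with replacement, recomputes the F84
#' distance matrix and tree, and reports for each internal node the
#' percentage of replicates containing the original bipartition.
#'
#' @param mat character matrix (rows = sequences).
#' @param n bootstrap replicates (default 100).
#' @param method `"upgma"` or `"nj"`.
#' @param seed integer seed.
#' @return `list(tree, support)`; `support` is a numeric vector in
#'   `[0, 100]` over the tree's internal nodes.
#' @export
bootstrap_support <- function(mat, n = 100L, method = c("upgma", "nj"),
                              seed = 1L) {
  method <- match.arg(method)
  build <- function(m) {
    D <- f84_dist_matrix(m)
    if (method == "upgma") upgma_tree(D) else nj_tree(D)
  }
  tree <- build(mat)
  counts <- withr::with_seed(as.integer(seed), {
    ape::boot.phylo(tree, mat, build, B = n, quiet = TRUE,
                    rooted = method == "upgma")
  })
  list(tree = tree, support = 100 * counts / n)
}

#' Leaves of the two deepest clades of a rooted tree
#'
#' Splits a rooted (e.g. UPGMA) tree at its root into the two child clades
#' and returns their leaf label sets — the grouping used to ask whether
#' CENP-A[+] and CENP-A[-] reads fall into largely distinct clades.
#'
#' @param tree a rooted `ape::phylo`.
#' @return List of two character vectors of leaf labels.
#' @export
root_clades <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  lapply(kids, function(k) {
    if (k <= ape::Ntip(tree)) return(tree$tip.label[k])
    tree$tip.label[phangorn::Descendants(tree, k, type = "tips")[[1]]]
  })
}
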