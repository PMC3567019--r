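#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair (i, j) minimizing
#' the Q-criterion `Q(i,j) = (m - 2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`,
#' assign branch lengths by the three-point equations, and reduce the matrix
#' with the standard update `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties
#' on Q are broken towards the label-sorted smallest pair, so the output is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister branch. The tree is returned unrooted
#' (trifurcating basal node for >= 3 taxa).
#'
#' @param D symmetric numeric distance matrix with labels as dimnames and
#'   non-negative entries, e.g. from [ibsDistanceMatrix()]
#' @return an [ape] `"phylo"` tree (also serialisable with
#'   [ape::write.tree()])
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (nrow(D) < 2L) stop("need >= 2 labels")
  if (any(D < 0)) stop("negative distances")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  fmt <- function(x) sprintf("%.12g", x)
  labels <- rownames(D)
  if (nrow(D) == 2L)
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         labels[1], fmt(D[1, 2] / 2),
                                         labels[2], fmt(D[1, 2] / 2))))
  # each active cluster is a valid newick node string; sortkey = smallest leaf
  sub <- labels
  key <- labels
  Dm <- D

  while (length(sub) > 2L) {
    k <- length(sub)
    rs <- rowSums(Dm)
    Q <- (k - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pairkey <- vapply(seq_len(nrow(idx)), function(r)
      paste(sort(c(key[idx[r, 1]], key[idx[r, 2]])), collapse = "\r"),
      character(1))
    pick <- idx[order(pairkey)[1L], ]
    i <- pick[1]; j <- pick[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (k - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newsub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    newkey <- min(key[i], key[j])
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], newsub)
    key <- c(key[keep], newkey)
  }
  # final edge: splice one cluster into the other's child list (trifurcation)
  d12 <- Dm[1, 2]
  int <- if (startsWith(sub[2], "(")) 2L else 1L
  oth <- 3L - int
  inner <- substr(sub[int], 2L, nchar(sub[int]) - 1L)
  newick <- sprintf("(%s,%s:%s);", inner, sub[oth], fmt(max(d12, 0)))
  ape::read.tree(text = newick)
}
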