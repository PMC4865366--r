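#' @include AllClasses.R
NULL

#' One-sided Fisher's exact overlap test between gene sets
#'
#' Tests whether two gene sets drawn from a common universe overlap more
#' than expected by chance: with universe size N and set sizes |A| and |B|,
#' the overlap k is compared to the hypergeometric null,
#' `p = P(K >= k)` with `K ~ Hypergeom(N, |A|, |B|)` (the one-sided
#' enrichment tail of Fisher's exact test), computed exactly in log space.
#'
#' @param setA,setB character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all eligible gene ids (e.g. all
#'   annotated protein-coding genes).
#' @return list with `p.value`, `table` (the 2x2 contingency matrix),
#'   `overlap` (k), `expected` (|A||B|/N) and `universe_size`.
#' @examples
#' overlapFisher(letters[1:5], letters[1:5], letters[1:10])$p.value # 1/252
#' @export
overlapFisher <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  offA <- setdiff(setA, universe)
  offB <- setdiff(setB, universe)
  if (length(offA) || length(offB))
    stop("ids outside the universe: ",
         paste(unique(c(offA, offB)), collapse = ", "))
  N <- length(universe)
  nA <- length(setA)
  nB <- length(setB)
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  tab <- matrix(c(k, nB - k, nA - k, N - nA - nB + k), nrow = 2,
                dimnames = list(inA = c("yes", "no"), inB = c("yes", "no")))
  list(p.value = p, table = tab, overlap = k,
       expected = nA * nB / N, universe_size = N)
}

#' Welch's two-sample t-test (unequal variances)
#'
#' The two-sample t-test without the equal-variance assumption, using the
#' Welch-Satterthwaite degrees of freedom, as used to compare ChIP
#' enrichment means between strains.
#'
#' @param groupA,groupB numeric vectors with at least two values each;
#'   at least one group must have non-zero variance.
#' @return list with `t`, `df` and the two-sided `p.value`.
#' @export
welchTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least two values")
  if (sd(groupA) == 0 && sd(groupB) == 0)
    stop("both groups have zero variance")
  ht <- t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
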