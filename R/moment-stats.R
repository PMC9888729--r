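# Per-pair moment sums, the pairwise Hudson-type estimator, and the S
# statistic feeding tree inference.  All pairwise sums run over loci
# non-missing in both members of the pair; a locus monomorphic in the two
# units combined contributes zero to every sum and so never affects a
# statistic.  Sums are accumulated in double precision.

# core: returns K x K matrices of sums; ref/n are integer matrices with NA
# for missing cells.
.pairSumsCore <- function(ref, n) {
  K <- ncol(ref)
  if (!anyNA(ref)) {
    P <- ref / n
    H <- P * (1 - P)
    f <- n / (n - 1)
    hN <- colSums(f * H)              # per-unit corrected heterozygosity sum
    g <- colSums(H / (n - 1))         # small-sample correction term
    s1 <- colSums(P)
    Q <- colSums(P * P)
    C <- crossprod(P)
    sumD <- outer(s1, s1, "+") - 2 * C
    sumD[sumD < 0] <- 0               # guard against crossprod round-off
    sumNH <- outer(Q, Q, "+") - 2 * C - outer(g, g, "+")
    sumN <- matrix(hN, K, K)          # row k: depends on first unit only
    nLoci <- matrix(nrow(ref), K, K)
  } else {
    sumN <- sumD <- sumNH <- matrix(0, K, K)
    nLoci <- matrix(0L, K, K)
    obs <- !is.na(ref)
    for (k in seq_len(K - 1)) for (kp in (k + 1):K) {
      idx <- obs[, k] & obs[, kp]
      nk <- n[idx, k]; nkp <- n[idx, kp]
      pk <- ref[idx, k] / nk; pkp <- ref[idx, kp] / nkp
      hk <- pk * (1 - pk); hkp <- pkp * (1 - pkp)
      sumN[k, kp] <- sum(nk / (nk - 1) * hk)
      sumN[kp, k] <- sum(nkp / (nkp - 1) * hkp)
      d <- pk * (1 - pkp) + pkp * (1 - pk)
      sumD[k, kp] <- sumD[kp, k] <- sum(d)
      nh <- (pk - pkp)^2 - hk / (nk - 1) - hkp / (nkp - 1)
      sumNH[k, kp] <- sumNH[kp, k] <- sum(nh)
      nLoci[k, kp] <- nLoci[kp, k] <- sum(idx)
    }
  }
  dn <- list(colnames(ref), colnames(ref))
  dimnames(sumN) <- dimnames(sumD) <- dimnames(sumNH) <- dimnames(nLoci) <- dn
  list(sumN = sumN, sumD = sumD, sumNH = sumNH, nLoci = nLoci)
}

#' Per-pair moment sums and the S statistic
#'
#' Computes, for every ordered pair of units, the locus sums behind the
#' pairwise mismatch-type FST estimator and the scaled-heterozygosity
#' statistic `S`.  For pair (k, k'),
#' `S[k, k'] = 2 * sum[n_k/(n_k-1) p_k(1-p_k)] / sum[p_k(1-p_k') +
#' p_k'(1-p_k)]`, both sums over the loci observed in both units.  Under a
#' tree-structured drift model its expectation is the product of
#' `(1 - theta)` over the branches ancestral to k but not to k', which is
#' what the tree-fitting objective exploits.  With missing data the
#' `n/(n-1)` correction is applied per locus inside the sum.
#'
#' `S` is undefined for a pair whose denominator sum is zero (both units
#' fixed at every shared locus); such pairs are flagged in `sDefined` and
#' dropped from the least-squares system downstream.
#'
#' @param x an [AlleleCounts-class] object.
#' @param ... unused.
#' @return A [PairSummaries-class] object.
#' @examples
#' acm <- alleleCounts(ref = cbind(P1 = 5L, P2 = 5L),
#'                     n   = cbind(P1 = 10L, P2 = 10L))
#' sRaw(pairSums(acm))["P1", "P2"]   # 2*(10/9)*0.25/0.5 = 10/9
#' @export
setMethod("pairSums", "AlleleCounts", function(x, ...) {
  cs <- .pairSumsCore(refCounts(x), nGametes(x))
  K <- ncol(x)
  S <- matrix(NA_real_, K, K, dimnames = dimnames(cs$sumD))
  off <- which(!diag(K) & cs$sumD > 0)
  S[off] <- 2 * cs$sumN[off] / cs$sumD[off]
  sDef <- !diag(K) & cs$sumD > 0
  new("PairSummaries", labels = colnames(x), sumN = cs$sumN,
      sumD = cs$sumD, sumNH = cs$sumNH, nLoci = cs$nLoci, S = S,
      sDefined = sDef)
})

#' Raw (unclipped) S statistic matrix
#'
#' @param ps a [PairSummaries-class] object.
#' @return K x K matrix; entry (k, k') is the raw S value for the ordered
#'   pair, `NA` on the diagonal and for undefined pairs.  Finite-sample S
#'   can slightly exceed 1.
#' @export
sRaw <- function(ps) ps@S

#' Pairwise Hudson-type FST estimator (ratio of sums)
#'
#' For each pair of units the multi-locus estimator sums the per-locus
#' numerator (squared frequency difference minus the two within-unit
#' sampling corrections) and denominator (between-unit mismatch term)
#' separately and takes their ratio: the classical "ratio of averages"
#' form, preferred for its precision over averaging per-locus ratios.
#' Individual entries are not constrained to `[0, 1]` and can be negative.
#'
#' @param x an [AlleleCounts-class] or [PairSummaries-class] object.
#' @param ... unused.
#' @return Symmetric K x K matrix with a zero diagonal; `NA` for pairs
#'   whose denominator sum is zero.
#' @export
setMethod("hudsonPairwise", "AlleleCounts",
          function(x, ...) hudsonPairwise(pairSums(x)))

#' @rdname hudsonPairwise-AlleleCounts-method
#' @export
setMethod("hudsonPairwise", "PairSummaries", function(x, ...) {
  K <- length(x@labels)
  out <- matrix(NA_real_, K, K, dimnames = list(x@labels, x@labels))
  off <- which(!diag(K) & x@sumD > 0)
  out[off] <- x@sumNH[off] / x@sumD[off]
  diag(out) <- 0
  out
})

#' Clipped S matrix for the least-squares tree fit
#'
#' Clips raw S values into `[clipEps, 1]` so that `log(S)` is finite and
#' non-positive, matching the model range of its expectation.  Undefined
#' pairs stay `NA`; their rows are dropped from the fit.
#'
#' @param x a [PairSummaries-class] object.
#' @param clipEps lower clip bound (default `1e-12`).
#' @param ... unused.
#' @return K x K matrix of clipped S values, `NA` diagonal.
#' @export
setMethod("sMatrix", "PairSummaries", function(x, clipEps = 1e-12, ...) {
  S <- x@S
  ok <- !is.na(S)
  S[ok] <- pmin(pmax(S[ok], clipEps), 1)
  S
})

setMethod("show", "PairSummaries", function(object) {
  K <- length(object@labels)
  cat(sprintf("PairSummaries for %d units\n", K))
  nd <- sum(!object@sDefined[!diag(K)])
  if (nd > 0) cat(sprintf("undefined pairs: %d\n", nd))
  cat("S matrix (raw):\n")
  print(round(object@S, 4))
  invisible(object)
})
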