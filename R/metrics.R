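# Partition-agreement metrics: NMI, ARI, Purity.
#
# All three are computed from the contingency table between the predicted
# communities and the true classes. NMI uses arithmetic-mean normalization
# 2*I(X;Y)/(H(X)+H(Y)); the log base cancels in the ratio. ARI is the
# Hubert-Arabie adjusted Rand index over all sample pairs. Purity is the
# fraction of nodes lying in their predicted community's plurality class.

# Contingency counts between two assignments covering the same node set.
contingency <- function(p, t) {
  np <- names(p); nt <- names(t)
  if (is.null(np) || is.null(nt)) {
    stop("assignments must be named vectors (node -> label)", call. = FALSE)
  }
  if (length(np) != length(nt) || !setequal(np, nt) ||
      anyDuplicated(np) || anyDuplicated(nt)) {
    miss_p <- setdiff(nt, np); miss_t <- setdiff(np, nt)
    stop("node sets differ: ",
         if (length(miss_t)) paste0(length(miss_t),
           " node(s) missing from truth (e.g. ", miss_t[1L], ")") else "",
         if (length(miss_t) && length(miss_p)) "; " else "",
         if (length(miss_p)) paste0(length(miss_p),
           " node(s) missing from prediction (e.g. ", miss_p[1L], ")")
         else "",
         call. = FALSE)
  }
  table(pred = as.character(p)[order(np)],
        truth = as.character(t)[order(nt)])
}

entropy_nats <- function(sizes, n) {
  pr <- sizes[sizes > 0] / n
  -sum(pr * log(pr)) # 0*log(0) terms excluded: standard limit convention
}

#' Normalized mutual information between a partition and ground truth
#'
#' `2 * I(X;Y) / (H(X) + H(Y))`, with entropies taken over the empirical
#' community/class proportions. Ranges over \[0, 1\]; 1 means the two
#' assignments carry identical information, 0 that they are independent.
#' Symmetric in its arguments and invariant to community relabelling. When
#' both entropies are zero (both sides a single cluster) the assignments are
#' identical and 1 is returned.
#'
#' @param p Predicted partition: named character vector (node -> community).
#' @param t Ground truth: named character vector (node -> class).
#' @return A number in \[0, 1\].
#' @export
nmi <- function(p, t) {
  ct <- contingency(p, t)
  n <- sum(ct)
  hx <- entropy_nats(rowSums(ct), n)
  hy <- entropy_nats(colSums(ct), n)
  if (hx + hy == 0) {
    return(if (identical(unname(sort(rowSums(ct))),
                         unname(sort(colSums(ct))))) 1 else 0)
  }
  pj <- ct / n
  ex <- outer(rowSums(ct) / n, colSums(ct) / n)
  nz <- pj > 0
  i <- sum(pj[nz] * log(pj[nz] / ex[nz]))
  2 * i / (hx + hy)
}

#' Adjusted Rand index between a partition and ground truth
#'
#' The Hubert-Arabie chance-corrected Rand index over all node pairs:
#' `(RI - E[RI]) / (max RI - E[RI])` computed from the contingency table.
#' Equals 1 for identical partitions, has expectation 0 for independent
#' random ones, and can be negative. Symmetric and relabelling-invariant.
#'
#' @inheritParams nmi
#' @return A number in \[-1, 1\].
#' @export
ari <- function(p, t) {
  ct <- contingency(p, t)
  n <- sum(ct)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  total <- comb2(n)
  expected <- sum_a * sum_b / total
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1) # both trivial partitions: identical
  (sum_ij - expected) / (maximum - expected)
}

#' Purity of a partition against ground truth
#'
#' The fraction of nodes that fall in the plurality true class of their
#' predicted community: `(1/N) * sum_i max_j |w_i intersect c_j|`. Always in
#' (0, 1]. Not symmetric — an all-singletons prediction scores a perfect 1
#' against any truth — so it is reported alongside NMI and ARI, never alone.
#'
#' @inheritParams nmi
#' @return A number in (0, 1].
#' @export
purity <- function(p, t) {
  ct <- contingency(p, t)
  sum(apply(ct, 1L, max)) / sum(ct)
}

#' Score a predicted partition against ground truth on all three metrics
#'
#' @inheritParams nmi
#' @return A list of class `"iacd_metrics"` with elements `nmi`, `ari`,
#'   `purity`.
#' @examples
#' ex <- example_network()
#' evaluate_partitions(iacd_detect(ex$network), ex$truth)
#' @export
evaluate_partitions <- function(p, t) {
  structure(list(nmi = nmi(p, t), ari = ari(p, t), purity = purity(p, t)),
            class = "iacd_metrics")
}

#' Write a metric report as a flat TSV (metric<TAB>value, 4 decimals)
#'
#' @param x An `"iacd_metrics"` object from [evaluate_partitions()].
#' @param path Output path, or `""` to print to stdout.
#' @return Invisibly, the formatted lines.
#' @export
write_metrics <- function(x, path = "") {
  lines <- sprintf("%s\t%.4f", c("nmi", "ari", "purity"),
                   c(x$nmi, x$ari, x$purity))
  writeLines(lines, if (identical(path, "")) stdout() else path)
  invisible(lines)
}

#' @export
print.iacd_metrics <- function(x, ...) {
  cat(sprintf("nmi     %.4f\nari     %.4f\npurity  %.4f\n",
              x$nmi, x$ari, x$purity))
  invisible(x)
}
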