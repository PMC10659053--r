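#' Likelihood-ratio test for differential editing at one site
#'
#' Fits the per-site binomial logistic regression used for differential
#' editing: under the null all replicates share one editing proportion;
#' under the alternative each group has its own proportion
#' (`logit p = b0 + b1 * group`). Replicates within a group share the group
#' proportion (no overdispersion term), so the maximised likelihoods have
#' closed forms at the pooled group proportions and the deviance equals
#' the likelihood-ratio (G) statistic of the pooled 2x2 table. The p-value
#' is the chi-squared(1) upper tail.
#'
#' @param k_a,n_a edited and total read counts per replicate in group A.
#' @param k_b,n_b edited and total read counts per replicate in group B.
#' @return a list with `statistic`, `p.value`, `level_a`, `level_b` (pooled
#'   group levels) and `delta` (`level_b - level_a`).
#' @export
lrt_binomial_glm <- function(k_a, n_a, k_b, n_b) {
  stopifnot(all(k_a >= 0), all(k_b >= 0), all(k_a <= n_a), all(k_b <= n_b),
            length(k_a) == length(n_a), length(k_b) == length(n_b))
  if (sum(n_a) <= 0 || sum(n_b) <= 0)
    stop("both groups need positive total counts", call. = FALSE)
  r <- lrt_pooled(sum(k_a), sum(n_a), sum(k_b), sum(n_b))
  list(statistic = r$statistic, p.value = r$p.value,
       level_a = r$level_a, level_b = r$level_b, delta = r$delta)
}

# vectorised closed-form LRT on pooled group counts
lrt_pooled <- function(KA, NA_, KB, NB) {
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  ll <- function(K, N, p) xlogy(K, p) + xlogy(N - K, 1 - p)
  pa <- KA / NA_
  pb <- KB / NB
  p0 <- (KA + KB) / (NA_ + NB)
  D <- pmax(0, 2 * (ll(KA, NA_, pa) + ll(KB, NB, pb) -
                      ll(KA + KB, NA_ + NB, p0)))
  list(statistic = D, p.value = pchisq(D, df = 1L, lower.tail = FALSE),
       level_a = pa, level_b = pb, delta = pb - pa)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment of p-values (wraps [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Classify differential-editing results at FDR and difference thresholds
#'
#' A site is `up` at a threshold pair when `q < fdr` and
#' `delta >= diff`, `down` when `q < fdr` and `delta <= -diff`, otherwise
#' `ns`. One class column is added per difference threshold (`class_10p`,
#' `class_20p` for the defaults); by construction the calls at a larger
#' difference threshold are a subset of those at a smaller one.
#'
#' @param results a differential-result table with `q.value` and `delta`.
#' @param fdr FDR threshold.
#' @param diffs difference-value thresholds.
#' @return a list with `results` (classified table) and `summary`, the
#'   up/down counts per threshold.
#' @export
classify_sites <- function(results, fdr = 0.05, diffs = c(0.10, 0.20)) {
  results <- as.data.table(results)
  summ <- vector("list", length(diffs))
  for (i in seq_along(diffs)) {
    d <- diffs[i]
    cl <- fifelse(results$q.value < fdr & results$delta >= d, "up",
                  fifelse(results$q.value < fdr & results$delta <= -d,
                          "down", "ns"))
    col <- sprintf("class_%dp", round(100 * d))
    results[, (col) := cl]
    summ[[i]] <- data.table(diff = d, up = sum(cl == "up"),
                            down = sum(cl == "down"), ns = sum(cl == "ns"))
  }
  list(results = results[], summary = rbindlist(summ))
}

#' Differential editing between two groups of replicate count tables
#'
#' Runs the per-site binomial logistic-regression LRT over all sites
#' testable in a two-group comparison, applies BH-FDR across sites, and
#' classifies sites at the difference thresholds. A site is testable only
#' when every replicate in both groups reaches `min_coverage` total reads.
#' The group difference `delta` is the difference of pooled group levels
#' (`sum(k)/sum(n)` per group) by default, or of replicate-mean levels
#' with `delta_mode = "mean"`.
#'
#' @param counts a long table with columns `site`, `group`, `replicate`,
#'   `k` (edited reads) and `n` (total reads).
#' @param group_a,group_b labels in `counts$group` to compare (B vs A;
#'   positive `delta` means higher editing in B).
#' @param fdr,diffs thresholds passed to [classify_sites()].
#' @param min_coverage per-replicate coverage required for testability.
#' @param delta_mode `"pooled"` or `"mean"`.
#' @return a list with `results` (one row per testable site: pooled
#'   levels, `delta`, `statistic`, `p.value`, `q.value` and class columns),
#'   `summary` (up/down counts per threshold) and `n_untestable`.
#' @export
differential_editing <- function(counts, group_a, group_b, fdr = 0.05,
                                 diffs = c(0.10, 0.20), min_coverage = 10L,
                                 delta_mode = c("pooled", "mean")) {
  delta_mode <- match.arg(delta_mode)
  counts <- as.data.table(counts)
  counts <- counts[group %in% c(group_a, group_b)]
  ok <- counts[, .(testable = all(n >= min_coverage) &&
                     length(unique(group)) == 2L), by = site]
  testable_sites <- ok[testable == TRUE, site]
  sub <- counts[site %in% testable_sites]
  if (!nrow(sub)) {
    return(list(results = data.table(site = character(0),
                                     level_a = numeric(0),
                                     level_b = numeric(0),
                                     delta = numeric(0),
                                     statistic = numeric(0),
                                     p.value = numeric(0),
                                     q.value = numeric(0)),
                summary = data.table(diff = diffs, up = 0L, down = 0L,
                                     ns = 0L),
                n_untestable = length(unique(counts$site))))
  }
  pooled <- sub[, .(K = sum(k), N = sum(n), mlvl = mean(k / n)),
                by = .(site, group)]
  wide <- dcast(pooled, site ~ group, value.var = c("K", "N", "mlvl"))
  ka <- wide[[paste0("K_", group_a)]]
  na_ <- wide[[paste0("N_", group_a)]]
  kb <- wide[[paste0("K_", group_b)]]
  nb <- wide[[paste0("N_", group_b)]]
  r <- lrt_pooled(ka, na_, kb, nb)
  res <- data.table(site = wide$site, level_a = r$level_a,
                    level_b = r$level_b,
                    delta = if (delta_mode == "pooled") r$delta else
                      wide[[paste0("mlvl_", group_b)]] -
                      wide[[paste0("mlvl_", group_a)]],
                    statistic = r$statistic, p.value = r$p.value)
  res[, q.value := bh_fdr(p.value)]
  cl <- classify_sites(res, fdr = fdr, diffs = diffs)
  c(cl, list(n_untestable = length(unique(counts$site)) -
               length(testable_sites)))
}

#' Per-replicate edited/total counts at given sites
#'
#' Extracts the `G` (edited) and `G+A` (total) counts of each site from a
#' set of per-replicate RNA pileups, producing the long count table
#' consumed by [differential_editing()].
#'
#' @param pileups a named list of RNA `site_pileup` tables; names encode
#'   `<condition>.<replicate>`.
#' @param sites an edit-site table (`chrom`, `pos`, `strand`, `ref_tx`,
#'   `alt_tx`).
#' @return a long data.table (`site`, `group`, `replicate`, `k`, `n`).
#' @export
site_replicate_counts <- function(pileups, sites) {
  sites <- as.data.table(sites)
  out <- vector("list", length(pileups))
  for (i in seq_along(pileups)) {
    nm <- names(pileups)[i]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    pp <- as.data.table(pileups[[i]])
    j <- pp[sites, on = c("chrom", "pos", "strand")]
    cm <- as.matrix(j[, .(A, C, G, T)])
    cm[is.na(cm)] <- 0L
    kk <- cm[cbind(seq_len(nrow(j)), match(j$alt_tx, BASES))]
    rr <- cm[cbind(seq_len(nrow(j)), match(j$ref_tx, BASES))]
    out[[i]] <- data.table(site = site_key(j$chrom, j$pos, j$strand),
                           group = parts[1],
                           replicate = if (length(parts) > 1L) parts[2] else "1",
                           k = kk, n = kk + rr)
  }
  rbindlist(out)
}
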