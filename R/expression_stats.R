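#' qPCR relative expression and the supporting significance tests
#'
#' Efficiency-corrected relative expression (Pfaffl) ratios normalized to a
#' reference gene and calibrator group, classic pooled-variance Student's t
#' tests between genotype groups, and the exact two-sided Fisher test for
#' 2x2 contingency tables of transgenic counts.
#'
#' @name expression_stats
NULL

#' Pfaffl efficiency-corrected expression ratio
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref` where
#' `dCt = mean Ct(calibrator) - mean Ct(sample)` and `E` is the
#' amplification efficiency (2 = perfect doubling per cycle). Comparing the
#' calibrator with itself gives exactly 1.
#'
#' @param e_target,e_ref amplification efficiencies, in \[1, 2.2\].
#' @param dct_target,dct_ref Ct differences (calibrator minus sample) for
#'   the target and reference gene.
#' @return positive fold change.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (e_target < 1 || e_ref < 1) stop("efficiencies must be >= 1")
  (e_target ^ dct_target) / (e_ref ^ dct_ref)
}

#' Pfaffl fold changes from a replicate Ct table
#'
#' @param ct data.frame with columns `gene`, `group`, `ct` (one row per
#'   replicate; extra columns ignored).
#' @param ref_gene reference (normalizer) gene, e.g. beta-actin.
#' @param calibrator group whose fold change is defined as 1 (wildtype).
#' @param efficiencies named numeric vector of per-gene efficiencies;
#'   unlisted genes default to 2.
#' @return data.frame `gene`, `group`, `fold_change`.
#' @export
pfaffl_fold_changes <- function(ct, ref_gene, calibrator = "wt",
                                efficiencies = NULL) {
  need <- c("gene", "group", "ct")
  if (!all(need %in% names(ct))) stop("ct table needs gene, group, ct")
  if (!ref_gene %in% ct$gene) stop("reference gene absent from table")
  eff <- function(g) {
    if (!is.null(efficiencies) && g %in% names(efficiencies)) {
      efficiencies[[g]]
    } else 2
  }
  mean_ct <- aggregate(ct ~ gene + group, data = ct, FUN = mean)
  get_mean <- function(g, grp) {
    v <- mean_ct$ct[mean_ct$gene == g & mean_ct$group == grp]
    if (length(v) != 1L) NA_real_ else v
  }
  genes <- setdiff(unique(ct$gene), ref_gene)
  groups <- unique(ct$group)
  out <- expand.grid(gene = genes, group = groups, stringsAsFactors = FALSE)
  out$fold_change <- vapply(seq_len(nrow(out)), function(i) {
    g <- out$gene[i]; grp <- out$group[i]
    dct_t <- get_mean(g, calibrator) - get_mean(g, grp)
    dct_r <- get_mean(ref_gene, calibrator) - get_mean(ref_gene, grp)
    pfaffl_ratio(eff(g), dct_t, eff(ref_gene), dct_r)
  }, numeric(1))
  out
}

#' Pooled-variance two-sample Student's t test
#'
#' Classic equal-variance t with `n_a + n_b - 2` degrees of freedom and a
#' two-tailed p value. Degenerate zero-pooled-variance inputs follow the
#' convention p = 1 for equal means and p = 0 otherwise. Welch's unequal
#' variance form is available behind `welch = TRUE`.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param welch use Welch's t instead of the pooled form.
#' @return list with `t`, `df`, `p`.
#' @export
student_t_test <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 observations")
  }
  na <- length(group_a); nb <- length(group_b)
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                   sum((group_b - mean(group_b))^2)) / (na + nb - 2L)
  if (pooled_var == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(t = if (equal) 0 else Inf * sign(mean(group_a) -
                                                   mean(group_b)),
                df = na + nb - 2L, p = if (equal) 1 else 0))
  }
  fit <- t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Conditional on the observed margins, sums the hypergeometric
#' probabilities of every table whose probability does not exceed that of
#' the observed table (the probability-mass rule, the common two-sided
#' convention). Probabilities are computed in log space.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return list with `p` and the observed-table log probability
#'   `log_p_obs`.
#' @export
fisher_exact_two_sided <- function(table) {
  x <- as.integer(table)
  if (length(x) != 4L || any(x < 0L)) stop("need a 2x2 table of counts >= 0")
  if (sum(x) == 0L) stop("all-zero table")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- dhyper(support, m, n, k, log = TRUE)
  log_obs <- dhyper(a, m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= log_obs + 1e-7]))
  list(p = min(p, 1), log_p_obs = log_obs)
}

#' Group-wise expression analysis from a Ct table
#'
#' Combines [pfaffl_fold_changes()] with per-gene Student's t tests of the
#' replicate delta-Ct values between each group and the calibrator.
#'
#' @inheritParams pfaffl_fold_changes
#' @return data.frame `gene`, `group`, `fold_change`, `t`, `p` (`NA` for
#'   the calibrator rows).
#' @export
expression_report <- function(ct, ref_gene, calibrator = "wt",
                              efficiencies = NULL) {
  fc <- pfaffl_fold_changes(ct, ref_gene, calibrator, efficiencies)
  ref_by_group <- split(ct$ct[ct$gene == ref_gene],
                        ct$group[ct$gene == ref_gene])
  fc$t <- NA_real_; fc$p <- NA_real_
  for (i in seq_len(nrow(fc))) {
    g <- fc$gene[i]; grp <- fc$group[i]
    if (grp == calibrator) next
    # per-replicate Ct normalized to the reference gene's group mean
    dct_grp <- ct$ct[ct$gene == g & ct$group == grp] -
      mean(ref_by_group[[grp]])
    dct_cal <- ct$ct[ct$gene == g & ct$group == calibrator] -
      mean(ref_by_group[[calibrator]])
    if (length(dct_grp) >= 2L && length(dct_cal) >= 2L) {
      tt <- student_t_test(dct_grp, dct_cal)
      fc$t[i] <- tt$t; fc$p[i] <- tt$p
    }
  }
  fc
}

#' Read a Ct table / write an expression report as TSV
#'
#' @param path TSV with columns `gene`, `group`, `replicate`, `ct`.
#' @export
read_ct_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_ct_table
#' @param report data.frame from [expression_report()].
#' @export
write_expression_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
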