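# Cohort-genetics arithmetic: minor allele frequency in a sequenced
# cohort, and the 2x2 chi-square test of association with Yates
# continuity correction.

#' Allele frequency in a cohort
#'
#' @param n_variant_alleles number of variant alleles observed.
#' @param n_individuals number of sequenced individuals.
#' @param ploidy alleles per individual (2 for autosomal diploid).
#' @return frequency in `[0, 1]`:
#'   `n_variant_alleles / (ploidy * n_individuals)`.
#' @examples
#' # one heterozygote among 53 diploid individuals
#' allele_frequency(1, 53)  # 0.0094 at 2 significant figures
#' @export
allele_frequency <- function(n_variant_alleles, n_individuals, ploidy = 2) {
  if (n_individuals < 1) stop("`n_individuals` must be positive")
  if (ploidy < 1) stop("`ploidy` must be >= 1")
  if (n_variant_alleles < 0 ||
      n_variant_alleles > ploidy * n_individuals) {
    stop("`n_variant_alleles` must lie in [0, ploidy * n_individuals]")
  }
  n_variant_alleles / (ploidy * n_individuals)
}

#' 2x2 chi-square test with Yates continuity correction
#'
#' For the table `(a, b; c, d)` with `N = a + b + c + d`:
#' `chi2 = N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' clamped to 0 when the correction overshoots
#' (`|ad - bc| <= N/2`). The p-value is the upper tail of the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative integer counts, or a numeric
#'   vector `c(a, b, c, d)` read row-wise.
#' @param correct apply the Yates correction (default TRUE; FALSE gives
#'   the uncorrected Pearson statistic).
#' @return list with `chi2`, `df` (1), and `p`.
#' @export
yates_chi2 <- function(table, correct = TRUE) {
  x <- as.numeric(table)
  if (length(x) != 4 || any(x < 0) || any(x != round(x))) {
    stop("`table` must be four nonnegative integer counts")
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if (is.matrix(table)) { b <- table[1, 2]; c <- table[2, 1] }
  N <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_,
                undefined = TRUE))
  }
  delta <- abs(a * d - b * c)
  if (correct) delta <- max(delta - N / 2, 0)
  chi2 <- N * delta^2 / prod(marg)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       undefined = FALSE)
}
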