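# ---- Exclusion ledger -------------------------------------------------------

#' Create an empty exclusion ledger
#'
#' The ledger is the auditable probe/gene exclusion flow: an ordered table of
#' (criterion, count before, count excluded) steps whose chained counts must
#' conserve probes — the count entering step i+1 equals the count entering
#' step i minus its exclusions.
#'
#' @return An empty `exclusion_ledger` data frame.
#' @export
new_ledger <- function() {
  structure(data.frame(criterion = character(0), n_before = integer(0),
                       n_excluded = integer(0), stringsAsFactors = FALSE),
            class = c("exclusion_ledger", "data.frame"))
}

#' Append a step to an exclusion ledger
#'
#' @param ledger An exclusion ledger.
#' @param criterion Text label of the exclusion criterion.
#' @param n_before Count entering this step.
#' @param n_excluded Count removed by this step.
#' @return The extended ledger; chaining and non-negativity are enforced.
#' @export
ledger_append <- function(ledger, criterion, n_before, n_excluded) {
  n_before <- as.integer(n_before); n_excluded <- as.integer(n_excluded)
  if (n_before < 0 || n_excluded < 0 || n_excluded > n_before)
    stop("ledger counts must satisfy 0 <= n_excluded <= n_before")
  k <- nrow(ledger)
  if (k > 0) {
    expected <- ledger$n_before[k] - ledger$n_excluded[k]
    if (n_before != expected)
      stop(sprintf("ledger conservation violated: step '%s' starts at %d, expected %d",
                   criterion, n_before, expected))
  }
  out <- rbind(as.data.frame(unclass(ledger)),
               data.frame(criterion = criterion, n_before = n_before,
                          n_excluded = n_excluded, stringsAsFactors = FALSE))
  structure(out, class = c("exclusion_ledger", "data.frame"))
}

#' Number of items surviving all ledger steps
#' @param ledger An exclusion ledger with at least one step.
#' @return Integer count remaining after the last step.
#' @export
ledger_remaining <- function(ledger) {
  k <- nrow(ledger)
  if (k == 0) stop("empty ledger has no remaining count")
  ledger$n_before[k] - ledger$n_excluded[k]
}

# ---- Jarque-Bera normality --------------------------------------------------

#' Jarque-Bera statistic from population moments
#'
#' Classic Jarque-Bera form on population (biased, divide-by-n) moments:
#' skewness \eqn{S = m_3 / m_2^{3/2}}, non-excess kurtosis
#' \eqn{K = m_4 / m_2^2}, and
#' \eqn{JB = (n/6)\,(S^2 + (K-3)^2/4)}. A `sample_corrected` switch applies
#' the small-sample skewness/kurtosis corrections instead; the default is the
#' uncorrected population form.
#'
#' @param values Numeric vector, length >= 4, non-constant.
#' @param sample_corrected Use bias-corrected sample skewness/kurtosis.
#' @return A list with `skewness`, `kurtosis` (non-excess), `jb_statistic`.
#' @export
jarque_bera <- function(values, sample_corrected = FALSE) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4) stop("Jarque-Bera needs at least 4 values")
  x <- values - mean(values)
  m2 <- mean(x^2)
  if (m2 == 0) stop("constant sequence: Jarque-Bera undefined at zero variance")
  S <- mean(x^3) / m2^1.5
  K <- mean(x^4) / m2^2
  if (sample_corrected) {
    S <- S * sqrt(n * (n - 1)) / (n - 2)
    K <- 3 + ((n + 1) * (K - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  jb <- (n / 6) * (S^2 + (K - 3)^2 / 4)
  list(skewness = S, kurtosis = K, jb_statistic = jb)
}

#' Chi-square (df = 2) survival function
#'
#' The survival function of a chi-square variate with two degrees of freedom
#' has the exact closed form \eqn{P(X \ge x) = e^{-x/2}}, which is what the
#' Jarque-Bera statistic is referred to.
#'
#' @param x Non-negative numeric vector.
#' @return `exp(-x/2)`, elementwise.
#' @export
chi2_sf_df2 <- function(x) {
  if (any(x < 0)) stop("chi-square statistic must be non-negative")
  exp(-x / 2)
}

#' Screen probes for normality and append the exclusions to the ledger
#'
#' Computes the Jarque-Bera statistic for every probe row, converts it to a
#' p-value with the exact chi-square(2) survival function, and removes probes
#' with `p < alpha_norm` (ties at exactly `alpha_norm` are retained).
#' Constant-valued probes cannot be tested and are removed first under their
#' own ledger criterion.
#'
#' @param mat An expression matrix.
#' @param alpha_norm Significance level for the normality screen (default
#'   0.05).
#' @param ledger An exclusion ledger to append to.
#' @param sample_corrected Passed to [jarque_bera()].
#' @param exempt Probe IDs never excluded by the screen (their statistics
#'   are still recorded). The pipeline exempts the seed's reference probe:
#'   the screen protects the correlation panel, while the reference probe's
#'   distributional adequacy is a precondition checked when the seed is
#'   chosen, not a per-run random event.
#' @return A list with `matrix` (surviving probes), `records` (a data frame
#'   of per-probe S, K, JB, p, passed), and the extended `ledger`.
#' @export
filter_normality <- function(mat, alpha_norm = 0.05, ledger = new_ledger(),
                             sample_corrected = FALSE, exempt = character(0)) {
  if (alpha_norm < 0 || alpha_norm >= 1) stop("alpha_norm must lie in [0, 1)")
  n <- ncol(mat)
  centred <- mat - rowMeans(mat)
  m2 <- rowMeans(centred^2)
  constant <- m2 == 0
  if (any(constant)) {
    ledger <- ledger_append(ledger, "Constant-valued probe",
                            nrow(mat), sum(constant))
    mat <- mat[!constant, , drop = FALSE]
    centred <- centred[!constant, , drop = FALSE]
    m2 <- m2[!constant]
  }
  S <- rowMeans(centred^3) / m2^1.5
  K <- rowMeans(centred^4) / m2^2
  if (sample_corrected) {
    S <- S * sqrt(n * (n - 1)) / (n - 2)
    K <- 3 + ((n + 1) * (K - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  }
  jb <- (n / 6) * (S^2 + (K - 3)^2 / 4)
  p <- chi2_sf_df2(jb)
  passed <- p >= alpha_norm | rownames(mat) %in% exempt
  records <- data.frame(probe_id = rownames(mat), skewness = S, kurtosis = K,
                        jb_statistic = jb, p_value = p, passed = passed,
                        row.names = NULL, stringsAsFactors = FALSE)
  ledger <- ledger_append(ledger,
                          "Failed Jarque-Bera normality test / significance",
                          nrow(mat), sum(!passed))
  surviving <- mat[passed, , drop = FALSE]
  if (nrow(surviving) == 0) stop("no probes survive the normality screen")
  list(matrix = expression_matrix(unclass(surviving)), records = records,
       ledger = ledger)
}
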