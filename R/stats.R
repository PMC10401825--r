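# Statistical comparisons used by the strategy-comparison stage: paired
# t-tests, Pearson/Spearman correlations and two-way (region x strategy)
# repeated-measures ANOVA. Two-tailed p-values throughout; no sphericity
# correction is applied.

#' Paired two-tailed Student's t-test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the paired differences d = a - b,
#' df = n - 1, two-tailed p from the t distribution.
#'
#' @param a,b Paired condition values (equal length, no missing pairs).
#' @return A list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (any(is.na(a)) || any(is.na(b))) stop("missing pairs are not allowed")
  d <- a - b
  if (stats::sd(d) < 1e-12)
    stop("zero-variance differences: paired t-test undefined")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), n = length(d))
}

#' Pearson or Spearman correlation
#'
#' Product-moment correlation, or correlation of average ranks (ties
#' averaged) for Spearman; p-value via the t transform.
#'
#' @param x,y Numeric vectors (n >= 3, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `p`, `n`, `method`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("constant input: correlation undefined")
  ht <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x),
       method = method)
}

#' Two-way repeated-measures ANOVA (region x strategy)
#'
#' Fully within-subject two-factor ANOVA on a complete balanced design:
#' each effect (region, strategy, region x strategy) is tested against its
#' own subject-by-effect interaction error term.
#'
#' @param values Numeric array `subject x region x strategy`, or a long data
#'   frame with columns `value`, `subject`, `region`, `strategy`.
#' @return A data frame with effect, df, df_error, ss, ss_error, F, p.
#' @export
rm_anova_two_way <- function(values) {
  if (is.data.frame(values)) {
    df <- values
    stopifnot(all(c("value", "subject", "region", "strategy") %in% names(df)))
  } else {
    stopifnot(length(dim(values)) == 3L)
    dn <- dimnames(values)
    ds <- dim(values)
    df <- data.frame(
      value = as.vector(values),
      subject = rep(if (is.null(dn[[1]])) seq_len(ds[1]) else dn[[1]],
                    times = ds[2] * ds[3]),
      region = rep(rep(if (is.null(dn[[2]])) seq_len(ds[2]) else dn[[2]],
                       each = ds[1]), times = ds[3]),
      strategy = rep(if (is.null(dn[[3]])) seq_len(ds[3]) else dn[[3]],
                     each = ds[1] * ds[2]))
  }
  df$subject <- factor(df$subject)
  df$region <- factor(df$region)
  df$strategy <- factor(df$strategy)
  counts <- table(df$subject, df$region, df$strategy)
  if (any(counts != 1L) || nlevels(df$region) < 2L ||
      nlevels(df$strategy) < 2L || nlevels(df$subject) < 2L)
    stop("design must be complete and balanced (one value per cell, ",
         "at least two levels per factor)")
  fit <- stats::aov(value ~ region * strategy +
                      Error(subject / (region * strategy)), data = df)
  sm <- summary(fit)
  pick <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    i <- match(effect, trimws(rownames(tab)))
    e <- match("Residuals", trimws(rownames(tab)))
    data.frame(effect = effect, df = tab$Df[i], df_error = tab$Df[e],
               ss = tab$`Sum Sq`[i], ss_error = tab$`Sum Sq`[e],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i])
  }
  out <- rbind(pick("Error: subject:region", "region"),
               pick("Error: subject:strategy", "strategy"),
               pick("Error: subject:region:strategy", "region:strategy"))
  rownames(out) <- NULL
  # a numerically null effect (zero SS up to rounding) is reported as F = 0
  # rather than the 0/0 ratio of two vanishing sums of squares
  tot <- sum(out$ss + out$ss_error)
  null_eff <- out$ss <= 1e-10 * max(tot, .Machine$double.xmin)
  out$F[null_eff] <- 0
  out$p[null_eff] <- 1
  out
}
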