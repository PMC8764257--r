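# Trait-level computations: carbon isotope composition, descriptive
# statistics, growth increments, and family/genotype one-way ANOVAs.

#' Carbon isotope composition (delta 13C)
#'
#' \deqn{\delta^{13}C\ (\text{per mil}) = (R_{sa} - R_{sd}) / R_{sd} \times 1000}
#' where `r_sa` and `r_sd` are the 13C/12C ratios of the sample and the
#' standard (Vienna Peedee Belemnite).
#'
#' @param r_sa Sample isotope ratio(s), > 0.
#' @param r_sd Standard isotope ratio, > 0.
#' @return delta 13C in per mil.
#' @export
delta13c <- function(r_sa, r_sd) {
  if (any(!is.finite(r_sd)) || any(r_sd <= 0))
    stopf("standard isotope ratio must be positive")
  (r_sa - r_sd) / r_sd * 1000
}

#' Maximum quantum yield of photosystem II
#'
#' `(F_m - F_o) / F_m` from dark-adapted maximum and minimum chlorophyll
#' fluorescence. The instrument-level signal processing is out of scope; this
#' is the trait arithmetic only.
#'
#' @param f_m Maximum fluorescence, > 0.
#' @param f_o Minimum fluorescence.
#' @return Y (dimensionless).
#' @export
fvfm <- function(f_m, f_o) {
  if (any(!is.finite(f_m)) || any(f_m <= 0)) stopf("F_m must be positive")
  (f_m - f_o) / f_m
}

#' Descriptive summary of a trait
#'
#' N (non-missing), mean, sample SD (n-1 denominator), min, max and the
#' coefficient of variation `CV% = SD/mean * 100`. The CV is signed (negative
#' for traits with negative means, such as delta 13C); `cv_abs` carries the
#' magnitude.
#'
#' @param values Numeric vector; missing values allowed.
#' @return List with `n`, `mean`, `sd`, `min`, `max`, `cv`, `cv_abs`.
#' @export
summarize_trait <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stopf("need at least 2 non-missing values")
  m <- mean(v); s <- stats::sd(v)
  cv <- if (m == 0) NA_real_ else s / m * 100
  list(n = length(v), mean = m, sd = s, min = min(v), max = max(v),
       cv = cv, cv_abs = abs(cv))
}

#' Table of descriptive statistics for several traits
#'
#' @param data Data frame holding the trait columns.
#' @param traits Character vector of trait column names.
#' @return Data frame, one row per trait: `trait`, `n`, `mean`, `sd`, `min`,
#'   `max`, `cv`.
#' @export
summarize_traits <- function(data, traits) {
  rows <- lapply(traits, function(tr) {
    s <- summarize_trait(data[[tr]])
    data.frame(trait = tr, n = s$n, mean = s$mean, sd = s$sd,
               min = s$min, max = s$max, cv = s$cv)
  })
  do.call(rbind, rows)
}

#' Percent growth increase between two means
#'
#' `100 * (after - before) / before`.
#'
#' @param mean_before Baseline mean, > 0.
#' @param mean_after Later mean.
#' @return Percent increase (negative for a decrease).
#' @export
growth_increase <- function(mean_before, mean_after) {
  if (!is.finite(mean_before) || mean_before <= 0)
    stopf("baseline mean must be positive")
  100 * (mean_after - mean_before) / mean_before
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition testing whether group means differ
#' (e.g. trait means across families or genotypes), with F on (k-1, N-k)
#' degrees of freedom.
#'
#' @param values Numeric response.
#' @param groups Factor or character group labels.
#' @return List with `F`, `p`, `df` (length 2), `infinite` (TRUE when the
#'   within-group variance is zero while group means differ).
#' @export
oneway_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  y <- values[keep]; g <- factor(groups[keep])
  if (nlevels(g) < 2) stopf("need at least 2 groups")
  if (length(y) <= nlevels(g)) stopf("need more observations than groups")
  # lm warns on an essentially perfect fit; the degenerate cases are handled
  # explicitly below
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ss_b <- tab$`Sum Sq`[1]; ss_w <- tab$`Sum Sq`[2]
  df <- tab$Df
  if (ss_w <= .Machine$double.eps * sum(y^2)) {
    if (ss_b <= .Machine$double.eps * sum(y^2))
      stopf("F undefined: zero variance both between and within groups")
    return(list(F = Inf, p = 0, df = df, infinite = TRUE))
  }
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1], df = df, infinite = FALSE)
}

#' Correlation between two traits at group-mean level
#'
#' Aggregates both traits to group (family or genotype) means and reports the
#' Pearson correlation, ordinary least-squares slope and its p-value.
#'
#' @param x,y Numeric plant-level traits.
#' @param groups Group labels (same length).
#' @return List with `r`, `slope`, `p`, `n_groups`, and the mean table.
#' @export
trait_correlation <- function(x, y, groups) {
  keep <- !is.na(x) & !is.na(y) & !is.na(groups)
  mx <- tapply(x[keep], groups[keep], mean)
  my <- tapply(y[keep], groups[keep], mean)
  if (length(mx) < 3) stopf("need at least 3 groups")
  fit <- stats::lm(my ~ mx)
  sm <- summary(fit)
  list(r = stats::cor(mx, my), slope = unname(stats::coef(fit)[2]),
       p = sm$coefficients[2, 4], n_groups = length(mx),
       means = data.frame(group = names(mx), x = as.numeric(mx),
                          y = as.numeric(my)))
}
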