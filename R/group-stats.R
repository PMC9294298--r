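#' @importFrom rlang .data
NULL

stat_result <- function(effect, statistic, df, p, method,
                        p_adjusted = NA_real_, correction = "none") {
  tibble::tibble(
    effect = effect,
    statistic = as.numeric(statistic),
    df1 = as.numeric(df[1]),
    df2 = if (length(df) > 1) as.numeric(df[2]) else NA_real_,
    p = as.numeric(p),
    p_adjusted = as.numeric(p_adjusted),
    correction = correction,
    method = method
  )
}

#' One-way repeated-measures ANOVA for a frequency effect
#'
#' Tests whether a dynamics metric differs across frequency bands when every
#' subject is measured in every band. Classical within-subject ANOVA: the
#' band effect is tested against the subject-by-band residual.
#'
#' @param values Numeric subjects-by-bands matrix (complete: no missing
#'   cells) or a data frame in that shape.
#' @return A one-row tibble: `effect`, `statistic` (F), `df1`, `df2`, `p`.
#' @export
repeated_measures_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(values); b <- ncol(values)
  if (n < 2 || b < 2) stop("need >= 2 subjects and >= 2 conditions",
                           call. = FALSE)
  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- b * sum((rowMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- b - 1
  df2 <- (n - 1) * (b - 1)
  if (ss_err < 1e-300 && ss_cond < 1e-300) {
    return(stat_result("band", 0, c(df1, df2), 1, "repeated-measures ANOVA"))
  }
  f <- (ss_cond / df1) / (ss_err / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  stat_result("band", f, c(df1, df2), p, "repeated-measures ANOVA")
}

#' Mixed group-by-frequency ANOVA with covariates
#'
#' Split-plot ANOVA for a two-group, two-band design: group is the
#' between-subject factor (tested against the subject stratum, after the
#' covariates), band and the group-by-band interaction are within-subject
#' (tested against the subject-by-band residual). Covariates (age, sex,
#' mean framewise displacement) are subject-level nuisance terms entered
#' before group. With two within levels sphericity is not an issue.
#'
#' @param values Subjects-by-bands numeric matrix (two columns).
#' @param group Factor-like vector, one entry per subject, two levels.
#' @param covariates Optional data frame of per-subject covariates
#'   (numeric or factor columns, e.g. `age`, `sex`, `mean_fd`).
#' @return Tibble with one row per effect (`group`, `band`, `group:band`):
#'   F statistic, degrees of freedom, p.
#' @export
mixed_anova <- function(values, group, covariates = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); b <- ncol(values)
  stopifnot(length(group) == n, b >= 2)
  group <- factor(group)
  if (nlevels(group) != 2) stop("need exactly two groups", call. = FALSE)
  long <- data.frame(
    value = as.vector(values),
    subject = factor(rep(seq_len(n), times = b)),
    band = factor(rep(seq_len(b), each = n)),
    group = rep(group, times = b)
  )
  rhs <- "group * band"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) long[[nm]] <- rep(covariates[[nm]], times = b)
    rhs <- paste(paste(names(covariates), collapse = " + "), "+", rhs)
  }
  form <- stats::as.formula(paste("value ~", rhs, "+ Error(subject)"))
  fit <- stats::aov(form, data = long)
  if (any(vapply(stats::coef(fit), anyNA, logical(1)))) {
    stop("singular design (collinear covariates or confounded group)",
         call. = FALSE)
  }
  smry <- summary(fit)
  rows <- purrr::map_dfr(smry, function(stratum) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    keep <- terms %in% c("group", "band", "group:band")
    if (!any(keep)) return(tibble::tibble())
    tibble::tibble(
      effect = terms[keep],
      statistic = tab[keep, "F value"],
      df1 = tab[keep, "Df"],
      df2 = tab[nrow(tab), "Df"],
      p = tab[keep, "Pr(>F)"]
    )
  })
  rows$p_adjusted <- NA_real_
  rows$correction <- "none"
  rows$method <- "mixed group-by-frequency ANOVA"
  rows[match(c("group", "band", "group:band"), rows$effect), ]
}

#' Paired t-test
#'
#' Two-tailed paired t-test on subject-wise differences, used for
#' within-subject band comparisons (e.g. slow-5 vs slow-4 per ROI or per
#' dynamics metric). Identical pairs return t = 0, p = 1.
#'
#' @param x,y Numeric vectors of equal length, paired by subject.
#' @return One-row stat tibble.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) < 1e-300) {
    t_val <- if (abs(mean(d)) < 1e-300) 0 else Inf * sign(mean(d))
    p <- if (t_val == 0) 1 else 0
    return(stat_result("paired difference", t_val, length(x) - 1, p,
                       "paired t-test"))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired difference", ht$statistic, ht$parameter, ht$p.value,
              "paired t-test")
}

#' Two-sample t-test with optional covariate adjustment
#'
#' Without covariates: Welch's two-sample t-test. With covariates: the
#' group difference is the t-test on the group coefficient in
#' `outcome ~ group + covariates` — the standard way to test a group effect
#' "with age, gender and mean FD controlled". When the covariates are
#' orthogonal to group and outcome the two routes agree.
#'
#' @param x,y Numeric outcome vectors for the two groups.
#' @param covariates Optional data frame with one row per subject, rows of
#'   `x` first then `y`.
#' @return One-row stat tibble.
#' @export
two_sample_t_adjusted <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    if (stats::sd(c(x, y)) < 1e-300) {
      return(stat_result("group", 0, length(x) + length(y) - 2, 1,
                         "two-sample t-test (Welch)"))
    }
    ht <- stats::t.test(x, y)
    return(stat_result("group", ht$statistic, ht$parameter, ht$p.value,
                       "two-sample t-test (Welch)"))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(x) + length(y))
  dat <- cbind(
    data.frame(outcome = c(x, y),
               group = factor(rep(c("a", "b"), c(length(x), length(y))))),
    covariates
  )
  fit <- stats::lm(outcome ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    stop("collinear covariates: design is singular", call. = FALSE)
  }
  tab <- summary(fit)$coefficients
  row <- grep("^groupb$", rownames(tab))
  stat_result("group", -tab[row, "t value"], fit$df.residual,
              tab[row, "Pr(>|t|)"], "covariate-adjusted two-sample t-test")
}

#' Two-sample t-test from printed summary statistics
#'
#' Welch's t-test reconstructed from group means, standard deviations and
#' sizes — the form needed to check a published demographics table when the
#' underlying per-subject values are not available.
#'
#' @param mean1,sd1,n1 First group's mean, SD (n-1 convention), size.
#' @param mean2,sd2,n2 Second group's summary statistics.
#' @return One-row stat tibble.
#' @export
two_sample_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t_val <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_val), df, lower.tail = FALSE)
  stat_result("group", t_val, df, p, "two-sample t-test (Welch, summary)")
}

#' Permutation test for a group difference in means
#'
#' Two-sided permutation test on the absolute difference of group means,
#' for outcomes whose distribution is visibly non-Gaussian (e.g. mean
#' framewise displacement). Uses the add-one estimator
#' `p = (1 + #{|perm diff| >= |observed|}) / (1 + n_perm)` so p is never
#' exactly zero; seeded and reproducible.
#'
#' @param x,y Numeric outcome vectors for the two groups.
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Seed.
#' @return One-row stat tibble (statistic is the observed mean difference).
#' @export
permutation_test <- function(x, y, n_perm = 5000, seed = 1) {
  stopifnot(n_perm >= 1)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  # seed a private stream and restore the caller's RNG state afterwards,
  # so calling this inside a simulation loop cannot couple the loop's
  # data stream to the permutation stream
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  total <- sum(pooled); n <- nx + ny
  count <- 0L
  for (i in seq_len(n_perm)) {
    sx <- sum(pooled[sample.int(n, nx)])
    d <- abs(sx / nx - (total - sx) / ny)
    if (d >= obs - 1e-12) count <- count + 1L
  }
  p <- (1 + count) / (1 + n_perm)
  stat_result("group", mean(x) - mean(y), NA_real_, p,
              sprintf("permutation test (%d permutations)", n_perm))
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Group difference in a categorical variable (e.g. sex by diagnosis).
#' Pearson statistic without continuity correction, df = 1, so identical
#' margins give statistic 0 and p = 1 exactly.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return One-row stat tibble.
#' @export
chi_square_table <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result("association", ht$statistic, ht$parameter, ht$p.value,
              "Pearson chi-square (no continuity correction)")
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for a family of `m` comparisons (e.g. `m = 408` for
#' ROI-wise paired tests).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= length(p))
  pmin(1, p * m)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values.
#' @export
fdr_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Apply a multiple-comparison correction to a stat table
#'
#' Fills `p_adjusted` and `correction` across the rows of a tibble of test
#' results, treating all its rows as one family (e.g. the six states of one
#' metric).
#'
#' @param results Tibble with a `p` column (rows = one family).
#' @param method `"fdr_bh"` or `"bonferroni"`.
#' @param m Family size for Bonferroni; defaults to `nrow(results)`.
#' @return The tibble with `p_adjusted` and `correction` filled in.
#' @export
adjust_family <- function(results, method = c("fdr_bh", "bonferroni"),
                          m = nrow(results)) {
  method <- match.arg(method)
  results$p_adjusted <- switch(method,
    fdr_bh = fdr_bh(results$p),
    bonferroni = bonferroni(results$p, m)
  )
  results$correction <- method
  results
}
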