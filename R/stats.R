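#' Per-gene expression summaries
#'
#' Log-normalizes FPKM as `log2(FPKM + 1)` and reports, per gene, the maximum
#' and median of the logged values across tissues plus the expression breadth
#' (fraction of tissues with FPKM > 0).
#'
#' @param fpkm numeric matrix genes x tissues (no negative values), with gene
#'   ids as row names.
#' @param log_base 2 (default) or `exp(1)` for natural-log normalization.
#' @return data.frame: `gene_id`, `max_expr`, `med_expr`, `breadth`.
#' @export
expression_summaries <- function(fpkm, log_base = 2) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  lg <- log(fpkm + 1, base = log_base)
  data.frame(gene_id = rownames(fpkm),
             max_expr = apply(lg, 1L, max),
             med_expr = apply(lg, 1L, stats::median),
             breadth = rowMeans(fpkm > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman rank correlation
#'
#' Midranks for ties; p-value by the t approximation.
#'
#' @param x,y numeric vectors.
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Partial correlation controlling for covariates
#'
#' Rank-transforms all variables (Spearman flavour, the default) and
#' computes the partial correlation of `x` and `y` given the controls from
#' the inverse of their joint correlation matrix. With a single control `z`
#' this equals the recursive closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`; with no controls
#' it is the plain correlation. Rows with missing values are dropped
#' listwise. The p-value uses the t approximation with `n - 2 - k` degrees
#' of freedom (`k` controls).
#'
#' @param table data.frame of variables.
#' @param x,y column names of the two variables of interest.
#' @param controls character vector of control column names (may be empty).
#' @param method `"spearman"` (rank-transform first) or `"pearson"`.
#' @return list: `rho`, `p_value`, `n`, `df`.
#' @export
partial_correlation <- function(table, x, y, controls = character(0),
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  vars <- c(x, y, controls)
  m <- as.matrix(table[, vars, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- length(controls)
  if (n < k + 3L) stop("need at least ", k + 3L, " complete rows")
  if (method == "spearman") m <- apply(m, 2L, rank)
  cm <- stats::cor(m)
  prec <- tryCatch(solve(cm), error = function(e) {
    sv <- svd(cm)$d
    stop("singular correlation matrix among: ",
         paste(vars, collapse = ", "),
         " (smallest singular value ", format(min(sv), digits = 3), ")")
  })
  rho <- -prec[1L, 2L] / sqrt(prec[1L, 1L] * prec[2L, 2L])
  rho <- max(min(rho, 1), -1)
  df <- n - 2L - k
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(rho = rho, p_value = p, n = n, df = df)
}

#' Normal and partial correlations of predictors with evolutionary rate
#'
#' For each predictor, its plain Spearman correlation with the response and
#' its full partial correlation (controlling for all other predictors), with
#' a Bonferroni significance flag at the 5% level for a configurable family
#' size (default 14: seven predictors in each of two gene classes).
#'
#' @param table data.frame holding the response and predictors.
#' @param response response column name (default `"evolutionary_rate"`).
#' @param predictors predictor column names (default: all other numeric
#'   columns).
#' @param family Bonferroni family size (default 14).
#' @param method passed to [partial_correlation()].
#' @return data.frame: `predictor`, `rho`, `p`, `partial_rho`, `partial_p`,
#'   `significant`, `partial_significant`.
#' @export
correlation_report <- function(table, response = "evolutionary_rate",
                               predictors = NULL, family = 14L,
                               method = "spearman") {
  if (is.null(predictors)) {
    num <- names(table)[vapply(table, is.numeric, logical(1))]
    predictors <- setdiff(num, response)
  }
  alpha <- 0.05 / family
  rows <- lapply(predictors, function(p) {
    nc <- spearman(table[[response]], table[[p]])
    pc <- partial_correlation(table, response, p,
                              controls = setdiff(predictors, p),
                              method = method)
    data.frame(predictor = p, rho = nc$rho, p = nc$p_value,
               partial_rho = pc$rho, partial_p = pc$p_value,
               significant = nc$p_value < alpha,
               partial_significant = pc$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# kernel weight functions on |u| <= 1 (internal)
loess_kernel <- function(name) {
  switch(name,
         tricube = function(u) (1 - pmin(abs(u), 1)^3)^3,
         epanechnikov = function(u) pmax(1 - u^2, 0),
         gaussian = function(u) exp(-u^2 / 2),
         uniform = function(u) as.numeric(abs(u) <= 1),
         stop("unknown kernel '", name, "'"))
}

#' Local polynomial regression (loess-style)
#'
#' At every x, fits a weighted polynomial of the given degree over the
#' `span` fraction of nearest neighbours, with kernel weights on the scaled
#' distance (tricube by default; Epanechnikov, Gaussian and uniform
#' alternatives). With `span = 1`, `degree = 1` and the uniform kernel this
#' reduces exactly to the ordinary least-squares line.
#'
#' @param x,y numeric vectors.
#' @param span neighbourhood fraction in (0, 1].
#' @param degree local polynomial degree (0, 1 or 2).
#' @param kernel kernel name.
#' @return list: `x`, `fitted`, `residuals`, `span`, `degree`, `kernel`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1L,
                      kernel = c("tricube", "epanechnikov", "gaussian",
                                 "uniform")) {
  kernel <- match.arg(kernel)
  stopifnot(span > 0, span <= 1, degree %in% 0:2)
  n <- length(x)
  q <- max(ceiling(span * n), degree + 2L)
  if (q > n) stop("span too small: neighbourhood needs ", q,
                  " points but only ", n, " available")
  kf <- loess_kernel(kernel)
  fitted <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    w <- if (h > 0) kf(d / h) else as.numeric(d <= 0)
    use <- w > 0
    if (sum(use) < degree + 1L) { use <- rank(d, ties.method = "first") <= q
                                  w[use] <- pmax(w[use], 1e-8) }
    xd <- x[use] - x[i]
    X <- stats::poly(xd, degree = max(degree, 1L), raw = TRUE,
                     simple = TRUE)[, seq_len(degree), drop = FALSE]
    X <- cbind(1, X)
    fit <- stats::lm.wfit(X, y[use], w[use])
    fit$coefficients[1L]
  }, numeric(1))
  list(x = x, fitted = fitted, residuals = y - fitted, span = span,
       degree = degree, kernel = kernel)
}

#' Compare group residuals around a common local-regression trend
#'
#' Fits a loess-style trend to the pooled data for each span and compares
#' the residuals between two groups with a Mann-Whitney test, reporting the
#' per-group residual medians.
#'
#' @param x,y numeric vectors.
#' @param groups factor/character vector with exactly two levels.
#' @param spans numeric vector of spans (default `c(0.3, 0.5, 0.75, 1.0)`).
#' @param kernel kernel passed to [loess_fit()].
#' @param degree degree passed to [loess_fit()].
#' @return data.frame: `span`, `median_g1`, `median_g2`, `median_diff`
#'   (g1 - g2), `p_value`, with attribute `groups` naming g1/g2.
#' @export
residual_group_comparison <- function(x, y, groups,
                                      spans = c(0.3, 0.5, 0.75, 1.0),
                                      kernel = "tricube", degree = 1L) {
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) stop("exactly two groups required")
  rows <- lapply(spans, function(s) {
    fit <- loess_fit(x, y, span = s, degree = degree, kernel = kernel)
    r1 <- fit$residuals[groups == lv[1L]]
    r2 <- fit$residuals[groups == lv[2L]]
    wt <- suppressWarnings(stats::wilcox.test(r1, r2))
    data.frame(span = s, median_g1 = stats::median(r1),
               median_g2 = stats::median(r2),
               median_diff = stats::median(r1) - stats::median(r2),
               p_value = wt$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}

#' Fraction of subsamples reaching a correlation threshold
#'
#' Repeatedly subsamples `k` of the `n` observations without replacement,
#' computes the Spearman correlation in each subsample, and reports the
#' fraction of subsamples with `rho <= threshold_rho` (how often a
#' small-sample analysis would recover a correlation at least as negative).
#'
#' @param x,y numeric vectors.
#' @param k subsample size (`k <= length(x)`).
#' @param n_reps number of subsamples.
#' @param threshold_rho threshold.
#' @param seed integer seed.
#' @return list: `fraction`, `rhos` (per-subsample values).
#' @export
subsample_correlation_fraction <- function(x, y, k, n_reps = 1000L,
                                           threshold_rho, seed = 1L) {
  n <- length(x)
  stopifnot(k <= n, length(y) == n)
  set.seed(seed)
  rhos <- vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n, k)
    stats::cor(x[idx], y[idx], method = "spearman")
  }, numeric(1))
  list(fraction = mean(rhos <= threshold_rho), rhos = rhos)
}

#' Retain the top fraction of rows by a key column
#'
#' Rows are ordered by the key (stable for ties) and the top
#' `ceiling(fraction * n)` retained.
#'
#' @param table data.frame.
#' @param by key column name.
#' @param fraction fraction in (0, 1].
#' @return the filtered data.frame.
#' @export
top_fraction_filter <- function(table, by = "max_expr", fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  ord <- order(table[[by]], decreasing = TRUE)
  table[sort(ord[seq_len(ceiling(fraction * nrow(table)))]), , drop = FALSE]
}

#' Three-way interaction test for RNA stability on expression parameters
#'
#' Fits the full-factorial linear model
#' `stability ~ max_expr * med_expr * breadth` and reports the F-test of the
#' three-way interaction term from the ANOVA table.
#'
#' @param stability,max_expr,med_expr,breadth numeric vectors.
#' @return list: `F`, `p_value`, `anova` (the full table).
#' @export
ols_interaction_anova <- function(stability, max_expr, med_expr, breadth) {
  df <- data.frame(stability, max_expr, med_expr, breadth)
  fit <- stats::lm(stability ~ max_expr * med_expr * breadth, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("collinear expression parameters: interaction not estimable")
  an <- stats::anova(fit)
  term <- "max_expr:med_expr:breadth"
  list(F = an[term, "F value"], p_value = an[term, "Pr(>F)"], anova = an)
}
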