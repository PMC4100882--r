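## Statistical layer: through-origin regression with AIC model selection,
## ANCOVA on slopes, one-way ANOVA with Tukey HSD, and Pearson
## correlations.
##
## Conventions (declared, since through-origin R^2 and least-squares AIC
## both have competing definitions): R^2 is computed against the grand-mean
## baseline and can be negative; AIC = n * log(RSS / n) + 2k with the error
## variance counted among the k = degree + 1 parameters. Only AIC
## differences between the two candidate fits are meaningful.

#' Least-squares fit through the origin
#'
#' Fits y over the basis {x} (degree 1) or {x, x^2} (degree 2) with no
#' intercept: the curves are constrained to pass through the origin (zero
#' deposited energy cannot create cavity volume), which removes one degree
#' of freedom. Coefficients solve the normal equations directly.
#'
#' @param x,y numeric vectors of equal length, n >= degree + 1.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return A [RegressionResult-class].
#' @examples
#' f <- fitThroughOrigin(1:8, 2 * (1:8), degree = 1)
#' f@coefficients # 2
#' @export
fitThroughOrigin <- function(x, y, degree = 1) {
  degree <- as.integer(degree)
  if (!degree %in% c(1L, 2L)) stop("degree must be 1 or 2")
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < degree + 1L) stop("need at least degree + 1 observations")
  if (all(x == 0)) stop("x must not be all zero")
  X <- if (degree == 1L) cbind(x = x) else cbind(x = x, x2 = x^2)
  xtx <- crossprod(X)
  if (abs(det(xtx)) < 1e-12 * prod(diag(xtx) + .Machine$double.eps))
    stop("singular design")
  beta <- drop(solve(xtx, crossprod(X, y)))
  if (degree == 1L) beta <- c(x = unname(beta))
  rss <- sum((y - drop(X %*% beta))^2)
  tss <- sum((y - mean(y))^2)
  k <- degree + 1L # coefficients + error variance
  aic <- if (rss <= 0) -Inf else n * log(rss / n) + 2 * k
  new("RegressionResult",
      model = if (degree == 1L) "linear_origin" else "quadratic_origin",
      coefficients = beta, rss = rss,
      rSquared = if (tss > 0) 1 - rss / tss else NA_real_,
      aic = aic, n = as.integer(n))
}

#' Select between linear and quadratic through-origin fits by AIC
#'
#' The model with the lower AIC is preferred; at equal AIC (e.g. identical
#' RSS) the linear model wins through its smaller parameter penalty.
#'
#' @param fitLinear,fitQuadratic [RegressionResult-class] objects fitted on
#'   the same data.
#' @return list with `preferred` (`"linear_origin"` or
#'   `"quadratic_origin"`), `delta_aic` (AIC quadratic - AIC linear) and
#'   `aic` (both values).
#' @export
aicSelect <- function(fitLinear, fitQuadratic) {
  stopifnot(is(fitLinear, "RegressionResult"),
            is(fitQuadratic, "RegressionResult"))
  if (fitLinear@model != "linear_origin" ||
      fitQuadratic@model != "quadratic_origin")
    stop("pass the linear fit first and the quadratic fit second")
  if (fitLinear@n != fitQuadratic@n)
    stop("fits were not computed on the same data (different n)")
  delta <- fitQuadratic@aic - fitLinear@aic
  if (is.nan(delta)) delta <- 0 # both -Inf: perfect fits, prefer linear
  list(preferred = if (delta >= 0) "linear_origin" else "quadratic_origin",
       delta_aic = delta,
       aic = c(linear = fitLinear@aic, quadratic = fitQuadratic@aic))
}

.asGroupedXY <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(group = nm[i], x = as.numeric(g$x), y = as.numeric(g$y))
  }))
}

#' Compare regression slopes across groups (ANCOVA)
#'
#' F-test of the group-by-slope interaction in the pooled linear model
#' `y ~ group + x + group:x`: under the null all groups share one slope.
#'
#' @param groups named list, each element a list or data.frame with `x` and
#'   `y` (each group n >= 3, non-constant x).
#' @return list with `F`, `p`, `df` (numerator, denominator).
#' @export
ancovaSlopes <- function(groups) {
  df <- .asGroupedXY(groups)
  ns <- table(df$group)
  if (any(ns < 3L)) stop("each group needs at least 3 observations")
  sds <- tapply(df$x, df$group, sd)
  if (any(sds == 0)) stop("a group has constant x; slope undefined")
  df$group <- factor(df$group)
  fit0 <- lm(y ~ group + x, data = df)
  fit1 <- lm(y ~ group + x + group:x, data = df)
  a <- anova(fit0, fit1)
  list(F = a$F[2], p = a$`Pr(>F)`[2],
       df = c(a$Df[2], a$Res.Df[2]))
}

#' One-way ANOVA with Tukey's multiple comparison test
#'
#' Compares a quantity (e.g. deflection angle or depth of maximal damage)
#' between bullet types: one-way ANOVA F-test plus Tukey HSD adjusted
#' p-values for every pair via the studentized-range distribution.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p` and `pairwise` (data.frame: `comparison`,
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anovaTukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 observations")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(nm, vapply(groups, length, 1L)), levels = nm))
  fit <- aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  Fv <- s$`F value`[1]
  pv <- s$`Pr(>F)`[1]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 } # zero residual + zero group variance
  list(F = Fv, p = pv, pairwise = pairwise)
}

#' Reproducibility correlation between repeated shots
#'
#' Pearson correlation of a quantity (typically CT cavity volume) between
#' all first and second shots of the repeated design; optionally also per
#' bullet type.
#'
#' @param firstShots,secondShots paired numeric vectors (length >= 3, non
#'   zero variance).
#' @param group optional factor/character of the same length for per-group
#'   correlations (groups with n < 3 or zero variance give NA).
#' @return list with `r`, `p` (from [stats::cor.test()]) and optionally
#'   `by_group`.
#' @export
reproducibilityCorrelation <- function(firstShots, secondShots,
                                       group = NULL) {
  if (length(firstShots) != length(secondShots))
    stop("paired lists must have equal length")
  if (length(firstShots) < 3L) stop("need at least 3 pairs")
  if (sd(firstShots) == 0 || sd(secondShots) == 0)
    stop("zero variance in one of the lists")
  ct <- cor.test(firstShots, secondShots)
  out <- list(r = unname(ct$estimate), p = ct$p.value)
  if (!is.null(group)) {
    out$by_group <- vapply(split(seq_along(group), group), function(i) {
      if (length(i) < 3L) return(NA_real_)
      a <- firstShots[i]; b <- secondShots[i]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
  }
  out
}
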