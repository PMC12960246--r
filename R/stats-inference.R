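## Self-contained statistical inference used throughout the package:
## contingency tests (asymptotic and exact-by-enumeration), rank tests,
## correlation, logistic regression by IRLS, BH-FDR, and survival analysis
## (product-limit estimator, log-rank, Cox proportional hazards with Efron
## ties). Exact p values are computed from integer enumeration so they are
## reproducible to machine precision.

acroTest <- function(statistic, p.value, method, df = NULL, estimate = NULL,
                     alternative = "two.sided", ...) {
  out <- c(list(statistic = statistic, df = df, p.value = p.value,
                estimate = estimate, method = method,
                alternative = alternative), list(...))
  class(out) <- "acroTest"
  out
}

#' @export
print.acroTest <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  if (!is.null(x$statistic))
    cat("statistic = ", format(x$statistic, digits = 6),
        if (!is.null(x$df)) paste0(", df = ", x$df) else "", "\n", sep = "")
  if (!is.null(x$estimate))
    cat("estimate  = ", format(x$estimate, digits = 6), "\n", sep = "")
  cat("p-value   = ", format.pval(x$p.value, digits = 4), " (",
      x$alternative, ")\n", sep = "")
  invisible(x)
}

checkTable <- function(tab) {
  if (!is.matrix(tab) || !is.numeric(tab))
    stop("'tab' must be a numeric matrix", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must contain non-negative integer counts", call. = FALSE)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("'tab' must be at least 2 x 2", call. = FALSE)
  if (sum(tab) == 0) stop("'tab' has zero total", call. = FALSE)
  tab
}

#' Pearson chi-squared test of independence
#'
#' Classical chi-squared test on an r x c contingency table, without
#' continuity correction. Expected counts are formed from the observed
#' margins; the p value is the upper tail of the chi-squared distribution
#' with (r-1)(c-1) degrees of freedom.
#'
#' @param tab Non-negative integer matrix (at least 2 x 2).
#' @return An object of class `acroTest` with `statistic`, `df`, `p.value`
#'   and the expected-count matrix in `$expected`.
#' @examples
#' pearsonChi2(matrix(c(28, 16, 14, 27), 2))
#' @export
pearsonChi2 <- function(tab) {
  tab <- checkTable(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin", call. = FALSE)
  E <- outer(rs, cs) / n
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  acroTest(statistic = stat, df = df,
           p.value = stats::pchisq(stat, df, lower.tail = FALSE),
           method = "Pearson chi-squared test (no continuity correction)",
           expected = E)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact conditional test with both margins fixed. The two-sided p value
#' follows the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table. The reported effect is the conditional
#' maximum-likelihood odds ratio of the non-central hypergeometric model.
#'
#' @param tab 2 x 2 non-negative integer matrix.
#' @param alternative One of `"two.sided"`, `"less"`, `"greater"` (referring
#'   to the odds ratio of the first row).
#' @return An `acroTest` with `estimate` the conditional odds ratio.
#' @export
fisherExact2x2 <- function(tab, alternative = c("two.sided", "less",
                                                "greater")) {
  alternative <- match.arg(alternative)
  tab <- checkTable(tab)
  if (!all(dim(tab) == 2L)) stop("'tab' must be 2 x 2", call. = FALSE)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  x <- tab[1, 1]
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  dd <- stats::dhyper(support, c1, n - c1, r1)
  pobs <- dd[support == x]
  relErr <- 1 + 1e-7
  p <- switch(alternative,
    two.sided = sum(dd[dd <= pobs * relErr]),
    less      = sum(dd[support <= x]),
    greater   = sum(dd[support >= x]))
  p <- min(1, p)
  ## conditional MLE of the odds ratio: solve E_psi[X] = x
  orHat <- if (x == hi && x == lo) NA_real_ else if (x == hi) Inf
    else if (x == lo) 0 else {
      condMean <- function(logpsi) {
        w <- log(dd) + support * logpsi
        w <- exp(w - max(w))
        sum(support * w) / sum(w) - x
      }
      exp(stats::uniroot(condMean, c(-30, 30), tol = 1e-10)$root)
    }
  acroTest(statistic = x, p.value = p, estimate = orHat,
           method = "Fisher's exact test (conditional MLE odds ratio)",
           alternative = alternative, exact = TRUE)
}

#' Freeman-Halton exact test for an r x c table
#'
#' Generalization of Fisher's exact test to arbitrary r x c tables by
#' exhaustive enumeration of the margin-constrained lattice. The p value is
#' the total multivariate-hypergeometric probability of all tables (with the
#' observed margins) whose probability does not exceed that of the observed
#' table.
#'
#' @param tab Non-negative integer matrix.
#' @param maxTotal Enumeration guard on the table total (default 200);
#'   larger tables raise an error suggesting a Monte-Carlo variant.
#' @return An `acroTest`; `$tablesVisited` reports the lattice size.
#' @export
fisherExactRxC <- function(tab, maxTotal = 200) {
  tab <- checkTable(tab)
  n <- sum(tab)
  if (n > maxTotal)
    stop("table total ", n, " exceeds the enumeration guard (", maxTotal,
         "); use a Monte-Carlo variant for large tables", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  r <- nrow(tab); cc <- ncol(tab)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logpObs <- const - sum(lgamma(tab + 1))
  cutoff <- logpObs + log(1 + 1e-7)
  acc <- new.env(parent = emptyenv())
  acc$p <- 0; acc$count <- 0L
  ## enumerate rows 1..r-1; last row is fixed by the column margins
  enumRow <- function(i, colRem, lgAcc) {
    if (i == r) {
      lp <- const - lgAcc - sum(lgamma(colRem + 1))
      acc$count <- acc$count + 1L
      if (lp <= cutoff) acc$p <- acc$p + exp(lp)
      return(invisible())
    }
    cells <- integer(cc)
    enumCell <- function(j, rem) {
      if (j == cc) {
        if (rem <= colRem[cc]) {
          cells[cc] <<- rem
          enumRow(i + 1L, colRem - cells, lgAcc + sum(lgamma(cells + 1)))
        }
        return(invisible())
      }
      for (v in 0:min(rem, colRem[j])) {
        cells[j] <<- v
        enumCell(j + 1L, rem - v)
      }
    }
    enumCell(1L, rs[i])
  }
  enumRow(1L, cs, 0)
  acroTest(statistic = NA_real_, p.value = min(1, acc$p),
           method = "Freeman-Halton exact test (exhaustive enumeration)",
           exact = TRUE, tablesVisited = acc$count)
}

## number of arrangements with Mann-Whitney statistic u for sample sizes
## (m, n): the classical cwilcox recurrence, memoized.
uCountTable <- function(m, n) {
  memo <- new.env(parent = emptyenv())
  cw <- function(k, mm, nn) {
    if (k < 0 || k > mm * nn) return(0)
    if (mm == 0 || nn == 0) return(as.numeric(k == 0))
    key <- paste(k, mm, nn)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- cw(k - nn, mm - 1, nn) + cw(k, mm, nn - 1)
    memo[[key]] <- v
    v
  }
  vapply(0:(m * n), cw, numeric(1), mm = m, nn = n)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' U statistic with midranks for ties. The p value is exact (by enumeration
#' of the U distribution) when both samples have at most `exactLimit`
#' observations and there are no ties; otherwise a normal approximation with
#' tie correction and continuity correction is used. `alternative =
#' "greater"` means the first sample tends to be larger.
#'
#' @param x,y Numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param exactLimit Largest per-group size for exact enumeration.
#' @return An `acroTest` with `statistic` = U (for `x`), group medians in
#'   `$medians` and `$exact` indicating the method used.
#' @export
mannWhitney <- function(x, y, alternative = c("two.sided", "less",
                                              "greater"), exactLimit = 12) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)
  exact <- !hasTies && n1 <= exactLimit && n2 <= exactLimit
  if (exact) {
    cnt <- uCountTable(n1, n2)
    tot <- sum(cnt)
    pLow <- sum(cnt[seq_len(U + 1)]) / tot          # P(U <= u)
    pHigh <- sum(cnt[(U + 1):length(cnt)]) / tot    # P(U >= u)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pLow, pHigh)),
                less = pLow, greater = pHigh)
  } else {
    mu <- n1 * n2 / 2
    tieAdj <- sum(ties^3 - ties)
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tieAdj / (N * (N - 1))))
    if (sigma == 0) {  # fully tied data carry no ordering information
      return(acroTest(statistic = U, p.value = 1,
                      method = "Wilcoxon-Mann-Whitney rank-sum test",
                      alternative = alternative, exact = FALSE,
                      medians = c(x = stats::median(x),
                                  y = stats::median(y))))
    }
    cc <- 0.5  # continuity correction
    z <- switch(alternative,
                two.sided = (U - mu - sign(U - mu) * cc) / sigma,
                greater = (U - mu - cc) / sigma,
                less = (U - mu + cc) / sigma)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
  }
  acroTest(statistic = U, p.value = p,
           method = "Wilcoxon-Mann-Whitney rank-sum test",
           alternative = alternative, exact = exact,
           medians = c(x = stats::median(x), y = stats::median(y)))
}

#' Pearson product-moment correlation with t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3), non-constant.
#' @return An `acroTest` with `estimate` = r.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input vector", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    tstat <- Inf * sign(r); p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  acroTest(statistic = tstat, df = n - 2, p.value = p, estimate = r,
           method = "Pearson product-moment correlation")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; the output is
#' in the input order.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted q values.
#' @export
bhFdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary-outcome logistic model. Convergence is
#' declared when the largest absolute score component falls below `tol`
#' (default 1e-8) within `maxIter` iterations. Wald standard errors come
#' from the observed information; odds ratios carry Wald 95\% confidence
#' intervals. Complete or quasi-complete separation is detected (fitted
#' probabilities collapsing to 0/1 with diverging coefficients) and flagged
#' rather than silently returned.
#'
#' @param x Numeric matrix of covariates (no intercept column; one is
#'   added), or a data.frame of numeric columns.
#' @param y Binary (0/1) outcome vector.
#' @param tol,maxIter Convergence controls.
#' @return An object of class `acroGlm`: a list with `coefficients`, `se`,
#'   `or`, `ciLower`, `ciUpper`, `z`, `p.value`, `vcov`, `logLik`,
#'   `converged`, `separation`.
#' @export
logisticFit <- function(x, y, tol = 1e-8, maxIter = 50) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (ncol(x) > 0 && any(apply(x, 2, stats::sd) == 0))
    stop("constant covariate column (other than the intercept)",
         call. = FALSE)
  X <- cbind("(Intercept)" = 1, x)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more parameters than observations", call. = FALSE)
  beta <- numeric(p)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    info <- crossprod(X, X * W)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
  }
  eta <- drop(X %*% beta); mu <- stats::plogis(eta)
  separation <- max(abs(beta)) > 15 && any(mu < 1e-8 | mu > 1 - 1e-8)
  info <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X))))
  se <- sqrt(diag(vc))
  z <- beta / se
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  zq <- stats::qnorm(0.975)
  out <- list(coefficients = stats::setNames(beta, colnames(X)), se = se,
              or = exp(beta), ciLower = exp(beta - zq * se),
              ciUpper = exp(beta + zq * se), z = z,
              p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
              vcov = vc, logLik = ll, converged = converged,
              separation = separation, n = n)
  class(out) <- "acroGlm"
  out
}

#' @export
print.acroGlm <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n,
      if (!x$converged) "[NOT CONVERGED]" else "",
      if (x$separation) "[SEPARATION]" else "", "\n")
  print(data.frame(beta = x$coefficients, se = x$se, OR = x$or,
                   lo95 = x$ciLower, hi95 = x$ciUpper, p = x$p.value))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival curve with Greenwood variance and log-log 95\% confidence bands.
#'
#' @param time Non-negative follow-up times.
#' @param event Binary event indicators (1 = event, 0 = censored).
#' @return An object of class `acroKM`: a list with `time` (unique event
#'   times), `nRisk`, `nEvent`, `surv`, `se`, `lower`, `upper`.
#' @export
kmEstimate <- function(time, event) {
  if (any(time < 0)) stop("negative time", call. = FALSE)
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  ut <- sort(unique(time[event == 1]))
  nRisk <- nEvent <- numeric(length(ut))
  surv <- se <- lower <- upper <- numeric(length(ut))
  s <- 1; gw <- 0
  zq <- stats::qnorm(0.975)
  for (i in seq_along(ut)) {
    t0 <- ut[i]
    nRisk[i] <- sum(time >= t0)
    nEvent[i] <- sum(time == t0 & event == 1)
    s <- s * (1 - nEvent[i] / nRisk[i])
    surv[i] <- s
    if (nRisk[i] > nEvent[i])
      gw <- gw + nEvent[i] / (nRisk[i] * (nRisk[i] - nEvent[i]))
    else gw <- Inf
    se[i] <- s * sqrt(gw)
    if (s > 0 && s < 1 && is.finite(gw)) {
      seLL <- sqrt(gw) / abs(log(s))
      lower[i] <- s^exp(zq * seLL)
      upper[i] <- s^exp(-zq * seLL)
    } else {
      # log-log bands undefined at S = 0 (or exhausted risk sets)
      lower[i] <- upper[i] <- NA_real_
    }
  }
  out <- list(time = ut, nRisk = nRisk, nEvent = nEvent, surv = surv,
              se = se, lower = lower, upper = upper)
  class(out) <- "acroKM"
  out
}

#' @export
print.acroKM <- function(x, ...) {
  print(data.frame(time = x$time, n.risk = x$nRisk, n.event = x$nEvent,
                   surv = x$surv, lower95 = x$lower, upper95 = x$upper))
  invisible(x)
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times; chi-squared with (g - 1) degrees of freedom.
#' Groups fully censored before the first event simply contribute no events.
#'
#' @param time,event As in [kmEstimate()].
#' @param group Group labels (>= 2 groups).
#' @return An `acroTest` with per-group observed and expected counts.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  g <- nlevels(group)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  stopifnot(length(time) == length(event), length(time) == length(group))
  ut <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(g), levels(group))
  V <- matrix(0, g, g)
  for (t0 in ut) {
    atRisk <- time >= t0
    n <- sum(atRisk)
    d <- sum(time == t0 & event == 1)
    ng <- vapply(levels(group), function(l) sum(atRisk & group == l),
                 numeric(1))
    dg <- vapply(levels(group), function(l)
      sum(time == t0 & event == 1 & group == l), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      ## V_gh = d(n-d)/(n^2(n-1)) * (delta_gh * ng * n - ng * nh)
      f <- d * (n - d) / (n^2 * (n - 1))
      V <- V + f * (diag(ng * n, nrow = g) - outer(ng, ng))
    }
  }
  idx <- seq_len(g - 1)
  d <- (O - E)[idx]
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(d) %*% solve(Vsub, d)), error = function(e) 0)
  acroTest(statistic = stat, df = g - 1,
           p.value = stats::pchisq(stat, g - 1, lower.tail = FALSE),
           method = "Log-rank test", observed = O, expected = E)
}

#' Cox proportional hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with Efron (the
#' default) or Breslow handling of tied event times. Supports delayed entry
#' (left truncation) through `entry`: a subject is at risk at event time t
#' when `entry < t <= time`. Monotone-likelihood situations (no events, or
#' perfect separation of the risk ordering) are flagged.
#'
#' @param time,event As in [kmEstimate()].
#' @param x Covariate matrix (or data.frame of numeric columns).
#' @param entry Optional entry times for delayed-entry risk sets (default 0).
#' @param ties `"efron"` or `"breslow"`.
#' @param tol,maxIter Convergence controls.
#' @return An object of class `acroCox` with `coefficients`, `se`, `hr`,
#'   `ciLower`, `ciUpper`, `p.value`, `logLik`, `converged`, `flagged`.
#' @export
coxphFit <- function(time, event, x, entry = NULL,
                     ties = c("efron", "breslow"), tol = 1e-8,
                     maxIter = 30) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(time) == n, length(event) == n, all(event %in% c(0, 1)))
  if (is.null(entry)) entry <- rep(0, n)
  if (any(entry >= time)) stop("entry times must precede follow-up times",
                               call. = FALSE)
  if (sum(event) == 0) {
    out <- list(coefficients = stats::setNames(rep(NA_real_, p),
                                               colnames(x)),
                flagged = TRUE, converged = FALSE, logLik = NA_real_)
    class(out) <- "acroCox"
    return(out)
  }
  ut <- sort(unique(time[event == 1]))
  objective <- function(beta, derivatives = TRUE) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
    for (t0 in ut) {
      R <- which(entry < t0 & time >= t0)
      D <- which(time == t0 & event == 1)
      d <- length(D)
      s0R <- sum(w[R]); s1R <- drop(crossprod(x[R, , drop = FALSE], w[R]))
      s2R <- crossprod(x[R, , drop = FALSE], x[R, , drop = FALSE] * w[R])
      s0D <- sum(w[D]); s1D <- drop(crossprod(x[D, , drop = FALSE], w[D]))
      s2D <- crossprod(x[D, , drop = FALSE], x[D, , drop = FALSE] * w[D])
      ll <- ll + sum(eta[D])
      for (j in seq_len(d) - 1L) {
        frac <- if (ties == "efron") j / d else 0
        s0 <- s0R - frac * s0D
        s1 <- s1R - frac * s1D
        s2 <- s2R - frac * s2D
        ll <- ll - log(s0)
        if (derivatives) {
          U <- U - s1 / s0
          I <- I + s2 / s0 - tcrossprod(s1) / s0^2
        }
      }
      if (derivatives) U <- U + colSums(x[D, , drop = FALSE])
    }
    list(ll = ll, U = U, I = I)
  }
  beta <- numeric(p)
  converged <- FALSE
  ob <- objective(beta)
  for (it in seq_len(maxIter)) {
    if (max(abs(ob$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(ob$I, ob$U), error = function(e) NULL)
    if (is.null(step)) break
    newBeta <- beta + step
    newOb <- objective(newBeta)
    halvings <- 0
    while (is.finite(ob$ll) && (!is.finite(newOb$ll) ||
                                newOb$ll < ob$ll - 1e-12) && halvings < 20) {
      step <- step / 2
      newBeta <- beta + step
      newOb <- objective(newBeta)
      halvings <- halvings + 1
    }
    beta <- newBeta; ob <- newOb
  }
  flagged <- !converged || max(abs(beta)) > 15
  vc <- tryCatch(solve(ob$I), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vc))
  zq <- stats::qnorm(0.975)
  z <- beta / se
  out <- list(coefficients = stats::setNames(beta, colnames(x)), se = se,
              hr = exp(beta), ciLower = exp(beta - zq * se),
              ciUpper = exp(beta + zq * se), z = z,
              p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
              vcov = vc, logLik = ob$ll, converged = converged,
              flagged = flagged, ties = ties, nEvent = sum(event), n = n)
  class(out) <- "acroCox"
  out
}

#' @export
print.acroCox <- function(x, ...) {
  cat("Cox proportional hazards (", x$ties, " ties), n = ", x$n,
      ", events = ", x$nEvent,
      if (isTRUE(x$flagged)) " [FLAGGED]" else "", "\n", sep = "")
  if (!is.null(x$se))
    print(data.frame(beta = x$coefficients, se = x$se, HR = x$hr,
                     lo95 = x$ciLower, hi95 = x$ciUpper, p = x$p.value))
  invisible(x)
}
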