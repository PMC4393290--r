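#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided p-value computed from first principles: with both margins
#' fixed, the probability of each admissible table is hypergeometric, and
#' the p-value is the sum of the probabilities of all tables at most as
#' probable as the observed one (a relative tolerance of 1e-7 is applied
#' when comparing probabilities, the common convention). A table with a zero
#' margin carries no information about association: p = 1, logged.
#'
#' @param a,b,c,d Non-negative integer cell counts (rows = in-class /
#'   out-of-class, columns = observed set / background), or a 2x2 matrix as
#'   \code{a}.
#' @return Two-sided p-value in [0, 1].
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    .stopf("cell counts must be non-negative integers")
  if (sum(cells) == 0) .stopf("empty contingency table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    .log("degenerate 2x2 table (zero margin): p = 1 by convention")
    return(1)
  }
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom,
#' computed from first principles (the t distribution function is the only
#' borrowed piece). Missing values are dropped with a log line. With zero
#' variance in both groups, equal means give p = 1 and unequal means p = 0.
#'
#' @param x,y Numeric samples (e.g. mRNA half-lives in minutes), each with
#'   at least two finite values.
#' @param labels Length-2 character vector of group labels.
#' @return list with \code{groups}, \code{n}, \code{mean}, \code{se}
#'   (sd/sqrt(n)), \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(x, y, labels = c("x", "y")) {
  nx0 <- length(x); ny0 <- length(y)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < nx0 || length(y) < ny0)
    .log(sprintf("dropped %d missing value(s)",
                 nx0 - length(x) + ny0 - length(y)))
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) .stopf("each group needs at least 2 finite values")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    t <- if (mx == my) 0 else sign(mx - my) * Inf
    p <- if (mx == my) 1 else 0
    df <- NA_real_
  } else {
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(groups = labels, n = c(nx, ny), mean = c(mx, my),
       se = c(sqrt(vx / nx), sqrt(vy / ny)), t = t, df = df, p = p)
}

#' Enrichment tests of peak classes against a genomic background
#'
#' For each class, a 2x2 table is built (peaks in the class vs peaks not in
#' it; background elements in the class vs not) and tested with
#' [fisher_exact()]. The constructed tables are returned so the exact
#' construction can be audited. With no background counts available the
#' test set is skipped with an explicit message.
#'
#' @param observed Named integer vector: peak counts per class.
#' @param background Named integer vector: background element counts per
#'   class (same class universe).
#' @return data.frame with one row per class: \code{class, a, b, c, d, p};
#'   or NULL when the background is unavailable.
#' @export
enrichment_tables <- function(observed, background) {
  if (is.null(background) || !length(background)) {
    .log("background counts unavailable: enrichment test skipped")
    return(NULL)
  }
  classes <- union(names(observed), names(background))
  obs <- stats::setNames(rep(0L, length(classes)), classes)
  bg <- obs
  obs[names(observed)] <- observed
  bg[names(background)] <- background
  res <- lapply(classes, function(cl) {
    a <- obs[[cl]]; b <- sum(obs) - a
    c <- bg[[cl]]; d <- sum(bg) - c
    data.frame(class = cl, a = a, b = b, c = c, d = d,
               p = fisher_exact(a, b, c, d), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
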