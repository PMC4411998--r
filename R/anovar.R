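# Repeated-measures ANOVA (ANOVAR) for weekly root traits.
#
# The design is a split plot: plants (subjects) nested in treatment groups,
# weeks as the repeated within-subject factor. Classical F tests for the
# within-subject effects assume sphericity of the within-subject covariance;
# departures are absorbed by multiplying both degrees of freedom by Box's
# epsilon, estimated here in the Greenhouse-Geisser form from the sample
# covariance. With only two repeated measures epsilon is identically 1 and
# no adjustment occurs.

#' Greenhouse-Geisser estimate of Box's epsilon
#'
#' \deqn{\hat\epsilon = (\sum\lambda_i)^2 / ((k-1)\sum\lambda_i^2)}
#' over the eigenvalues of the doubly-centered within-subject covariance,
#' clamped to \eqn{[1/(k-1), 1]}. Equals 1 exactly under compound symmetry
#' (sphericity) and for k = 2.
#'
#' @param within_covariance symmetric k x k sample covariance of the
#'   repeated measures.
#' @return epsilon in \eqn{[1/(k-1), 1]}.
#' @examples
#' ggEpsilon(diag(3) * 2)  # 1 under sphericity
#' @export
ggEpsilon <- function(within_covariance) {
  S <- as.matrix(within_covariance)
  k <- nrow(S)
  if (k < 2L || ncol(S) != k) stop("covariance must be k x k with k >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance matrix must be symmetric")
  if (k == 2L) return(1)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  lam <- eigen((Sc + t(Sc)) / 2, symmetric = TRUE, only.values = TRUE)$values
  denom <- (k - 1) * sum(lam^2)
  if (denom < 1e-300) return(1)  # degenerate (zero) covariance: no departure
  eps <- sum(lam)^2 / denom
  min(max(eps, 1 / (k - 1)), 1)
}

#' Assemble a repeated-measures dataset
#'
#' @param values numeric vector of responses.
#' @param subject subject (plant) identifier per response.
#' @param group between-subject group per response (constant within
#'   subject).
#' @param time within-subject time level per response.
#' @return data.frame of class \code{RepeatedMeasuresData}, balanced across
#'   time (every subject observed at every time level).
#' @export
repeatedMeasuresData <- function(values, subject, group, time) {
  d <- data.frame(value = as.numeric(values), subject = factor(subject),
                  group = factor(group), time = factor(time))
  if (anyNA(d$value)) stop("responses must be complete (drop missing times first)")
  tab <- table(d$subject, d$time)
  if (any(tab != 1L))
    stop("design must be balanced: every subject once at every time level")
  gs <- tapply(as.character(d$group), d$subject, function(g) length(unique(g)))
  if (any(gs != 1L)) stop("each subject must belong to exactly one group")
  if (nlevels(d$time) < 2L) stop("need at least 2 time levels")
  class(d) <- c("RepeatedMeasuresData", "data.frame")
  d
}

#' Univariate repeated-measures ANOVA with epsilon-adjusted F tests
#'
#' Classical split-plot decomposition: the Group effect is tested against
#' subjects-within-group; Time and Time x Group are tested against the
#' Time x subject error. Within-subject P values are reported both
#' unadjusted and with numerator and denominator degrees of freedom
#' multiplied by the Greenhouse-Geisser epsilon. Significance is flagged at
#' 0.01, 0.05 and 0.10 with no multiplicity correction.
#'
#' @param data a \code{\link{repeatedMeasuresData}} data.frame.
#' @return list of class \code{AnovarTable} with components \code{table}
#'   (data.frame of effects: df1, df2, F, P, P_adjusted), \code{epsilon},
#'   \code{per_time} (per-time-level group contrasts) and \code{flags}.
#' @export
anovarUnivariate <- function(data) {
  stopifnot(inherits(data, "RepeatedMeasuresData"))
  k <- nlevels(data$time)
  g <- nlevels(data$group)
  n_sub <- nlevels(data$subject)

  fit <- stats::aov(value ~ group * time + Error(subject), data = data)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))

  pick <- function(tab, rn, name) {
    i <- match(name, rn)
    c(df = tab[i, "Df"], ss = tab[i, "Sum Sq"])
  }
  b_grp <- pick(between, rn_b, "group")
  b_err <- pick(between, rn_b, "Residuals")
  w_time <- pick(within, rn_w, "time")
  w_int <- pick(within, rn_w, "group:time")
  w_err <- pick(within, rn_w, "Residuals")

  # epsilon from the pooled within-group sample covariance of the k measures
  wide <- stats::reshape(data[, c("subject", "group", "time", "value")],
                         direction = "wide", idvar = c("subject", "group"),
                         timevar = "time")
  Y <- as.matrix(wide[, -(1:2), drop = FALSE])
  covs <- lapply(split(as.data.frame(Y), wide$group), function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2) NULL else stats::cov(m) * (nrow(m) - 1)
  })
  covs <- covs[!vapply(covs, is.null, logical(1))]
  pooled_df <- n_sub - g
  eps <- if (length(covs) && pooled_df > 0)
    ggEpsilon(Reduce(`+`, covs) / pooled_df) else 1

  scale <- stats::var(data$value)
  ftest <- function(eff, err, adjust = FALSE) {
    if (is.na(eff["ss"])) return(c(NA, NA, NA, NA, NA))
    ms_e <- err["ss"] / err["df"]
    # a zero error variance (all responses equal within cells) leaves F
    # undefined; guard relative to the response scale, not exact zero
    if (!is.finite(ms_e) || ms_e <= 1e-12 * max(scale, 1e-300) ||
        !is.finite(scale) || scale <= 0)
      return(c(eff["df"], err["df"], NA, NA, NA))  # F undefined, not NaN
    Fv <- (eff["ss"] / eff["df"]) / ms_e
    p <- stats::pf(Fv, eff["df"], err["df"], lower.tail = FALSE)
    # the sphericity adjustment guards against liberal within-subject
    # tests; it is never allowed to increase the reported significance
    padj <- if (adjust)
      max(p, stats::pf(Fv, eps * eff["df"], eps * err["df"],
                       lower.tail = FALSE))
    else p
    c(eff["df"], err["df"], Fv, p, padj)
  }
  rows <- rbind(
    Group = ftest(b_grp, b_err, adjust = FALSE),
    Time = ftest(w_time, w_err, adjust = TRUE),
    `Time x Group` = ftest(w_int, w_err, adjust = TRUE)
  )
  tab <- data.frame(effect = rownames(rows), df1 = rows[, 1], df2 = rows[, 2],
                    F = rows[, 3], P = rows[, 4], P_adjusted = rows[, 5],
                    row.names = NULL)

  per_time <- do.call(rbind, lapply(levels(data$time), function(tl) {
    dsub <- data[data$time == tl, ]
    if (g == 2L) {
      sp <- split(dsub$value, dsub$group)
      ct <- perWeekContrast(sp[[1]], sp[[2]])
      data.frame(time = tl, df1 = ct["df1"], df2 = ct["df2"],
                 F = ct["F"], P = ct["P"], row.names = NULL)
    } else {
      a <- stats::anova(stats::lm(value ~ group, data = dsub))
      data.frame(time = tl, df1 = a$Df[1], df2 = a$Df[2],
                 F = a$F[1], P = a$`Pr(>F)`[1], row.names = NULL)
    }
  }))

  flags <- within(tab, {
    sig_0.10 <- !is.na(P_adjusted) & P_adjusted < 0.10
    sig_0.05 <- !is.na(P_adjusted) & P_adjusted < 0.05
    sig_0.01 <- !is.na(P_adjusted) & P_adjusted < 0.01
  })[, c("effect", "sig_0.01", "sig_0.05", "sig_0.10")]

  structure(list(table = tab, epsilon = eps, per_time = per_time,
                 flags = flags, k = k, n_groups = g),
            class = "AnovarTable")
}

#' @export
print.AnovarTable <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d time levels, %d groups), epsilon = %.4f\n",
              x$k, x$n_groups, x$epsilon))
  print(x$table, digits = 4)
  cat("Per-time group contrasts:\n")
  print(x$per_time, digits = 4)
  invisible(x)
}

#' Two-group contrast at a single time point
#'
#' One-way two-group ANOVA F test, equivalent to the square of the
#' pooled-variance two-sample t statistic.
#'
#' @param values_g1,values_g2 numeric samples, each of size >= 2.
#' @return named vector with \code{F}, \code{df1}, \code{df2}, \code{P};
#'   F and P are NA (degenerate) when the pooled within-group variance
#'   is zero.
#' @export
perWeekContrast <- function(values_g1, values_g2) {
  n1 <- length(values_g1); n2 <- length(values_g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  y <- c(values_g1, values_g2)
  grp <- factor(rep(1:2, c(n1, n2)))
  # zero within-group variance (relative to the data scale) leaves the
  # F ratio undefined: report a degenerate result rather than +/- Inf
  pooled <- ((n1 - 1) * stats::var(values_g1) +
             (n2 - 1) * stats::var(values_g2)) / (n1 + n2 - 2)
  if (!is.finite(pooled) || pooled <= 1e-20 * max(mean(y)^2, 1e-300))
    return(c(F = NA_real_, df1 = 1, df2 = n1 + n2 - 2, P = NA_real_))
  a <- stats::anova(stats::lm(y ~ grp))
  c(F = a$F[1], df1 = a$Df[1], df2 = a$Df[2], P = a$`Pr(>F)`[1])
}

#' Two-sided variance-ratio test of between-group homogeneity
#'
#' F = s1^2/s2^2 on (n1 - 1, n2 - 1) degrees of freedom, two-sided.
#'
#' @param values_g1,values_g2 numeric samples, each of size >= 2.
#' @return named vector with \code{F}, \code{df1}, \code{df2}, \code{P};
#'   degenerate (NA) when both variances are zero.
#' @export
varianceHomogeneity <- function(values_g1, values_g2) {
  n1 <- length(values_g1); n2 <- length(values_g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  v1 <- stats::var(values_g1); v2 <- stats::var(values_g2)
  if (v1 == 0 && v2 == 0)
    return(c(F = NA_real_, df1 = n1 - 1, df2 = n2 - 1, P = NA_real_))
  ht <- stats::var.test(values_g1, values_g2)
  c(F = unname(ht$statistic), df1 = n1 - 1, df2 = n2 - 1,
    P = unname(ht$p.value))
}
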