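# Within-subject ANOVA machinery for fully crossed repeated-measures designs.
#
# The decomposition is the standard univariate repeated-measures partition:
# every subset of {subject, A, B, C} owns one sum of squares (computed by
# inclusion-exclusion over marginal means), each within effect is tested
# against its own effect-by-subject interaction, and sphericity is handled
# per effect on the orthonormal contrast space.

# orthonormalised Helmert contrasts, k x (k-1)
.ortho_contrasts <- function(k) {
  if (k < 2L) return(matrix(numeric(0), nrow = k, ncol = 0))
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# mean of Y over all dims not in `keep`, broadcast back to full dims
.mean_full <- function(Y, keep) {
  d <- dim(Y)
  if (length(keep) == 0L) return(array(mean(Y), d))
  m <- apply(Y, keep, mean)
  full <- array(m, dim = c(d[keep], d[-keep]))
  aperm(full, order(c(keep, setdiff(seq_along(d), keep))))
}

# interaction-effect array for subset T (inclusion-exclusion over U <= T)
.effect_array <- function(Y, subset) {
  acc <- array(0, dim(Y))
  subs <- list(integer(0))
  for (j in subset) subs <- c(subs, lapply(subs, function(u) c(u, j)))
  for (u in subs)
    acc <- acc + (-1)^(length(subset) - length(u)) * .mean_full(Y, u)
  acc
}

.mauchly_from_A <- function(A, n) {
  d <- nrow(A)
  if (d < 2L) return(list(W = 1, p = 1))
  tr <- sum(diag(A))
  W <- det(A) / (tr / d)^d
  if (!is.finite(W) || W <= 0) return(list(W = NA_real_, p = NA_real_))
  # chi-square approximation with the second-order Box expansion term,
  # matching the canonical implementations (stats::mauchly.test, ezANOVA)
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
  chi <- -(n - 1) * f * log(W)
  df <- d * (d + 1) / 2 - 1
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * (d + 1) + 2) /
    (288 * ((n - 1) * d * f)^2)
  p1 <- stats::pchisq(chi, df, lower.tail = FALSE)
  p2 <- stats::pchisq(chi, df + 4, lower.tail = FALSE)
  list(W = W, p = min(1, max(0, p1 + w2 * (p2 - p1))))
}

.gg_from_A <- function(A) {
  d <- nrow(A)
  if (d < 2L) return(1)
  eps <- sum(diag(A))^2 / (d * sum(A * A))
  min(1, max(1 / d, eps))
}

#' Greenhouse-Geisser epsilon from a within-factor covariance matrix
#'
#' For a within-subject factor with `k` levels and score covariance `S`,
#' epsilon is `tr(A)^2 / (d * tr(A^2))` with `A = M' S M` for orthonormal
#' contrasts `M` and `d = k - 1`. Epsilon is 1 under compound symmetry and
#' bounded below by `1/(k-1)`.
#'
#' @param S Covariance matrix (k x k) of the subject-by-level cell scores.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 2L || k != ncol(S))
    stop("S must be a square covariance matrix with >= 2 levels", call. = FALSE)
  M <- .ortho_contrasts(k)
  .gg_from_A(t(M) %*% S %*% M)
}

#' Mauchly's test of sphericity
#'
#' @param scores An `n x k` matrix of per-subject scores on the `k` levels of
#'   a within-subject factor (one row per subject).
#' @return List with `W` (in (0, 1]), `p` (chi-square approximation), and
#'   `gg_epsilon`. With `k = 2` the test is degenerate: `W = 1`, `p = 1`.
#' @export
mauchly_sphericity <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 within levels", call. = FALSE)
  M <- .ortho_contrasts(k)
  A <- t(M) %*% stats::cov(scores) %*% M
  mt <- .mauchly_from_A(A, n)
  if (is.na(mt$W) && k > 2L)
    warning("singular contrast covariance; Mauchly W undefined", call. = FALSE)
  c(mt, list(gg_epsilon = .gg_from_A(A)))
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] with a defensive check for
#' degenerate (constant) input.
#'
#' @param values Numeric sample (3 to 5000 values).
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate input: all values are identical", call. = FALSE)
  r <- stats::shapiro.test(values)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Bonferroni adjustment
#'
#' @param p_values Raw p values.
#' @param m Number of comparisons in the family (default `length(p_values)`).
#' @return `pmin(1, m * p_values)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  pmin(1, m * p_values)
}

.rate_d <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE)
}

.rate_eta <- function(eta) {
  cut(eta, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE)
}

#' Cohen's d for paired samples
#'
#' Primary variant is `d_z = mean(x - y) / sd(x - y)`, the convention coupled
#' to paired-test power machinery; the average-variance variant
#' `d_av = mean(x - y) / sqrt((var(x) + var(y)) / 2)` is also returned.
#' Ratings follow Cohen's bands: negligible < 0.2 <= small < 0.5 <= medium
#' < 0.8 <= large.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `d` (= d_z), `d_av`, and `rating` (on `|d|`).
#' @export
cohens_d_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  diffs <- x - y
  s <- stats::sd(diffs)
  if (length(diffs) >= 2L && s == 0 && mean(diffs) != 0)
    stop("zero-variance differences", call. = FALSE)
  d <- if (all(diffs == 0)) 0 else mean(diffs) / s
  d_av <- if (all(diffs == 0)) 0 else
    mean(diffs) / sqrt((stats::var(x) + stats::var(y)) / 2)
  list(d = d, d_av = d_av, rating = as.character(.rate_d(d)))
}

#' Partial eta squared
#'
#' `SS_effect / (SS_effect + SS_error)`, rated on Cohen's bands
#' (negligible < 0.01 <= small < 0.06 <= medium < 0.14 <= large).
#'
#' @param ss_effect,ss_error Sums of squares (>= 0).
#' @return List with `value` and `rating`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0)
    stop("sums of squares must be non-negative", call. = FALSE)
  if (ss_effect + ss_error == 0)
    stop("both sums of squares are zero", call. = FALSE)
  v <- ss_effect / (ss_effect + ss_error)
  list(value = v, rating = as.character(.rate_eta(v)))
}

#' Ordinary least-squares slope of condition means against a covariate
#'
#' Reproduces the reporting convention "metric changed by b per unit":
#' the OLS slope of per-condition group means against the condition
#' covariate (e.g. speed in km/h, or elevation in km).
#'
#' @param cell_means Numeric vector of condition means.
#' @param covariate_values Covariate value for each condition.
#' @return The slope (change per unit covariate).
#' @export
condition_slopes <- function(cell_means, covariate_values) {
  if (length(cell_means) != length(covariate_values) || length(cell_means) < 2L)
    stop("need >= 2 (covariate, mean) points", call. = FALSE)
  if (stats::sd(covariate_values) == 0)
    stop("constant covariate", call. = FALSE)
  xc <- covariate_values - mean(covariate_values)
  sum(xc * cell_means) / sum(xc^2)
}

#' Three-way repeated-measures ANOVA
#'
#' Fully within-subject three-factor ANOVA with the standard univariate
#' partition: each of the seven effects (three main, three two-way, one
#' three-way) is tested against its own effect-by-subject interaction.
#' Sphericity is assessed per effect with Mauchly's test on the orthonormal
#' contrast space; the Greenhouse-Geisser corrected p value is always
#' reported, and the primary `p` column applies it only when Mauchly's test
#' rejects at 0.05 (sphericity "could not be assumed"). Effect sizes are
#' partial eta squared with Cohen ratings.
#'
#' @param data Long-format `data.frame`, one row per subject x cell, balanced
#'   and complete.
#' @param outcome Name of the outcome column.
#' @param subject Name of the subject identifier column.
#' @param factors Character vector of the three within-subject factor columns.
#' @param sphericity_alpha Mauchly significance level gating the GG
#'   correction in the primary `p` column.
#' @return `data.frame` of class `rm_anova_table`, one row per effect, with
#'   `effect`, `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`,
#'   `p_uncorrected`, `mauchly_w`, `mauchly_p`, `gg_epsilon`, `p_gg`, `p`,
#'   `partial_eta_sq`, `rating`. Attribute `ss_partition` holds the full SS
#'   decomposition (including the subject stratum) for auditing.
#' @export
rm_anova_3way <- function(data, outcome, subject = "subject",
                          factors = c("elevation_m", "speed_level", "surface"),
                          sphericity_alpha = 0.05) {
  stopifnot(is.data.frame(data), length(factors) == 3L)
  need <- c(subject, factors, outcome)
  if (!all(need %in% names(data)))
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "),
         call. = FALSE)
  f_sub <- factor(data[[subject]])
  f_fac <- lapply(factors, function(f) factor(data[[f]]))
  n <- nlevels(f_sub)
  if (n < 3L) stop("insufficient subjects: need >= 3 for rmANOVA", call. = FALSE)
  lev <- vapply(f_fac, nlevels, 1L)
  counts <- table(f_sub, f_fac[[1]], f_fac[[2]], f_fac[[3]])
  if (any(counts != 1L)) {
    bad <- dimnames(counts)[[1]][apply(counts != 1L, 1, any)]
    stop("unbalanced or incomplete design for subjects: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Y <- tapply(data[[outcome]],
              list(f_sub, f_fac[[1]], f_fac[[2]], f_fac[[3]]), mean)
  Y <- array(Y, dim = c(n, lev))

  # SS for every non-empty subset of {subject(1), A(2), B(3), C(4)}
  all_subsets <- list()
  for (j in 1:4) {
    prev <- all_subsets
    all_subsets <- c(all_subsets, list(j))
    for (u in prev) all_subsets <- c(all_subsets, list(c(u, j)))
  }
  dims_all <- c(n, lev)
  names_all <- c(".subject", factors)
  ss <- df <- numeric(length(all_subsets))
  labels <- character(length(all_subsets))
  for (i in seq_along(all_subsets)) {
    T <- all_subsets[[i]]
    ss[i] <- sum(.effect_array(Y, T)^2)
    df[i] <- prod(dims_all[T] - 1L)
    labels[i] <- paste(names_all[T], collapse = ":")
  }
  names(ss) <- names(df) <- labels

  effects <- list(c(2L), c(3L), c(4L), c(2L, 3L), c(2L, 4L), c(3L, 4L),
                  c(2L, 3L, 4L))
  out <- lapply(effects, function(E) {
    lab <- paste(factors[E - 1L], collapse = ":")
    err_lab <- paste(c(".subject", factors[E - 1L]), collapse = ":")
    ss_e <- ss[[lab]]; df_e <- df[[lab]]
    ss_r <- ss[[err_lab]]; df_r <- df[[err_lab]]
    Fv <- (ss_e / df_e) / (ss_r / df_r)
    p_unc <- stats::pf(Fv, df_e, df_r, lower.tail = FALSE)
    # subject scores on this effect's cells, contrasted
    D <- apply(Y, c(1L, E), mean)
    D <- matrix(D, nrow = n)
    M <- Reduce(function(a, b) kronecker(b, a),
                lapply(dims_all[E], .ortho_contrasts))
    A <- t(M) %*% stats::cov(D) %*% M
    mt <- .mauchly_from_A(A, n)
    eps <- .gg_from_A(A)
    p_gg <- stats::pf(Fv, eps * df_e, eps * df_r, lower.tail = FALSE)
    use_gg <- !is.na(mt$p) && mt$p < sphericity_alpha && df_e > 1L
    eta <- ss_e / (ss_e + ss_r)
    data.frame(effect = lab, df_num = df_e, df_den = df_r,
               ss_effect = ss_e, ss_error = ss_r, F = Fv,
               p_uncorrected = p_unc, mauchly_w = mt$W, mauchly_p = mt$p,
               gg_epsilon = eps, p_gg = p_gg,
               p = if (use_gg) p_gg else p_unc,
               partial_eta_sq = eta, rating = as.character(.rate_eta(eta)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ss_partition") <- data.frame(term = labels, ss = unname(ss),
                                          df = unname(df),
                                          stringsAsFactors = FALSE)
  attr(res, "n_subjects") <- n
  class(res) <- c("rm_anova_table", "data.frame")
  res
}

#' @export
print.rm_anova_table <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects)\n", attr(x, "n_subjects")))
  show <- x[, c("effect", "df_num", "df_den", "F", "gg_epsilon", "p",
                "partial_eta_sq", "rating")]
  print.data.frame(show, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' Paired comparisons between the levels of one within-subject factor on
#' subject means (collapsed over the remaining factors, optionally within
#' fixed levels of conditioning factors). Each family (one `by` cell) is
#' Bonferroni-corrected by its own number of comparisons.
#'
#' @param data Long-format metrics table.
#' @param outcome Outcome column name.
#' @param factor_name Within-subject factor whose levels are compared.
#' @param subject Subject identifier column.
#' @param by Optional character vector of conditioning factor columns.
#' @param conf_level Confidence level of the mean-difference interval.
#' @return `data.frame` with one row per comparison: levels compared,
#'   mean difference with CI, t, raw and Bonferroni p, Cohen's `d` (d_z)
#'   and rating.
#' @export
posthoc_pairwise <- function(data, outcome, factor_name, subject = "subject",
                             by = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  fam_key <- if (is.null(by)) rep("all", nrow(data)) else
    interaction(data[by], drop = TRUE, sep = "/")
  out <- list()
  for (fam in unique(as.character(fam_key))) {
    d <- data[as.character(fam_key) == fam, , drop = FALSE]
    m <- tapply(d[[outcome]], list(factor(d[[subject]]), factor(d[[factor_name]])),
                mean)
    levs <- colnames(m)
    pairs <- utils::combn(levs, 2, simplify = FALSE)
    n_cmp <- length(pairs)
    for (pr in pairs) {
      x <- m[, pr[1]]; y <- m[, pr[2]]
      diffs <- x - y
      nn <- length(diffs)
      se <- stats::sd(diffs) / sqrt(nn)
      tv <- mean(diffs) / se
      p_raw <- 2 * stats::pt(abs(tv), nn - 1, lower.tail = FALSE)
      ci <- mean(diffs) + c(-1, 1) * stats::qt((1 + conf_level) / 2, nn - 1) * se
      es <- cohens_d_paired(x, y)
      out[[length(out) + 1L]] <- data.frame(
        family = fam, level_a = pr[1], level_b = pr[2],
        mean_diff = mean(diffs), ci_lower = ci[1], ci_upper = ci[2],
        t = tv, df = nn - 1, p_raw = p_raw,
        p_bonferroni = bonferroni_adjust(p_raw, n_cmp),
        cohens_d = es$d, rating = es$rating,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
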