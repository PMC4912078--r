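#' Factorial fixed-effects ANOVA with Tukey post-hoc comparisons
#'
#' Fits a fully crossed fixed-effects ANOVA (all interactions) for one to
#' three categorical factors, reports Type II tests (robust to the unbalanced
#' cells that arise from discarded conditions), cell means with 95%
#' confidence intervals, and Tukey HSD pairwise tables.
#'
#' @param data Long-format data frame.
#' @param response Name of the response column.
#' @param factors Character vector of 1-3 factor column names.
#' @param tukey Factors (or interactions, e.g. `"session:group"`) for which
#'   Tukey HSD tables are requested; defaults to all single factors.
#' @param type Sum-of-squares type for [car::Anova()] (default `"II"`).
#' @return A `factorial_anova` list: `table` (effect, F, df1, df2, p),
#'   `cell_means` (factor combination, n, mean, lwr, upr), `tukey` (list of
#'   `TukeyHSD` tables), `empty_cells`, and the fitted `aov` object.
#' @export
factorial_anova <- function(data, response, factors, tukey = factors,
                            type = "II") {
  stopifnot(length(factors) >= 1, length(factors) <= 3,
            response %in% names(data), all(factors %in% names(data)))
  data <- data[stats::complete.cases(data[, c(response, factors)]), ,
               drop = FALSE]
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (any(vapply(data[factors], nlevels, 1L) < 2)) {
    stop("every factor needs at least 2 observed levels")
  }
  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*")))
  fit <- stats::aov(form, data = data)
  if (fit$rank < ncol(stats::model.matrix(fit)) ||
      any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: some factor-level combinations are aliased; ",
         "check for structurally empty cells")
  }
  zero_resid <- sum(stats::residuals(fit)^2) <=
    1e-20 * max(1, sum(data[[response]]^2))
  if (zero_resid) {
    # zero residual variance: F undefined; flag rather than fail
    effs <- attr(stats::terms(fit), "term.labels")
    tab <- data.frame(effect = effs, F = NA_real_, df1 = NA_real_,
                      df2 = stats::df.residual(fit), p = NA_real_)
  } else {
    at <- car::Anova(fit, type = type)
    eff <- rownames(at)
    keep <- !(eff %in% c("Residuals", "(Intercept)"))
    df2 <- at$Df[eff == "Residuals"]
    tab <- data.frame(effect = eff[keep], F = at$`F value`[keep],
                      df1 = at$Df[keep], df2 = df2,
                      p = at$`Pr(>F)`[keep], row.names = NULL)
  }

  cells <- stats::aggregate(data[[response]], data[factors],
                            function(x) c(n = length(x), mean = mean(x),
                                          sd = stats::sd(x)))
  cm <- cells[factors]
  cm$n <- cells$x[, "n"]
  cm$mean <- cells$x[, "mean"]
  se <- cells$x[, "sd"] / sqrt(cm$n)
  tq <- ifelse(cm$n > 1, stats::qt(0.975, pmax(cm$n - 1, 1)), NA)
  cm$lwr <- cm$mean - tq * se
  cm$upr <- cm$mean + tq * se

  full_grid <- expand.grid(lapply(data[factors], levels))
  observed <- do.call(paste, c(cm[factors], sep = "\r"))
  all_cells <- do.call(paste, c(full_grid, sep = "\r"))
  empty <- full_grid[!(all_cells %in% observed), , drop = FALSE]

  tk <- tryCatch(stats::TukeyHSD(fit, which = tukey),
                 error = function(e) NULL)
  structure(list(table = tab, cell_means = cm, tukey = tk,
                 empty_cells = empty, zero_residual = zero_resid, fit = fit),
            class = "factorial_anova")
}

#' @export
print.factorial_anova <- function(x, ...) {
  cat("<factorial_anova> Type II tests:\n")
  print(transform(x$table, F = round(F, 3), p = signif(p, 3)))
  if (nrow(x$empty_cells) > 0) {
    cat(sprintf("  (%d empty cells)\n", nrow(x$empty_cells)))
  }
  invisible(x)
}

#' Kruskal-Wallis test with pairwise mean-rank comparisons
#'
#' Kruskal-Wallis rank ANOVA (tie-corrected H) followed by pairwise z-type
#' comparisons of mean ranks (Dunn's procedure on the joint ranking, with
#' tie correction) and Bonferroni adjustment over the pairs.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (>= 2 groups with >= 2 observations each).
#' @return List with `H`, `df`, `p`, and `pairwise` (data frame: groups,
#'   mean-rank difference, z, raw and adjusted p).
#' @export
kruskal_wallis_ranks <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  if (length(unique(values)) == 1) {
    # all observations tied across all groups: no evidence of any difference
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     mean_rank_diff = 0, z = 0, p = 1, p_adj = 1)
    return(list(H = 0, df = nlevels(groups) - 1, p = 1, pairwise = pw))
  }
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- diffs <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diffs[k] <- mean_ranks[[i]] - mean_ranks[[j]]
    sed <- sqrt(sigma2 * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- diffs[k] / sed
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   mean_rank_diff = diffs, z = z, p = p,
                   p_adj = stats::p.adjust(p, "bonferroni"))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pw)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact p-value for small
#' samples without ties, normal approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples (non-empty).
#' @return List with `U` (the Mann-Whitney U statistic for sample `a`),
#'   `p`, and `exact` (whether the exact distribution was used).
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && (length(a) + length(b)) <= 20
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = !use_exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Kolmogorov-Smirnov comparisons of tinnitus-frequency count distributions
#'
#' Runs the full comparison battery on per-animal counts of
#' tinnitus-affected frequencies: the two groups against each other at every
#' session, and every session pair within each group. The D statistic is the
#' maximum ECDF gap; because the counts are small-sample and heavily tied,
#' p-values come from a Monte Carlo permutation of group labels rather than
#' the asymptotic KS distribution (which is invalid under ties). Bonferroni
#' adjustment is applied within each comparison family (between-group;
#' within-group per group).
#'
#' @param counts Data frame with columns `animal`, `group`, `session`,
#'   `n_affected`.
#' @param sessions Sessions to include (default: all present, in
#'   [time_points()] order).
#' @param alpha Significance level for the flags (default 0.05).
#' @param n_perm Number of label permutations per comparison (default 1999).
#' @return A `distribution_comparison` data frame: `family`, `comparison`,
#'   `D`, `p`, `p_adj`, `significant_raw`, `significant_adj`. Comparisons
#'   with fewer than 2 animals on a side are skipped with a warning.
#' @export
compare_tinnitus_distributions <- function(counts, sessions = NULL,
                                           alpha = 0.05, n_perm = 1999) {
  stopifnot(all(c("animal", "group", "session", "n_affected") %in% names(counts)))
  if (is.null(sessions)) {
    sessions <- intersect(time_points(), unique(counts$session))
  }
  rows <- list()
  add <- function(family, comparison, x, y) {
    if (length(x) < 2 || length(y) < 2) {
      warning(sprintf("skipping %s (%s): fewer than 2 animals on one side",
                      comparison, family))
      return()
    }
    ks <- ks_permutation(x, y, n_perm)
    rows[[length(rows) + 1]] <<- data.frame(
      family = family, comparison = comparison, D = ks$D, p = ks$p)
  }
  for (s in sessions) {
    x <- counts$n_affected[counts$session == s & counts$group == "G"]
    y <- counts$n_affected[counts$session == s & counts$group == "V"]
    add("between_group", sprintf("G vs V @ %s", s), x, y)
  }
  for (g in c("G", "V")) {
    if (length(sessions) < 2) break
    prs <- utils::combn(sessions, 2)
    for (k in seq_len(ncol(prs))) {
      x <- counts$n_affected[counts$session == prs[1, k] & counts$group == g]
      y <- counts$n_affected[counts$session == prs[2, k] & counts$group == g]
      add(paste0("within_", g),
          sprintf("%s: %s vs %s", g, prs[1, k], prs[2, k]), x, y)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparisons could be performed")
  out$p_adj <- NA_real_
  for (fam in unique(out$family)) {
    idx <- out$family == fam
    out$p_adj[idx] <- stats::p.adjust(out$p[idx], "bonferroni")
  }
  out$significant_raw <- out$p < alpha
  out$significant_adj <- out$p_adj < alpha
  class(out) <- c("distribution_comparison", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute gap between the two empirical distribution functions,
#' evaluated over the pooled support (ties allowed).
#'
#' @param x,y Numeric samples.
#' @return The D statistic in `[0, 1]`.
#' @export
ks_statistic <- function(x, y) {
  codes <- match(c(x, y), sort(unique(c(x, y))))
  m <- max(codes)
  cx <- cumsum(tabulate(codes[seq_along(x)], m)) / length(x)
  cy <- cumsum(tabulate(codes[-seq_along(x)], m)) / length(y)
  max(abs(cx - cy))
}

# Two-sample KS D with Monte Carlo permutation p-value (valid under ties).
ks_permutation <- function(x, y, n_perm = 1999) {
  codes <- match(c(x, y), sort(unique(c(x, y))))
  m <- max(codes)
  nx <- length(x)
  ny <- length(y)
  ix <- seq_len(nx)
  D_of <- function(cd) {
    max(abs(cumsum(tabulate(cd[ix], m)) / nx -
              cumsum(tabulate(cd[-ix], m)) / ny))
  }
  D0 <- D_of(codes)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (D_of(codes[sample.int(nx + ny)]) >= D0 - 1e-12) ge <- ge + 1L
  }
  list(D = D0, p = (ge + 1) / (n_perm + 1))
}
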