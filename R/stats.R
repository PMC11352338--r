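# Group-comparison statistics mirroring the study's testing scheme:
# a variance-homogeneity gate (Bartlett or Brown-Forsythe) chooses between
# one-way ANOVA with Tukey's post hoc and Kruskal-Wallis with Dunn's test.

#' Dunn's post hoc test
#'
#' Pairwise rank comparisons after Kruskal-Wallis: with overall ranks R and
#' mean ranks per group, `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)
#' (1/n_i + 1/n_j))` where `T = sum(t^3 - t) / (12 (N - 1))` corrects for
#' ties. Two-sided normal p-values, multiplicity-adjusted with
#' [stats::p.adjust()].
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @param adjust p-adjustment method (default `"holm"`).
#' @return data.frame with columns `pair`, `z`, `p_raw`, `p_adj`.
#' @export
dunnTest <- function(values, groups, adjust = "holm") {
  g <- factor(groups)
  .stopIfNot(nlevels(g) >= 2, "need >= 2 groups")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(pair = paste(pairs[1L, ], pairs[2L, ], sep = "-"),
             z = z, p_raw = p, p_adj = stats::p.adjust(p, adjust))
}

#' Gate-and-test group comparison
#'
#' Decision scheme: a variance-homogeneity gate (Bartlett's test, or
#' Brown-Forsythe — Levene on deviations from group medians) decides
#' between the parametric branch (one-way ANOVA, Tukey HSD post hoc) and
#' the rank branch (Kruskal-Wallis, Dunn post hoc with Holm adjustment).
#' The branch can be forced with `branch`. The post hoc table is reported
#' only when the omnibus p-value is below `alpha` (set
#' `alwaysPosthoc = TRUE` to always report it). Constant-valued data are a
#' flagged degenerate case with no test. The full decision trail is
#' returned.
#'
#' @param data data.frame holding the response and grouping columns.
#' @param valueCol,groupCol column names (defaults `"value"`, `"group"`).
#' @param measure label for the measure under test.
#' @param gate `"bartlett"` or `"brown-forsythe"`.
#' @param branch `"auto"`, `"anova"` or `"kruskal"`.
#' @param alpha significance level (default 0.05).
#' @param adjust Dunn p-adjustment method (default `"holm"`).
#' @param alwaysPosthoc report the post hoc table regardless of omnibus p.
#' @return a `GroupComparison` list: `measure`, `degenerate`, `gate`
#'   (list: test, p), `branch`, `omnibus` (list: test, statistic, p),
#'   `posthoc` (data.frame or NULL), `alpha`, `trail` (character).
#' @export
chooseAndTest <- function(data, valueCol = "value", groupCol = "group",
                          measure = valueCol,
                          gate = c("bartlett", "brown-forsythe"),
                          branch = c("auto", "anova", "kruskal"),
                          alpha = 0.05, adjust = "holm",
                          alwaysPosthoc = FALSE) {
  gate <- match.arg(gate)
  branch <- match.arg(branch)
  v <- data[[valueCol]]
  g <- factor(data[[groupCol]])
  .stopIfNot(nlevels(g) >= 2, "need >= 2 groups")
  n <- tapply(v, g, length)
  if (any(n < 3)) stop("insufficient replicates: need >= 3 per group",
                       call. = FALSE)
  trail <- character(0)
  res <- list(measure = measure, degenerate = FALSE, gate = NULL,
              branch = NA_character_, omnibus = NULL, posthoc = NULL,
              alpha = alpha)

  if (stats::sd(v) == 0) {
    res$degenerate <- TRUE
    res$trail <- "constant-valued data: degenerate case, no test run"
    class(res) <- "GroupComparison"
    return(res)
  }

  gateP <- NA_real_
  if (branch == "auto") {
    gateP <- if (gate == "bartlett") {
      stats::bartlett.test(v, g)$p.value
    } else {
      car::leveneTest(v ~ g, center = stats::median)[1L, "Pr(>F)"]
    }
    res$gate <- list(test = gate, p = gateP)
    branch <- if (!is.na(gateP) && gateP < alpha) "kruskal" else "anova"
    trail <- c(trail, sprintf(
      "gate %s p = %.4g -> %s branch", gate, gateP, branch))
  } else {
    trail <- c(trail, paste("branch forced:", branch))
  }
  res$branch <- branch

  if (branch == "anova") {
    fit <- stats::aov(v ~ g)
    p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    stat <- summary(fit)[[1L]][["F value"]][1L]
    res$omnibus <- list(test = "one-way ANOVA", statistic = stat, p = p)
    if (alwaysPosthoc || (!is.na(p) && p < alpha)) {
      tk <- stats::TukeyHSD(fit)$g
      res$posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                                p_adj = tk[, "p adj"], row.names = NULL)
      trail <- c(trail, "post hoc: Tukey HSD")
    }
  } else {
    kw <- stats::kruskal.test(v, g)
    res$omnibus <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                        p = kw$p.value)
    if (alwaysPosthoc || (!is.na(kw$p.value) && kw$p.value < alpha)) {
      res$posthoc <- dunnTest(v, g, adjust = adjust)
      trail <- c(trail, sprintf("post hoc: Dunn (%s adjustment)", adjust))
    }
  }
  trail <- c(trail, sprintf("omnibus %s p = %.4g (alpha %.3g)",
                            res$omnibus$test, res$omnibus$p, alpha))
  res$trail <- trail
  class(res) <- "GroupComparison"
  res
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Group comparison:", x$measure, "\n")
  if (x$degenerate) {
    cat("  degenerate (constant data), no test\n")
    return(invisible(x))
  }
  if (!is.null(x$gate)) {
    cat(sprintf("  gate: %s, p = %.4g\n", x$gate$test, x$gate$p))
  }
  cat(sprintf("  omnibus: %s, stat = %.4g, p = %.4g\n",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p))
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
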