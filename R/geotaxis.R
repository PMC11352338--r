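# Negative geotaxis: startle-induced climbing, scored as the percentage of
# flies that climb 5 cm within 5 s of being knocked down.

#' Score negative-geotaxis trials
#'
#' @param trials data.frame with columns `genotype`, `group`, `trial`,
#'   `n_flies`, `n_climbed` (see [simulateGeotaxis()] for the dialect).
#' @return the same data.frame with a `score_pct` column,
#'   `100 * n_climbed / n_flies`.
#' @export
scoreTrials <- function(trials) {
  .stopIfNot(all(trials$n_flies > 0), "n_flies must be positive")
  .stopIfNot(all(trials$n_climbed >= 0 & trials$n_climbed <= trials$n_flies),
             "n_climbed must lie in 0..n_flies")
  trials$score_pct <- 100 * trials$n_climbed / trials$n_flies
  trials
}

#' Aggregate climbing performance
#'
#' Group score = mean over the group's trials; genotype summary = mean and
#' SEM over group scores (`scheme = "group"`, the default unit of
#' replication) or over all pooled trials (`scheme = "pooled"`).
#'
#' @param trials trial table (scored or not; see [scoreTrials()]).
#' @param scheme `"group"` or `"pooled"`.
#' @return list with `groups` (data.frame `genotype`, `group`,
#'   `score_pct`, `n_trials`) and `genotypes` (data.frame `genotype`,
#'   `mean_pct`, `sem_pct`, `n`).
#' @export
aggregateGeotaxis <- function(trials, scheme = c("group", "pooled")) {
  scheme <- match.arg(scheme)
  if (!"score_pct" %in% names(trials)) trials <- scoreTrials(trials)
  gkey <- interaction(trials$genotype, trials$group, drop = TRUE)
  groups <- data.frame(
    genotype = tapply(as.character(trials$genotype), gkey, `[`, 1L),
    group = tapply(trials$group, gkey, `[`, 1L),
    score_pct = as.numeric(tapply(trials$score_pct, gkey, mean)),
    n_trials = as.integer(tapply(trials$score_pct, gkey, length))
  )
  rownames(groups) <- NULL
  groups <- groups[order(groups$genotype, groups$group), , drop = FALSE]
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  unit <- if (scheme == "group") groups else trials
  genotypes <- do.call(rbind, lapply(split(unit, unit$genotype), function(d) {
    data.frame(genotype = d$genotype[1L], mean_pct = mean(d$score_pct),
               sem_pct = sem(d$score_pct), n = nrow(d))
  }))
  rownames(genotypes) <- NULL
  list(groups = groups, genotypes = genotypes)
}

#' Read / write geotaxis trial tables
#'
#' CSV dialect: columns `genotype`, `group`, `trial`, `n_flies`,
#' `n_climbed`.
#'
#' @param path file path.
#' @return `readGeotaxis`: the trial data.frame.
#' @export
readGeotaxis <- function(path) {
  d <- utils::read.csv(path)
  need <- c("genotype", "group", "trial", "n_flies", "n_climbed")
  .stopIfNot(all(need %in% names(d)),
             paste("geotaxis file needs columns:", paste(need, collapse = ", ")))
  d
}

#' @rdname readGeotaxis
#' @param trials trial table.
#' @return `writeGeotaxis`: `path`, invisibly.
#' @export
writeGeotaxis <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
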