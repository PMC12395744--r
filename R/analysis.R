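#' Round half away from zero
#'
#' Reporting convention for percentages: 13.5 rounds to 14 (base R's
#' `round()` rounds half to even). Unrounded values are always retained
#' alongside.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  sc <- 10^digits
  sign(x) * floor(abs(x) * sc + 0.5) / sc
}

#' Cross-tabulate screening recommendations under two risk models
#'
#' Builds the (clinical-model recommendation) x (PRS-modified recommendation)
#' contingency table for one age stratum, over non-carrier, scoreable,
#' year-1 records. Pathogenic-variant carriers are excluded because the PRS
#' plays no role in their screening.
#'
#' @param records Data frame with columns `rec_bcsc` and `rec_combined`;
#'   optional columns `age` (used with `age_stratum`), `pv` and `scoreable`
#'   (used to filter).
#' @param age_stratum Optional length-2 numeric `c(lo, hi)` restricting to
#'   `lo <= age <= hi`.
#' @return A `reassignment_table`: counts matrix (rows = clinical model,
#'   columns = PRS-modified model), `n_total`, and the stratum.
#' @export
cross_tabulate <- function(records, age_stratum = NULL) {
  r <- as.data.frame(records, stringsAsFactors = FALSE)
  if ("pv" %in% names(r)) r <- r[!r$pv, , drop = FALSE]
  r <- r[r$rec_bcsc != "pv_guideline" & r$rec_combined != "pv_guideline", ,
         drop = FALSE]
  if ("scoreable" %in% names(r)) r <- r[r$scoreable, , drop = FALSE]
  if (!is.null(age_stratum)) {
    r <- r[r$age >= age_stratum[1] & r$age <= age_stratum[2], , drop = FALSE]
  }
  lv <- screening_levels(include_pv = FALSE)
  counts <- unclass(table(factor(r$rec_bcsc, levels = lv),
                          factor(r$rec_combined, levels = lv)))
  dimnames(counts) <- list(lv, lv)
  reassignment_table(counts, age_stratum = age_stratum)
}

#' @rdname cross_tabulate
#' @param counts Square counts matrix with recommendation labels as both
#'   dimnames (rows: clinical model, columns: PRS-modified model).
#' @export
reassignment_table <- function(counts, age_stratum = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) ||
      !identical(rownames(counts), colnames(counts))) {
    stop("counts must be square with identical row/column labels")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, n_total = sum(counts),
                 age_stratum = age_stratum),
            class = "reassignment_table")
}

#' @export
print.reassignment_table <- function(x, ...) {
  if (!is.null(x$age_stratum)) {
    cat("Age stratum ", x$age_stratum[1], "-", x$age_stratum[2], ", ", sep = "")
  }
  cat("n =", x$n_total, "\n")
  print(x$counts)
  if (x$n_total > 0) {
    d <- discordance_percentage(x)
    cat(sprintf("discordant: %.2f%% (%d%%)\n", d$percent, d$percent_rounded))
  }
  invisible(x)
}

#' Discordance between two models' screening recommendations
#'
#' The off-diagonal fraction of the cross-tabulation: participants whose
#' recommendation changes when the PRS is incorporated, divided by all
#' participants in the stratum.
#'
#' @param table A `reassignment_table` with `n_total > 0`.
#' @return List with `percent` (unrounded), `percent_rounded` (half-up
#'   integer percent), `n_discordant` and `n_total`.
#' @export
discordance_percentage <- function(table) {
  if (table$n_total == 0) stop("empty reassignment table")
  nd <- sum(table$counts) - sum(diag(table$counts))
  pct <- 100 * nd / table$n_total
  list(percent = pct, percent_rounded = round_half_up(pct),
       n_discordant = nd, n_total = table$n_total)
}

#' Fraction of one model's recommendation group reassigned to another
#'
#' Of the participants the clinical model places in `from`, the percentage
#' the PRS-modified model places in `to` (a row-conditional percentage of
#' the cross-tab).
#'
#' @param table A `reassignment_table`.
#' @param from,to Recommendation labels.
#' @return List with `percent`, `percent_rounded`, `n`, `row_total`.
#' @export
cell_reassignment_fraction <- function(table, from, to) {
  if (!from %in% rownames(table$counts) || !to %in% colnames(table$counts)) {
    stop("unknown recommendation label")
  }
  row_total <- sum(table$counts[from, ])
  if (row_total == 0) stop("empty '", from, "' row")
  n <- table$counts[from, to]
  pct <- 100 * n / row_total
  list(percent = pct, percent_rounded = round_half_up(pct),
       n = n, row_total = row_total)
}

#' Projected screening utilization
#'
#' Mean screening encounters per woman per year implied by a set of
#' recommendations, and its reciprocal rounded to the "1 screen per N
#' women/year" form used for reporting.
#'
#' @param x Either a data frame of assignment records or a named numeric
#'   vector of recommendation counts.
#' @param model When `x` is a data frame: which column to use, `"bcsc"`,
#'   `"combined"` or `"final"` (column `rec_<model>`).
#' @param freq_map Recommendation -> screens/year map; see
#'   [default_freq_map()]. Pathogenic-variant carriers are dropped before
#'   averaging.
#' @return List with `mean_screens` (per woman-year), `women_per_screen`
#'   (half-up rounded reciprocal integer, `NA` when no screening at all) and
#'   `n`.
#' @export
mean_screens_per_woman_year <- function(x, model = c("combined", "bcsc", "final"),
                                        freq_map = default_freq_map()) {
  if (is.data.frame(x)) {
    model <- match.arg(model)
    rec <- x[[paste0("rec_", model)]]
    if (is.null(rec)) stop("records lack column rec_", model)
    rec <- rec[rec != "pv_guideline"]
    counts <- table(rec)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    if (is.null(names(x))) stop("counts vector must be named by recommendation")
    counts <- x[names(x) != "pv_guideline"]
  }
  n <- sum(counts)
  if (n == 0) stop("no records to summarize")
  spw <- sum(screens_per_year(names(counts), freq_map) * counts) / n
  list(mean_screens = spw,
       women_per_screen = if (spw > 0) round_half_up(1 / spw) else NA_real_,
       n = n)
}

#' Export Sankey flows of screening-assignment change
#'
#' One flow per nonzero transition, for the clinical-model to PRS-modified
#' transition and (when a `rec_final` column is present) the PRS-modified to
#' final-issued transition. Flow totals conserve the participant count.
#'
#' @param records Assignment records with `rec_bcsc`, `rec_combined` and
#'   optionally `rec_final` (pathogenic-variant carriers excluded as in
#'   [cross_tabulate()]).
#' @return Data frame with columns `stage`, `source`, `target`, `count`.
#' @export
sankey_flows <- function(records) {
  flows_of <- function(tab, stage) {
    nz <- which(tab$counts > 0, arr.ind = TRUE)
    if (!nrow(nz)) {
      return(data.frame(stage = character(), source = character(),
                        target = character(), count = numeric()))
    }
    data.frame(stage = stage,
               source = rownames(tab$counts)[nz[, 1]],
               target = colnames(tab$counts)[nz[, 2]],
               count = tab$counts[nz],
               stringsAsFactors = FALSE)
  }
  out <- flows_of(cross_tabulate(records), "bcsc_to_combined")
  if ("rec_final" %in% names(records)) {
    r2 <- records
    r2$rec_bcsc <- r2$rec_combined
    r2$rec_combined <- r2$rec_final
    out <- rbind(out, flows_of(cross_tabulate(r2), "combined_to_final"))
  }
  rownames(out) <- NULL
  out
}

#' @rdname sankey_flows
#' @param flows Output of `sankey_flows()`.
#' @param path Destination JSON path.
#' @export
write_sankey_json <- function(flows, path) {
  jsonlite::write_json(flows, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Rank-based comparison of PRS across groups
#'
#' Two groups: two-sided Wilcoxon rank-sum (exact when both groups have at
#' most 25 untied values, normal approximation with continuity and tie
#' correction otherwise). Three or more groups: Kruskal-Wallis with tie
#' correction.
#'
#' @param values Numeric vector (e.g. PRS values).
#' @param labels Group labels, same length.
#' @return List with `method`, `statistic`, `p.value`, `groups`.
#' @export
rank_group_compare <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  gs <- split(values, labels)
  if (length(gs) < 2L) stop("need at least two groups")
  if (length(gs) == 2L) {
    exact <- !any(duplicated(values)) && max(lengths(gs)) <= 25L
    ht <- stats::wilcox.test(gs[[1]], gs[[2]], exact = exact,
                             correct = !exact)
    list(method = "wilcoxon_rank_sum", statistic = unname(ht$statistic),
         p.value = ht$p.value, groups = names(gs))
  } else {
    ht <- stats::kruskal.test(values, factor(labels))
    list(method = "kruskal_wallis", statistic = unname(ht$statistic),
         p.value = ht$p.value, groups = names(gs))
  }
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# Mann-Whitney counts, ties counted 1/2 (midrank identity).
.jt_statistic <- function(gs) {
  k <- length(gs)
  jt <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ni <- length(gs[[i]]); nj <- length(gs[[j]])
      r <- rank(c(gs[[i]], gs[[j]]))
      jt <- jt + sum(r[ni + seq_len(nj)]) - nj * (nj + 1) / 2
    }
  }
  jt
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests for a monotone increasing trend in a numeric variable across
#' rank-ordered categories (e.g. PRS across increasing extent of family
#' history). The statistic is the sum over ordered category pairs of
#' Mann-Whitney exceedance counts, ties counted one half. For total n at
#' most 8 the one-sided p-value is computed by exhaustive permutation of
#' the group assignment; otherwise a normal approximation with tie-corrected
#' variance is used. If every value is tied the statistic sits at its null
#' mean and the one-sided p-value is 0.5.
#'
#' @param values Numeric vector.
#' @param ordered_labels Category labels; an ordered factor, or a factor /
#'   character vector whose level order (or order of first appearance) gives
#'   the hypothesized ranking. At least 3 categories are required.
#' @param exact_max Largest total n for which the exact permutation null is
#'   enumerated (default 8).
#' @return List with `statistic`, `null_mean`, `p.value` (one-sided,
#'   increasing trend), `method`.
#' @export
trend_test <- function(values, ordered_labels, exact_max = 8L) {
  keep <- !is.na(values) & !is.na(ordered_labels)
  values <- values[keep]; ordered_labels <- ordered_labels[keep]
  if (is.factor(ordered_labels)) {
    lv <- levels(ordered_labels)
  } else {
    lv <- unique(as.character(ordered_labels))
  }
  f <- factor(as.character(ordered_labels), levels = lv)
  if (nlevels(droplevels(f)) < 3L) stop("need at least 3 ordered categories")
  f <- droplevels(f)
  gs <- split(values, f)
  n_i <- lengths(gs)
  n <- sum(n_i)
  jt <- .jt_statistic(gs)
  null_mean <- (n^2 - sum(n_i^2)) / 4

  if (n <= exact_max) {
    perms <- .permutations(n)
    grp <- rep(seq_along(gs), n_i)
    ge <- 0L
    for (r in seq_len(nrow(perms))) {
      gs_p <- split(values[perms[r, ]], grp)
      if (.jt_statistic(gs_p) >= jt - 1e-9) ge <- ge + 1L
    }
    p <- ge / nrow(perms)
    method <- "jonckheere_terpstra_exact"
  } else {
    t_j <- table(values)
    a <- n * (n - 1) * (2 * n + 5) -
      sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
      sum(t_j * (t_j - 1) * (2 * t_j + 5))
    b <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
    cc <- sum(n_i * (n_i - 1)) * sum(t_j * (t_j - 1))
    v <- a / 72 + b / (36 * n * (n - 1) * (n - 2)) + cc / (8 * n * (n - 1))
    if (v <= 0) {
      p <- 0.5
    } else {
      p <- stats::pnorm((jt - null_mean) / sqrt(v), lower.tail = FALSE)
    }
    method <- "jonckheere_terpstra_normal"
  }
  list(statistic = jt, null_mean = null_mean, p.value = p, method = method)
}

# all permutations of 1..n as rows (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    unname(cbind(first, sub + (sub >= first)))
  }))
}

#' Squared Pearson correlation with its two-sided test
#'
#' @param x,y Paired numeric vectors (at least 3 complete pairs, nonzero
#'   variance in both).
#' @return List with `r`, `r2` and two-sided `p.value`.
#' @export
pearson_r2 <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ht$estimate)
  list(r = r, r2 = r^2, p.value = ht$p.value)
}

#' Descriptive PRS summaries by group
#'
#' Per-group n, mean, sample SD, median and quartiles (linear-interpolation
#' percentiles, matching the quintile convention). Groups with no values are
#' dropped with a warning; a single-value group reports `NA` for the SD.
#'
#' @param values Numeric vector.
#' @param labels Group labels.
#' @return Data frame with one row per non-empty group.
#' @export
summarize_prs_by_group <- function(values, labels) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- factor(labels[keep],
                   levels = if (is.factor(labels)) levels(labels)
                            else unique(as.character(labels)))
  empty <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  }
  gs <- split(values, droplevels(labels))
  out <- do.call(rbind, lapply(names(gs), function(g) {
    v <- gs[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
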