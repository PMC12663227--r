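#' Germination success with a Wilson 95% confidence interval
#'
#' Point estimate `germinated / total` with the Wilson score interval, which
#' behaves well at 0/n and n/n. Vectorized over counts.
#'
#' @param germinated,total non-negative counts, `germinated <= total`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame: `germinated`, `total`, `estimate`, `lower`, `upper`.
#' @examples
#' germination_success(138, 151)$estimate  # 0.914
#' @export
germination_success <- function(germinated, total, conf_level = 0.95) {
  stopifnot(length(germinated) == length(total))
  if (any(total <= 0) || any(germinated < 0) || any(germinated > total))
    stop("need 0 <= germinated <= total, total > 0", call. = FALSE)
  p <- germinated / total
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / total
  center <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  data.frame(germinated = germinated, total = total, estimate = p,
             lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Holobiont fitness index
#'
#' The product of germination success and the fraction of spores harboring
#' bacteria: the fraction of viable offspring that carry the endosymbiont.
#' Commutative and bounded in \[0, 1\].
#'
#' @param germination_success,positive_fraction fractions in \[0, 1\].
#' @return unitless fitness index.
#' @export
fitness_index <- function(germination_success, positive_fraction) {
  if (any(germination_success < 0 | germination_success > 1) ||
      any(positive_fraction < 0 | positive_fraction > 1))
    stop("both fractions must be in [0, 1]", call. = FALSE)
  germination_success * positive_fraction
}

#' Split a positive spore population into low (B+) and high (B++) load halves
#'
#' Median split of the per-spore load vector: B+ is the lower 50% of the
#' positive population, B++ the upper 50%. With an odd count the median
#' element goes to B+. If all loads are equal the split is size-balanced but
#' arbitrary and flagged degenerate.
#'
#' @param loads non-negative per-spore load values (a.u.).
#' @return list of class `load_gate`: `b_plus`, `b_plusplus` (values),
#'   `index_b_plus`, `index_b_plusplus` (indices into `loads`), `degenerate`.
#' @export
gate_by_load <- function(loads) {
  if (length(loads) == 0L) stop("empty load vector", call. = FALSE)
  if (any(loads < 0)) stop("loads must be >= 0", call. = FALSE)
  ord <- order(loads)
  n_low <- ceiling(length(loads) / 2)
  idx_low <- ord[seq_len(n_low)]
  idx_high <- ord[setdiff(seq_along(ord), seq_len(n_low))]
  structure(list(b_plus = loads[idx_low], b_plusplus = loads[idx_high],
                 index_b_plus = idx_low, index_b_plusplus = idx_high,
                 degenerate = length(unique(loads)) == 1L),
            class = "load_gate")
}

#' Normalize positive-spore germination success to negative spores
#'
#' @param pos_success,neg_success fractions; `neg_success` must be > 0.
#' @return ratio `pos_success / neg_success`.
#' @export
normalize_to_negative <- function(pos_success, neg_success) {
  if (any(neg_success <= 0))
    stop("negative-spore success must be > 0", call. = FALSE)
  pos_success / neg_success
}

#' Bacterial retention by storage day
#'
#' Summarizes per-germling bacteria-present flags into a per-day table of the
#' fraction of germlings that retained bacteria.
#'
#' @param day storage day of each tested germling.
#' @param positive logical: bacteria detected in the germling.
#' @return data.frame: `day`, `n_tested`, `n_positive`, `fraction_retained`.
#' @export
retention_summary <- function(day, positive) {
  stopifnot(length(day) == length(positive), is.logical(positive))
  sp <- split(positive, day)
  data.frame(day = as.numeric(names(sp)),
             n_tested = lengths(sp),
             n_positive = vapply(sp, sum, integer(1)),
             fraction_retained = vapply(sp, mean, numeric(1)),
             row.names = NULL)
}

#' Nonparametric group comparison
#'
#' Either the omnibus Kruskal-Wallis test followed by Dunn's rank-based
#' post-hoc z test with Bonferroni correction over all pairwise comparisons
#' (two-sided), or all pairwise two-sided Mann-Whitney U tests with
#' Benjamini-Hochberg FDR adjustment. A compact letter display at `alpha`
#' summarizes which groups differ. Groups with fewer than 2 observations are
#' excluded with a warning.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @param method `"kruskal-dunn"` or `"mann-whitney"`.
#' @param alpha significance level for the letter display.
#' @return object of class `group_comparison`: list with `method`, `omnibus`
#'   (for kruskal-dunn), `pairwise` (data.frame: `group1`, `group2`,
#'   `statistic`, `p`, `p_adj`), `letters` (named character), `alpha`.
#' @export
group_compare <- function(values, groups,
                          method = c("kruskal-dunn", "mann-whitney"),
                          alpha = 0.05) {
  method <- match.arg(method)
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0L) {
    warning("excluding groups with < 2 observations: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2)

  omnibus <- NULL
  if (method == "kruskal-dunn") {
    kw <- stats::kruskal.test(values, factor(groups))
    omnibus <- data.frame(statistic = unname(kw$statistic),
                          df = unname(kw$parameter), p = kw$p.value)
    dunn <- dunn_pairwise(values, groups, pairs)
    dunn$p_adj <- pmin(1, dunn$p * ncol(pairs))  # Bonferroni
    pw <- dunn
  } else {
    stat <- p <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      wt <- suppressWarnings(
        stats::wilcox.test(values[groups == pairs[1, j]],
                           values[groups == pairs[2, j]],
                           alternative = "two.sided"))
      stat[j] <- unname(wt$statistic)
      p[j] <- wt$p.value
    }
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     statistic = stat, p = p,
                     p_adj = stats::p.adjust(p, method = "BH"))
  }
  letters <- letter_display(lev, pw, alpha)
  structure(list(method = method, omnibus = omnibus, pairwise = pw,
                 letters = letters, alpha = alpha),
            class = "group_comparison")
}

# Dunn's z statistic with tie correction
dunn_pairwise <- function(values, groups, pairs) {
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  sizes <- table(groups)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], statistic = z, p = p)
}

# insert-and-absorb compact letter display
letter_display <- function(lev, pairwise, alpha) {
  sets <- list(lev)
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    a <- sig$group1[j]; b <- sig$group2[j]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (k in seq_along(new_sets)) {
        if (i != k && keep[i] && keep[k] &&
            all(new_sets[[i]] %in% new_sets[[k]]) &&
            !(all(new_sets[[k]] %in% new_sets[[i]]) && i < k)) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  out <- stats::setNames(rep("", length(lev)), lev)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group comparison (", x$method, ")\n", sep = "")
  if (!is.null(x$omnibus))
    cat(sprintf("  Kruskal-Wallis: chi^2 = %.4g, df = %d, p = %.4g\n",
                x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  print(x$pairwise, row.names = FALSE)
  cat("  letters (alpha =", x$alpha, "):",
      paste(names(x$letters), x$letters, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Enrichment fraction with optional hypergeometric test
#'
#' Percentage of hits in a gene set, reported to one decimal, with an optional
#' one-sided hypergeometric enrichment p value against a genome background.
#'
#' @param hits,total foreground counts, `0 <= hits <= total`.
#' @param hits_bg,total_bg optional background counts for the hypergeometric
#'   tail probability of observing `>= hits` by drawing `total` genes from a
#'   background of `total_bg` genes of which `hits_bg` are in the category.
#' @return list of class `enrichment_fraction`: `percent` (one decimal),
#'   `fraction`, `hits`, `total`, and `p_hyper` when a background is given.
#' @examples
#' enrichment_fraction(20, 591)$percent    # 3.4
#' enrichment_fraction(401, 21522)$percent # 1.9
#' @export
enrichment_fraction <- function(hits, total, hits_bg = NULL, total_bg = NULL) {
  if (hits < 0 || total <= 0 || hits > total)
    stop("need 0 <= hits <= total, total > 0", call. = FALSE)
  out <- list(percent = round(100 * hits / total, 1),
              fraction = hits / total, hits = hits, total = total)
  if (!is.null(hits_bg) && !is.null(total_bg)) {
    out$p_hyper <- stats::phyper(hits - 1, hits_bg, total_bg - hits_bg,
                                 total, lower.tail = FALSE)
  }
  class(out) <- "enrichment_fraction"
  out
}

#' @export
print.enrichment_fraction <- function(x, ...) {
  cat(sprintf("%d / %d = %.1f%%", x$hits, x$total, x$percent))
  if (!is.null(x$p_hyper)) cat(sprintf(" (hypergeometric p = %.3g)", x$p_hyper))
  cat("\n")
  invisible(x)
}
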