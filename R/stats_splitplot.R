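# Split-plot (mixed) repeated-measures ANOVA with one between-subject factor
# (HD group) and three crossed within-subject factors (gum, drug, block),
# with Greenhouse-Geisser correction, Bonferroni pairwise follow-ups, change
# scores, and Pearson correlation helpers.
#
# Sums of squares are computed directly from cell and marginal means via
# inclusion-exclusion (valid for the balanced complete design this package
# enforces), with subject-stratified error terms: subjects-within-groups for
# the between effect, and the W x subject-within-group interaction for every
# within effect whose within-factor part is W.

WITHIN_FACTORS <- c("gum", "drug", "block")

# mean of `arr` over the dims not in `keep`, expanded back to full shape
marginal_expand <- function(arr, keep) {
  dims <- dim(arr)
  all_d <- seq_along(dims)
  if (length(keep) == 0) return(array(mean(arr), dims))
  keep <- sort(keep)
  rest <- setdiff(all_d, keep)
  if (length(rest) == 0) return(arr)
  m <- aperm(arr, c(rest, keep))
  mm <- .colMeans(m, prod(dims[rest]), prod(dims[keep]))
  full <- array(mm, dim = c(dims[keep], dims[rest]))
  aperm(full, order(c(keep, rest)))
}

# all subsets of an index vector (combn would misread a length-1 set)
subsets_of <- function(v) {
  out <- list(integer(0))
  for (x in v) {
    out <- c(out, lapply(out, function(s) c(s, x)))
  }
  out
}

# normalized Helmert-style orthonormal contrast columns for l levels
.contrast_cache <- new.env(parent = emptyenv())
orthonormal_contrasts <- function(l) {
  key <- as.character(l)
  if (is.null(.contrast_cache[[key]])) {
    q <- qr.Q(qr(cbind(1, stats::contr.helmert(l))))
    .contrast_cache[[key]] <- q[, -1, drop = FALSE]
  }
  .contrast_cache[[key]]
}

#' Box/Greenhouse-Geisser epsilon from a within-factor covariance matrix
#'
#' Computes Box's sphericity index from the double-centered covariance of a
#' k-level repeated factor: `eps = (sum lambda)^2 / ((k - 1) * sum lambda^2)`
#' over the nonzero eigenvalues of the double-centered matrix. Equals 1
#' under compound symmetry and is bounded below by `1/(k - 1)`.
#'
#' @param within_cov Symmetric positive semi-definite k x k covariance
#'   matrix, k >= 2.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(within_cov) {
  within_cov <- as.matrix(within_cov)
  k <- nrow(within_cov)
  if (k < 2 || ncol(within_cov) != k) {
    stop("within_cov must be a square matrix with k >= 2")
  }
  if (max(abs(within_cov - t(within_cov))) > 1e-8 * max(1, max(abs(within_cov)))) {
    stop("within_cov must be symmetric")
  }
  ctr <- diag(k) - 1 / k
  b <- ctr %*% within_cov %*% ctr
  tr <- sum(diag(b))
  tr2 <- sum(b * b)
  if (tr2 <= 0) return(1) # degenerate: no within variance
  (tr^2) / ((k - 1) * tr2)
}

box_epsilon_from_scores <- function(z, group) {
  # pooled within-group covariance of orthonormal contrast scores
  d <- ncol(z)
  if (d == 1) return(1)
  n <- nrow(z)
  g <- factor(group)
  means <- rowsum(z, g) / as.integer(table(g)) # rows in level order
  centered <- z - means[as.integer(g), , drop = FALSE]
  s <- crossprod(centered) / (n - nlevels(g))
  tr <- sum(diag(s))
  tr2 <- sum(s * s)
  if (tr2 <= 0) return(1)
  (tr^2) / (d * tr2)
}

check_long_table <- function(data, dv) {
  need <- c("subject", "group", WITHIN_FACTORS, dv)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[need])) stop("missing values are not allowed (complete crossover design)")
  data
}

#' Split-plot repeated-measures ANOVA
#'
#' Fits the 2 (group, between) x 2 (gum) x 2 (drug) x 3 (block) split-plot
#' ANOVA used for every dependent measure in this design. Sums of squares
#' are formed from cell/marginal means (balanced complete data required; no
#' imputation), the between effect is tested against subjects-within-groups,
#' and each within effect against its own factor x subject-within-group
#' interaction. Greenhouse-Geisser epsilon is estimated per within-factor
#' combination from the pooled within-group covariance of orthonormal
#' contrast scores and applied to every effect with more than one numerator
#' contrast (for 2-level factors epsilon is identically 1); both raw and
#' corrected p values are always reported.
#'
#' @param data Long-format data.frame with columns `subject`, `group`,
#'   `gum`, `drug`, `block`, and the dependent variable. Every subject must
#'   have exactly one observation per gum x drug x block cell, one group
#'   label, and groups must be of equal size (>= 2 subjects each).
#' @param dv Name of the dependent-variable column (default `"value"`).
#' @return An object of class `splitplot_anova`: `table` (one row per
#'   effect: `effect`, `ss`, `df1`, `df2`, `ms`, `ss_error`, `ms_error`,
#'   `F`, `epsilon`, `p`, `p_gg`), `strata` (error-term SS/df), `cell_means`,
#'   and `n_per_group`. Effects with zero error variance report `F = NA`.
#' @export
split_plot_anova <- function(data, dv = "value") {
  data <- check_long_table(as.data.frame(data), dv)
  subj <- factor(data$subject)
  fx <- lapply(data[WITHIN_FACTORS], factor)
  lv <- vapply(fx, nlevels, integer(1))
  n_s <- nlevels(subj)

  g_by_subj <- tapply(as.character(data$group), subj, unique)
  if (any(lengths(g_by_subj) != 1)) {
    stop("each subject must carry exactly one group label")
  }
  group <- factor(unlist(g_by_subj))
  n_g <- nlevels(group)
  if (n_g < 2) stop("need at least two groups")
  gsize <- table(group)
  if (length(unique(gsize)) != 1 || any(gsize < 2)) {
    stop("groups must be balanced with >= 2 subjects each")
  }
  n_per_group <- unname(gsize[1])

  cell_id <- interaction(subj, fx$gum, fx$drug, fx$block, drop = FALSE)
  counts <- table(cell_id)
  if (nrow(data) != n_s * prod(lv) || any(counts != 1)) {
    stop("design is unbalanced or incomplete: every subject needs exactly ",
         "one observation per gum x drug x block cell")
  }

  # subject-level response array [subject, gum, drug, block]
  y <- array(NA_real_, dim = c(n_s, lv),
             dimnames = c(list(levels(subj)), lapply(fx, levels)))
  y[cbind(as.integer(subj), as.integer(fx$gum), as.integer(fx$drug),
          as.integer(fx$block))] <- data[[dv]]

  # group-cell mean array [group, gum, drug, block]
  gm <- array(0, dim = c(n_g, lv),
              dimnames = c(list(levels(group)), lapply(fx, levels)))
  for (gi in seq_len(n_g)) {
    gm[gi, , , ] <- colMeans(y[group == levels(group)[gi], , , ,
                               drop = FALSE], dims = 1)
  }

  within_subsets <- subsets_of(1:3)

  # marginal means are shared across effects: memoize per keep-set
  marg_y <- local({
    cache <- list()
    function(keep) {
      key <- paste0("k", paste(keep, collapse = ","))
      if (is.null(cache[[key]])) cache[[key]] <<- marginal_expand(y, keep)
      cache[[key]]
    }
  })
  marg_gm <- local({
    cache <- list()
    function(keep) {
      key <- paste0("k", paste(keep, collapse = ","))
      if (is.null(cache[[key]])) cache[[key]] <<- marginal_expand(gm, keep)
      cache[[key]]
    }
  })
  ie_component <- function(margfun, retain, eff) {
    comp <- 0
    for (s in subsets_of(eff)) {
      comp <- comp + (-1)^(length(eff) - length(s)) *
        margfun(sort(c(retain, s)))
    }
    comp
  }

  # error strata: W = integer(0) is the between stratum
  strata <- list()
  for (w in within_subsets) {
    d_sub <- ie_component(marg_y, 1L, 1L + w)
    d_grp <- ie_component(marg_gm, 1L, 1L + w)[as.integer(group), , , ,
                                               drop = FALSE]
    ss_err <- sum((d_sub - d_grp)^2)
    df_err <- (n_s - n_g) * prod(pmax(lv[w] - 1, 1))
    strata[[paste(c("subj", WITHIN_FACTORS[w]), collapse = ":")]] <-
      list(w = w, ss = ss_err, df = df_err)
  }

  # epsilon per within stratum from orthonormal contrast scores
  yv <- matrix(aperm(y, c(2, 3, 4, 1)), nrow = n_s, byrow = TRUE)
  # yv rows: subject; columns vectorized with gum fastest (matches kronecker
  # of the per-factor contrast matrices below)
  eps_by_w <- list()
  for (w in within_subsets) {
    if (length(w) == 0) { eps_by_w[["0"]] <- 1; next }
    mats <- lapply(1:3, function(f) {
      if (f %in% w) orthonormal_contrasts(lv[f])
      else matrix(1 / sqrt(lv[f]), lv[f], 1)
    })
    kmat <- kronecker(mats[[3]], kronecker(mats[[2]], mats[[1]]))
    z <- yv %*% kmat
    eps_by_w[[paste(w, collapse = "")]] <- box_epsilon_from_scores(z, group)
  }

  rows <- list()
  for (w in within_subsets) {
    for (with_g in c(FALSE, TRUE)) {
      if (length(w) == 0 && !with_g) next # grand mean: not an effect
      name <- paste(c(if (with_g) "group" else NULL, WITHIN_FACTORS[w]),
                    collapse = ":")
      comp <- ie_component(marg_gm, integer(0),
                           c(if (with_g) 1L else NULL, 1L + w))
      ss <- n_per_group * sum(comp^2)
      df1 <- prod(c(if (with_g) n_g - 1 else NULL, lv[w] - 1))
      stratum <- strata[[paste(c("subj", WITHIN_FACTORS[w]), collapse = ":")]]
      eps <- eps_by_w[[if (length(w) == 0) "0" else paste(w, collapse = "")]]
      ms <- ss / df1
      ms_err <- stratum$ss / stratum$df
      fval <- if (ms_err > 0) ms / ms_err else NA_real_
      rows[[name]] <- list(name, ss, df1, stratum$df, ms, stratum$ss, ms_err,
                           fval, eps)
    }
  }
  get_col <- function(i) vapply(rows, function(r) as.numeric(r[[i]]), 0)
  tab <- data.frame(effect = vapply(rows, `[[`, "", 1),
                    ss = get_col(2), df1 = get_col(3), df2 = get_col(4),
                    ms = get_col(5), ss_error = get_col(6),
                    ms_error = get_col(7), F = get_col(8),
                    epsilon = get_col(9), stringsAsFactors = FALSE)
  tab$p <- ifelse(is.na(tab$F), NA_real_,
                  stats::pf(tab$F, tab$df1, tab$df2, lower.tail = FALSE))
  tab$p_gg <- ifelse(is.na(tab$F), NA_real_,
                     stats::pf(tab$F, tab$epsilon * tab$df1,
                               tab$epsilon * tab$df2, lower.tail = FALSE))
  rownames(tab) <- NULL

  cm <- as.data.frame.table(gm, responseName = "mean")
  names(cm) <- c("group", WITHIN_FACTORS, "mean")
  structure(list(table = tab,
                 strata = do.call(rbind, lapply(names(strata), function(nm) {
                   data.frame(stratum = nm, ss = strata[[nm]]$ss,
                              df = strata[[nm]]$df, stringsAsFactors = FALSE)
                 })),
                 cell_means = cm, n_per_group = n_per_group,
                 dv = dv), class = "splitplot_anova")
}

#' @export
print.splitplot_anova <- function(x, digits = 4, ...) {
  cat("Split-plot ANOVA on '", x$dv, "' (", x$n_per_group,
      " subjects/group)\n\n", sep = "")
  tab <- x$table
  tab$ss <- signif(tab$ss, digits)
  tab$F <- signif(tab$F, digits)
  tab$epsilon <- signif(tab$epsilon, digits)
  tab$p <- signif(tab$p, digits)
  tab$p_gg <- signif(tab$p_gg, digits)
  print(tab[c("effect", "df1", "df2", "ss", "F", "epsilon", "p", "p_gg")],
        row.names = FALSE)
  invisible(x)
}

#' Bonferroni-adjusted pairwise comparisons of cell means
#'
#' Pairwise t comparisons of a table of cell means against a supplied error
#' term (normally the `ms_error`/`df2` of the effect being followed up),
#' with `p_adj = min(1, m * p_raw)`.
#'
#' @param cells Data.frame with columns `label`, `mean`, `n` (observations
#'   per cell mean).
#' @param ms_error,df_error Error mean square and its degrees of freedom.
#' @param m Family size for the Bonferroni adjustment; defaults to the
#'   number of pairs actually compared.
#' @param alpha Significance level for the `significant` flag.
#' @return A data.frame of class `pairwise_comparisons`: one row per pair
#'   with `diff`, `se`, `t`, `p_raw`, `p_bonferroni`, `significant`, plus the
#'   family size in attribute `m`.
#' @export
bonferroni_pairwise <- function(cells, ms_error, df_error, m = NULL,
                                alpha = 0.05) {
  stopifnot(all(c("label", "mean", "n") %in% names(cells)))
  if (nrow(cells) < 2) stop("need at least two cells to compare")
  pairs <- utils::combn(nrow(cells), 2)
  if (is.null(m)) m <- ncol(pairs)
  if (m < 1) stop("family size m must be >= 1")
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- cells$mean[i] - cells$mean[j]
    se <- sqrt(ms_error * (1 / cells$n[i] + 1 / cells$n[j]))
    tval <- diff / se
    p_raw <- 2 * stats::pt(-abs(tval), df_error)
    data.frame(a = cells$label[i], b = cells$label[j], diff = diff, se = se,
               t = tval, p_raw = p_raw,
               p_bonferroni = min(1, m * p_raw),
               significant = min(1, m * p_raw) < alpha,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "m") <- m
  class(res) <- c("pairwise_comparisons", class(res))
  res
}

#' Change scores relative to the double-placebo session
#'
#' Subtracts each subject's placebo (PG-PI) value from the value in each of
#' the three non-placebo sessions, within any additional grouping columns
#' present (e.g. block).
#'
#' @param measures Data.frame with columns `subject`, `gum`, `drug`, the
#'   value column, and optionally other key columns (kept and matched).
#' @param value_col Name of the value column (default `"value"`).
#' @param reference Named character vector giving the reference session
#'   (default `c(gum = "PG", drug = "PI")`).
#' @return The non-reference rows with an added `delta` column (session value
#'   minus the subject's reference value).
#' @export
change_scores <- function(measures, value_col = "value",
                          reference = c(gum = "PG", drug = "PI")) {
  measures <- as.data.frame(measures)
  need <- c("subject", "gum", "drug", value_col)
  if (!all(need %in% names(measures))) {
    stop("measures must contain columns: ", paste(need, collapse = ", "))
  }
  key_cols <- setdiff(names(measures), c("gum", "drug", value_col))
  is_ref <- measures$gum == reference["gum"] & measures$drug == reference["drug"]
  ref <- measures[is_ref, c(key_cols, value_col)]
  names(ref)[names(ref) == value_col] <- ".ref_value"
  rest <- measures[!is_ref, , drop = FALSE]
  merged <- merge(rest, ref, by = key_cols, all.x = TRUE, sort = FALSE)
  if (anyNA(merged$.ref_value)) {
    stop("missing reference (", reference["gum"], "-", reference["drug"],
         ") session for some subjects")
  }
  merged$delta <- merged[[value_col]] - merged$.ref_value
  merged$.ref_value <- NULL
  merged
}

#' Pearson correlation between MMN amplitude and d-prime
#'
#' Standard Pearson r with a two-sided t-based p value, for paired values
#' collapsed across groups and time blocks (placebo data or change scores).
#'
#' @param mmn_values,dprime_values Paired numeric vectors, length >= 3.
#' @return A one-row data.frame: `r`, `df`, `t`, `p`, `n`.
#' @export
mmn_dprime_correlation <- function(mmn_values, dprime_values) {
  if (length(mmn_values) != length(dprime_values)) {
    stop("inputs must be paired vectors of equal length")
  }
  if (length(mmn_values) < 3) stop("need at least 3 pairs")
  if (stats::var(mmn_values) == 0 || stats::var(dprime_values) == 0) {
    stop("zero variance in one of the vectors")
  }
  ct <- stats::cor.test(mmn_values, dprime_values, method = "pearson")
  data.frame(r = unname(ct$estimate), df = unname(ct$parameter),
             t = unname(ct$statistic), p = ct$p.value,
             n = length(mmn_values))
}

#' Simulate a null split-plot dataset with non-spherical covariance
#'
#' Generates balanced long-format data with no mean effects: each subject's
#' 12 within-cell values are drawn from a multivariate normal whose
#' covariance is `session_cov` (4 x 4, gum x drug cells) combined with
#' `block_cov` (3 x 3) as a Kronecker product. Used for type-I-error
#' calibration of the Greenhouse-Geisser corrected block tests.
#'
#' @param n_per_group Subjects per group.
#' @param block_cov 3 x 3 within-block covariance; the default
#'   `diag(c(1, 2, 4)) + 0.3` is deliberately non-spherical.
#' @param session_cov 4 x 4 across-session covariance (default exchangeable
#'   with correlation 0.3).
#' @param seed Optional integer seed.
#' @return A long-format data.frame suitable for [split_plot_anova()].
#' @export
simulate_null_splitplot <- function(n_per_group = 12,
                                    block_cov = diag(c(1, 2, 4)) + 0.3,
                                    session_cov = 0.3 + 0.7 * diag(4),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- kronecker(block_cov, session_cov)
  rt <- chol(sigma)
  n_s <- 2L * n_per_group
  z <- matrix(stats::rnorm(n_s * 12), n_s, 12) %*% rt
  grid <- expand.grid(gum = GUM_LEVELS, drug = DRUG_LEVELS,
                      block = 1:3, stringsAsFactors = FALSE)
  data.frame(subject = rep(seq_len(n_s), each = 12),
             group = rep(rep(GROUP_LEVELS, each = n_per_group), each = 12),
             gum = rep(grid$gum, n_s), drug = rep(grid$drug, n_s),
             block = rep(grid$block, n_s),
             value = as.vector(t(z)), stringsAsFactors = FALSE)
}
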