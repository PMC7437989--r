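#' Aggregate per-point results to the cup level
#'
#' The unit of statistical analysis is the cup: the twelve measurement
#' points of a cup are averaged into one mean (and SD) per parameter, and
#' cohort tests then run on n = 3 cup means per group. Flagged points
#' (failed fits, clipped areas) are excluded and counted; parameters that
#' are undefined at single points (e.g. the orientation ratio when
#' A1065 = 0) are dropped point-wise.
#'
#' @param points data frame of per-point results; any numeric columns named
#'   in `parameters` are summarized. A logical `flagged` column marks
#'   points to exclude (absent = none flagged).
#' @param parameters character vector of parameter columns to summarize.
#' @return list of class `cup_summary`: `mean` and `sd` named vectors,
#'   `n_valid`, `n_flagged`, `n_points`.
#' @export
summarize_cup <- function(points,
                          parameters = c("alpha_o", "alpha_a", "alpha_b",
                                         "all_trans", "ortho_trans",
                                         "ratio_1130_1065")) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L)
  flagged <- if ("flagged" %in% names(points)) isTRUE_vec(points$flagged) else
    rep(FALSE, nrow(points))
  keep <- !flagged
  if (!any(keep)) {
    stop("all ", nrow(points), " points flagged: cup excluded", call. = FALSE)
  }
  parameters <- intersect(parameters, names(points))
  m <- vapply(parameters, function(p) mean(points[[p]][keep], na.rm = TRUE), 1.0)
  s <- vapply(parameters, function(p) stats::sd(points[[p]][keep], na.rm = TRUE), 1.0)
  structure(list(mean = m, sd = s, n_valid = sum(keep),
                 n_flagged = sum(flagged), n_points = nrow(points)),
            class = "cup_summary")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# --- Kruskal-Wallis with exact permutation tail ------------------------------

# Enumerate the group rank-sum vectors of every distinct assignment of the
# pooled ranks into groups of the given sizes. Row count is the multinomial
# coefficient; the statistic ordering only needs U = sum(R_j^2 / n_j).
rank_sum_enumeration <- function(vals, sizes) {
  k <- length(sizes)
  if (k == 1L) return(matrix(sum(vals), 1L, 1L))
  cmb <- utils::combn(seq_along(vals), sizes[1])
  parts <- vector("list", ncol(cmb))
  for (j in seq_len(ncol(cmb))) {
    s1 <- sum(vals[cmb[, j]])
    rest <- rank_sum_enumeration(vals[-cmb[, j]], sizes[-1L])
    parts[[j]] <- cbind(s1, rest, deparse.level = 0)
  }
  do.call(rbind, parts)
}

.kw_cache <- new.env(parent = emptyenv())

# Null distribution of U = sum(R_j^2/n_j) over all assignments. Cached for
# the tie-free case (pooled ranks are then always 1..N for given sizes).
kw_exact_U_dist <- function(ranks, sizes) {
  tie_free <- !anyDuplicated(ranks)
  key <- if (tie_free) paste0("n", paste(sort(sizes), collapse = "_")) else NA
  if (tie_free && !is.null(.kw_cache[[key]])) return(.kw_cache[[key]])
  rs <- rank_sum_enumeration(ranks, sizes)
  U <- as.vector(rs^2 %*% (1 / sizes))
  if (tie_free) .kw_cache[[key]] <- U
  U
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based omnibus comparison of k groups with mid-rank tie handling.
#' The H statistic and the chi-squared approximation (df = k - 1) come
#' from [stats::kruskal.test()]; for the small cohorts this package is
#' built for (total N <= `exact_max`, e.g. 4 materials x 3 cup means) the
#' p value is instead computed exactly by enumerating every assignment of
#' the pooled ranks to the groups, since the asymptotic approximation is
#' poor at n = 3 per group.
#'
#' @param groups list of >= 2 numeric vectors (e.g. cup means per
#'   material), each non-empty.
#' @param method `"auto"` (exact when total N <= `exact_max`), `"exact"`,
#'   or `"asymptotic"`.
#' @param exact_max largest total N for which `"auto"` enumerates.
#' @return list of class `kw_test`: `H`, `df`, `p` (by the chosen method),
#'   `p_chisq`, `method`, `rank_means`, `n`, `n_permutations` (exact only).
#' @export
kruskal_wallis <- function(groups, method = c("auto", "exact", "asymptotic"),
                           exact_max = 12L) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group must contain at least one value",
                            call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("groups must not contain NA", call. = FALSE)
  N <- length(x)
  if (N < 3L) stop("need a total of at least 3 observations", call. = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  p_chisq <- unname(kt$p.value)
  if (!is.finite(H)) {
    # every pooled value identical: no rank information at all
    H <- 0
    p_chisq <- 1
  }
  r <- rank(x)
  rank_means <- tapply(r, g, mean)
  names(rank_means) <- names(groups) %||% paste0("group", seq_along(groups))

  use_exact <- method == "exact" || (method == "auto" && N <= exact_max)
  if (use_exact) {
    U <- kw_exact_U_dist(r, sizes)
    U_obs <- sum(tapply(r, g, sum)^2 / sizes)
    p <- mean(U >= U_obs - 1e-9)
    res_method <- "exact permutation"
    nperm <- length(U)
  } else {
    p <- p_chisq
    res_method <- "chi-squared approximation"
    nperm <- NA_integer_
  }
  structure(list(H = H, df = length(groups) - 1L, p = p,
                 p_chisq = p_chisq, method = res_method,
                 rank_means = rank_means, n = sizes, n_permutations = nperm),
            class = "kw_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (%s)\n",
              x$H, x$df, x$p, x$method))
  invisible(x)
}

#' Dunn post-hoc comparisons with Bonferroni adjustment
#'
#' Pairwise Dunn z statistics on the pooled mid-ranks with the standard tie
#' correction; two-sided normal p values adjusted by Bonferroni over the
#' k(k-1)/2 comparisons (`p_adj = min(1, raw * m)`), and a compact letter
#' display at level `alpha` (groups sharing a letter are not significantly
#' different). Comparisons are computed even when the omnibus test is not
#' significant, but the result is then flagged `post_hoc_not_licensed` to
#' mirror the conditional protocol of only interpreting the post hoc after
#' a significant omnibus test.
#'
#' @inheritParams kruskal_wallis
#' @param alpha significance level for the letter display.
#' @param omnibus optional [kruskal_wallis()] result on the same groups
#'   (computed if missing) used for the licensing flag.
#' @return list of class `dunn_test`: `comparisons` data frame (`group1`,
#'   `group2`, `z`, `p_raw`, `p_adj`, `significant`), `letters` named
#'   character vector, `alpha`, `flags`.
#' @export
dunn_bonferroni <- function(groups, alpha = 0.05, omnibus = NULL,
                            method = c("auto", "exact", "asymptotic")) {
  stopifnot(is.list(groups))
  if (length(groups) < 2L) {
    stop("post-hoc comparisons need at least two groups", call. = FALSE)
  }
  method <- match.arg(method)
  if (is.null(omnibus)) omnibus <- kruskal_wallis(groups, method = method)
  sizes <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  g <- factor(rep(seq_along(groups), sizes))
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_term
  gnames <- names(groups) %||% paste0("group", seq_along(groups))
  pairs <- utils::combn(length(groups), 2L)
  m <- ncol(pairs)
  comp <- data.frame(group1 = gnames[pairs[1, ]], group2 = gnames[pairs[2, ]],
                     z = NA_real_, p_raw = NA_real_, p_adj = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(sigma2_base * (1 / sizes[i1] + 1 / sizes[i2]))
    z <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    comp$z[j] <- z
    comp$p_raw[j] <- 2 * stats::pnorm(-abs(z))
  }
  comp$p_adj <- stats::p.adjust(comp$p_raw, method = "bonferroni")
  comp$significant <- comp$p_adj < alpha
  letters_vec <- compact_letters(gnames, comp)
  flags <- if (omnibus$p >= alpha) "post_hoc_not_licensed" else character(0)
  structure(list(comparisons = comp, letters = letters_vec, alpha = alpha,
                 omnibus = omnibus, flags = flags),
            class = "dunn_test")
}

# Compact letter display: letters index the maximal cliques of the
# "not significantly different" graph, so two groups share a letter iff
# their adjusted p is >= alpha. Subset enumeration; fine for cohort-sized k.
compact_letters <- function(gnames, comparisons) {
  k <- length(gnames)
  if (k > 15L) stop("letter display supports at most 15 groups", call. = FALSE)
  adj <- matrix(TRUE, k, k, dimnames = list(gnames, gnames))
  for (j in seq_len(nrow(comparisons))) {
    if (comparisons$significant[j]) {
      adj[comparisons$group1[j], comparisons$group2[j]] <- FALSE
      adj[comparisons$group2[j], comparisons$group1[j]] <- FALSE
    }
  }
  is_clique <- function(members) all(adj[members, members])
  cliques <- list()
  for (code in seq_len(2^k - 1L)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0L)
    if (!is_clique(members)) next
    extendable <- any(vapply(setdiff(seq_len(k), members), function(v) {
      all(adj[v, members])
    }, TRUE))
    if (!extendable) cliques[[length(cliques) + 1L]] <- members
  }
  cliques <- cliques[order(vapply(cliques, min, 1L))]
  out <- stats::setNames(rep("", k), gnames)
  for (i in seq_along(cliques)) {
    lab <- letters[(i - 1L) %% 26L + 1L]
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], lab)
  }
  out
}

#' @export
print.dunn_test <- function(x, ...) {
  cat(sprintf("Dunn-Bonferroni post hoc (alpha = %g)%s\n", x$alpha,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  print(x$comparisons, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Percent change upon wear
#'
#' `100 * (after - before) / before`, elementwise. Undefined where
#' `before == 0` (returned as `NA` with a warning).
#'
#' @param before,after numeric vectors (recycled).
#' @return numeric vector of percent changes.
#' @export
percent_change <- function(before, after) {
  out <- 100 * (after - before) / before
  bad <- before == 0
  if (any(bad)) {
    warning("percent change undefined where before == 0; returning NA")
    out[bad] <- NA_real_
  }
  out
}

#' Least-squares trend of paired percent changes
#'
#' Ordinary least-squares line through (x, y) pairs — typically the percent
#' change in all-trans content against the percent change in ortho-trans
#' content across cups or groups — plus the Pearson correlation.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return list of class `trend_fit`: `slope`, `intercept`, `r`, `n`.
#' @export
trend_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("trend needs at least 2 finite points", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("x is constant: slope undefined", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::sd(y) == 0) {
    # flat but defined line: perfect fit, correlation degenerate
    NA_real_
  } else stats::cor(x, y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r = r, n = length(x)),
            class = "trend_fit")
}

#' Soak-corrected mass loss
#'
#' Loaded cups both lose material and absorb lubricant; non-loaded soak
#' controls stored in serum measure the absorption alone. The corrected
#' wear mass loss adds the material-matched mean soak-control gain back to
#' the measured loss: `corrected = measured_loss + mean(soak gain)`,
#' reported at the 0.01 mg balance resolution.
#'
#' @param gravimetry data frame with columns `role` (`loaded` /
#'   `soak_control`), `cup_id`, `material`, `measured_mass_change_mg`
#'   (loaded rows: measured mass loss, positive = lighter; soak rows:
#'   measured mass gain, positive = heavier).
#' @return data frame of loaded cups with `soak_gain_mg` (the material mean
#'   applied) and `corrected_mass_loss_mg`.
#' @export
correct_mass_loss <- function(gravimetry) {
  stopifnot(is.data.frame(gravimetry),
            all(c("role", "cup_id", "material", "measured_mass_change_mg")
                %in% names(gravimetry)))
  loaded <- gravimetry[gravimetry$role == "loaded", , drop = FALSE]
  soak <- gravimetry[gravimetry$role == "soak_control", , drop = FALSE]
  if (!nrow(loaded)) stop("no loaded cups in gravimetry", call. = FALSE)
  out <- loaded[, c("cup_id", "material", "measured_mass_change_mg")]
  out$soak_gain_mg <- NA_real_
  for (mat in unique(out$material)) {
    gains <- soak$measured_mass_change_mg[soak$material == mat]
    if (!length(gains)) {
      stop("no soak control for material ", mat,
           ": cannot correct mass loss", call. = FALSE)
    }
    out$soak_gain_mg[out$material == mat] <- mean(gains)
  }
  out$corrected_mass_loss_mg <-
    round(out$measured_mass_change_mg + out$soak_gain_mg, 2)
  out
}
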