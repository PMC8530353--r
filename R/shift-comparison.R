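#' Representative mid-shift autonomic indices
#'
#' The representative "driving" value of each autonomic index is its mean
#' over the quality-passing 120-s windows that start within the first
#' \code{span_min} minutes (default 30) after the initiation of driving work.
#'
#' @param anf_windows an \code{\link{compute_anf_series}} result.
#' @param driving_start_ms start of driving work, ms on the window clock.
#' @param span_min averaging span in minutes (default 30).
#' @return list with \code{values} (named means over the qualifying windows)
#'   and \code{n_windows}.
#' @export
representative_mid <- function(anf_windows, driving_start_ms,
                               span_min = 30) {
  span_ms <- span_min * 60 * 1000
  sel <- anf_windows$quality_pass &
    anf_windows$win_start_ms >= driving_start_ms &
    anf_windows$win_start_ms < driving_start_ms + span_ms
  if (!any(sel)) stop("no quality-passing windows in the representative span")
  idx <- c("avghr", "lf_score", "hf_score", "lfhf_ratio", "sdnn", "nn50",
           "rmssd")
  vals <- colMeans(anf_windows[sel, idx, drop = FALSE], na.rm = TRUE)
  list(values = vals, n_windows = sum(sel))
}

#' Tukey-Kramer all-pairs comparison
#'
#' Studentized-range all-pairs test honoring unequal group sizes, used when
#' every group passes the normality gate.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return data.frame with \code{group1}, \code{group2}, \code{p}.
#' @export
tukey_kramer <- function(groups) {
  check_groups(groups)
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      length(unique(unlist(groups))) == 1) {
    stop("zero pooled variance")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  hsd <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  data.frame(group1 = vapply(pairs, `[`, "", 2),
             group2 = vapply(pairs, `[`, "", 1),
             p = unname(hsd[, "p adj"]),
             row.names = NULL)
}

#' Steel-Dwass all-pairs comparison
#'
#' Nonparametric all-pairs procedure: each pair of groups is jointly ranked
#' (mid-ranks for ties, with the tie-corrected variance) and the standardized
#' rank-sum statistic is referred to the studentized-range distribution with
#' \code{k} groups (large-sample form).  For small groups
#' (\code{min(n) <= exact_max}) the pair's p-value is instead computed by
#' exhaustive enumeration of all assignments of the pooled observations,
#' i.e. the exact two-sided permutation tail of the standardized statistic.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param exact_max largest per-group size for the exact enumeration
#'   fallback (default 6).
#' @return data.frame with \code{group1}, \code{group2}, \code{p},
#'   \code{method} ("exact" or "large-sample").
#' @export
steel_dwass <- function(groups, exact_max = 6) {
  check_groups(groups)
  if (length(unique(unlist(groups))) == 1) stop("all observations tied")
  k <- length(groups)
  combs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    a <- groups[[i]]; b <- groups[[j]]
    na <- length(a); nb <- length(b); n <- na + nb
    r <- rank(c(a, b))
    t_obs <- sd_pair_stat(r, na)
    if (min(na, nb) <= exact_max) {
      sel <- utils::combn(n, na)
      t_null <- apply(sel, 2, function(s) sd_pair_stat(r, na, s))
      p <- mean(abs(t_null) >= abs(t_obs) - 1e-10)
      method <- "exact"
    } else {
      p <- 1 - stats::ptukey(sqrt(2) * abs(t_obs), nmeans = k, df = Inf)
      method <- "large-sample"
    }
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               p = p, method = method)
  })
  do.call(rbind, out)
}

# standardized rank-sum statistic of the first group (indices sel) within a
# jointly ranked pair; mid-ranks with tie-corrected variance
sd_pair_stat <- function(r, na, sel = seq_len(na)) {
  n <- length(r)
  w <- sum(r[sel])
  e <- na * (n + 1) / 2
  v <- na * (n - na) / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (v <= 0) return(0)
  (w - e) / sqrt(v)
}

check_groups <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be named")
  }
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  invisible(groups)
}

#' Compare autonomic indices across shift phases
#'
#' All-pairs comparison of each autonomic index between the pre-shift resting
#' state, the early mid-shift driving state and the post-shift resting state.
#' The test is gated on normality: if every phase's sample passes the
#' Shapiro-Wilk test at \code{alpha}, the parametric Tukey-Kramer procedure
#' is used; otherwise the nonparametric Steel-Dwass procedure.
#'
#' @param pre,mid,post data.frames (one row per driver) whose shared numeric
#'   columns are the indices to compare (e.g. \code{avghr},
#'   \code{lf_score}, \code{hf_score}, \code{lfhf_ratio}).
#' @param alpha significance level of the normality gate (default 0.05).
#' @return data.frame of class \code{"comparison_table"}: one row per index
#'   with the chosen \code{method} and the pairwise p-values
#'   \code{p_mid_pre}, \code{p_post_pre}, \code{p_post_mid}.
#' @export
compare_shifts <- function(pre, mid, post, alpha = 0.05) {
  idx <- intersect(intersect(names(pre), names(mid)), names(post))
  idx <- idx[vapply(idx, function(v) is.numeric(pre[[v]]), logical(1))]
  if (!length(idx)) stop("no shared numeric index columns")
  rows <- lapply(idx, function(v) {
    g <- list(pre = pre[[v]][!is.na(pre[[v]])],
              mid = mid[[v]][!is.na(mid[[v]])],
              post = post[[v]][!is.na(post[[v]])])
    if (any(lengths(g) < 3)) stop("index ", v, ": need n >= 3 per phase")
    normal <- all(vapply(g, function(s) {
      stats::shapiro.test(s)$p.value >= alpha
    }, logical(1)))
    tab <- if (normal) tukey_kramer(g) else steel_dwass(g)
    pick <- function(a, b) {
      tab$p[(tab$group1 == a & tab$group2 == b) |
              (tab$group1 == b & tab$group2 == a)]
    }
    data.frame(index = v,
               method = if (normal) "Tukey-Kramer" else "Steel-Dwass",
               p_mid_pre = pick("mid", "pre"),
               p_post_pre = pick("post", "pre"),
               p_post_mid = pick("post", "mid"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}
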