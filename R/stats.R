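#' Two-group comparison
#'
#' Paired or unpaired t test (via [stats::t.test()]) or the Mann-Whitney U
#' test. The Mann-Whitney p value is exact — by complete enumeration of all
#' group assignments, which also handles ties exactly — when both groups have
#' at most `exact_max` observations, and otherwise uses the tie-corrected
#' normal approximation (no continuity correction). Degenerate inputs (zero
#' variance in the t modes) are flagged instead of erroring.
#'
#' @param x,y numeric samples (equal length required for `paired_t`).
#' @param mode `"paired_t"`, `"unpaired_t"` or `"mann_whitney"`.
#' @param exact_max enumeration bound per group for the exact Mann-Whitney p.
#' @return one-row tibble: `method`, `statistic`, `df`, `p_value`, `flag`.
#' @export
group_compare <- function(x, y, mode = c("paired_t", "unpaired_t", "mann_whitney"),
                          exact_max = 8L) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  row <- function(stat, df, p, flag = NA_character_) {
    tibble::tibble(method = mode, statistic = stat, df = df,
                   p_value = p, flag = flag)
  }
  if (mode %in% c("paired_t", "unpaired_t")) {
    paired <- mode == "paired_t"
    if (paired && length(x) != length(y)) {
      stop("paired test requires equal lengths", call. = FALSE)
    }
    degen <- if (paired) stats::sd(x - y) == 0 else
      (stats::sd(x) == 0 && stats::sd(y) == 0)
    if (degen) return(row(NA_real_, NA_real_, NA_real_, "degenerate: zero variance"))
    tt <- stats::t.test(x, y, paired = paired)
    return(row(unname(tt$statistic), unname(tt$parameter), tt$p.value))
  }
  mw <- mann_whitney_u(x, y, exact_max)
  row(mw$U, NA_real_, mw$p, mw$flag)
}

mann_whitney_u <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # U of x over y
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    dev <- abs(U - mu)
    combos <- utils::combn(n1 + n2, n1)
    devs <- apply(combos, 2L, function(i) {
      abs(sum(r[i]) - n1 * (n1 + 1) / 2 - mu)
    })
    p <- mean(devs >= dev - 1e-9)
    return(list(U = U, p = p, flag = "exact"))
  }
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (v <= 0) return(list(U = U, p = 1, flag = "degenerate: all tied"))
  z <- (U - mu) / sqrt(v)
  list(U = U, p = 2 * stats::pnorm(-abs(z)), flag = "normal approximation")
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups the two-sample rank sum is computed on the joint
#' ranks of that pair (with tie correction of the variance) and the
#' standardized statistic `t` is referred to the studentized range
#' distribution with `k` means: `p_adj = P(Q_k >= sqrt(2) |t|)` — the
#' standard Steel-Dwass procedure controlling the family-wise error over all
#' pairwise comparisons.
#'
#' @param groups list of (>= 3) numeric samples, each with >= 3 observations;
#'   names are used as group labels.
#' @return tibble: `group1`, `group2`, `n1`, `n2`, `statistic`, `p_adjusted`.
#' @export
steel_dwass <- function(groups) {
  k <- length(groups)
  if (k < 3L) stop("Steel-Dwass requires at least 3 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    stop("every group needs at least 3 observations", call. = FALSE)
  }
  nms <- names(groups)
  if (is.null(nms)) nms <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- vector("list", ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    xi <- groups[[i]]; xj <- groups[[j]]
    n1 <- length(xi); n2 <- length(xj); N <- n1 + n2
    r <- rank(c(xi, xj))
    W <- sum(r[seq_len(n1)])
    E <- n1 * (N + 1) / 2
    V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    tstat <- if (V > 0) (W - E) / sqrt(V) else 0
    p <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    out[[q]] <- tibble::tibble(group1 = nms[i], group2 = nms[j],
                               n1 = n1, n2 = n2,
                               statistic = tstat, p_adjusted = p)
  }
  dplyr::bind_rows(out)
}

#' Cohort summary in the style of a multicentre CBF table
#'
#' Per institution, region and condition: mean and sample (n-1) standard
#' deviation of the regional CBF over subjects, plus the cerebrovascular
#' reactivity summarised per subject and then averaged (not derived from the
#' group means). An `"all"` institution block pools every subject. A single
#' subject yields SD 0 with a flag.
#'
#' @param cohort tibble with columns `institution`, `subject`, `region`,
#'   `condition` (`"rest"`/`"acz"`) and `cbf`; one row per
#'   subject x region x condition.
#' @return tibble: `institution`, `region`, `n`, `rest_mean`, `rest_sd`,
#'   `acz_mean`, `acz_sd`, `cvr_mean`, `cvr_sd`, `flag`.
#' @export
summary_table <- function(cohort) {
  need <- c("institution", "subject", "region", "condition", "cbf")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(cohort$cbf < 0, na.rm = TRUE)) stop("negative CBF in cohort", call. = FALSE)
  wide <- cohort |>
    tidyr::pivot_wider(names_from = "condition", values_from = "cbf") |>
    dplyr::mutate(cvr = ifelse(.data$rest > 0,
                               100 * (.data$acz - .data$rest) / .data$rest, NA_real_))
  pooled <- dplyr::mutate(wide, institution = "all")
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  dplyr::bind_rows(wide, pooled) |>
    dplyr::group_by(.data$institution, .data$region) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$subject),
      rest_mean = mean(.data$rest), rest_sd = sd0(.data$rest),
      acz_mean = mean(.data$acz), acz_sd = sd0(.data$acz),
      cvr_mean = mean(.data$cvr, na.rm = TRUE),
      cvr_sd = sd0(.data$cvr[!is.na(.data$cvr)]),
      flag = ifelse(dplyr::n_distinct(.data$subject) == 1L,
                    "single subject: SD reported as 0", NA_character_),
      .groups = "drop"
    )
}
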