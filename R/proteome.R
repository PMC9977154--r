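#' Median-centre a log-intensity matrix
#'
#' Shifts every sample column so its median equals the grand median of
#' the input; pairwise group differences are unchanged by any global
#' constant.
#'
#' @param mat Wide tibble (protein_id first column, log2 intensities).
#' @return Tibble of the same shape with equal column medians.
#' @export
normalize_median <- function(mat) {
  m <- count_matrix(mat)
  if (nrow(m) < 1) abort("at least one protein is required")
  med <- apply(m, 2, stats::median)
  m <- sweep(m, 2, med - stats::median(m), "-")
  dplyr::bind_cols(mat[, 1], tibble::as_tibble(m))
}

# Invert trigamma by Newton iteration (50 steps, tol 1e-10): solve
# trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10) break
  }
  y
}

# Empirical-Bayes prior (d0, s0^2) by matching moments of log s^2.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(prior_df = Inf, prior_var = mean(s2[s2 > 0])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) - trigamma(df / 2)
  if (excess <= 0) {
    # no excess spread beyond chi-square sampling noise: infinite prior df
    return(list(prior_df = Inf, prior_var = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(prior_df = d0, prior_var = s0)
}

#' Moderated t-test for differential protein abundance
#'
#' Per protein, the pooled within-group residual variance s^2 (d degrees
#' of freedom) is shrunk toward a prior (d0, s0^2) estimated from all
#' proteins by matching moments of log s^2 (trigamma inversion by Newton
#' iteration). The posterior variance (d0 s0^2 + d s^2) / (d0 + d) feeds
#' a t statistic on d0 + d degrees of freedom. Raw two-sided p-values are
#' reported; calls downstream gate on raw p.
#'
#' Limits: `prior_df = 0` recovers the ordinary two-sample pooled t-test;
#' `prior_df = Inf` a z-test against s0.
#'
#' @param mat Wide tibble (protein_id first, log2 intensities).
#' @param groups Named character vector sample -> group (two groups).
#'   The fold change is the non-reference group minus the reference;
#'   swapping the labels between samples negates it exactly.
#' @param prior_df,prior_var Optional prior overrides; both default to
#'   the empirical-Bayes estimates.
#' @param reference Group used as the baseline; default the
#'   alphabetically first label.
#' @return Tibble of class `oomics_modt` (protein_id, log2fc, t,
#'   df_total, p, s2, s2_post) with prior_df/prior_var attributes.
#' @export
moderated_t <- function(mat, groups, prior_df = NULL, prior_var = NULL,
                        reference = NULL) {
  m <- count_matrix(mat)
  samples <- colnames(m)
  g <- groups[samples]
  lv <- sort(unique(unname(g)))
  if (length(lv) != 2) abort("exactly two groups are required")
  if (!is.null(reference)) {
    if (!reference %in% lv) abort("`reference` is not a group label")
    lv <- c(reference, setdiff(lv, reference))
  }
  if (any(table(g) < 2)) abort("at least two replicates per group are required")
  idx_a <- which(g == lv[1]); idx_b <- which(g == lv[2])
  n_a <- length(idx_a); n_b <- length(idx_b)
  df <- n_a + n_b - 2

  m_a <- rowMeans(m[, idx_a, drop = FALSE])
  m_b <- rowMeans(m[, idx_b, drop = FALSE])
  v_a <- apply(m[, idx_a, drop = FALSE], 1, stats::var)
  v_b <- apply(m[, idx_b, drop = FALSE], 1, stats::var)
  s2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / df

  if (is.null(prior_df) || is.null(prior_var)) {
    if (all(s2 <= .Machine$double.eps)) {
      inform("zero within-group variance everywhere; using pooled variance (infinite prior df)")
      prior <- list(prior_df = Inf, prior_var = mean(s2))
    } else {
      prior <- estimate_variance_prior(s2, df)
    }
    prior_df <- prior_df %||% prior$prior_df
    prior_var <- prior_var %||% prior$prior_var
  }

  s2_post <- if (is.infinite(prior_df)) rep(prior_var, length(s2))
             else (prior_df * prior_var + df * s2) / (prior_df + df)
  df_total <- prior_df + df
  lfc <- m_b - m_a
  tstat <- lfc / sqrt(s2_post * (1 / n_a + 1 / n_b))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- tibble::tibble(protein_id = mat[[1]], log2fc = lfc, t = tstat,
                        df_total = df_total, p = p, s2 = s2,
                        s2_post = s2_post)
  class(out) <- c("oomics_modt", class(out))
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  attr(out, "groups") <- lv
  out
}

#' Call differentially abundant proteins
#'
#' Up: raw p below `p` and log2FC at or above `lfc`; down symmetric. The
#' gate uses the raw (unadjusted) p-value, matching the reporting
#' convention of TMT oocyte proteomes (documented deviation from the
#' usual FDR gate).
#'
#' @param res Output of [moderated_t()].
#' @param p Raw p-value threshold (default 0.05).
#' @param lfc Log2 fold-change threshold (default 0.3).
#' @return `res` with a `call` column in {up, down, none}.
#' @export
call_diff_proteins <- function(res, p = 0.05, lfc = 0.3) {
  sig <- !is.na(res$p) & res$p < p
  res$call <- dplyr::case_when(
    sig & res$log2fc >= lfc ~ "up",
    sig & res$log2fc <= -lfc ~ "down",
    TRUE ~ "none")
  res
}
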