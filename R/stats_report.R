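#' Choose and run the appropriate two-group (or k-group) test
#'
#' Mirrors the reference statistical battery: Shapiro-Wilk normality on
#' each group at alpha = 0.05; if all groups are compatible with
#' normality, a Student t test (paired or unpaired); otherwise the
#' rank-based equivalent (Wilcoxon signed-rank / rank-sum). More than two
#' groups use Kruskal-Wallis with Holm-Sidak-adjusted pairwise rank-sum
#' comparisons. Groups with fewer than 3 values default to the rank-based
#' branch with a warning (normality untestable).
#'
#' @param samples list of numeric vectors (>= 2 groups)
#' @param paired paired comparison (2 groups only)
#' @param alpha normality alpha
#' @return list: `test` (label), `p` (main p-value), `normal` (per-group
#'   normality verdicts), `pairwise` (adjusted pairwise p's, k > 2 only)
#' @export
choose_test <- function(samples, paired = FALSE, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  k <- length(samples)
  small <- any(vapply(samples, length, numeric(1)) < 3)
  if (small) {
    warning("groups with n < 3: defaulting to rank-based test")
    normal <- rep(FALSE, k)
  } else {
    normal <- vapply(samples, function(v) {
      if (length(unique(v)) == 1) return(FALSE)
      shapiro.test(v)$p.value >= alpha
    }, logical(1))
  }
  if (k == 2) {
    if (all(normal)) {
      tst <- t.test(samples[[1]], samples[[2]], paired = paired)
      lab <- if (paired) "paired t test" else "unpaired t test"
    } else {
      tst <- suppressWarnings(
        wilcox.test(samples[[1]], samples[[2]], paired = paired,
                    exact = FALSE))
      lab <- if (paired) "Wilcoxon signed rank" else "Wilcoxon rank sum"
    }
    return(list(test = lab, p = tst$p.value, normal = normal,
                pairwise = NULL))
  }
  grp <- factor(rep(seq_len(k), vapply(samples, length, numeric(1))))
  kw <- kruskal.test(unlist(samples), grp)
  pw <- list()
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    p <- suppressWarnings(
      wilcox.test(samples[[a]], samples[[b]], exact = FALSE))$p.value
    pw[[paste(a, b, sep = "-")]] <- p
  }
  raw <- unlist(pw)
  list(test = "Kruskal-Wallis", p = kw$p.value, normal = normal,
       pairwise = data.frame(pair = names(raw), p_raw = raw,
                             p_adj = holm_sidak(raw)))
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak: the i-th smallest raw p is adjusted as
#' `1 - (1 - p)^(m - i + 1)`, with monotonicity enforced.
#'
#' @param p raw p-values
#' @return adjusted p-values, same order as input
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities, over all tables
#' with the observed margins, of every table at most as probable as the
#' observed one. A table with a zero margin carries no information and
#' returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return two-sided p-value
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(abs(tab - round(tab)) < 1e-8))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Trigger-versus-nontrigger gradient comparison
#'
#' Group means and SDs for the APD80 and RT gradients at trigger origins
#' versus nontrigger reference sites, with rank-sum p-values — the layout
#' of the reference study's gradient panel.
#'
#' @param trigger data.frame of trigger-site measurements (columns
#'   `apd_gradient`, `rt_gradient`, optionally `prep`)
#' @param nontrigger data.frame of nontrigger measurements, same columns
#' @return list with `summary` (per group x quantity), `p_apd`, `p_rt`,
#'   `ratio_apd` (trigger mean / nontrigger mean)
#' @export
gradient_comparison <- function(trigger, nontrigger) {
  if (nrow(trigger) < 2 || nrow(nontrigger) < 2)
    stop("need at least 2 sites per group")
  sm <- function(df, role) data.frame(
    role = role, n = nrow(df),
    apd_mean = mean(df$apd_gradient), apd_sd = sd(df$apd_gradient),
    rt_mean = mean(df$rt_gradient), rt_sd = sd(df$rt_gradient))
  p_apd <- suppressWarnings(wilcox.test(trigger$apd_gradient,
                                        nontrigger$apd_gradient,
                                        exact = FALSE))$p.value
  p_rt <- suppressWarnings(wilcox.test(trigger$rt_gradient,
                                       nontrigger$rt_gradient,
                                       exact = FALSE))$p.value
  list(summary = rbind(sm(trigger, "trigger"), sm(nontrigger, "nontrigger")),
       p_apd = p_apd, p_rt = p_rt,
       ratio_apd = mean(trigger$apd_gradient) / mean(nontrigger$apd_gradient))
}

#' Render a Markdown study report
#'
#' Deterministic (timestamp-free) Markdown report assembling the incidence
#' counts, coupling statistics, T-wave correlation and gradient panels
#' plus a configuration echo.
#'
#' @param tables named list; recognized entries: `episode_summary` (from
#'   [episode_summary()]), `gradients` (from [gradient_comparison()]),
#'   `incidence` (list with `table` 2x2 and `p`), `config_echo` (character),
#'   `seeds` (numeric)
#' @param path output file path
#' @return the path, invisibly
#' @export
render_report <- function(tables, path) {
  ln <- c("# Spontaneous VF trigger study report", "")
  fmt <- function(x, d = 1) formatC(x, format = "f", digits = d)
  es <- tables$episode_summary
  if (!is.null(es)) {
    ln <- c(ln, "## Incidence of spontaneous VF", "",
            sprintf("- preparations: %d", es$counts$n_preparations),
            sprintf("- spontaneous VF episodes: %d (sustained %d, nonsustained %d)",
                    es$counts$n_spont_vf, es$counts$n_sustained,
                    es$counts$n_nonsustained),
            sprintf("- mean episodes per preparation: %s (rounds to %d)",
                    fmt(es$counts$mean_per_prep, 3),
                    es$counts$mean_per_prep_rounded), "")
    if (nrow(es$coupling) > 0) {
      ln <- c(ln, "## Trigger coupling intervals", "",
              "| class | n | mean (ms) | sd (ms) | R-on-T fraction |",
              "|---|---|---|---|---|")
      for (i in seq_len(nrow(es$coupling))) {
        r <- es$coupling[i, ]
        ln <- c(ln, sprintf("| %s | %d | %s | %s | %s |", r$class, r$n,
                            fmt(r$mean_ms), fmt(r$sd_ms),
                            ifelse(is.na(r$r_on_t_frac), "-",
                                   fmt(r$r_on_t_frac, 2))))
      }
      ln <- c(ln, "")
    }
  }
  inc <- tables$incidence
  if (!is.null(inc)) {
    ln <- c(ln, "## Incidence comparison (Fisher exact)", "",
            sprintf("- table: [[%d, %d], [%d, %d]]", inc$table[1, 1],
                    inc$table[1, 2], inc$table[2, 1], inc$table[2, 2]),
            sprintf("- two-sided p = %s", format(inc$p, digits = 3)), "")
  }
  gr <- tables$gradients
  if (!is.null(gr)) {
    ln <- c(ln, "## Local gradients at trigger vs nontrigger sites", "",
            "| group | n | APD80 grad (ms/mm) | RT grad (ms/mm) |",
            "|---|---|---|---|")
    for (i in seq_len(nrow(gr$summary))) {
      r <- gr$summary[i, ]
      ln <- c(ln, sprintf("| %s | %d | %s +/- %s | %s +/- %s |", r$role,
                          r$n, fmt(r$apd_mean), fmt(r$apd_sd),
                          fmt(r$rt_mean), fmt(r$rt_sd)))
    }
    ln <- c(ln, "",
            sprintf("- rank-sum p (APD80 gradient): %s",
                    format(gr$p_apd, digits = 3)),
            sprintf("- rank-sum p (RT gradient): %s",
                    format(gr$p_rt, digits = 3)),
            sprintf("- trigger / nontrigger APD-gradient ratio: %s",
                    fmt(gr$ratio_apd)), "")
  }
  if (!is.null(tables$seeds))
    ln <- c(ln, sprintf("Seeds: %s", paste(tables$seeds, collapse = ", ")), "")
  if (!is.null(tables$config_echo))
    ln <- c(ln, "## Configuration", "", "```", tables$config_echo, "```", "")
  ver <- tryCatch(as.character(utils::packageVersion("vftrig")),
                  error = function(e) "dev")
  ln <- c(ln, sprintf("Software: vftrig %s", ver))
  writeLines(ln, path)
  invisible(path)
}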