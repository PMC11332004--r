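#' Run the full battery of cohort-level group comparisons
#'
#' Applies, per cohort and for all cohorts combined: Mann-Whitney tests
#' (high vs low synchronizers) on age, years of education, years of musical
#' training and musical expertise level; Fisher's exact test on sex by
#' group; a Spearman correlation between PLV and years of musical training;
#' and a one-sample KS test of the PLV distribution. With two cohorts, the
#' PLV distributions are additionally compared by a two-sample KS test and
#' a JZS Bayes factor; the combined PLVs are also KS-tested stratified by
#' sex. Tests whose covariate columns are missing are reported as notes;
#' the remaining tests still run.
#'
#' @param cohort Data frame with at least `plv` and `label`
#'   (`"high"`/`"low"`); optionally `cohort`, `sex`, `age`, `edu_years`,
#'   `music_years`, `music_level`.
#' @param mc_sims Monte-Carlo simulations for KS confidence intervals.
#' @param seed RNG seed for the Monte-Carlo runs.
#' @return A list of result objects plus a flat `summary` data frame with
#'   columns test, cohort, statistic, p, effect_size, ci_low, ci_high, n.
#' @export
run_group_comparisons <- function(cohort, mc_sims = 10000, seed = NULL) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) stop("empty cohort table")
  if (!all(c("plv", "label") %in% names(cohort))) {
    stop("cohort table needs columns plv and label")
  }
  if (!"cohort" %in% names(cohort)) cohort$cohort <- "all"

  results <- list()
  rows <- list()
  notes <- character(0)
  add_row <- function(test, coh, statistic, p, effect, ci, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      test = test, cohort = coh, statistic = statistic, p = p,
      effect_size = effect, ci_low = ci[1], ci_high = ci[2],
      n = paste(n, collapse = "/"), stringsAsFactors = FALSE)
  }

  cohorts <- unique(cohort$cohort)
  scopes <- c(as.list(cohorts), list(cohorts))
  scope_names <- c(cohorts, "combined")
  if (length(cohorts) == 1) {
    scopes <- scopes[1]
    scope_names <- scope_names[1]
  }

  covars <- c("age", "edu_years", "music_years", "music_level")
  for (s in seq_along(scopes)) {
    nm <- scope_names[s]
    sub <- cohort[cohort$cohort %in% scopes[[s]], , drop = FALSE]
    hi <- sub[sub$label == "high", , drop = FALSE]
    lo <- sub[sub$label == "low", , drop = FALSE]

    for (cv in covars) {
      if (!cv %in% names(sub)) {
        notes <- c(notes, sprintf("%s/%s: column missing, test skipped", nm, cv))
        next
      }
      r <- tryCatch(mann_whitney(hi[[cv]], lo[[cv]]), error = function(e) e)
      if (inherits(r, "error")) {
        notes <- c(notes, sprintf("%s/%s: %s", nm, cv, conditionMessage(r)))
        next
      }
      results[[paste0(nm, "_mw_", cv)]] <- r
      add_row(paste0("mann_whitney_", cv), nm, r$u_stat, r$p_value,
              r$rank_biserial_r, c(NA, NA), r$n)
    }

    if ("sex" %in% names(sub)) {
      tab <- sex_by_group_table(sub)
      r <- tryCatch(fisher_exact(tab), error = function(e) e)
      if (inherits(r, "error")) {
        notes <- c(notes, sprintf("%s/sex: %s", nm, conditionMessage(r)))
      } else {
        results[[paste0(nm, "_fisher_sex")]] <- r
        add_row("fisher_sex_group", nm, r$odds_ratio, r$p_value,
                r$odds_ratio, r$or_ci, sum(tab))
      }
    } else {
      notes <- c(notes, sprintf("%s/sex: column missing, test skipped", nm))
    }

    if ("music_years" %in% names(sub)) {
      r <- tryCatch(spearman_cor(sub$plv, sub$music_years),
                    error = function(e) e)
      if (inherits(r, "error")) {
        notes <- c(notes, sprintf("%s/spearman: %s", nm, conditionMessage(r)))
      } else {
        results[[paste0(nm, "_spearman_music")]] <- r
        add_row("spearman_plv_music_years", nm, r$rho, r$p_value, r$rho,
                r$ci, r$n)
      }
    }

    r <- ks_one_sample(sub$plv, n_sim = mc_sims, seed = seed)
    results[[paste0(nm, "_ks_plv")]] <- r
    add_row("ks_one_sample_plv", nm, r$d_stat, r$p_value, r$d_stat,
            c(r$ci_low, r$ci_high), r$n)

    if (nm == "combined" && "sex" %in% names(sub)) {
      for (sx in unique(sub$sex)) {
        xs <- sub$plv[sub$sex == sx]
        if (length(xs) < 2) next
        r <- ks_one_sample(xs, n_sim = mc_sims, seed = seed)
        results[[paste0("combined_ks_plv_", sx)]] <- r
        add_row(paste0("ks_one_sample_plv_", sx), nm, r$d_stat, r$p_value,
                r$d_stat, c(r$ci_low, r$ci_high), r$n)
      }
    }
  }

  if (length(cohorts) == 2) {
    x <- cohort$plv[cohort$cohort == cohorts[1]]
    y <- cohort$plv[cohort$cohort == cohorts[2]]
    r <- ks_two_sample(x, y, n_sim = mc_sims, seed = seed)
    results$ks_between_cohorts <- r
    add_row("ks_two_sample_cohorts", "between", r$d_stat, r$p_value,
            r$d_stat, c(r$ci_low, r$ci_high), r$n)
    b <- bayes_factor_ttest(x, y)
    results$bf_between_cohorts <- b
    add_row("bayes_factor_cohorts", "between", b$bf01, NA, b$posterior_mean,
            b$credible_interval, c(length(x), length(y)))
  }

  results$summary <- do.call(rbind, rows)
  results$notes <- notes
  results
}

# 2x2 counts: rows male/female, columns high/low.
sex_by_group_table <- function(sub) {
  m <- matrix(
    c(sum(sub$sex == "male" & sub$label == "high"),
      sum(sub$sex == "male" & sub$label == "low"),
      sum(sub$sex == "female" & sub$label == "high"),
      sum(sub$sex == "female" & sub$label == "low")),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("male", "female"), c("high", "low"))
  )
  m
}
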