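#' Species-level fold changes, SEMs and Student t-tests
#'
#' For every species, the per-animal normalized values of the two groups are
#' compared: the fold change is the ratio of group means
#' (treated / control), the effect-size error `sem_fc` is by default the
#' standard error of the treated per-animal values scaled by the control
#' mean (so that `|fc - 1|` and `sem_fc` live on the same axis), and the
#' p-value comes from the classical two-sample equal-variance Student
#' t-test on per-animal values (Welch available via `var_equal = FALSE`).
#' The t statistic and p-value are computed in closed form, vectorized over
#' species, which keeps panels of many thousands of species fast.
#'
#' @param norm Per-animal normalized table ([average_duplicates()] output,
#'   or [class_fraction_normalize()] output for the "/tot" scale).
#' @param scale Label recorded in the output: `"raw"` (lipid/standard
#'   ratios) or `"class_fraction"` ("/tot" fractions).
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @param sem_method `"control_scaled"` (default: SEM of treated values
#'   divided by the control mean) or `"pooled"` (delta-method SEM of the
#'   ratio of means).
#' @return Tibble with one row per tissue and species: group sizes and
#'   means, `fc`, `sem_fc`, `t`, `df`, `p`, `direction`
#'   (`"increased"` / `"decreased"`, `NA` at fc = 1), `scale`.
#' @export
species_stats <- function(norm, scale = c("raw", "class_fraction"),
                          var_equal = TRUE,
                          sem_method = c("control_scaled", "pooled")) {
  scale <- match.arg(scale)
  sem_method <- match.arg(sem_method)
  need <- c("animal_id", "group", "tissue", "species", "lipid_class", "value")
  if (!all(need %in% names(norm))) {
    abort_input("normalized table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(norm$group %in% c("control", "treated"))) {
    abort_input("group must be 'control' or 'treated'")
  }

  per_group <- dplyr::summarise(
    dplyr::group_by(norm, .data$tissue, .data$lipid_class, .data$species,
                    .data$group),
    n = dplyr::n(), mean = mean(.data$value), var = stats::var(.data$value),
    .groups = "drop"
  )
  agg <- tidyr::pivot_wider(
    per_group,
    names_from = "group", values_from = c("n", "mean", "var"),
    values_fill = list(n = 0L)
  )
  for (col in c("n_control", "n_treated", "mean_control", "mean_treated",
                "var_control", "var_treated")) {
    if (!col %in% names(agg)) agg[[col]] <- if (grepl("^n_", col)) 0L else NA_real_
  }
  if (any(agg$n_control < 2 | agg$n_treated < 2)) {
    bad <- agg$species[which(agg$n_control < 2 | agg$n_treated < 2)[1]]
    abort_input("species '", bad, "' needs >= 2 animals per group")
  }
  if (any(agg$mean_control == 0)) {
    bad <- agg$species[which(agg$mean_control == 0)[1]]
    abort_input("control mean is zero for species '", bad,
                "'; fold change undefined")
  }

  agg$fc <- agg$mean_treated / agg$mean_control
  agg$sem_fc <- if (sem_method == "control_scaled") {
    sqrt(agg$var_treated / agg$n_treated) / agg$mean_control
  } else {
    agg$fc * sqrt(agg$var_treated / agg$n_treated / agg$mean_treated^2 +
                  agg$var_control / agg$n_control / agg$mean_control^2)
  }

  diff <- agg$mean_treated - agg$mean_control
  if (var_equal) {
    sp2 <- ((agg$n_control - 1) * agg$var_control +
            (agg$n_treated - 1) * agg$var_treated) /
           (agg$n_control + agg$n_treated - 2)
    se <- sqrt(sp2 * (1 / agg$n_control + 1 / agg$n_treated))
    agg$df <- agg$n_control + agg$n_treated - 2
  } else {
    a <- agg$var_control / agg$n_control
    b <- agg$var_treated / agg$n_treated
    se <- sqrt(a + b)
    agg$df <- (a + b)^2 /
      (a^2 / (agg$n_control - 1) + b^2 / (agg$n_treated - 1))
  }
  agg$t <- diff / se
  agg$p <- 2 * stats::pt(-abs(agg$t), agg$df)
  # both groups constant: no sampling variability, p is 1 (equal) or 0
  degen <- se == 0
  agg$t[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
  agg$p[degen] <- as.numeric(diff[degen] == 0)
  agg$df[degen & is.nan(agg$df)] <- agg$n_control[degen & is.nan(agg$df)] +
    agg$n_treated[degen & is.nan(agg$df)] - 2

  agg$direction <- dplyr::case_when(
    agg$fc > 1 ~ "increased",
    agg$fc < 1 ~ "decreased",
    TRUE ~ NA_character_
  )
  agg$scale <- scale
  agg
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Adds BH step-up q-values with monotonicity enforcement
#' (via [stats::p.adjust()]), one adjustment family per tissue and scale —
#' raw-ratio and class-fraction results are adjusted separately.
#'
#' @param stats Species statistics from [species_stats()].
#' @return The input with a `q` column.
#' @export
bh_fdr <- function(stats) {
  if (!"p" %in% names(stats) || nrow(stats) == 0) {
    abort_input("bh_fdr() needs a non-empty table with a 'p' column")
  }
  if (any(stats$p < 0 | stats$p > 1 | is.na(stats$p))) {
    abort_input("p-values must lie in [0, 1]")
  }
  out <- dplyr::group_by(stats, .data$tissue, .data$scale)
  out <- dplyr::mutate(out, q = stats::p.adjust(.data$p, method = "BH"))
  dplyr::ungroup(out)
}

#' Mean-SEM effect-size threshold
#'
#' The effect filter used alongside the p-value: a species "has an effect"
#' when its fold-change deviation `|fc - 1|` exceeds the arithmetic mean of
#' `sem_fc` over all species of the family (one tissue at one scale).
#'
#' @param stats Species statistics of a single tissue x scale family.
#' @return The scalar threshold.
#' @export
effect_threshold <- function(stats) {
  if (nrow(stats) == 0) abort_input("effect_threshold() needs >= 1 species")
  if (dplyr::n_distinct(stats$tissue) > 1 || dplyr::n_distinct(stats$scale) > 1) {
    abort_input("effect_threshold() expects a single tissue x scale family; ",
                "use volcano_categorize() for mixed tables")
  }
  mean(stats$sem_fc)
}

#' Dual significance / effect-size volcano categories
#'
#' Partitions species into the four volcano tiers: `SIGNIFICANT_EFFECT`
#' (p < alpha and `|fc - 1|` above the effect threshold),
#' `SIGNIFICANT_ONLY` (p < alpha only), `EFFECT_ONLY` (effect only) and
#' `UNCHANGED`. When `threshold` is `NULL` it is computed per tissue x
#' scale family with [effect_threshold()].
#'
#' @param stats Species statistics (any mix of tissues/scales).
#' @param alpha Significance level (default 0.05).
#' @param threshold Effect threshold; `NULL` = mean SEM per family.
#' @return The input with `effect_threshold` and `category` columns.
#' @export
volcano_categorize <- function(stats, alpha = 0.05, threshold = NULL) {
  if (alpha <= 0 || alpha >= 1) abort_input("alpha must lie in (0, 1)")
  out <- dplyr::group_by(stats, .data$tissue, .data$scale)
  out <- dplyr::mutate(
    out,
    effect_threshold = if (is.null(threshold)) mean(.data$sem_fc) else threshold
  )
  out <- dplyr::ungroup(out)
  sig <- out$p < alpha
  eff <- abs(out$fc - 1) > out$effect_threshold
  out$category <- dplyr::case_when(
    sig & eff ~ "SIGNIFICANT_EFFECT",
    sig ~ "SIGNIFICANT_ONLY",
    eff ~ "EFFECT_ONLY",
    TRUE ~ "UNCHANGED"
  )
  out
}

#' Class-level summaries as percent of control
#'
#' Sums each animal's species values per lipid class (and, within the
#' carnitine class, the three reported subgroups: free carnitine C0,
#' acetylcarnitine C2, and acylcarnitines with three or more acyl carbons),
#' then expresses the treated group mean as a percent of the control mean.
#' The p-value is the two-tailed one-sample t-test of the treated totals —
#' each expressed as percent of the control mean — against 100%.
#'
#' @param norm Per-animal normalized table.
#' @param panel A [lipid_panel()].
#' @param carnitine_subgroups Also report the three carnitine subgroups
#'   (default `TRUE` when carnitines are present).
#' @return Tibble with one row per tissue and class/subgroup:
#'   `group_label`, `percent_of_control`, `p_one_sample`, `n_species`.
#' @export
class_summary <- function(norm, panel, carnitine_subgroups = TRUE) {
  stopifnot(inherits(panel, "lipid_panel"))
  info <- panel$species
  groupings <- split(info$canonical_label, info$lipid_class)
  if (carnitine_subgroups && "CARNITINE" %in% info$lipid_class) {
    carn <- info[info$lipid_class == "CARNITINE", ]
    groupings[["CARNITINE_FREE"]] <- carn$canonical_label[carn$carbons == 0]
    groupings[["CARNITINE_ACETYL"]] <- carn$canonical_label[carn$carbons == 2]
    groupings[["CARNITINE_ACYL"]] <- carn$canonical_label[carn$carbons >= 3]
  }
  groupings <- groupings[lengths(groupings) > 0]

  res <- lapply(names(groupings), function(lbl) {
    members <- groupings[[lbl]]
    sub <- norm[norm$species %in% members, ]
    if (nrow(sub) == 0) return(NULL)
    totals <- dplyr::summarise(
      dplyr::group_by(sub, .data$tissue, .data$animal_id, .data$group),
      total = sum(.data$value), .groups = "drop"
    )
    by_tissue <- lapply(split(totals, totals$tissue), function(tt) {
      ctrl <- tt$total[tt$group == "control"]
      trt <- tt$total[tt$group == "treated"]
      if (length(ctrl) == 0 || length(trt) == 0) {
        abort_input("class summary for ", lbl, " needs both groups present")
      }
      if (mean(ctrl) == 0) {
        abort_input("control class total is zero for ", lbl)
      }
      pct <- 100 * (trt / mean(ctrl))
      p <- one_sample_t_p(pct, mu = 100)
      tibble::tibble(
        tissue = tt$tissue[1], group_label = lbl,
        percent_of_control = 100 * (mean(trt) / mean(ctrl)),
        p_one_sample = p, n_species = length(members)
      )
    })
    dplyr::bind_rows(by_tissue)
  })
  dplyr::bind_rows(res)
}

# two-tailed one-sample t against mu; constant samples have no sampling
# variability, so p degenerates to 1 (equal) or 0
one_sample_t_p <- function(x, mu) {
  if (length(x) < 2) return(as.numeric(isTRUE(all.equal(mean(x), mu))))
  tryCatch(stats::t.test(x, mu = mu)$p.value,
           error = function(e) as.numeric(isTRUE(all.equal(mean(x), mu))))
}

# two-tailed two-sample Student t with the same degeneracy convention
two_sample_t_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    return(as.numeric(isTRUE(all.equal(mean(x), mean(y)))))
  }
  tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
           error = function(e) as.numeric(isTRUE(all.equal(mean(x), mean(y)))))
}

#' Direction-of-regulation counts and exact binomial test
#'
#' Counts the increased (fc > 1) and decreased (fc < 1) species within one
#' volcano tier; species with fc exactly 1 have no direction and are
#' excluded. The within-tissue p-value is the two-sided exact binomial test
#' of the split against a null proportion of 0.5 ([stats::binom.test()]).
#'
#' @param stats Categorized statistics from [volcano_categorize()].
#' @param tier Volcano category to count (default `"SIGNIFICANT_EFFECT"`;
#'   `"EFFECT_ONLY"` counts species with p > alpha but effect > threshold).
#' @return A list of class `direction_counts`: `tier`, `n_increased`,
#'   `n_decreased`, `binomial_p` (1 when the tier is empty).
#' @export
direction_counts <- function(stats, tier = "SIGNIFICANT_EFFECT") {
  if (!"category" %in% names(stats)) {
    abort_input("stats must be categorized first (volcano_categorize())")
  }
  tier <- match.arg(tier, c("SIGNIFICANT_EFFECT", "SIGNIFICANT_ONLY",
                            "EFFECT_ONLY", "UNCHANGED"))
  sub <- stats[stats$category == tier & !is.na(stats$direction), ]
  n_up <- sum(sub$direction == "increased")
  n_dn <- sum(sub$direction == "decreased")
  p <- if (n_up + n_dn == 0) 1 else {
    stats::binom.test(n_up, n_up + n_dn, p = 0.5)$p.value
  }
  structure(
    list(tier = tier, n_increased = n_up, n_decreased = n_dn, binomial_p = p),
    class = "direction_counts"
  )
}

#' @export
print.direction_counts <- function(x, ...) {
  cat(sprintf("<direction_counts> %s: %d increased / %d decreased (binomial p = %.4g)\n",
              x$tier, x$n_increased, x$n_decreased, x$binomial_p))
  invisible(x)
}

#' Compare direction frequencies between two tissues
#'
#' Fisher's exact test on the 2 x 2 table (tissue x direction) built from
#' two [direction_counts()] results, asking whether the up/down split of
#' regulated species differs between tissues.
#'
#' @param counts_a,counts_b `direction_counts` objects for the two tissues.
#' @return Two-sided Fisher exact p-value.
#' @export
direction_contrast <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "direction_counts"),
            inherits(counts_b, "direction_counts"))
  m <- matrix(c(counts_a$n_increased, counts_a$n_decreased,
                counts_b$n_increased, counts_b$n_decreased), nrow = 2)
  if (sum(m) == 0) return(1)
  stats::fisher.test(m)$p.value
}
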