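#' Average technical replicates per biological unit
#'
#' Collapses per-replicate population percentages to an unweighted mean per
#' unit (animal) x treatment -- each experimental condition for each
#' animal is typically run in technical triplicate, and the animal is the
#' biological unit of replication entering the group comparison.
#'
#' @param summaries data frame with columns `animal`, `treatment`,
#'   `pct_live`, `pct_etotic`, `pct_dead` (as from
#'   [population_percentages()]).
#' @param unit grouping column(s) defining the biological unit, default
#'   `"animal"`.
#' @return data frame with one row per unit x treatment, the mean
#'   percentages, and `n_replicates`.
#' @export
aggregate_replicates <- function(summaries, unit = "animal") {
  keys <- c(unit, "treatment")
  stopifnot(all(keys %in% names(summaries)))
  key <- interaction(summaries[keys], drop = TRUE, sep = "\r")
  first <- !duplicated(key)
  out <- summaries[first, keys, drop = FALSE]
  ord <- as.character(key[first])
  for (col in intersect(c("pct_live", "pct_etotic", "pct_dead"),
                        names(summaries)))
    out[[col]] <- as.numeric(tapply(summaries[[col]], key, mean)[ord])
  out$n_replicates <- as.integer(tapply(rep(1L, nrow(summaries)), key,
                                        sum)[ord])
  rownames(out) <- NULL
  out
}

#' Two-sample t test on population percentages
#'
#' Two-tailed unpaired Student t test with pooled (equal) variance by
#' default; `welch = TRUE` switches to the Welch unequal-variance form.
#' The statistic is `(mean(a) - mean(b)) / se`, so a negative `t` means
#' group `a` is lower.
#'
#' Degenerate inputs: zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero pooled variance with unequal means gives `p = 0`
#' with `degenerate = TRUE`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param welch use the Welch test instead of the pooled-variance test.
#' @return object of class `tq_ttest`: list with `t`, `df`, `p`, `stars`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `method`, `degenerate`.
#' @export
pooled_t_test <- function(values_a, values_b, welch = FALSE) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs >= 2 values")
  ma <- mean(values_a); mb <- mean(values_b)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  degenerate <- FALSE
  if (welch) {
    se2 <- va / na + vb / nb
    df <- if (se2 > 0)
      se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    else na + nb - 2
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 == 0) {
    if (ma == mb) {
      t <- 0; p <- 1
    } else {
      t <- sign(ma - mb) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t <- (ma - mb) / sqrt(se2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, stars = p_stars(p),
                 mean_a = ma, mean_b = mb, n_a = na, n_b = nb,
                 method = if (welch) "welch" else "student",
                 degenerate = degenerate),
            class = "tq_ttest")
}

#' @export
print.tq_ttest <- function(x, ...) {
  cat(sprintf("unpaired %s t test: t = %.4f, df = %.4g, p = %.4g %s (n = %d vs %d)\n",
              x$method, x$t, x$df, x$p, x$stars, x$n_a, x$n_b))
  if (x$degenerate) cat("  degenerate: zero variance with unequal means\n")
  invisible(x)
}

#' Significance stars for a p value
#'
#' The conventional mapping used in figure legends: `p < 0.05` `*`,
#' `p < 0.01` `**`, `p < 0.001` `***`, `p < 0.0001` `****`, otherwise
#' `ns`. All intervals are strict at the boundary.
#'
#' @param p p value(s) in `[0, 1]`.
#' @return character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Mean increase of a treated group over control, in percent
#'
#' `(mean(treated) - mean(control)) / mean(control) * 100`; the summary
#' used to report treatment effects relative to media-only controls.
#'
#' @param treated_values,control_values numeric vectors; the control mean
#'   must be positive.
#' @return percent increase (negative for a decrease).
#' @export
mean_increase <- function(treated_values, control_values) {
  mc <- mean(control_values)
  if (!is.finite(mc) || mc <= 0)
    stop("control mean must be > 0 to express a relative increase")
  (mean(treated_values) - mc) / mc * 100
}

#' Compare each treatment against a control, per metric
#'
#' Runs [pooled_t_test()] and [mean_increase()] for every non-control
#' treatment and each requested population metric on the per-unit table.
#'
#' @param per_unit output of [aggregate_replicates()] (or any table with
#'   `treatment` and the metric columns, one row per biological unit).
#' @param control name of the control treatment.
#' @param metrics metric columns to compare (default ETotic and dead
#'   percentages).
#' @param welch passed to [pooled_t_test()].
#' @return data frame, one row per (treatment, metric): `treatment_a`
#'   (treated), `treatment_b` (control), `metric`, `t`, `df`, `p`,
#'   `stars`, `mean_increase_pct`, `n_a`, `n_b`, `degenerate`.
#' @export
compare_treatments <- function(per_unit, control,
                               metrics = c("pct_etotic", "pct_dead"),
                               welch = FALSE) {
  stopifnot("treatment" %in% names(per_unit),
            all(metrics %in% names(per_unit)))
  if (!control %in% per_unit$treatment)
    stop("control treatment not present: ", control)
  others <- setdiff(unique(per_unit$treatment), control)
  rows <- list()
  for (tr in others) {
    for (m in metrics) {
      a <- per_unit[[m]][per_unit$treatment == tr]
      b <- per_unit[[m]][per_unit$treatment == control]
      tt <- pooled_t_test(a, b, welch = welch)
      inc <- if (mean(b) > 0) mean_increase(a, b) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(treatment_a = tr, treatment_b = control, metric = m,
                   t = tt$t, df = tt$df, p = tt$p, stars = tt$stars,
                   mean_increase_pct = inc, n_a = tt$n_a, n_b = tt$n_b,
                   degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
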