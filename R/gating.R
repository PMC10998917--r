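#' Bivariate gate configuration
#'
#' Thresholds, on the log10 mean-intensity scale, that delineate the three
#' populations of the Hoechst x SytoxGreen plane: objects above
#' `gate_sytox` are dead/dying regardless of Hoechst (dead cells span a
#' wide range of Hoechst staining); of the rest, objects below
#' `gate_hoechst` are ETotic (diffuse, Hoechst-low chromatin clouds); the
#' remainder are live. Mirrors a manual FlowJo-style quadrant gate, so
#' manually chosen coordinates are first-class; [auto_gates()] offers a
#' reproducible default.
#'
#' @param gate_sytox,gate_hoechst finite log10 mean-intensity thresholds.
#' @param epsilon additive offset used in `log10(mean + epsilon)` so
#'   zero-intensity objects are well defined; must be > 0.
#' @param min_et_area_px optional minimum area for the ETotic call;
#'   Hoechst-low objects smaller than this fall through to live.
#' @param provenance `"manual"` or `"auto"`.
#' @return object of class `gate_config`.
#' @export
gate_config <- function(gate_sytox, gate_hoechst, epsilon = 1e-6,
                        min_et_area_px = NULL, provenance = "manual") {
  if (!is_scalar_num(gate_sytox) || !is_scalar_num(gate_hoechst))
    stop("gates must be finite scalars")
  if (!is_scalar_num(epsilon) || epsilon <= 0)
    stop("epsilon must be > 0")
  structure(list(gate_sytox = gate_sytox, gate_hoechst = gate_hoechst,
                 epsilon = epsilon, min_et_area_px = min_et_area_px,
                 provenance = provenance, degenerate = FALSE),
            class = "gate_config")
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf("gates (%s): log10 Sytox > %.4f -> dead; log10 Hoechst < %.4f -> etotic; else live (epsilon %g)\n",
              x$provenance, x$gate_sytox, x$gate_hoechst, x$epsilon))
  if (isTRUE(x$degenerate))
    cat("  warning: derived from a zero-spread control (degenerate)\n")
  invisible(x)
}

#' Classify objects into live / ETotic / dead populations
#'
#' Applies the gate rules in fixed order: (1) dead if
#' `log10(sytox_mean + epsilon) > gate_sytox`; (2) otherwise ETotic if
#' `log10(hoechst_mean + epsilon) < gate_hoechst` (and the area condition
#' holds, when set); (3) otherwise live. Classes are exhaustive and
#' mutually exclusive.
#'
#' @param objects data frame with `hoechst_mean`, `sytox_mean` (and `area`
#'   when `min_et_area_px` is set).
#' @param gates a [gate_config()].
#' @return `objects` with added columns `log_hoechst`, `log_sytox`,
#'   `class` (character, one of `live`, `etotic`, `dead`).
#' @export
classify_objects <- function(objects, gates) {
  stopifnot(inherits(gates, "gate_config"),
            all(c("hoechst_mean", "sytox_mean") %in% names(objects)))
  ls <- log10(objects$sytox_mean + gates$epsilon)
  lh <- log10(objects$hoechst_mean + gates$epsilon)
  cls <- rep("live", nrow(objects))
  et <- lh < gates$gate_hoechst
  if (!is.null(gates$min_et_area_px))
    et <- et & objects$area >= gates$min_et_area_px
  cls[et] <- "etotic"
  cls[ls > gates$gate_sytox] <- "dead"
  objects$log_hoechst <- lh
  objects$log_sytox <- ls
  objects$class <- cls
  objects
}

#' Derive default gates from an unstimulated control population
#'
#' A reproducible stand-in for manual gate placement: on the control
#' objects (dominated by live cells), the Sytox gate is set at
#' `median + 3 * scaled MAD` of log10 Sytox mean intensity and the Hoechst
#' gate at `median - 3 * scaled MAD` of log10 Hoechst mean intensity
#' (scaled MAD = 1.4826 x MAD, consistent with the SD of a normal).
#' Multiplying all raw intensities by a factor `k` shifts both gates by
#' `log10 k`, so classification is invariant to global exposure changes.
#'
#' @param control_objects data frame of objects from the control condition
#'   (>= 50 rows).
#' @param epsilon log-transform offset, as in [gate_config()].
#' @param min_et_area_px passed through to the resulting config.
#' @return a [gate_config()] with `provenance = "auto"`; `degenerate` is
#'   set when either MAD is zero.
#' @export
auto_gates <- function(control_objects, epsilon = 1e-6,
                       min_et_area_px = NULL) {
  if (nrow(control_objects) < 50L)
    stop("need >= 50 control objects to derive gates automatically; ",
         "supply manual gates via gate_config() instead")
  ls <- log10(control_objects$sytox_mean + epsilon)
  lh <- log10(control_objects$hoechst_mean + epsilon)
  mad_s <- stats::mad(ls)           # 1.4826 scaling is mad()'s default
  mad_h <- stats::mad(lh)
  g <- gate_config(gate_sytox = stats::median(ls) + 3 * mad_s,
                   gate_hoechst = stats::median(lh) - 3 * mad_h,
                   epsilon = epsilon, min_et_area_px = min_et_area_px,
                   provenance = "auto")
  g$degenerate <- (mad_s == 0 || mad_h == 0)
  g
}

#' Population percentages per group
#'
#' Tallies classified objects per group and converts the counts into
#' percentages of live, ETotic and dead cells; within every non-empty
#' group the three percentages sum to 100.
#'
#' @param classified output of [classify_objects()].
#' @param group_keys character vector of grouping columns, a subset of the
#'   metadata columns present (e.g. `c("animal", "treatment",
#'   "replicate")`).
#' @return data frame with the group columns, `n_objects`, `pct_live`,
#'   `pct_etotic`, `pct_dead`.
#' @export
population_percentages <- function(classified,
                                   group_keys = c("animal", "treatment",
                                                  "replicate")) {
  stopifnot("class" %in% names(classified),
            all(group_keys %in% names(classified)))
  if (nrow(classified) == 0L) {
    out <- classified[0, group_keys, drop = FALSE]
    out$n_objects <- integer(0)
    out$pct_live <- out$pct_etotic <- out$pct_dead <- numeric(0)
    return(out)
  }
  key <- interaction(classified[group_keys], drop = TRUE, sep = "\r")
  first <- !duplicated(key)
  out <- classified[first, group_keys, drop = FALSE]
  ord <- as.character(key[first])
  n <- tapply(rep(1L, nrow(classified)), key, sum)[ord]
  pct <- function(cl)
    as.numeric(100 * tapply(classified$class == cl, key, sum)[ord] / n)
  out$n_objects <- as.integer(n)
  out$pct_live <- pct("live")
  out$pct_etotic <- pct("etotic")
  out$pct_dead <- pct("dead")
  rownames(out) <- NULL
  out
}
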