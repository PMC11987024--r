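#' ThT plate container
#'
#' Holds the raw fluorescence traces of one plate together with the layout
#' metadata: each well has a role (`sample`, `blank`, `control_no_compound`
#' or `control_positive`) and a condition label grouping replicate wells.
#'
#' @param times Sampling times (h), strictly increasing.
#' @param wells Numeric matrix, `length(times)` rows, one column per well;
#'   column names are well identifiers.
#' @param layout Data frame with columns `well`, `role`, `condition` (and
#'   optionally `compound`, `concentration`), one row per well column.
#' @return An object of class `"tht_plate"`.
#' @export
tht_plate <- function(times, wells, layout) {
  wells <- as.matrix(wells)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (nrow(wells) != length(times))
    stop("`wells` rows (", nrow(wells), ") must match `times` (",
         length(times), ")")
  req <- c("well", "role", "condition")
  if (!all(req %in% names(layout)))
    stop("`layout` must have columns: ", paste(req, collapse = ", "))
  if (is.null(colnames(wells))) colnames(wells) <- layout$well
  if (!setequal(colnames(wells), layout$well))
    stop("well columns and layout$well do not match")
  ok_roles <- c("sample", "blank", "control_no_compound", "control_positive")
  bad <- setdiff(unique(layout$role), ok_roles)
  if (length(bad)) stop("unknown well role(s): ", paste(bad, collapse = ", "))
  if (sum(layout$role == "blank") < 1L)
    stop("plate must contain at least one blank well")
  wells <- wells[, layout$well, drop = FALSE]
  structure(list(times = as.numeric(times), wells = wells,
                 layout = as.data.frame(layout),
                 blank_subtracted = FALSE, normalized = FALSE),
            class = "tht_plate")
}

#' @export
print.tht_plate <- function(x, ...) {
  cat("ThT plate:", ncol(x$wells), "wells x", length(x$times), "time points;",
      sum(x$layout$role == "blank"), "blank(s);",
      if (x$normalized) "normalized" else if (x$blank_subtracted)
        "blank-subtracted" else "raw", "\n")
  invisible(x)
}

#' Subtract the mean blank trace
#'
#' Baselines every non-blank well by the time-pointwise mean of the plate's
#' blank wells.
#'
#' @param plate A [tht_plate()].
#' @return The plate with baselined traces (`blank_subtracted = TRUE`).
#' @export
blank_subtract <- function(plate) {
  stopifnot(inherits(plate, "tht_plate"))
  is_blank <- plate$layout$role == "blank"
  if (!any(is_blank)) stop("no blank wells on plate")
  blank_mean <- rowMeans(plate$wells[, is_blank, drop = FALSE])
  plate$wells[, !is_blank] <- plate$wells[, !is_blank, drop = FALSE] - blank_mean
  plate$blank_subtracted <- TRUE
  plate
}

#' Normalize blank-subtracted traces per condition
#'
#' Within each condition group of non-blank wells, all replicate traces are
#' divided by the maximum over time of the replicate-mean trace, so the mean
#' trace of every condition plateaus at 1. Applying the operation twice is a
#' no-op.
#'
#' @param plate A blank-subtracted [tht_plate()].
#' @return The normalized plate.
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "tht_plate"))
  if (!plate$blank_subtracted)
    stop("normalize_plate expects a blank-subtracted plate; ",
         "call blank_subtract() first")
  lay <- plate$layout
  for (cond in unique(lay$condition[lay$role != "blank"])) {
    sel <- lay$role != "blank" & lay$condition == cond
    grp <- plate$wells[, lay$well[sel], drop = FALSE]
    divisor <- max(rowMeans(grp))
    if (!is.finite(divisor) || divisor <= 0)
      stop("condition '", cond, "': nonpositive normalization maximum ",
           "(flat or failed wells)")
    plate$wells[, lay$well[sel]] <- grp / divisor
  }
  plate$normalized <- TRUE
  plate
}

#' Per-well half-times for one condition
#'
#' @param plate A normalized [tht_plate()].
#' @param condition Condition label.
#' @return Named numeric vector of half-times (h); `NA` where a well never
#'   reaches half its plateau.
#' @export
well_half_times <- function(plate, condition) {
  lay <- plate$layout
  sel <- lay$role != "blank" & lay$condition == condition
  if (!any(sel)) stop("no wells for condition '", condition, "'")
  w <- plate$wells[, lay$well[sel], drop = FALSE]
  vapply(seq_len(ncol(w)), function(j) half_time(w[, j], plate$times),
         0, USE.NAMES = FALSE) |> stats::setNames(lay$well[sel])
}

#' Activity call from half-time fold-change and a rank test
#'
#' Computes per-well half-times for a compound condition and a no-compound
#' control, the fold-change of mean half-times (compound / control) with a
#' delta-method standard error, and a two-sided Mann-Whitney U test on the
#' per-well half-times (exact when both groups have at most 8 wells, normal
#' approximation with continuity correction above). A compound is called
#' active when the fold-change is at least `fold_high` or at most
#' `fold_low` *and* the p-value is below `p_threshold`; the direction is
#' `"inhibitor"` (slower aggregation) or `"accelerator"` (faster).
#' Wells without a measurable half-time are excluded and listed in the
#' result; if either group loses all wells the result is a no-call.
#'
#' @param plate A normalized [tht_plate()].
#' @param compound Condition label of the compound wells.
#' @param control Condition label of the control wells.
#' @param fold_low,fold_high Fold-change activity thresholds (defaults 0.8
#'   and 1.25).
#' @param p_threshold Significance threshold (default 1e-4).
#' @return List of class `"activity_call"`: `compound`, `fold_change`,
#'   `fold_change_se`, `p_value`, `active`, `direction`, per-group
#'   half-times, excluded wells.
#' @export
call_activity <- function(plate, compound, control,
                          fold_low = 0.8, fold_high = 1.25,
                          p_threshold = 1e-4) {
  t_c <- well_half_times(plate, compound)
  t_0 <- well_half_times(plate, control)
  excluded <- c(names(t_c)[is.na(t_c)], names(t_0)[is.na(t_0)])
  t_c <- t_c[!is.na(t_c)]; t_0 <- t_0[!is.na(t_0)]
  if (length(t_c) == 0L || length(t_0) == 0L) {
    return(structure(list(compound = compound, fold_change = NA_real_,
                          fold_change_se = NA_real_, p_value = NA_real_,
                          active = NA, direction = "none",
                          t50_compound = t_c, t50_control = t_0,
                          excluded = excluded, status = "no_call"),
                     class = "activity_call"))
  }
  fold <- mean(t_c) / mean(t_0)
  se_c <- stats::sd(t_c) / sqrt(length(t_c))
  se_0 <- stats::sd(t_0) / sqrt(length(t_0))
  fold_se <- fold * sqrt((se_c / mean(t_c))^2 + (se_0 / mean(t_0))^2)
  exact <- length(t_c) <= 8L && length(t_0) <= 8L
  p <- suppressWarnings(
    stats::wilcox.test(t_c, t_0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  active <- (fold >= fold_high || fold <= fold_low) &&
    is.finite(p) && p < p_threshold
  direction <- if (fold >= fold_high) "inhibitor"
               else if (fold <= fold_low) "accelerator" else "none"
  structure(list(compound = compound, fold_change = fold,
                 fold_change_se = fold_se, p_value = p, active = active,
                 direction = direction, t50_compound = t_c,
                 t50_control = t_0, excluded = excluded, status = "ok"),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf("Activity call '%s': fold-change = %.3f +- %.3f, p = %.3g -> %s\n",
              x$compound, x$fold_change, x$fold_change_se, x$p_value,
              if (isTRUE(x$active)) x$direction else
                if (is.na(x$active)) "no call" else "inactive"))
  if (length(x$excluded))
    cat("  excluded wells (no half-time):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Plateau (end-point) fluorescence per condition
#'
#' Mean and standard error of the final-window normalized intensity of each
#' condition; the final window is the last `window_frac` of the time range.
#' A condition is flagged (`plateau = FALSE`) when its replicate-mean trace
#' still changes by more than `slope_tol` across the window, i.e. the
#' plateau has not been reached; its value is reported regardless.
#'
#' @param plate A normalized [tht_plate()].
#' @param window_frac Fraction of the time range used as the end window
#'   (default 0.1).
#' @param slope_tol Maximum allowed change of the mean trace across the
#'   window before the condition is flagged (default 0.05, normalized
#'   units).
#' @return Data frame: `condition`, `endpoint`, `endpoint_sem`,
#'   `n_wells`, `plateau`.
#' @export
endpoint_intensity <- function(plate, window_frac = 0.1, slope_tol = 0.05) {
  stopifnot(inherits(plate, "tht_plate"))
  lay <- plate$layout
  n <- length(plate$times)
  win <- which(plate$times >= plate$times[n] -
                 window_frac * diff(range(plate$times)))
  if (length(win) < 2L) win <- c(n - 1L, n)
  conds <- unique(lay$condition[lay$role != "blank"])
  rows <- lapply(conds, function(cond) {
    sel <- lay$role != "blank" & lay$condition == cond
    w <- plate$wells[, lay$well[sel], drop = FALSE]
    per_well <- colMeans(w[win, , drop = FALSE])
    mu <- rowMeans(w)[win]
    drift <- abs(mu[length(mu)] - mu[1L])
    data.frame(condition = cond, endpoint = mean(per_well),
               endpoint_sem = if (length(per_well) > 1L)
                 stats::sd(per_well) / sqrt(length(per_well)) else NA_real_,
               n_wells = length(per_well), plateau = drift <= slope_tol)
  })
  out <- do.call(rbind, rows)
  if (any(!out$plateau))
    warning("condition(s) without a settled plateau: ",
            paste(out$condition[!out$plateau], collapse = ", "))
  out
}
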