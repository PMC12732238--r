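#' Background-subtracted stimulation
#'
#' Net percent of reporter-positive hybridoma cells after subtracting the
#' basal activation of the negative control (e.g. empty-vector-transfected
#' presenting cells), floored at 0.
#'
#' @param sample,background Percent reporter-positive cells in `[0, 100]`
#'   (vectorized; recycled as usual).
#' @return Net stimulation in percent, `>= 0`.
#' @export
net_stimulation <- function(sample, background) {
  check_pct(sample); check_pct(background)
  pmax(sample - background, 0)
}

#' Stimulation relative to a positive control
#'
#' Background-corrected ratio, in percent of the positive control (e.g. the
#' ADAMTSL5 peptide): `100 * (sample - background) / (positive - background)`,
#' floored at 0. Values above 100 indicate stronger-than-control stimulation
#' and are reported as such.
#'
#' @param sample,background,positive Percent reporter-positive cells in
#'   `[0, 100]`.
#' @return Relative stimulation in percent of the positive control.
#' @export
relative_stimulation <- function(sample, background, positive) {
  check_pct(sample); check_pct(background); check_pct(positive)
  if (any(positive <= background))
    stop("degenerate controls: positive must exceed background", call. = FALSE)
  pmax(100 * (sample - background) / (positive - background), 0)
}

check_pct <- function(x) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 100))
    stop(deparse(substitute(x)), " must be percent values in [0, 100]",
         call. = FALSE)
  invisible(x)
}

#' Normalize a table of stimulation readings
#'
#' Aggregates technical replicates (mean and SEM per condition) and
#' normalizes against the named controls. By default means are aggregated
#' first and then normalized; `per_replicate = TRUE` normalizes each
#' replicate against the control means before aggregating.
#'
#' @param readings Data frame with columns `condition`, `replicate`,
#'   `pct_positive` and optionally `mfi`.
#' @param background Condition name of the negative control (required).
#' @param positive Optional condition name of the positive control; when
#'   given, `relative` columns are added.
#' @param per_replicate Normalize per replicate before aggregating.
#' @return Data frame per condition: `condition`, `n`, `mean_pct`, `sem_pct`,
#'   `net` (and `relative` when a positive control is named); `mean_mfi` /
#'   `sem_mfi` when MFI is present.
#' @export
normalize_readings <- function(readings, background, positive = NULL,
                               per_replicate = FALSE) {
  need <- c("condition", "replicate", "pct_positive")
  if (!all(need %in% names(readings)))
    stop("readings need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!background %in% readings$condition)
    stop("background condition not found: ", background, call. = FALSE)
  if (!is.null(positive) && !positive %in% readings$condition)
    stop("positive condition not found: ", positive, call. = FALSE)
  agg <- function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
                       n = length(x))
  sp <- split(readings, readings$condition)
  out <- do.call(rbind, lapply(names(sp), function(cond) {
    a <- agg(sp[[cond]]$pct_positive)
    row <- data.frame(condition = cond, n = as.integer(a[["n"]]),
                      mean_pct = a[["mean"]], sem_pct = a[["sem"]])
    if ("mfi" %in% names(readings) && !all(is.na(sp[[cond]]$mfi))) {
      m <- agg(sp[[cond]]$mfi)
      row$mean_mfi <- m[["mean"]]; row$sem_mfi <- m[["sem"]]
    }
    row
  }))
  bg_mean <- out$mean_pct[out$condition == background]
  pos_mean <- if (!is.null(positive)) out$mean_pct[out$condition == positive]
  if (per_replicate) {
    per <- split(readings$pct_positive, readings$condition)
    out$net <- vapply(out$condition, function(cond)
      mean(net_stimulation(per[[cond]], bg_mean)), numeric(1))
    if (!is.null(positive))
      out$relative <- vapply(out$condition, function(cond)
        mean(relative_stimulation(per[[cond]], bg_mean, pos_mean)), numeric(1))
  } else {
    out$net <- net_stimulation(out$mean_pct, bg_mean)
    if (!is.null(positive))
      out$relative <- relative_stimulation(out$mean_pct, bg_mean, pos_mean)
  }
  rownames(out) <- NULL
  out
}
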