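#' qPCR detection call for a single reaction
#'
#' A reaction counts as detected when its crossing point lies strictly below
#' the cutoff, or when it sits at least `nc_margin` cycles below the
#' template-free negative control (which rescues late but specific
#' amplification). An absent negative control simply disables the second
#' clause.
#'
#' @param cp crossing point (cycles); vectorized.
#' @param negative_control_cp negative-control crossing point (cycles) or NA.
#' @param cp_cutoff detection cutoff (default 37, strict `<`).
#' @param nc_margin required gap below the negative control (default 3,
#'   inclusive `>=`).
#' @return logical vector.
#' @examples
#' assay_detected(36, NA)        # TRUE: below cutoff
#' assay_detected(37.5, 41)      # TRUE: 3.5 cycles below negative control
#' assay_detected(37.5, 39)      # FALSE: fails both clauses
#' @export
assay_detected <- function(cp, negative_control_cp = NA_real_,
                           cp_cutoff = 37, nc_margin = 3) {
  if (anyNA(cp)) stop("'cp' must be present for every reaction")
  (cp < cp_cutoff) |
    (!is.na(negative_control_cp) & (negative_control_cp - cp >= nc_margin))
}

#' Amplification-efficiency retention rule
#'
#' Reactions amplifying below the floor are unreliable and removed; the floor
#' itself is kept ("below" is strict).
#'
#' @param efficiency per-cycle amplification factor (ideal ~2); vectorized.
#'   NA efficiencies pass (no information, no removal).
#' @param floor removal threshold (default 1.6).
#' @return logical vector: TRUE = retain.
#' @examples
#' efficiency_pass(c(1.59, 1.6, 1.9))
#' @export
efficiency_pass <- function(efficiency, floor = 1.6) {
  is.na(efficiency) | efficiency >= floor
}

#' Per-sample global-mean normalization of detected Cp values
#'
#' Normalized expression is `-dCp = mean(Cp of the sample's assays with
#' Cp < cutoff) - assay Cp`. Only reactions under the cutoff define the
#' average (reactions rescued by the negative-control clause are normalized
#' but do not contribute to the mean), so the mean of -dCp over the averaging
#' set is exactly zero.
#'
#' @param cp crossing points of one sample's retained reactions.
#' @param cp_cutoff cutoff defining the averaging set (default 37).
#' @return numeric vector of -dCp values, same length/order as `cp`.
#' @examples
#' normalize_sample(c(20, 30))   # +5, -5
#' @export
normalize_sample <- function(cp, cp_cutoff = 37) {
  in_avg <- cp < cp_cutoff
  if (!any(in_avg)) {
    stop("sample has no assay detected below the Cp cutoff; cannot normalize")
  }
  mean(cp[in_avg]) - cp
}

#' Detection-rate molecule filter
#'
#' A molecule is retained when its detected fraction exceeds `rate` (strictly)
#' in at least one of the two classes.
#'
#' @param detected logical matrix, samples x molecules (TRUE = detected).
#' @param class two-level factor over rows.
#' @param rate detection-rate threshold (default 0.8, strict `>`).
#' @return character vector of retained molecule names.
#' @export
detection_filter <- function(detected, class, rate = 0.8) {
  class <- as.factor(class)
  stopifnot(nlevels(class) == 2, nrow(detected) == length(class))
  f1 <- colMeans(detected[class == levels(class)[1], , drop = FALSE])
  f2 <- colMeans(detected[class == levels(class)[2], , drop = FALSE])
  colnames(detected)[f1 > rate | f2 > rate]
}

#' Low-expression molecule filter
#'
#' Removes molecules whose median normalized expression (over detected
#' entries) lies strictly below the given quantile of those medians. The
#' reference statistic is the per-molecule median; the quantile is
#' configurable and 0 disables the filter.
#'
#' @param values numeric matrix, samples x molecules, NA = undetected.
#' @param quantile fraction in \[0, 1) (default 0.20).
#' @return character vector of retained molecule names; the quantile cut value
#'   is attached as attribute `"cut"`.
#' @export
low_expression_filter <- function(values, quantile = 0.20) {
  med <- apply(values, 2, stats::median, na.rm = TRUE)
  cut <- stats::quantile(med, probs = quantile, na.rm = TRUE, names = FALSE)
  keep <- colnames(values)[!(med < cut)]
  attr(keep, "cut") <- cut
  keep
}

#' Preprocess a raw Cp panel into a normalized expression set
#'
#' Applies the full filtering cascade: per-reaction detection call (Cp cutoff
#' or negative-control margin), efficiency removal, per-sample global-mean
#' normalization to -dCp, the per-class detection-rate filter, and the
#' low-expression filter. Samples with no assay under the Cp cutoff are
#' dropped. Undetected entries remain missing (NA); nothing is imputed.
#'
#' @param panel long-format data.frame with columns `sample_id`, `class`,
#'   `assay_id`, `cp`, `negative_control_cp`, `efficiency` (see
#'   [read_cp_panel()]).
#' @param cp_cutoff,nc_margin detection parameters, see [assay_detected()].
#' @param efficiency_floor see [efficiency_pass()].
#' @param detection_rate see [detection_filter()].
#' @param low_expr_quantile see [low_expression_filter()]; 0 disables.
#' @param control label of the control class; it becomes the first factor
#'   level (the reference for `r1` and for AUC orientation downstream). By
#'   default a class literally named `"control"` is used if present,
#'   otherwise the first level in sort order.
#' @return an [expression_set()] with attribute `"qc"`: a list of per-filter
#'   removal counts, dropped samples/molecules and the low-expression cut.
#' @export
preprocess_panel <- function(panel, cp_cutoff = 37, nc_margin = 3,
                             efficiency_floor = 1.6, detection_rate = 0.8,
                             low_expr_quantile = 0.20, control = NULL) {
  need <- c("sample_id", "class", "assay_id", "cp")
  if (!all(need %in% names(panel))) {
    stop("panel lacks required columns: ",
         paste(setdiff(need, names(panel)), collapse = ", "))
  }
  if (is.null(panel$negative_control_cp)) panel$negative_control_cp <- NA_real_
  if (is.null(panel$efficiency)) panel$efficiency <- NA_real_
  key <- paste(panel$sample_id, panel$assay_id)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, assay_id) records: each assay is measured once per sample")
  }
  if (any(panel$cp <= 0, na.rm = TRUE)) stop("'cp' must be positive")
  if (any(panel$efficiency <= 0, na.rm = TRUE)) stop("'efficiency' must be positive")

  qc <- list(n_records = nrow(panel))
  det <- assay_detected(panel$cp, panel$negative_control_cp, cp_cutoff, nc_margin)
  qc$removed_not_detected <- sum(!det)
  eff <- efficiency_pass(panel$efficiency, efficiency_floor)
  qc$removed_low_efficiency <- sum(det & !eff)
  keep <- det & eff

  samples <- unique(panel$sample_id)
  assays <- sort(unique(panel$assay_id))
  cls <- factor(panel$class[match(samples, panel$sample_id)])
  if (is.null(control) && "control" %in% levels(cls)) control <- "control"
  if (!is.null(control)) {
    if (!control %in% levels(cls)) {
      stop("control class '", control, "' not present in the panel")
    }
    cls <- stats::relevel(cls, control)
  }

  vals <- matrix(NA_real_, length(samples), length(assays),
                 dimnames = list(samples, assays))
  dropped_samples <- character()
  for (s in samples) {
    rows <- which(keep & panel$sample_id == s)
    if (!length(rows) || !any(panel$cp[rows] < cp_cutoff)) {
      dropped_samples <- c(dropped_samples, s)
      next
    }
    vals[s, panel$assay_id[rows]] <- normalize_sample(panel$cp[rows], cp_cutoff)
  }
  if (length(dropped_samples)) {
    message("dropped sample(s) with no assay below the Cp cutoff: ",
            paste(dropped_samples, collapse = ", "))
    ok <- !(samples %in% dropped_samples)
    vals <- vals[ok, , drop = FALSE]
    cls <- cls[ok]
    samples <- samples[ok]
  }
  qc$dropped_samples <- dropped_samples

  keep_det <- detection_filter(!is.na(vals), cls, detection_rate)
  qc$removed_detection_rate <- ncol(vals) - length(keep_det)
  vals <- vals[, keep_det, drop = FALSE]

  if (low_expr_quantile > 0) {
    keep_expr <- low_expression_filter(vals, low_expr_quantile)
    qc$low_expression_cut <- attr(keep_expr, "cut")
    qc$removed_low_expression <- ncol(vals) - length(keep_expr)
    qc$removed_low_expression_molecules <-
      setdiff(colnames(vals), keep_expr)
    vals <- vals[, keep_expr, drop = FALSE]
  } else {
    qc$removed_low_expression <- 0L
  }
  qc$n_samples <- nrow(vals)
  qc$n_molecules <- ncol(vals)

  es <- expression_set(vals, cls)
  attr(es, "qc") <- qc
  es
}
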