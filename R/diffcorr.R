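#' Differential correlation analysis of a two-class expression set
#'
#' The core fit of the package. For every molecule pair it computes the
#' per-class Spearman correlations `r1` (controls) and `r2` (cases), the
#' differential score `|r1 - r2|`, the per-class normal-scores correlations,
#' and a p-value for equality of the two correlation coefficients. All
#' `m(m-1)/2` pairs are ranked by score (descending; ties broken
#' lexicographically by molecule-ID pair, so the ranking is deterministic).
#' Spearman correlations drive the ranking; the normal-scores correlations
#' drive the p-value.
#'
#' Missing (undetected) entries are handled pairwise-complete, with the
#' per-pair, per-class sample counts recorded. Pairs whose correlation is
#' undefined in either class (fewer than 3 complete observations, or a
#' constant vector) are excluded from the ranking and listed with reasons.
#'
#' @param object an [expression_set()], or a numeric samples-by-molecules
#'   matrix (then `class` is required).
#' @param class two-level factor over samples (first level = controls);
#'   ignored when `object` is an [expression_set()].
#' @param p_method `"lrt"` for the profile likelihood-ratio test (default) or
#'   `"fisher"` for the Fisher z two-sample test.
#' @param score_threshold marker-selection threshold on `|r1 - r2|` stored in
#'   the fit and used by [markers()] (default 0.8, strict `>`).
#' @return an object of class `"diffcorr"`: list with `pairs` (data.frame:
#'   `rank`, `molecule_a`, `molecule_b`, `score`, `r1`, `r2`, `rn1`, `rn2`,
#'   `n1`, `n2`, `p_value`, `log10_p`, `auc` — AUC filled by
#'   [evaluate_pairs()]), `excluded` (pairs with undefined correlations and
#'   reasons), `data`, `class`, `p_method`, `score_threshold`, `call`.
#' @seealso [markers()], [evaluate_pairs()], [search_pair_combos()]
#' @examples
#' sim <- simulate_expression(synth_config(n_molecules = 8, seed = 42))
#' fit <- diffcorr(sim$data)
#' fit
#' @export
diffcorr <- function(object, class = NULL, p_method = c("lrt", "fisher"),
                     score_threshold = 0.8) {
  p_method <- match.arg(p_method)
  if (inherits(object, "expression_set")) {
    vals <- object$values
    class <- object$class
  } else {
    if (is.null(class)) stop("'class' is required when 'object' is a matrix")
    vals <- as.matrix(object)
    if (is.null(colnames(vals))) colnames(vals) <- sprintf("mol%03d", seq_len(ncol(vals)))
    class <- droplevels(as.factor(class))
    if (nlevels(class) != 2) stop("exactly two non-empty classes required")
  }
  m <- ncol(vals)
  if (m < 2) stop("at least two molecules required")
  mols <- colnames(vals)
  ptest <- if (p_method == "lrt") lrt_equal_correlation else fisher_z_test

  g1 <- vals[class == levels(class)[1], , drop = FALSE]
  g2 <- vals[class == levels(class)[2], , drop = FALSE]

  # Fast path for complete columns: per-class rank / normal-score matrices
  # give all Spearman and normal-scores correlations in two crossproducts.
  corr_mats <- function(g) {
    n <- nrow(g)
    rk <- apply(g, 2, rank)
    z <- stats::qnorm(rk / (n + 1))
    den <- sum(stats::qnorm(seq_len(n) / (n + 1))^2)
    rn <- crossprod(z) / den
    rn[] <- pmin(1, pmax(-1, rn))   # clamp in place, keep dimensions
    list(rs = suppressWarnings(stats::cor(rk)), rn = rn, n = n)
  }
  complete1 <- !colSums(is.na(g1))
  complete2 <- !colSums(is.na(g2))
  fast <- complete1 & complete2
  c1 <- corr_mats(g1[, fast, drop = FALSE])
  c2 <- corr_mats(g2[, fast, drop = FALSE])
  fast_idx <- match(mols[fast], mols)

  ij <- which(upper.tri(diag(m)), arr.ind = TRUE)
  np <- nrow(ij)
  r1 <- r2 <- rn1 <- rn2 <- rep(NA_real_, np)
  n1 <- rep(c1$n, np); n2 <- rep(c2$n, np)
  reason <- rep(NA_character_, np)

  both_fast <- fast[ij[, 1]] & fast[ij[, 2]]
  if (any(both_fast)) {
    fi <- match(ij[both_fast, 1], fast_idx)
    fj <- match(ij[both_fast, 2], fast_idx)
    k <- cbind(fi, fj)
    r1[both_fast] <- c1$rs[k];  rn1[both_fast] <- c1$rn[k]
    r2[both_fast] <- c2$rs[k];  rn2[both_fast] <- c2$rn[k]
    # constant column in a class yields NA from cor(); mark for exclusion
    bad <- both_fast & (is.na(r1) | is.na(r2))
    reason[bad] <- "constant vector"
  }
  slow <- which(!both_fast)
  for (k in slow) {
    i <- ij[k, 1]; j <- ij[k, 2]
    lab <- paste(mols[i], mols[j], sep = " / ")
    res <- tryCatch({
      d1 <- complete_xy(g1[, i], g1[, j], lab)
      d2 <- complete_xy(g2[, i], g2[, j], lab)
      list(r1 = stats::cor(d1$x, d1$y, method = "spearman"),
           r2 = stats::cor(d2$x, d2$y, method = "spearman"),
           rn1 = normalized_rank_corr(g1[, i], g1[, j], lab),
           rn2 = normalized_rank_corr(g2[, i], g2[, j], lab),
           n1 = d1$n, n2 = d2$n)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      reason[k] <- res
    } else {
      r1[k] <- res$r1; r2[k] <- res$r2
      rn1[k] <- res$rn1; rn2[k] <- res$rn2
      n1[k] <- res$n1; n2[k] <- res$n2
    }
  }

  ok <- is.na(reason)
  pv <- rep(NA_real_, np)
  for (k in which(ok)) {
    pv[k] <- tryCatch(ptest(rn1[k], n1[k], rn2[k], n2[k]),
                      error = function(e) NA_real_)
  }
  pairs <- data.frame(
    molecule_a = mols[ij[, 1]], molecule_b = mols[ij[, 2]],
    score = abs(r1 - r2), r1 = r1, r2 = r2, rn1 = rn1, rn2 = rn2,
    n1 = n1, n2 = n2, p_value = pv, log10_p = log10(pv),
    auc = NA_real_, stringsAsFactors = FALSE)
  excluded <- data.frame(molecule_a = mols[ij[!ok, 1]],
                         molecule_b = mols[ij[!ok, 2]],
                         reason = reason[!ok], stringsAsFactors = FALSE)
  pairs <- pairs[ok, , drop = FALSE]
  ord <- order(-pairs$score, pairs$molecule_a, pairs$molecule_b)
  pairs <- pairs[ord, , drop = FALSE]
  pairs <- cbind(rank = seq_len(nrow(pairs)), pairs)
  rownames(pairs) <- NULL

  structure(list(pairs = pairs, excluded = excluded, data = vals,
                 class = class, p_method = p_method,
                 score_threshold = score_threshold, call = match.call()),
            class = "diffcorr")
}

#' Select marker pairs from a differential-correlation fit
#'
#' Pairs whose score exceeds the threshold (strictly), in ranking order.
#'
#' @param fit a [diffcorr()] object.
#' @param threshold score threshold; defaults to the fit's stored value.
#' @return the selected rows of `fit$pairs`. An empty selection is valid and
#'   raised as a warning.
#' @export
markers <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "diffcorr"))
  if (is.null(threshold)) threshold <- fit$score_threshold
  sel <- fit$pairs[fit$pairs$score > threshold, , drop = FALSE]
  if (!nrow(sel)) {
    warning(sprintf("no pair exceeds the score threshold %.3g", threshold))
  }
  sel
}

#' @export
print.diffcorr <- function(x, digits = 3, ...) {
  cat(sprintf("Differential correlation analysis (%d molecules, %d ranked pairs)\n",
              ncol(x$data), nrow(x$pairs)))
  cat(sprintf("  classes: %s (n=%d) vs %s (n=%d); p-values: %s\n",
              levels(x$class)[1], sum(x$class == levels(x$class)[1]),
              levels(x$class)[2], sum(x$class == levels(x$class)[2]),
              if (x$p_method == "lrt") "profile LRT" else "Fisher z"))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded pairs (undefined correlation): %d\n", nrow(x$excluded)))
  }
  top <- utils::head(x$pairs[, c("rank", "molecule_a", "molecule_b", "score",
                                 "r1", "r2", "log10_p")], 5)
  cat("  top pairs:\n")
  print(format(top, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.diffcorr <- function(object, threshold = NULL, ...) {
  if (is.null(threshold)) threshold <- object$score_threshold
  sel <- object$pairs[object$pairs$score > threshold, , drop = FALSE]
  out <- list(
    n_molecules = ncol(object$data), n_pairs = nrow(object$pairs),
    n_excluded = nrow(object$excluded), threshold = threshold,
    n_selected = nrow(sel), selected = sel,
    auc_mean = if (any(!is.na(sel$auc))) mean(sel$auc, na.rm = TRUE) else NA_real_,
    auc_sd = if (sum(!is.na(sel$auc)) > 1) stats::sd(sel$auc, na.rm = TRUE) else NA_real_)
  class(out) <- "summary.diffcorr"
  out
}

#' @export
print.summary.diffcorr <- function(x, digits = 3, ...) {
  cat(sprintf("%d molecules, %d ranked pairs (%d excluded)\n",
              x$n_molecules, x$n_pairs, x$n_excluded))
  cat(sprintf("markers with |r1 - r2| > %.3g: %d\n", x$threshold, x$n_selected))
  if (!is.na(x$auc_mean)) {
    cat(sprintf("marker-pair AUC: %.3f +/- %.3f\n", x$auc_mean,
                if (is.na(x$auc_sd)) 0 else x$auc_sd))
  }
  if (nrow(x$selected)) {
    print(format(x$selected[, c("rank", "molecule_a", "molecule_b", "score",
                                "log10_p", "auc", "r1", "r2")],
                 digits = digits), row.names = FALSE)
  }
  invisible(x)
}

#' Plot a differential-correlation fit
#'
#' Scatter of per-class correlations: each point is a molecule pair at
#' `(r1, r2)`; selected markers are highlighted, and the band
#' `|r1 - r2| <= threshold` is delimited by the two dashed lines.
#'
#' @param x a [diffcorr()] object.
#' @param threshold marker threshold; defaults to the fit's stored value.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.diffcorr <- function(x, threshold = NULL, ...) {
  if (is.null(threshold)) threshold <- x$score_threshold
  p <- x$pairs
  sel <- p$score > threshold
  graphics::plot(p$r1, p$r2, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = expression(r[1] ~ "(controls)"),
                 ylab = expression(r[2] ~ "(cases)"),
                 col = ifelse(sel, "firebrick", "grey60"),
                 pch = ifelse(sel, 19, 1), ...)
  graphics::abline(0, 1, col = "grey40")
  graphics::abline(threshold, 1, lty = 2)
  graphics::abline(-threshold, 1, lty = 2)
  invisible(x)
}

#' Write the ranked pair table as delimited text
#'
#' Columns: rank, molecule_a, molecule_b, score, log10_p, auc, r1, r2.
#'
#' @param fit a [diffcorr()] object.
#' @param path file path.
#' @param sep field separator.
#' @export
write_pair_table <- function(fit, path, sep = "\t") {
  stopifnot(inherits(fit, "diffcorr"))
  utils::write.table(
    fit$pairs[, c("rank", "molecule_a", "molecule_b", "score", "log10_p",
                  "auc", "r1", "r2")],
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
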