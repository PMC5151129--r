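#' ROC area under the curve by rank concordance
#'
#' The Mann-Whitney concordance: the fraction of (case, control) sample pairs
#' in which the case scores higher, ties counted one half. Invariant to
#' strictly increasing transforms of the scores; reversing the class labels
#' maps AUC to 1 - AUC.
#'
#' @param scores numeric score per sample (e.g. fitted case probability).
#' @param class two-level factor; the second level is the positive (case)
#'   class.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.3, 0.5, 0.1), factor(c("case", "case", "ctrl", "ctrl"),
#'         levels = c("ctrl", "case")))  # 0.75
#' @export
roc_auc <- function(scores, class) {
  class <- droplevels(as.factor(class))
  if (nlevels(class) != 2) {
    stop("both classes must be present to compute an AUC")
  }
  stopifnot(length(scores) == length(class))
  pos <- class == levels(class)[2]
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Design matrix of the interaction-logistic model: one main-effect column per
# distinct molecule (entered once, however many pairs share it) plus one
# product column per pair.
interaction_design <- function(vals, pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("molecule_a", "molecule_b") %in% names(pairs)))
  mols <- unique(c(rbind(pairs$molecule_a, pairs$molecule_b)))
  missing <- setdiff(mols, colnames(vals))
  if (length(missing)) {
    stop("molecules absent from the expression data: ",
         paste(missing, collapse = ", "))
  }
  X <- vals[, mols, drop = FALSE]
  inter <- mapply(function(a, b) vals[, a] * vals[, b],
                  pairs$molecule_a, pairs$molecule_b)
  inter <- matrix(inter, nrow = nrow(vals))
  colnames(inter) <- paste(pairs$molecule_a, pairs$molecule_b, sep = ":")
  cbind("(Intercept)" = 1, X, inter)
}

#' Fit the interaction logistic model for one or more molecule pairs
#'
#' Logistic regression of case status on the molecules of the given pairs:
#' each distinct molecule contributes one main effect and each pair one
#' product (interaction) term,
#' \deqn{\log\frac{p}{1-p} = \beta_0 + \sum_k \beta_k X_k +
#'       \sum_{(i,j)\in C} \beta_{ij} X_i X_j.}
#' The interaction terms are what let a correlation change (rather than a mean
#' shift) separate the classes. Complete separation is detected and flagged;
#' fitted probabilities are then clamped to `[eps, 1-eps]` for AUC purposes
#' (AUC depends only on the score ordering).
#'
#' @param object an [expression_set()] or numeric matrix (then `class` is
#'   required).
#' @param pairs data.frame with columns `molecule_a`, `molecule_b`; one row
#'   per pair in the set C.
#' @param class two-level factor (ignored for an [expression_set()]).
#' @param eps probability clamp used when the fit is separated.
#' @return list of class `"interaction_logistic"`: `coefficients`, `fitted`
#'   (clamped probabilities), `auc`, `separated`, `converged`, `pairs`,
#'   `molecules`.
#' @export
fit_interaction_logistic <- function(object, pairs, class = NULL,
                                     eps = 1e-12) {
  if (inherits(object, "expression_set")) {
    vals <- object$values
    class <- object$class
  } else {
    vals <- as.matrix(object)
    if (is.null(class)) stop("'class' is required when 'object' is a matrix")
    class <- droplevels(as.factor(class))
  }
  if (nlevels(class) != 2) stop("both classes must be represented")
  X <- interaction_design(vals, pairs)
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  y <- as.integer(class[cc] == levels(class)[2])
  if (length(unique(y)) < 2) stop("both classes must be represented after removing incomplete cases")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design (collinear columns): ",
         paste(dep, collapse = ", "),
         "; remove duplicated molecules or pairs")
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100)))
  p <- fit$fitted.values
  separated <- !fit$converged || any(p < 1e-8 | p > 1 - 1e-8)
  p <- pmin(1 - eps, pmax(eps, p))
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    fitted = p,
    auc = roc_auc(p, class[cc]),
    separated = separated,
    converged = fit$converged,
    pairs = as.data.frame(pairs)[, c("molecule_a", "molecule_b")],
    molecules = unique(c(rbind(pairs$molecule_a, pairs$molecule_b)))),
    class = "interaction_logistic")
}

#' @export
print.interaction_logistic <- function(x, digits = 3, ...) {
  cat(sprintf("Interaction logistic model: %d pair(s), AUC %.3f%s\n",
              nrow(x$pairs), x$auc,
              if (x$separated) " (separated fit)" else ""))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Evaluate marker pairs by interaction-logistic ROC/AUC
#'
#' Fits the single-pair interaction model to every selected marker pair and
#' fills the `auc` column of the fit's pair table with the in-sample AUC.
#' Per-pair fit failures are recorded, not fatal.
#'
#' @param fit a [diffcorr()] object.
#' @param threshold marker threshold; defaults to the fit's stored value. Use
#'   `threshold = -Inf` to evaluate every ranked pair.
#' @return `fit` with `pairs$auc` filled for the evaluated pairs, plus
#'   elements `auc_summary` (mean, sd, range over evaluated pairs) and
#'   `auc_failures`.
#' @export
evaluate_pairs <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "diffcorr"))
  if (is.null(threshold)) threshold <- fit$score_threshold
  idx <- which(fit$pairs$score > threshold)
  failures <- character()
  for (k in idx) {
    res <- tryCatch(
      fit_interaction_logistic(fit$data, fit$pairs[k, ], fit$class),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s/%s: %s", fit$pairs$molecule_a[k],
                                      fit$pairs$molecule_b[k], res))
    } else {
      fit$pairs$auc[k] <- res$auc
    }
  }
  aucs <- fit$pairs$auc[idx]
  fit$auc_summary <- c(mean = mean(aucs, na.rm = TRUE),
                       sd = stats::sd(aucs, na.rm = TRUE),
                       min = suppressWarnings(min(aucs, na.rm = TRUE)),
                       max = suppressWarnings(max(aucs, na.rm = TRUE)))
  fit$auc_failures <- failures
  fit
}

#' Exhaustive search over combinations of marker pairs
#'
#' Evaluates every combination of `combo_size` marker pairs with the
#' multi-interaction logistic model and ranks the combinations by in-sample
#' AUC (descending). Equal AUCs are broken by the sum of the constituent
#' pairs' original ranks, then lexicographically, so the ranking is
#' deterministic. Combinations whose fit fails are kept, ranked last, with
#' the failure message.
#'
#' @param fit a [diffcorr()] object (pass through [evaluate_pairs()] first if
#'   the per-pair AUC columns should be populated in the output).
#' @param threshold marker threshold; defaults to the fit's stored value.
#' @param combo_size number of pairs per combination (default 2).
#' @return data.frame of class `"combo_scores"`: one row per combination with
#'   `rank`, `auc`, `separated`, the constituent pairs' molecules, original
#'   ranks and original AUCs.
#' @export
search_pair_combos <- function(fit, threshold = NULL, combo_size = 2) {
  stopifnot(inherits(fit, "diffcorr"))
  mk <- markers(fit, threshold)
  k <- nrow(mk)
  if (k < combo_size) {
    stop(sprintf("need at least %d marker pairs, have %d", combo_size, k))
  }
  combos <- utils::combn(seq_len(k), combo_size)
  nc <- ncol(combos)
  auc <- rep(NA_real_, nc)
  separated <- rep(NA, nc)
  failure <- rep(NA_character_, nc)
  for (ci in seq_len(nc)) {
    rows <- mk[combos[, ci], ]
    res <- tryCatch(
      fit_interaction_logistic(fit$data, rows, fit$class),
      error = function(e) conditionMessage(e))
    if (is.character(res)) failure[ci] <- res
    else {
      auc[ci] <- res$auc
      separated[ci] <- res$separated
    }
  }
  out <- data.frame(auc = auc, separated = separated, failure = failure,
                    stringsAsFactors = FALSE)
  for (s in seq_len(combo_size)) {
    rows <- combos[s, ]
    out[[paste0("pair", s, "_molecule_a")]] <- mk$molecule_a[rows]
    out[[paste0("pair", s, "_molecule_b")]] <- mk$molecule_b[rows]
    out[[paste0("pair", s, "_rank")]] <- mk$rank[rows]
    out[[paste0("pair", s, "_auc")]] <- mk$auc[rows]
  }
  rank_sum <- colSums(matrix(mk$rank[combos], nrow = combo_size))
  lex <- do.call(paste, out[grep("_molecule_", names(out))])
  ord <- order(is.na(out$auc), -ifelse(is.na(out$auc), -Inf, out$auc),
               rank_sum, lex)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("combo_scores", "data.frame")
  out
}

#' @export
print.combo_scores <- function(x, digits = 3, n = 10, ...) {
  cat(sprintf("Pair-combination search: %d combinations\n", nrow(x)))
  print(format(utils::head(as.data.frame(x)[, setdiff(names(x), "failure")], n),
               digits = digits), row.names = FALSE)
  if (any(!is.na(x$failure))) {
    cat(sprintf("  fit failures: %d (ranked last)\n", sum(!is.na(x$failure))))
  }
  invisible(x)
}
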