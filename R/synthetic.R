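#' Configuration for the synthetic two-class expression generator
#'
#' Defines the simulated study: a control and a case cohort measured on the
#' same molecule panel, with a per-class Spearman correlation structure. The
#' defaults emulate a plasma miRNA qPCR case/control study: 30 controls vs 23
#' cases over an 85-molecule panel, with three planted differentially
#' correlated pairs (Spearman 0.8 in controls vs -0.2 in cases), two planted
#' mean-shift molecules, and independent background.
#'
#' @param n_controls,n_cases samples per class (each must be >= 3; pairwise
#'   correlations are undefined below that).
#' @param n_molecules number of molecules on the panel.
#' @param differential_pairs data.frame with columns `i`, `j` (molecule column
#'   indices), `rho1`, `rho2` (target Spearman correlation in controls and
#'   cases). Pairs must reference distinct molecules and correlations must lie
#'   in \[-1, 1\].
#' @param mean_shift_molecules data.frame with columns `molecule` (column
#'   index) and `effect` (shift of the case-class mean, in within-class SD
#'   units).
#' @param background_rho Spearman correlation of all non-planted pairs
#'   (default 0, independent background).
#' @param marginal_mean,marginal_sd marginal location/scale on the -dCp scale
#'   (cycles). The per-sample normalization downstream centres samples, so the
#'   mean is a free knob; 2 cycles is a realistic spread for a plasma panel.
#' @param seed integer seed; identical config + seed reproduces output exactly.
#' @param pd_floor eigenvalue floor used when the implied Pearson target matrix
#'   must be repaired to positive definiteness.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(n_controls = 30, n_cases = 23, n_molecules = 85,
                         differential_pairs = data.frame(
                           i = c(1L, 3L, 5L), j = c(2L, 4L, 6L),
                           rho1 = 0.8, rho2 = -0.2),
                         mean_shift_molecules = data.frame(
                           molecule = c(7L, 8L), effect = c(1.0, 1.5)),
                         background_rho = 0,
                         marginal_mean = 0, marginal_sd = 2,
                         seed = 1L, pd_floor = 1e-8) {
  if (n_controls < 3 || n_cases < 3) {
    stop("each class needs at least 3 samples; correlations are undefined below that")
  }
  # the default planted sets scale down with small panels; user-supplied
  # sets are validated strictly below
  if (missing(differential_pairs)) {
    differential_pairs <-
      differential_pairs[pmax(differential_pairs$i,
                              differential_pairs$j) <= n_molecules, ,
                         drop = FALSE]
  }
  if (missing(mean_shift_molecules)) {
    mean_shift_molecules <-
      mean_shift_molecules[mean_shift_molecules$molecule <= n_molecules, ,
                           drop = FALSE]
  }
  dp <- as.data.frame(differential_pairs)
  if (nrow(dp)) {
    stopifnot(all(c("i", "j", "rho1", "rho2") %in% names(dp)))
    if (any(dp$i == dp$j)) stop("planted pairs must reference distinct molecules")
    if (any(abs(c(dp$rho1, dp$rho2)) > 1)) stop("target Spearman correlations must lie in [-1, 1]")
    if (any(c(dp$i, dp$j) > n_molecules | c(dp$i, dp$j) < 1)) {
      stop("planted pair indices outside 1..n_molecules")
    }
  }
  ms <- as.data.frame(mean_shift_molecules)
  if (nrow(ms)) {
    stopifnot(all(c("molecule", "effect") %in% names(ms)))
    if (any(ms$molecule > n_molecules | ms$molecule < 1)) {
      stop("mean-shift molecule indices outside 1..n_molecules")
    }
  }
  if (abs(background_rho) > 1) stop("'background_rho' must lie in [-1, 1]")
  structure(list(n_controls = n_controls, n_cases = n_cases,
                 n_molecules = n_molecules, differential_pairs = dp,
                 mean_shift_molecules = ms, background_rho = background_rho,
                 marginal_mean = marginal_mean, marginal_sd = marginal_sd,
                 seed = as.integer(seed), pd_floor = pd_floor),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synth_config: %d controls / %d cases, %d molecules, seed %d\n",
              x$n_controls, x$n_cases, x$n_molecules, x$seed))
  cat(sprintf("  planted differential pairs: %d; mean-shift molecules: %d; background rho %.2f\n",
              nrow(x$differential_pairs), nrow(x$mean_shift_molecules),
              x$background_rho))
  invisible(x)
}

molecule_names <- function(m) sprintf("mol%03d", seq_len(m))

# Target Spearman matrix for one class, converted to the Pearson scale of the
# Gaussian copula and repaired to positive definiteness if needed.
class_target_pearson <- function(config, class_id) {
  m <- config$n_molecules
  S <- matrix(config$background_rho, m, m)
  diag(S) <- 1
  dp <- config$differential_pairs
  rho <- if (class_id == 1L) dp$rho1 else dp$rho2
  for (k in seq_len(nrow(dp))) {
    S[dp$i[k], dp$j[k]] <- S[dp$j[k], dp$i[k]] <- rho[k]
  }
  R <- spearman_to_pearson(S)
  diag(R) <- 1
  repair_correlation(R, floor = config$pd_floor, labels = molecule_names(m))
}

#' Draw one class block of the synthetic expression matrix
#'
#' Samples a Gaussian copula with normal marginals whose population Spearman
#' correlations match the configured per-class targets; case-class mean shifts
#' are applied to the planted molecules only.
#'
#' @param config a [synth_config()].
#' @param class_id 1 for the control class, 2 for the case class.
#' @return numeric matrix `n_class x n_molecules`. Drawn in the caller's RNG
#'   state; [simulate_expression()] handles seeding.
#' @export
generate_class_matrix <- function(config, class_id) {
  stopifnot(inherits(config, "synth_config"), class_id %in% 1:2)
  R <- class_target_pearson(config, class_id)
  n <- if (class_id == 1L) config$n_controls else config$n_cases
  m <- config$n_molecules
  L <- chol(R)
  X <- matrix(stats::rnorm(n * m), n, m) %*% L
  X <- config$marginal_mean + config$marginal_sd * X
  if (class_id == 2L) {
    ms <- config$mean_shift_molecules
    for (k in seq_len(nrow(ms))) {
      X[, ms$molecule[k]] <- X[, ms$molecule[k]] + ms$effect[k] * config$marginal_sd
    }
  }
  colnames(X) <- molecule_names(m)
  X
}

#' Simulate a two-class expression study with known ground truth
#'
#' @param config a [synth_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a list with elements `data` (an [expression_set()], controls first)
#'   and `truth` (class `"synthetic_truth"`: the planted differential pairs
#'   with molecule names and targets, the planted mean shifts, and the seed).
#' @export
simulate_expression <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  with_seed(config$seed, {
    X1 <- generate_class_matrix(config, 1L)
    X2 <- generate_class_matrix(config, 2L)
    vals <- rbind(X1, X2)
    rownames(vals) <- c(sprintf("ctrl%02d", seq_len(config$n_controls)),
                        sprintf("case%02d", seq_len(config$n_cases)))
    es <- expression_set(vals, rep(c("control", "case"),
                                   c(config$n_controls, config$n_cases)))
    es$class <- stats::relevel(es$class, "control")
    nm <- molecule_names(config$n_molecules)
    dp <- config$differential_pairs
    truth <- structure(list(
      differential_pairs = data.frame(
        molecule_a = nm[dp$i], molecule_b = nm[dp$j],
        rho1 = dp$rho1, rho2 = dp$rho2, stringsAsFactors = FALSE),
      mean_shift_molecules = data.frame(
        molecule = nm[config$mean_shift_molecules$molecule],
        effect = config$mean_shift_molecules$effect, stringsAsFactors = FALSE),
      seed = config$seed), class = "synthetic_truth")
    list(data = es, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth (seed", x$seed, ")\n")
  cat("  differential pairs:\n")
  print(x$differential_pairs, row.names = FALSE)
  cat("  mean-shift molecules:\n")
  print(x$mean_shift_molecules, row.names = FALSE)
  invisible(x)
}

#' Write the planted ground truth as a JSON sidecar
#'
#' @param truth a `"synthetic_truth"` object from [simulate_expression()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Specify quality-control artifacts to plant in a synthetic Cp panel
#'
#' @param undetected data.frame with columns `sample` and `assay` (IDs):
#'   reactions rewritten so that Cp = 39 with negative control 40 (fails both
#'   the Cp < 37 cutoff and the 3-cycle negative-control margin).
#' @param low_efficiency data.frame with columns `sample` and `assay`:
#'   reactions whose amplification efficiency is set to 1.45 (< 1.6 removal
#'   floor).
#' @return an object of class `"qc_spec"`.
#' @export
qc_spec <- function(undetected = data.frame(sample = character(),
                                            assay = character()),
                    low_efficiency = data.frame(sample = character(),
                                                assay = character())) {
  undetected <- as.data.frame(undetected, stringsAsFactors = FALSE)
  low_efficiency <- as.data.frame(low_efficiency, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "assay") %in% names(undetected)),
            all(c("sample", "assay") %in% names(low_efficiency)))
  structure(list(undetected = undetected, low_efficiency = low_efficiency),
            class = "qc_spec")
}

#' Simulate a raw qPCR Cp panel with planted QC failures
#'
#' Generates an expression study via [simulate_expression()], converts it to
#' per-reaction crossing points (`cp = cp_base - expression`, negative control
#' 40 cycles, efficiency 1.9), then rewrites the reactions named in `qc` so
#' that preprocessing removes exactly the planted artifacts. The surviving
#' reactions' -dCp values reproduce the underlying expression matrix up to the
#' per-sample normalization offset.
#'
#' @param config a [synth_config()].
#' @param qc a [qc_spec()]; defaults to a clean panel.
#' @param cp_base baseline cycles mapping expression to Cp (default 28).
#' @param seed optional integer overriding `config$seed`.
#' @return list with `panel` (long-format data.frame: `sample_id`, `class`,
#'   `assay_id`, `cp`, `negative_control_cp`, `efficiency`), `expression`
#'   (the underlying clean [expression_set()]) and `truth`.
#' @export
simulate_cp_panel <- function(config = synth_config(), qc = qc_spec(),
                              cp_base = 28, seed = NULL) {
  stopifnot(inherits(qc, "qc_spec"))
  sim <- simulate_expression(config, seed = seed)
  es <- sim$data
  n <- nrow(es$values); m <- ncol(es$values)
  panel <- data.frame(
    sample_id = rep(es$samples, times = m),
    class = rep(as.character(es$class), times = m),
    assay_id = rep(es$molecules, each = n),
    cp = cp_base - as.vector(es$values),
    negative_control_cp = 40,
    efficiency = 1.9,
    stringsAsFactors = FALSE)
  plant <- function(spec, what) {
    if (!nrow(spec)) return(invisible())
    idx <- match(paste(spec$sample, spec$assay),
                 paste(panel$sample_id, panel$assay_id))
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(sprintf("qc_spec %s refers to unknown sample/assay: %s / %s",
                   what, spec$sample[bad], spec$assay[bad]))
    }
    idx
  }
  iu <- plant(qc$undetected, "undetected")
  if (length(iu)) {
    panel$cp[iu] <- 39
    panel$negative_control_cp[iu] <- 40
  }
  ie <- plant(qc$low_efficiency, "low_efficiency")
  if (length(ie)) panel$efficiency[ie] <- 1.45
  list(panel = panel, expression = es, truth = sim$truth)
}

#' Read / write a long-format Cp panel as delimited text
#'
#' Columns: `sample_id`, `class`, `assay_id`, `cp`, `negative_control_cp`,
#' `efficiency`.
#'
#' @param panel data.frame as produced by [simulate_cp_panel()].
#' @param path file path.
#' @param sep field separator.
#' @export
write_cp_panel <- function(panel, path, sep = "\t") {
  utils::write.table(panel, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cp_panel
#' @export
read_cp_panel <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "assay_id", "cp", "negative_control_cp",
            "efficiency")
  if (!all(need %in% names(df))) {
    stop("Cp panel file lacks required columns (", paste(need, collapse = ", "),
         "): ", path)
  }
  df
}
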