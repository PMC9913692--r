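#' Deconvolution configuration
#'
#' @param nu_grid Candidate nu values for the nu-SVR fit, each in (0, 1].
#'   The fit with the lowest reconstruction RMSE (standardized scale) is
#'   kept; ties go to the smallest nu.
#' @param n_permutations Permutations for the empirical p-value (default
#'   1000). Set to 0 to skip p-value computation.
#' @param mode `"svr"` (linear nu-support-vector regression, the primary
#'   estimator) or `"nnls"` (non-negative least squares on the same
#'   standardized system; exact on noiseless mixtures and used as the
#'   cross-check).
#' @param seed Integer seed; permutation draws are derived from it and the
#'   sample identifier, so per-sample results do not depend on sample order.
#' @param standardize Z-score the mixture and each signature column before
#'   fitting (the CIBERSORT-family convention; the estimated coefficients
#'   are mapped back to the linear scale afterwards). Inputs themselves are
#'   used on the linear scale: no library-size normalization and no log
#'   transform are applied.
#' @param correlation `"reconstruction"` (Pearson r between mixture and its
#'   reconstruction, the default) or `"centroid"` (r between the mixture and
#'   the mean z-scored signature profile).
#' @param min_overlap Minimum fraction of signature genes that must be
#'   present in a bulk matrix for its samples to be deconvolved.
#' @param svm_cost Cost parameter of the nu-SVR.
#' @return A `deconv_config` list.
#' @export
deconv_config <- function(nu_grid = c(0.25, 0.5, 0.75), n_permutations = 1000L,
                          mode = c("svr", "nnls"), seed = 1L,
                          standardize = TRUE,
                          correlation = c("reconstruction", "centroid"),
                          min_overlap = 0.5, svm_cost = 1) {
  mode <- match.arg(mode)
  correlation <- match.arg(correlation)
  if (!length(nu_grid) || any(nu_grid <= 0 | nu_grid > 1)) {
    stop("nu_grid values must lie in (0, 1]")
  }
  if (n_permutations < 0) stop("n_permutations must be >= 0")
  structure(list(nu_grid = sort(nu_grid), n_permutations = as.integer(n_permutations),
                 mode = mode, seed = as.integer(seed),
                 standardize = standardize, correlation = correlation,
                 min_overlap = min_overlap, svm_cost = svm_cost),
            class = "deconv_config")
}

# Restrict mixture and signature to their common genes and z-score the
# system. Returns NULL sy for a zero-variance (degenerate) mixture.
standardize_system <- function(mixture, signature, standardize = TRUE) {
  genes <- intersect(rownames(signature), names(mixture))
  if (length(genes) < 2L * ncol(signature)) {
    stop("only ", length(genes), " signature genes present in mixture; need >= ",
         2L * ncol(signature))
  }
  y <- mixture[genes]
  X <- signature[genes, , drop = FALSE]
  if (!standardize) {
    return(list(ys = y, Xs = X, sy = 1, sj = rep(1, ncol(X)), genes = genes,
                degenerate = stats::sd(y) == 0))
  }
  sy <- stats::sd(y)
  sj <- apply(X, 2L, stats::sd)
  if (any(sj == 0)) {
    stop("signature column(s) with zero variance over common genes: ",
         paste(colnames(X)[sj == 0], collapse = ", "))
  }
  list(ys = if (sy > 0) (y - mean(y)) / sy else y * 0,
       Xs = scale(X), sy = sy, sj = sj, genes = genes, degenerate = sy == 0)
}

# Single fit on an already-standardized system; returns the standardized-
# scale coefficient vector with negatives truncated to zero.
fit_standardized <- function(ys, Xs, mode, nu = NULL, svm_cost = 1) {
  if (mode == "nnls") {
    beta <- pracma::lsqnonneg(Xs, as.vector(ys))$x
  } else {
    fit <- e1071::svm(Xs, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = svm_cost, scale = FALSE)
    beta <- as.vector(t(fit$coefs) %*% fit$SV)
    beta[beta < 0] <- 0
  }
  beta
}

#' Estimate cell-type coefficients for one bulk sample
#'
#' Fits the mixture against the signature columns. In `svr` mode a linear
#' nu-support-vector regression is fitted for every nu on the grid and the
#' fit with the smallest standardized reconstruction RMSE is kept (ties to
#' the smallest nu); negative coefficients are truncated to zero. In `nnls`
#' mode a non-negative least squares solves the same standardized system.
#' Coefficients are returned on the linear scale of the inputs.
#'
#' @param mixture Named expression vector (linear scale) covering at least
#'   twice as many signature genes as there are cell types.
#' @param signature Signature matrix (genes x cell types).
#' @param config A [deconv_config()].
#' @return List with `coefficients` (named, non-negative, original scale),
#'   `chosen_nu` (`NA` in nnls mode), `degenerate` flag.
#' @export
fit_coefficients <- function(mixture, signature, config = deconv_config()) {
  sys <- standardize_system(mixture, signature, config$standardize)
  k <- ncol(signature)
  if (sys$degenerate) {
    return(list(coefficients = stats::setNames(rep(0, k), colnames(signature)),
                chosen_nu = NA_real_, degenerate = TRUE))
  }
  if (config$mode == "nnls") {
    beta <- fit_standardized(sys$ys, sys$Xs, "nnls")
    chosen_nu <- NA_real_
  } else {
    best <- NULL
    for (nu in config$nu_grid) {
      b <- fit_standardized(sys$ys, sys$Xs, "svr", nu = nu,
                            svm_cost = config$svm_cost)
      rmse <- sqrt(mean((sys$ys - sys$Xs %*% b)^2))
      if (is.null(best) || rmse < best$rmse - 1e-12) {
        best <- list(beta = b, rmse = rmse, nu = nu)
      }
    }
    beta <- best$beta
    chosen_nu <- best$nu
  }
  w <- beta * sys$sy / sys$sj
  list(coefficients = stats::setNames(as.vector(w), colnames(signature)),
       chosen_nu = chosen_nu, degenerate = FALSE)
}

#' Reconstruction error and correlation of a deconvolution
#'
#' Both metrics are computed over the signature genes on the standardized
#' scale used for fitting: the linear-scale coefficients are mapped back to
#' that scale and the reconstruction is the standardized signature times
#' those coefficients. `rmse` is the root-mean-square residual; `pearson_r`
#' is by default the Pearson correlation between mixture and reconstruction
#' (`correlation = "centroid"` instead correlates the mixture with the mean
#' z-scored signature profile).
#'
#' @param mixture Named expression vector (linear scale).
#' @param signature Signature matrix.
#' @param coefficients Named coefficient vector from [fit_coefficients()].
#' @param standardize,correlation See [deconv_config()].
#' @return List with `rmse`, `pearson_r` and `degenerate` flag (constant
#'   reconstruction; `pearson_r` recorded as 0 with a warning).
#' @export
reconstruction_metrics <- function(mixture, signature, coefficients,
                                   standardize = TRUE,
                                   correlation = c("reconstruction", "centroid")) {
  correlation <- match.arg(correlation)
  sys <- standardize_system(mixture, signature, standardize)
  beta <- coefficients[colnames(signature)] * sys$sj / sys$sy
  recon <- as.vector(sys$Xs %*% beta)
  rmse <- sqrt(mean((sys$ys - recon)^2))
  ref <- if (correlation == "centroid") rowMeans(sys$Xs) else recon
  degenerate <- stats::sd(ref) == 0 || stats::sd(sys$ys) == 0
  if (degenerate) {
    warning("constant reconstruction or mixture; pearson_r recorded as 0")
    r <- 0
  } else {
    r <- stats::cor(sys$ys, ref)
  }
  list(rmse = rmse, pearson_r = r, degenerate = degenerate)
}

#' Permutation empirical p-value of a deconvolution
#'
#' Forms `n_permutations` pseudo-mixtures by drawing, with replacement, as
#' many values from the sample's full expression profile as there are
#' signature genes, refits each against the signature, and records its
#' reconstruction correlation. The p-value uses the add-one estimator
#' p = (1 + #\{permuted r >= observed r\}) / (1 + n_permutations), avoiding
#' exact zeros. In `svr` mode permutations are refitted at the nu chosen for
#' the observed mixture.
#'
#' @param mixture_full Full expression vector of the sample (all genes, not
#'   just signature genes); must be at least as long as the signature.
#' @param signature Signature matrix.
#' @param observed_r Observed reconstruction correlation.
#' @param config A [deconv_config()].
#' @param chosen_nu nu at which svr permutations are refitted (defaults to
#'   the middle of the grid when not supplied).
#' @param seed Seed for the permutation draws (defaults to `config$seed`).
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p_value <- function(mixture_full, signature, observed_r,
                              config = deconv_config(), chosen_nu = NULL,
                              seed = NULL) {
  n_genes <- nrow(signature)
  if (length(mixture_full) < n_genes) {
    stop("full profile (", length(mixture_full),
         " genes) shorter than the signature (", n_genes, ")")
  }
  if (config$n_permutations < 1L) return(NA_real_)
  if (is.null(seed)) seed <- config$seed
  if (is.null(chosen_nu) || is.na(chosen_nu)) {
    chosen_nu <- config$nu_grid[ceiling(length(config$nu_grid) / 2)]
  }
  pool <- as.vector(mixture_full)
  Xs0 <- if (config$standardize) scale(signature) else signature
  centroid <- rowMeans(Xs0)
  perm_r <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(config$n_permutations), function(i) {
      y <- sample(pool, n_genes, replace = TRUE)
      sy <- stats::sd(y)
      # a pseudo-mixture that reconstructs nothing scores the worst possible r
      if (sy == 0) return(-1)
      ys <- if (config$standardize) (y - mean(y)) / sy else y
      beta <- fit_standardized(ys, Xs0, config$mode, nu = chosen_nu,
                               svm_cost = config$svm_cost)
      ref <- if (config$correlation == "centroid") centroid else
        as.vector(Xs0 %*% beta)
      if (stats::sd(ref) == 0) return(-1)
      stats::cor(ys, ref)
    }, numeric(1))
  })
  (1 + sum(perm_r >= observed_r)) / (1 + config$n_permutations)
}

# Deterministic per-sample seed so results are independent of sample order.
sample_seed <- function(base_seed, sample_id) {
  v <- utf8ToInt(sample_id)
  h <- sum(v * seq_along(v)) %% 1000003L
  as.integer((abs(base_seed) * 7919L + h * 31L) %% 2147483647L)
}

#' Deconvolve a bulk cohort against a signature
#'
#' Per sample: coefficient fit, reconstruction metrics, permutation
#' empirical p-value, relative proportions (all coefficients divided by
#' their sum), then aggregation under the cell-type model. A sample with a
#' constant expression profile (or an all-zero coefficient vector) is
#' flagged `degenerate` and does not affect the others; results are returned
#' in input sample order and each sample's permutation stream is derived
#' from its identifier, so reordering the cohort only reorders the rows.
#'
#' @param bulk Genes x samples expression matrix (linear-scale TPM).
#' @param signature Signature matrix whose columns cover the model's base
#'   types.
#' @param model A [cell_type_model()].
#' @param config A [deconv_config()].
#' @return data.frame, one row per sample: `sample_id`, `status`,
#'   `chosen_nu`, `rmse`, `pearson_r`, `p_value`, base-type relative
#'   proportions (`prop_*`) and model-type proportions (`model_*`).
#' @export
deconvolve_cohort <- function(bulk, signature, model = cell_type_model("mixed"),
                              config = deconv_config()) {
  stopifnot(inherits(model, "cell_type_model"))
  miss <- setdiff(model$base_types, colnames(signature))
  if (length(miss)) stop("signature lacks base type(s): ", paste(miss, collapse = ", "))
  signature <- signature[, model$base_types, drop = FALSE]
  common <- intersect(rownames(bulk), rownames(signature))
  overlap <- length(common) / nrow(signature)
  message(sprintf("%d/%d signature genes present in bulk (%.0f%%)",
                  length(common), nrow(signature), 100 * overlap))
  base <- model$base_types
  mt <- model$model_types
  rows <- lapply(colnames(bulk), function(s) {
    row <- data.frame(sample_id = s, status = "ok", chosen_nu = NA_real_,
                      rmse = NA_real_, pearson_r = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    props <- stats::setNames(rep(NA_real_, length(base)), base)
    mprops <- stats::setNames(rep(NA_real_, length(mt)), mt)
    if (overlap < config$min_overlap) {
      row$status <- "failed"
    } else {
      y <- bulk[, s]
      fit <- tryCatch(fit_coefficients(y, signature, config),
                      error = function(e) NULL)
      if (is.null(fit)) {
        row$status <- "failed"
      } else if (fit$degenerate || sum(fit$coefficients) == 0) {
        row$status <- "degenerate"
      } else {
        met <- reconstruction_metrics(y, signature, fit$coefficients,
                                      standardize = config$standardize,
                                      correlation = config$correlation)
        row$chosen_nu <- fit$chosen_nu
        row$rmse <- met$rmse
        row$pearson_r <- met$pearson_r
        row$p_value <- empirical_p_value(y, signature, met$pearson_r, config,
                                         chosen_nu = fit$chosen_nu,
                                         seed = sample_seed(config$seed, s))
        props[base] <- fit$coefficients[base] / sum(fit$coefficients)
        mprops[mt] <- aggregate_proportions(props, model)
      }
    }
    names(props) <- paste0("prop_", base)
    names(mprops) <- paste0("model_", mt)
    cbind(row, as.data.frame(as.list(props)), as.data.frame(as.list(mprops)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the deconvolution feature matrix for classification
#'
#' Fixed feature order: the model-type proportions in the model's declared
#' order, then the empirical p-value, reconstruction RMSE and correlation r.
#' For the mixed model this is exactly eight features per sample (alpha,
#' beta, gamma, delta, exocrine_like, p_value, rmse, pearson_r); the
#' endocrine-only model yields seven. None of them is informed by
#' proliferation.
#'
#' @param results data.frame from [deconvolve_cohort()].
#' @param model The [cell_type_model()] the results were computed under.
#' @return Numeric matrix, one row per sample (rownames = sample_id); rows
#'   of failed/degenerate samples are `NA`.
#' @export
extract_features <- function(results, model) {
  stopifnot(inherits(model, "cell_type_model"))
  prop_cols <- paste0("model_", model$model_types)
  miss <- setdiff(prop_cols, colnames(results))
  if (length(miss)) stop("results lack model type column(s): ",
                         paste(miss, collapse = ", "))
  feat <- as.matrix(results[, c(prop_cols, "p_value", "rmse", "pearson_r")])
  colnames(feat) <- c(model$model_types, "p_value", "rmse", "pearson_r")
  rownames(feat) <- results$sample_id
  feat
}
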