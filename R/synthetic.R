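#' Configuration for a synthetic single-cell reference
#'
#' Describes the reference the generator emulates: a set of pancreatic cell
#' types, each with a block of planted marker genes expressed
#' `marker_fold_change` times above baseline in its own type. Counts are
#' negative-binomial with a common dispersion (variance = mu + dispersion *
#' mu^2), the standard overdispersed model for expression counts.
#'
#' @param n_genes Total number of genes.
#' @param cell_types data.frame with columns `name`, `n_cells`,
#'   `n_marker_genes`, `marker_fold_change`.
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param library_scale Multiplier on all baseline means (> 0).
#' @param seed Integer seed; all outputs are reproducible under it.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_genes, cell_types, nb_dispersion = 0.3,
                              library_scale = 1, seed = 1L) {
  stopifnot(is.data.frame(cell_types),
            all(c("name", "n_cells", "n_marker_genes", "marker_fold_change")
                %in% colnames(cell_types)))
  if (anyDuplicated(cell_types$name)) stop("duplicate cell type names")
  if (any(cell_types$n_cells < 2L)) stop("every cell type needs >= 2 cells")
  if (any(cell_types$marker_fold_change < 1)) stop("marker_fold_change must be >= 1")
  if (sum(cell_types$n_marker_genes) > n_genes) {
    stop("total planted marker genes (", sum(cell_types$n_marker_genes),
         ") exceed n_genes (", n_genes, ")")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (library_scale <= 0) stop("library_scale must be > 0")
  structure(list(n_genes = as.integer(n_genes), cell_types = cell_types,
                 nb_dispersion = nb_dispersion, library_scale = library_scale,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default reference configuration: six pancreatic cell types
#'
#' Four endocrine types (alpha, beta, gamma, delta) and two exocrine types
#' (acinar, ductal), 50 cells and 50 planted markers each at fold change 8,
#' 2000 genes. These are the conditions the package's recovery experiments
#' are run under.
#'
#' @param seed Integer seed.
#' @param n_cells Cells per type.
#' @param n_markers Planted markers per type.
#' @param fold_change Marker fold change over baseline.
#' @param n_genes Total genes.
#' @export
default_reference_config <- function(seed = 1L, n_cells = 50L, n_markers = 50L,
                                     fold_change = 8, n_genes = 2000L) {
  types <- c("alpha", "beta", "gamma", "delta", "acinar", "ductal")
  simulation_config(
    n_genes = n_genes,
    cell_types = data.frame(name = types, n_cells = n_cells,
                            n_marker_genes = n_markers,
                            marker_fold_change = fold_change,
                            stringsAsFactors = FALSE),
    seed = seed)
}

#' Simulate a single-cell reference with planted marker genes
#'
#' Per-gene baseline means are drawn from a Gamma distribution; a planted
#' marker of a cell type has its mean multiplied by the type's fold change
#' in cells of that type only. Counts are negative-binomial. Marker blocks
#' of different types are disjoint by construction.
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (genes x cells), `annotation` (cell_id,
#'   cell_type) and `markers` (named list, planted marker genes per type).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ct <- config$cell_types
  withr::with_seed(config$seed, {
    gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
    baseline <- stats::rgamma(config$n_genes, shape = 2, scale = 5) *
      config$library_scale
    # disjoint marker blocks, assigned in declaration order
    markers <- list()
    offset <- 0L
    for (i in seq_len(nrow(ct))) {
      idx <- offset + seq_len(ct$n_marker_genes[i])
      markers[[ct$name[i]]] <- gene_ids[idx]
      offset <- offset + ct$n_marker_genes[i]
    }
    size <- 1 / config$nb_dispersion
    cols <- list()
    cell_ids <- character(0)
    cell_types <- character(0)
    for (i in seq_len(nrow(ct))) {
      mu <- baseline
      midx <- match(markers[[ct$name[i]]], gene_ids)
      mu[midx] <- mu[midx] * ct$marker_fold_change[i]
      n <- ct$n_cells[i]
      block <- matrix(stats::rnbinom(config$n_genes * n, mu = mu, size = size),
                      nrow = config$n_genes, ncol = n)
      cols[[i]] <- block
      cell_ids <- c(cell_ids, sprintf("%s_c%03d", ct$name[i], seq_len(n)))
      cell_types <- c(cell_types, rep(ct$name[i], n))
    }
    mat <- do.call(cbind, cols)
    dimnames(mat) <- list(gene_ids, cell_ids)
  })
  ann <- data.frame(cell_id = cell_ids, cell_type = cell_types,
                    stringsAsFactors = FALSE)
  list(matrix = mat, annotation = ann, markers = markers)
}

#' Per-cell-type mean expression profiles
#'
#' Arithmetic mean of each gene over the cells of each type, on the linear
#' scale. The column space of this matrix is where noiseless bulk mixtures
#' live.
#'
#' @param reference Genes x cells matrix, or the list from
#'   [simulate_reference()].
#' @param annotation Cell annotation data.frame (ignored when `reference` is
#'   the simulation list).
#' @return Genes x cell-types matrix.
#' @export
cell_type_profiles <- function(reference, annotation = NULL) {
  if (is.list(reference) && !is.null(reference$matrix)) {
    annotation <- reference$annotation
    reference <- reference$matrix
  }
  stopifnot(!is.null(annotation))
  types <- unique(annotation$cell_type)
  prof <- vapply(types, function(t) {
    rowMeans(reference[, annotation$cell_id[annotation$cell_type == t],
                       drop = FALSE])
  }, numeric(nrow(reference)))
  rownames(prof) <- rownames(reference)
  prof
}

#' Simulate bulk mixtures with known cell-type proportions
#'
#' Each sample's expected profile is the proportion-weighted sum of the
#' cell-type profiles (columns of `profiles`); with `noise = "none"` the
#' sample equals that expectation exactly, so it lies exactly in the
#' profiles' column space. With `noise = "nb"` each value is replaced by a
#' negative-binomial draw around the expectation.
#'
#' @param profiles Genes x cell-types matrix: per-type mean profiles from
#'   [cell_type_profiles()], or a signature matrix to mix signature columns
#'   directly.
#' @param n_samples Number of mixtures.
#' @param proportions Either `"dirichlet"` (draw from Dirichlet(`alpha`)) or
#'   a numeric matrix/vector of fixed proportions (rows = samples, columns
#'   matching `colnames(profiles)`); vectors are recycled across samples.
#' @param alpha Dirichlet concentration, scalar or per-type vector.
#' @param noise `"none"` or `"nb"`.
#' @param nb_dispersion Dispersion for `noise = "nb"`.
#' @param library_size If non-`NULL`, each sample column is rescaled to this
#'   total ("TPM-like"); relative proportions are invariant under this
#'   per-sample scalar.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples) and `truth` (data.frame of
#'   true proportions, one row per sample).
#' @export
simulate_bulk_mixtures <- function(profiles, n_samples,
                                   proportions = "dirichlet", alpha = 1,
                                   noise = c("none", "nb"),
                                   nb_dispersion = 0.3, library_size = NULL,
                                   seed = 1L) {
  noise <- match.arg(noise)
  types <- colnames(profiles)
  if (is.null(types)) stop("profiles must have cell-type colnames")
  withr::with_seed(as.integer(seed), {
    if (is.character(proportions) && identical(proportions, "dirichlet")) {
      a <- if (length(alpha) == 1L) rep(alpha, length(types)) else alpha
      stopifnot(length(a) == length(types))
      P <- t(vapply(seq_len(n_samples), function(i) {
        g <- stats::rgamma(length(types), shape = a)
        g / sum(g)
      }, numeric(length(types))))
    } else {
      P <- proportions
      if (is.vector(P)) P <- matrix(P, nrow = n_samples, ncol = length(P),
                                    byrow = TRUE)
      P <- as.matrix(P)
      if (ncol(P) != length(types)) stop("proportion vectors must cover all cell types")
      if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
        stop("proportion vectors must be non-negative and sum to 1")
      }
    }
    colnames(P) <- types
    M <- profiles %*% t(P)
    if (noise == "nb") {
      M[] <- stats::rnbinom(length(M), mu = as.vector(M),
                            size = 1 / nb_dispersion)
    }
    if (!is.null(library_size)) {
      cs <- colSums(M)
      cs[cs == 0] <- 1
      M <- sweep(M, 2L, library_size / cs, "*")
    }
  })
  sample_ids <- sprintf("mix%04d", seq_len(n_samples))
  colnames(M) <- sample_ids
  truth <- data.frame(sample_id = sample_ids, P, check.names = FALSE,
                      stringsAsFactors = FALSE)
  list(matrix = M, truth = truth)
}

#' Simulate a clinical cohort with grade-linked exocrine-like fractions
#'
#' Emulates the structure the deconvolution framework assumes in tumor
#' cohorts: the true exocrine-like (acinar + ductal) fraction is drawn from
#' a grade-specific Beta distribution whose mean increases from G1 to G3;
#' the remaining mass is split over the four endocrine types by a Dirichlet
#' draw; a configurable fraction of G3 samples are carcinomas (NEC) and
#' receive an additive shift on their exocrine-like fraction; survival times
#' are exponential with a per-grade hazard, censored by an independent
#' exponential calibrated to the requested censoring rate.
#'
#' @param n_per_grade Named vector, samples per grade, e.g.
#'   `c(G1 = 100, G2 = 100, G3 = 100)`.
#' @param exocrine_beta Named list, per grade `c(shape1, shape2)` of the Beta
#'   distribution of the true exocrine-like fraction. Defaults have means
#'   0.2 / 0.3 / 0.6 at concentration 30.
#' @param hazard_by_grade Named vector of exponential hazards (events per
#'   month).
#' @param censoring_rate Expected fraction of censored samples in (0, 1);
#'   0 disables censoring.
#' @param nec_fraction Probability that a G3 sample is a NEC.
#' @param nec_exocrine_shift Additive shift on the exocrine-like fraction of
#'   NEC samples (truncated to stay below 0.95).
#' @param endocrine_alpha Dirichlet concentration over alpha/beta/gamma/delta
#'   for the endocrine remainder.
#' @param profiles Genes x cell-types profile matrix; default builds one
#'   from [default_reference_config()] with the same seed. Column names must
#'   include acinar, ductal and the endocrine types.
#' @param noise,nb_dispersion Passed to the mixture step.
#' @param seed Integer seed.
#' @return List with `matrix` (bulk genes x samples), `cohort` (clinical
#'   table: sample_id, grading, status, survival_time, event, study_id) and
#'   `truth` (true base-type proportions).
#' @export
simulate_cohort <- function(n_per_grade = c(G1 = 100L, G2 = 100L, G3 = 100L),
                            exocrine_beta = list(G1 = c(6, 24),
                                                 G2 = c(9, 21),
                                                 G3 = c(18, 12)),
                            hazard_by_grade = c(G1 = 0.008, G2 = 0.02,
                                                G3 = 0.08),
                            censoring_rate = 0.3,
                            nec_fraction = 0.35,
                            nec_exocrine_shift = 0.15,
                            endocrine_alpha = c(alpha = 4, beta = 4,
                                                gamma = 2, delta = 2),
                            profiles = NULL,
                            noise = c("nb", "none"), nb_dispersion = 0.3,
                            seed = 1L) {
  noise <- match.arg(noise)
  grades <- names(n_per_grade)
  if (!all(grades %in% c("G1", "G2", "G3"))) stop("grades must be G1/G2/G3")
  if (any(hazard_by_grade <= 0)) stop("hazards must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1) stop("censoring_rate must be in [0, 1)")
  seed <- as.integer(seed)
  if (is.null(profiles)) {
    profiles <- cell_type_profiles(simulate_reference(default_reference_config(seed = seed)))
  }
  types <- colnames(profiles)
  endo <- names(endocrine_alpha)
  if (!all(c("acinar", "ductal", endo) %in% types)) {
    stop("profiles must cover acinar, ductal and the endocrine types")
  }
  n_total <- sum(n_per_grade)
  withr::with_seed(seed, {
    grading <- rep(grades, times = n_per_grade)
    status <- rep(NA_character_, n_total)
    is_g3 <- grading == "G3"
    status[is_g3] <- ifelse(stats::runif(sum(is_g3)) < nec_fraction, "NEC", "NET")
    status[!is_g3] <- "NET"
    exo <- numeric(n_total)
    for (g in grades) {
      sel <- grading == g
      ab <- exocrine_beta[[g]]
      exo[sel] <- stats::rbeta(sum(sel), ab[1L], ab[2L])
    }
    exo[status %in% "NEC"] <- pmin(exo[status %in% "NEC"] + nec_exocrine_shift, 0.95)
    # endocrine remainder over the four islet types
    endo_w <- t(vapply(seq_len(n_total), function(i) {
      g <- stats::rgamma(length(endo), shape = endocrine_alpha)
      g / sum(g)
    }, numeric(length(endo))))
    P <- matrix(0, n_total, length(types), dimnames = list(NULL, types))
    # split exocrine-like mass 50/50 acinar/ductal
    P[, "acinar"] <- exo / 2
    P[, "ductal"] <- exo / 2
    P[, endo] <- endo_w * (1 - exo)
    # survival: exponential event time, independent exponential censoring
    hz <- hazard_by_grade[grading]
    t_event <- stats::rexp(n_total, rate = hz)
    if (censoring_rate > 0) {
      c_rate <- hz * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(n_total, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n_total)
    }
    survival_time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    mix_seed <- (seed + 104729L) %% .Machine$integer.max
  })
  mix <- simulate_bulk_mixtures(profiles, n_samples = n_total,
                                proportions = P, noise = noise,
                                nb_dispersion = nb_dispersion,
                                seed = mix_seed)
  sample_ids <- sprintf("s%04d", seq_len(n_total))
  colnames(mix$matrix) <- sample_ids
  cohort <- data.frame(sample_id = sample_ids, grading = grading,
                       status = status,
                       survival_time = survival_time, event = event,
                       study_id = "synthetic", stringsAsFactors = FALSE)
  truth <- mix$truth
  truth$sample_id <- sample_ids
  list(matrix = mix$matrix, cohort = cohort, truth = truth)
}
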