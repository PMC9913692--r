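#' Select cell-type marker genes from a single-cell reference
#'
#' One-vs-rest differential expression per cell type: a Welch two-sample
#' t-test per gene on log2(x + 1) values, Benjamini-Hochberg adjustment
#' across genes within each contrast, then genes with positive effect
#' (higher in the type) and adjusted p below `alpha`, truncated to the top
#' `n_per_type` by log2 fold change. The test statistic is a plain location
#' test; at the effect sizes signature genes show, any reasonable
#' alternative (e.g. a moderated linear-model test) selects essentially the
#' same genes, and the implementation is deliberately swappable.
#'
#' @param reference Genes x cells matrix.
#' @param annotation Cell annotation data.frame (`cell_id`, `cell_type`).
#' @param n_per_type Maximum markers kept per type (default 800).
#' @param alpha BH-adjusted significance threshold.
#' @return Named list (one element per cell type) of data.frames with
#'   columns `gene_id`, `effect_size` (log2 fold change), `p_adjusted`,
#'   sorted by descending effect size.
#' @export
select_marker_genes <- function(reference, annotation, n_per_type = 800L,
                                alpha = 0.05) {
  types <- unique(annotation$cell_type)
  if (length(types) < 2L) stop("marker selection needs >= 2 cell types")
  counts <- table(annotation$cell_type)
  if (any(counts < 2L)) {
    stop("cell type(s) with fewer than 2 cells: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  reference <- reference[, annotation$cell_id, drop = FALSE]
  logx <- log2(reference + 1)
  out <- list()
  for (t in types) {
    in_t <- annotation$cell_type == t
    res <- welch_one_vs_rest(logx, in_t)
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    keep <- res$effect_size > 0 & res$p_adjusted < alpha & !is.na(res$p_adjusted)
    sel <- res[keep, , drop = FALSE]
    sel <- sel[order(-sel$effect_size, sel$gene_id), , drop = FALSE]
    if (nrow(sel) > n_per_type) {
      sel <- sel[seq_len(n_per_type), , drop = FALSE]
    } else if (nrow(sel) < n_per_type) {
      message("cell type '", t, "': only ", nrow(sel),
              " marker gene(s) pass the filter (requested ", n_per_type, ")")
    }
    if (nrow(sel) == 0L) {
      warning("cell type '", t, "': no marker genes pass the filter")
    }
    rownames(sel) <- NULL
    out[[t]] <- sel[, c("gene_id", "effect_size", "p_adjusted")]
  }
  out
}

# Vectorized Welch t: group = logical over columns; returns per-gene effect
# (mean log2 difference), t statistic and two-sided p.
welch_one_vs_rest <- function(logx, in_group) {
  nA <- sum(in_group); nB <- sum(!in_group)
  A <- logx[, in_group, drop = FALSE]
  B <- logx[, !in_group, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1L)
  vB <- rowSums((B - mB)^2) / (nB - 1L)
  se2 <- vA / nA + vB / nB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  # zero variance in both groups: no evidence either way
  p[se2 == 0] <- 1
  data.frame(gene_id = rownames(logx), effect_size = mA - mB,
             t_statistic = tstat, p_value = p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build a signature matrix from selected markers
#'
#' Rows are the union of all selected marker genes (a gene selected for
#' several types appears once); entry (g, t) is the arithmetic mean linear-
#' scale expression of gene g over the reference cells of type t. Testing
#' happens on the log scale but the signature is linear because the
#' deconvolution operates on linear TPM values.
#'
#' @param reference Genes x cells matrix.
#' @param annotation Cell annotation data.frame.
#' @param markers Marker list from [select_marker_genes()].
#' @return Genes x cell-types signature matrix.
#' @export
build_signature_matrix <- function(reference, annotation, markers) {
  empty <- names(markers)[vapply(markers, nrow, integer(1)) == 0L]
  if (length(empty)) {
    stop("no marker genes for cell type(s): ", paste(empty, collapse = ", "))
  }
  genes <- unique(unlist(lapply(markers, `[[`, "gene_id"), use.names = FALSE))
  missing <- setdiff(genes, rownames(reference))
  if (length(missing)) stop("marker gene(s) absent from reference: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  prof <- cell_type_profiles(reference[genes, , drop = FALSE], annotation)
  prof <- prof[, names(markers), drop = FALSE]
  zero <- rowSums(prof) == 0
  if (any(zero)) prof <- prof[!zero, , drop = FALSE]
  prof
}

#' Define a cell-type model with aggregation
#'
#' A cell-type model names the base types the deconvolution estimates and an
#' aggregation map combining some of them into derived types. The
#' `endocrine_only` model uses the four islet types; `mixed` adds the two
#' exocrine types and aggregates them into a single artificial
#' `exocrine_like` type (sum of acinar and ductal proportions).
#'
#' @param name `"endocrine_only"`, `"mixed"`, or `"custom"`.
#' @param base_types For `custom`: character vector of base cell types.
#' @param aggregation For `custom`: named list mapping each derived type to
#'   the (disjoint) set of base types it sums over.
#' @return A `cell_type_model` list with `name`, `base_types`, `aggregation`
#'   and `model_types` (reporting order: derived types replace their
#'   sources, in base-type order).
#' @export
cell_type_model <- function(name = c("mixed", "endocrine_only", "custom"),
                            base_types = NULL, aggregation = NULL) {
  name <- match.arg(name)
  if (name == "endocrine_only") {
    base_types <- c("alpha", "beta", "gamma", "delta")
    aggregation <- list()
  } else if (name == "mixed") {
    base_types <- c("alpha", "beta", "gamma", "delta", "acinar", "ductal")
    aggregation <- list(exocrine_like = c("acinar", "ductal"))
  } else {
    stopifnot(is.character(base_types), length(base_types) >= 1L)
    if (is.null(aggregation)) aggregation <- list()
  }
  src <- unlist(aggregation, use.names = FALSE)
  if (anyDuplicated(src)) stop("aggregation sources must be disjoint")
  if (!all(src %in% base_types)) stop("aggregation sources must be base types")
  # reporting order: base order, each aggregated block replaced by its
  # derived type at the position of its first source
  model_types <- character(0)
  for (b in base_types) {
    hit <- names(aggregation)[vapply(aggregation, function(s) b %in% s, logical(1))]
    if (length(hit)) {
      if (!hit %in% model_types) model_types <- c(model_types, hit)
    } else {
      model_types <- c(model_types, b)
    }
  }
  structure(list(name = name, base_types = base_types,
                 aggregation = aggregation, model_types = model_types),
            class = "cell_type_model")
}

#' Aggregate base-type proportions under a cell-type model
#'
#' Derived types are sums of their source proportions; un-aggregated base
#' types pass through unchanged. Total mass is preserved exactly.
#'
#' @param proportions Named numeric vector over the model's base types.
#' @param model A [cell_type_model()].
#' @return Named numeric vector over the model types.
#' @export
aggregate_proportions <- function(proportions, model) {
  stopifnot(inherits(model, "cell_type_model"))
  miss <- setdiff(model$base_types, names(proportions))
  if (length(miss)) stop("missing base type(s): ", paste(miss, collapse = ", "))
  out <- stats::setNames(numeric(length(model$model_types)), model$model_types)
  for (mt in model$model_types) {
    src <- if (mt %in% names(model$aggregation)) model$aggregation[[mt]] else mt
    out[mt] <- sum(proportions[src])
  }
  out
}

#' Fraction of signature genes overlapping a probe gene set
#'
#' QC check on a signature: e.g. the fraction of its marker genes that are
#' proliferation-annotated, or differentially expressed between tissue
#' sites. Defined as |signature genes intersect probe set| / |signature genes|.
#'
#' @param markers Marker list from [select_marker_genes()], a character
#'   vector of genes, or a signature matrix (rownames used).
#' @param probe_set Character vector of probe genes.
#' @return Fraction in \[0, 1\].
#' @export
gene_set_overlap_fraction <- function(markers, probe_set) {
  genes <- if (is.list(markers) && !is.null(markers[[1L]]$gene_id)) {
    unique(unlist(lapply(markers, `[[`, "gene_id"), use.names = FALSE))
  } else if (is.matrix(markers)) {
    rownames(markers)
  } else {
    unique(as.character(markers))
  }
  if (!length(genes)) stop("empty signature gene set")
  if (!length(probe_set)) stop("empty probe gene set")
  length(intersect(genes, probe_set)) / length(genes)
}
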