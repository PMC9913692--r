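# Shared fixtures, built once per test run. The reference uses the default
# study conditions: 6 pancreatic cell types, 50 cells and 50 planted markers
# per type at fold change 8, 2000 genes.
ref_fixture <- simulate_reference(default_reference_config(seed = 1L))
markers_fixture <- select_marker_genes(ref_fixture$matrix, ref_fixture$annotation,
                                       n_per_type = 50L)
signature_fixture <- build_signature_matrix(ref_fixture$matrix,
                                            ref_fixture$annotation,
                                            markers_fixture)
profiles_fixture <- cell_type_profiles(ref_fixture)
mixed_model <- cell_type_model("mixed")

# Hand-rolled product-limit estimator, independent of the survival package;
# the oracle for Kaplan-Meier checks.
km_oracle <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, survival = surv)
}

# Per-type mean oracle for the signature matrix: naive loops.
signature_oracle <- function(reference, annotation, genes) {
  types <- unique(annotation$cell_type)
  out <- matrix(NA_real_, length(genes), length(types),
                dimnames = list(genes, types))
  for (g in genes) {
    for (t in types) {
      cells <- annotation$cell_id[annotation$cell_type == t]
      out[g, t] <- mean(reference[g, cells])
    }
  }
  out
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
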