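# The planted benchmark: 3 clusters x 6 diseases, p_within 0.8,
# p_background 0.01, 5000 reports. Mining uses the fractional support alias
# (1% of reports) because an absolute count calibrated to a multi-million
# report corpus has no meaning at this scale; see the methods vignette.

benchmark_spec <- function(seed = 20260901L, n_reports = 5000L) {
  synthetic_spec(
    n_reports = n_reports,
    clusters = list(paste0("dis_a", 1:6), paste0("dis_b", 1:6),
                    paste0("dis_c", 1:6)),
    p_within = 0.8,
    p_background = 0.01,
    rng_seed = seed,
    genes_per_cluster = 3L,
    drugs_per_cluster = 3L
  )
}

benchmark_params <- function() {
  mining_params(min_confidence = 0.5, min_support_fraction = 0.01)
}

planted_labels <- function(spec) {
  stats::setNames(rep(seq_along(spec$clusters), lengths(spec$clusters)),
                  unlist(spec$clusters, use.names = FALSE))
}

# Cached single run of the benchmark pipeline shared across test files.
benchmark_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- benchmark_spec()
      db <- generate_transactions(spec)
      pipe <- comorbidity_pipeline(db, benchmark_params(),
                                   node_category = spec$category_of,
                                   min_report_size = 5L)
      cache <<- c(list(spec = spec, db = db,
                       maps = generate_annotations(spec),
                       reference = generate_reference_comorbidities(spec)),
                  pipe)
    }
    cache
  }
})
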