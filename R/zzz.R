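#' @keywords internal
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  register_context_backend("jaccard", jaccard_scorer)
  register_context_backend("constant0", function(a, b) 0)
  register_context_backend("constant1", function(a, b) 1)
  register_reranker("idf_overlap", idf_overlap_scorer)
  register_accuracy_backend("heuristic", function(context, evidence,
                                                  instance_id = NULL) {
    heuristic_backend(context, evidence)
  })
  invisible()
}
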